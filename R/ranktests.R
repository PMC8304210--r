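# Friedman rank test across matched measurements and the Nemenyi post-hoc
# critical distance for comparing several models.

#' Friedman rank test over matched measurements
#'
#' Ranks the k models within each of N matched measurements (mid-ranks for
#' ties; higher measurement = better = rank 1 when \code{decreasing}), then
#' computes the chi-square statistic
#' 12N / (k(k+1)) * sum_j (Rbar_j - (k+1)/2)^2 with k - 1 degrees of freedom
#' and its upper-tail p value. For small tables an exact permutation p value
#' (over all within-measurement orderings) is available.
#'
#' @param measurements k x N numeric matrix: rows = models, columns = matched
#'   measurements.
#' @param decreasing rank larger values as better (default TRUE).
#' @param exact compute the exact permutation p value (only for
#'   k! ^ N <= 1e6); default FALSE (chi-square approximation).
#' @return List with \code{statistic}, \code{pValue}, \code{averageRanks},
#'   \code{k}, \code{n} and \code{method}.
#' @examples
#' m <- rbind(modelA = c(3, 2, 4), modelB = c(2, 1, 2), modelC = c(1, 0.5, 1))
#' friedmanRankTest(m)
#' @export
friedmanRankTest <- function(measurements, decreasing = TRUE, exact = FALSE) {
  m <- as.matrix(measurements)
  k <- nrow(m); n <- ncol(m)
  if (k < 2L) stop("at least two models are required")
  if (n < 2L) stop("at least two matched measurements are required")
  ranks <- apply(m, 2, function(col) rank(if (decreasing) -col else col))
  avg <- rowMeans(ranks)
  stat <- .friedmanStat(avg, k, n)
  p <- if (exact) {
    .friedmanExactP(m, decreasing, stat)
  } else {
    pchisq(stat, df = k - 1, lower.tail = FALSE)
  }
  list(statistic = stat, pValue = p, averageRanks = avg, k = k, n = n,
       method = if (exact) "exact permutation" else "chi-square approximation")
}

.friedmanStat <- function(avgRanks, k, n) {
  12 * n / (k * (k + 1)) * sum((avgRanks - (k + 1) / 2)^2)
}

# exact p over independent within-column rank permutations
.friedmanExactP <- function(m, decreasing, statObs) {
  k <- nrow(m); n <- ncol(m)
  nPerm <- factorial(k)^n
  if (nPerm > 1e6)
    stop("exact permutation p value limited to factorial(k)^N <= 1e6")
  perms <- .permutations(k)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), n)))
  count <- 0L
  baseRanks <- seq_len(k)
  for (g in seq_len(nrow(grid))) {
    rk <- vapply(seq_len(n), function(j) perms[grid[g, j], ], numeric(k))
    stat <- .friedmanStat(rowMeans(rk), k, n)
    if (stat >= statObs - 1e-12) count <- count + 1L
  }
  count / nrow(grid)
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Nemenyi post-hoc critical distance
#'
#' CD = q_alpha(k) * sqrt(k (k + 1) / (6 N)), where q_alpha(k) is the
#' studentized-range critical value at infinite degrees of freedom divided by
#' sqrt(2) (computed from \code{qtukey}; e.g. q_{0.05}(4) = 2.569). Two models
#' whose average ranks differ by more than CD perform significantly
#' differently.
#'
#' @param k number of compared models (2..10).
#' @param n number of matched measurements.
#' @param alpha significance level, 0.05 or 0.10.
#' @return Critical distance (numeric scalar).
#' @examples
#' nemenyiCD(k = 4, n = 6)  # 1.915
#' @export
nemenyiCD <- function(k, n, alpha = 0.05) {
  if (k < 2 || k > 10) stop("k must be between 2 and 10 (tabulated range)")
  if (!isTRUE(all.equal(alpha, 0.05)) && !isTRUE(all.equal(alpha, 0.10)))
    stop("alpha must be 0.05 or 0.10")
  if (n < 1) stop("n must be >= 1")
  q <- qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  q * sqrt(k * (k + 1) / (6 * n))
}
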