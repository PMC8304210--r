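# Shared fixtures and independent oracles for the test suite.

# session cache so expensive artifacts (trained models, datasets) are built
# once and reused across test files
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# small architecture for fast mechanical tests
tinyConfig <- function(...) {
  compactNetConfig(blockChannels = c(16L, 32L), blockStrides = c(1L, 1L),
                   seRatio = 4L, fc0Width = 64L, inputSize = 32L, ...)
}

randomImage <- function(h, w, seed = 1) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}

# The confusion matrix of the clinical test set as printed (rows = true class,
# order basophil, eosinophil, lymphocyte, monocyte, promyelocyte, neutrophil).
clinicalConfusion <- function() {
  matrix(c(190, 0, 0, 0, 0, 0,
           1, 210, 1, 0, 0, 0,
           0, 0, 191, 2, 2, 0,
           0, 0, 1, 180, 1, 0,
           0, 0, 0, 1, 125, 0,
           0, 0, 0, 2, 0, 454),
         nrow = 6, byrow = TRUE,
         dimnames = list(LEUKOCYTE_CLASSES, LEUKOCYTE_CLASSES))
}

# published class sizes of the clinical dataset
clinicalClassSizes <- c(953, 1063, 976, 912, 628, 2282)

# brute-force 8-connected flood fill labeling (independent of the C++ path)
floodFillLabels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(queue) > 0L) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ni <- cur[1] + di; nj <- cur[2] + dj
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# boxes from a label matrix by direct enumeration
bruteForceBoxes <- function(mask, minArea = 1L) {
  lab <- floodFillLabels(mask)
  if (max(lab) == 0L)
    return(data.frame(x0 = integer(), y0 = integer(), width = integer(),
                      height = integer(), area_px = integer()))
  rows <- lapply(seq_len(max(lab)), function(l) {
    ij <- which(lab == l, arr.ind = TRUE)
    if (nrow(ij) < minArea) return(NULL)
    data.frame(x0 = min(ij[, 2]) - 1L, y0 = min(ij[, 1]) - 1L,
               width = diff(range(ij[, 2])) + 1L,
               height = diff(range(ij[, 1])) + 1L,
               area_px = nrow(ij))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$y0, out$x0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Mann-Whitney pair-counting AUC (independent of the sweep implementation)
pairCountAuc <- function(scores, pos) {
  ps <- scores[pos]; ns <- scores[!pos]
  tot <- 0
  for (a in ps) for (b in ns)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ps) * length(ns))
}

# per-sample one-vs-rest metric tally (independent of the matrix formulas)
bruteForceMetrics <- function(yTrue, yPred, classes) {
  res <- lapply(classes, function(cl) {
    tp <- sum(yTrue == cl & yPred == cl)
    fp <- sum(yTrue != cl & yPred == cl)
    fn <- sum(yTrue == cl & yPred != cl)
    tn <- sum(yTrue != cl & yPred != cl)
    data.frame(class = cl, TP = tp, FP = fp, TN = tn, FN = fn,
               TPR = tp / (tp + fn), TNR = tn / (tn + fp),
               precision = tp / (tp + fp))
  })
  do.call(rbind, res)
}

# mean color / texture nearest-centroid classifier (separability baseline)
colorFeatures <- function(x) {
  n <- dim(x)[4]
  t(vapply(seq_len(n), function(i) {
    img <- x[, , , i]
    perChan <- vapply(1:3, function(c) {
      ch <- img[, , c]
      grad <- mean(abs(diff(ch)))          # vertical texture energy
      c(mean(ch), sd(ch), grad, mean(ch < 180))
    }, numeric(4))
    as.vector(perChan)
  }, numeric(12)))
}

nearestCentroidAccuracy <- function(x, y, seed = 1) {
  feats <- scale(colorFeatures(x))
  set.seed(seed)
  test <- sample(seq_along(y), length(y) %/% 4)
  train <- setdiff(seq_along(y), test)
  cents <- vapply(levels(y), function(cl) {
    colMeans(feats[train[y[train] == cl], , drop = FALSE])
  }, numeric(ncol(feats)))
  pred <- levels(y)[apply(feats[test, , drop = FALSE], 1, function(f) {
    which.min(colSums((cents - f)^2))
  })]
  mean(pred == as.character(y[test]))
}
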