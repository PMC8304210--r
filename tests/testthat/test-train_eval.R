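# Cross-validation protocol, augmentation, optimizer mechanics and training
# at reduced scale.

test_that("stratified folds partition every class within one sample", {
  labels <- rep(LEUKOCYTE_CLASSES[1:5], each = 5)
  fs <- stratifiedKFold(labels, k = 5, seed = 1)
  tab <- table(fs$foldOfSample, labels)
  expect_true(all(tab == 1))   # 5 classes x 5 samples: one per fold

  # published clinical class sizes stratify within +-1 of size/5
  labels <- rep(LEUKOCYTE_CLASSES, clinicalClassSizes)
  fs <- stratifiedKFold(labels, k = 5, seed = 2)
  expect_equal(sort(unique(fs$foldOfSample)), 1:5)
  tab <- table(fs$foldOfSample, labels)
  for (cl in LEUKOCYTE_CLASSES) {
    expect_lte(diff(range(tab[, cl])), 1)
    expect_true(all(abs(tab[, cl] - sum(tab[, cl]) / 5) <= 1))
  }
  # partition: disjoint and exhaustive by construction of foldOfSample
  expect_equal(length(fs$foldOfSample), length(labels))
  expect_false(anyNA(fs$foldOfSample))

  # five rounds use five pairwise-different test folds, and roles never overlap
  rr <- fs$roundRoles
  expect_equal(sort(rr$testFold), 1:5)
  expect_equal(anyDuplicated(rr$testFold), 0L)
  for (r in 1:5) {
    train <- as.integer(strsplit(rr$trainFolds[r], ",")[[1]])
    expect_equal(sort(c(train, rr$testFold[r], rr$valFold[r])), 1:5)
  }

  # deterministic given the seed
  fs2 <- stratifiedKFold(labels, k = 5, seed = 2)
  expect_identical(fs$foldOfSample, fs2$foldOfSample)

  expect_error(stratifiedKFold(c(rep("basophil", 3), rep("monocyte", 9)),
                               k = 5), "basophil")
})

test_that("minority oversampling balances to the majority frequency", {
  set.seed(1)
  labels <- rep(c("a", "b", "c"), each = 4)
  idx <- oversampleMinority(labels)
  expect_equal(sort(idx), 1:12)   # balanced input: a permutation

  labels <- c(rep("a", 10), rep("b", 5))
  idx <- oversampleMinority(labels)
  expect_equal(length(idx), 20)
  expect_equal(as.integer(table(labels[idx])), c(10L, 10L))

  labels <- c(rep("a", 7), "b")
  idx <- oversampleMinority(labels)
  expect_equal(sum(labels[idx] == "b"), 7)
  expect_true(all(idx[labels[idx] == "b"] == 8))
})

test_that("augmentation preserves shape, is involutive and reproducible", {
  a <- array(sample(0:255, 16 * 16 * 3, TRUE), c(16, 16, 3))
  expect_identical(augmentCrop(a, FALSE, FALSE, 0), a)
  r180 <- augmentCrop(a, FALSE, FALSE, 180)
  expect_identical(augmentCrop(r180, FALSE, FALSE, 180), a)
  expect_identical(augmentCrop(augmentCrop(a, TRUE, FALSE, 0), TRUE, FALSE, 0), a)
  r90 <- augmentCrop(a, FALSE, FALSE, 90)
  expect_identical(dim(r90), dim(a))
  expect_identical(augmentCrop(r90, FALSE, FALSE, 270), a)

  set.seed(9)
  s1 <- replicate(5, augmentCrop(a), simplify = FALSE)
  set.seed(9)
  s2 <- replicate(5, augmentCrop(a), simplify = FALSE)
  expect_identical(s1, s2)
})

test_that("learning-rate schedule divides by 5 every 10 epochs", {
  tc <- trainConfig()
  expect_equal(learningRateAt(tc, c(0, 9, 10, 19, 20)),
               c(5e-3, 5e-3, 1e-3, 1e-3, 2e-4))
})

test_that("the SGD momentum update matches hand arithmetic", {
  # quadratic f(w) = w^2 at w = 1: grad = 2
  s1 <- sgdStep(w = 1, v = 0, grad = 2, lr = 0.1, momentum = 0.9)
  expect_equal(s1, c(0.8, 2))            # v' = 0.9*0 + 2; w' = 1 - 0.1*2
  # second step at w = 0.8: grad = 1.6
  s2 <- sgdStep(s1[1], s1[2], grad = 1.6, lr = 0.1, momentum = 0.9)
  expect_equal(s2[2], 0.9 * 2 + 1.6, tolerance = 1e-6)
  expect_equal(s2[1], 0.8 - 0.1 * (0.9 * 2 + 1.6), tolerance = 1e-6)
})

test_that("confusion matrix counts true-by-predicted pairs", {
  y <- rep(LEUKOCYTE_CLASSES, 3)
  expect_equal(confusionMatrix6(y, y), diag(3L, 6) + 0L,
               ignore_attr = TRUE)

  set.seed(3)
  yT <- sample(LEUKOCYTE_CLASSES, 100, TRUE)
  yP <- sample(LEUKOCYTE_CLASSES, 100, TRUE)
  cm <- confusionMatrix6(yT, yP)
  for (i in 1:6) for (j in 1:6)
    expect_equal(cm[i, j],
                 sum(yT == LEUKOCYTE_CLASSES[i] & yP == LEUKOCYTE_CLASSES[j]))
  expect_equal(sum(cm), 100)
  expect_error(confusionMatrix6(c(yT, "blast"), c(yP, "blast")), "blast")

  cmPub <- clinicalConfusion()
  expect_equal(sum(cmPub), 1361)
  expect_equal(sum(cmPub) - sum(diag(cmPub)), 11)
  # the shipped copy matches the independent restatement above
  expect_equal(unname(clinicalConfusionMatrix()), unname(cmPub))
})

test_that("matrix metrics agree with a per-sample brute-force tally", {
  ident <- diag(5L, 6)
  dimnames(ident) <- list(LEUKOCYTE_CLASSES, LEUKOCYTE_CLASSES)
  m <- metricsFromConfusion(ident)
  expect_equal(unname(m$weighted[c("TPR", "TNR", "precision", "fbeta")]),
               rep(1, 4))
  expect_equal(unname(m$weighted[c("FPR", "FNR")]), c(0, 0))

  set.seed(7)
  for (rep in 1:200) {
    n <- sample(20:60, 1)
    yT <- sample(LEUKOCYTE_CLASSES, n, TRUE)
    yP <- sample(LEUKOCYTE_CLASSES, n, TRUE)
    cm <- confusionMatrix6(yT, yP)
    got <- suppressWarnings(metricsFromConfusion(cm))
    want <- bruteForceMetrics(yT, yP, LEUKOCYTE_CLASSES)
    expect_equal(got$perClass$TP, want$TP)
    expect_equal(got$perClass$FP, want$FP)
    expect_equal(got$perClass$TN, want$TN)
    expect_equal(got$perClass$FN, want$FN)
    expect_equal(got$perClass$TPR, want$TPR)
    expect_equal(got$perClass$TNR, want$TNR)
    expect_equal(got$perClass$precision, want$precision)
    # complementarity and the weighted-TPR identity
    ok <- is.finite(got$perClass$TPR)
    expect_equal(got$perClass$TPR[ok] + got$perClass$FNR[ok], rep(1, sum(ok)))
    expect_equal(got$perClass$TNR + got$perClass$FPR, rep(1, 6))
    expect_equal(unname(got$weighted["TPR"]), sum(diag(cm)) / sum(cm))
  }
})

test_that("ROC AUC matches the rank-counting oracle", {
  # perfectly separated scores
  s <- matrix(0, 6, 2); s[1:3, 1] <- 0.9; s[4:6, 2] <- 0.9
  colnames(s) <- c("a", "b")
  r <- rocAuc(s, rep(c("a", "b"), each = 3), classes = c("a", "b"))
  expect_equal(unname(r$perClass), c(1, 1))
  expect_equal(r$weighted, 1)

  # 4-point toy against explicit Mann-Whitney pair counting
  s <- cbind(c(0.9, 0.4, 0.6, 0.2), c(0.1, 0.6, 0.4, 0.8))
  colnames(s) <- c("a", "b")
  y <- c("a", "b", "a", "b")
  r <- rocAuc(s, y, classes = c("a", "b"))
  expect_equal(unname(r$perClass["a"]), pairCountAuc(s[, 1], y == "a"))
  expect_equal(unname(r$perClass["b"]), pairCountAuc(s[, 2], y == "b"))

  # oracle agreement with ties, plus label-independent scores give ~0.5
  set.seed(11)
  for (i in 1:20) {
    n <- 30
    sc <- matrix(round(runif(2 * n), 1), n, 2)
    yy <- sample(c("a", "b"), n, TRUE)
    r <- rocAuc(sc, yy, classes = c("a", "b"))
    expect_equal(unname(r$perClass["a"]), pairCountAuc(sc[, 1], yy == "a"))
  }
  set.seed(12)
  n <- 4000
  sc <- matrix(runif(2 * n), n, 2)
  yy <- sample(c("a", "b"), n, TRUE)
  r <- rocAuc(sc, yy, classes = c("a", "b"))
  expect_lt(abs(r$perClass["a"] - 0.5), 0.05)

  # absent class is NaN
  r <- rocAuc(sc, rep("a", n), classes = c("a", "b"))
  expect_true(is.nan(r$perClass["b"]))
})

test_that("ROC AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(13)
  n <- 200
  sc <- matrix(runif(2 * n), n, 2)
  yy <- sample(c("a", "b"), n, TRUE, prob = c(0.3, 0.7))
  r <- rocAuc(sc, yy, classes = c("a", "b"))
  ref <- as.numeric(pROC::auc(pROC::roc(yy == "a", sc[, 1], quiet = TRUE,
                                        direction = "<")))
  expect_equal(unname(r$perClass["a"]), ref, tolerance = 1e-10)
})

test_that("Friedman rank test follows the textbook statistic", {
  ident <- matrix(1, 3, 4)
  r <- friedmanRankTest(ident)
  expect_equal(r$statistic, 0)
  expect_equal(r$pValue, 1)
  expect_equal(unname(r$averageRanks), rep(2, 3))

  # 3 models x 3 measurements, hand-ranked
  m <- rbind(A = c(3, 5, 4), B = c(2, 3, 2), C = c(1, 1, 1))
  r <- friedmanRankTest(m)
  avg <- rowMeans(apply(m, 2, function(col) rank(-col)))
  expect_equal(unname(r$averageRanks), unname(avg))
  k <- 3; n <- 3
  expect_equal(r$statistic,
               12 * n / (k * (k + 1)) * sum((avg - (k + 1) / 2)^2))
  expect_equal(r$pValue, pchisq(r$statistic, k - 1, lower.tail = FALSE))

  # rank conservation per measurement, with ties
  set.seed(14)
  mm <- matrix(sample(1:3, 4 * 5, TRUE), 4, 5)
  ranks <- apply(mm, 2, function(col) rank(-col))
  expect_equal(unname(colSums(ranks)), rep(4 * 5 / 2, 5))

  expect_error(friedmanRankTest(matrix(1, 3, 1)), "two")
  expect_error(friedmanRankTest(matrix(1, 1, 3)), "two")
})

test_that("Friedman chi-square approximation matches stats::friedman.test", {
  set.seed(15)
  m <- matrix(rnorm(4 * 8), 4, 8)   # continuous: no ties
  r <- friedmanRankTest(m)
  ref <- stats::friedman.test(t(m))
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$pValue, unname(ref$p.value))
})

test_that("exact permutation p agrees with the null for identical models", {
  m <- matrix(5, 3, 2)
  r <- friedmanRankTest(m, exact = TRUE)
  expect_equal(r$pValue, 1)
  # a strongly separated table: only the 6 column-wise identical orderings
  # reach the maximal statistic, so p = 6 / 6^3
  m <- rbind(c(3, 3, 3), c(2, 2, 2), c(1, 1, 1))
  r <- friedmanRankTest(m, exact = TRUE)
  expect_equal(r$pValue, 6 / 6^3, tolerance = 1e-9)
})

test_that("the Nemenyi critical distance uses studentized-range constants", {
  expect_equal(round(nemenyiCD(k = 4, n = 6), 3), 1.915)
  expect_equal(nemenyiCD(k = 2, n = 1),
               qtukey(0.95, 2, Inf) / sqrt(2), tolerance = 1e-9)
  expect_equal(round(nemenyiCD(k = 2, n = 1), 3), 1.96, tolerance = 1e-3)
  cds <- vapply(1:20, function(n) nemenyiCD(4, n), numeric(1))
  expect_true(all(diff(cds) < 0))   # strictly decreasing in N
  expect_error(nemenyiCD(k = 12, n = 5), "between")
  expect_error(nemenyiCD(k = 4, n = 5, alpha = 0.2), "alpha")
})

test_that("training at reduced scale learns and logs the schedule", {
  ds <- cached("tiny32", generateCellDataset(nPerClass = 18, seed = 21,
                                             imageSize = 32L))
  set.seed(22)
  val <- unlist(lapply(levels(ds$y), function(cl) {
    idx <- which(ds$y == cl); sample(idx, 4)
  }))
  tr <- setdiff(seq_along(ds$y), val)
  tc <- trainConfig(epochs = 10L, batchSize = 8L, seed = 5L)
  fit <- trainModel(tinyConfig(), tc,
                    train = list(x = ds$x[, , , tr, drop = FALSE],
                                 y = ds$y[tr]),
                    val = list(x = ds$x[, , , val, drop = FALSE],
                               y = ds$y[val]))
  expect_equal(nrow(fit$log), 10L)
  expect_equal(fit$log$lr, rep(5e-3, 10))
  expect_true(all(is.finite(fit$log$trainLoss)))
  # the synthetic classes are separable even at this scale
  expect_gt(fit$bestValAcc, 0.5)
  # best checkpoint restored: reported accuracy is reproducible
  acc <- mean(predictClasses(fit$model,
                             ds$x[, , , val, drop = FALSE]) == ds$y[val])
  expect_equal(acc, fit$bestValAcc)
})

test_that("the reduced-scale 5-fold protocol emits the reporting format", {
  ds <- cached("tiny32", generateCellDataset(nPerClass = 18, seed = 21,
                                             imageSize = 32L))
  # a 2-epoch run can leave classes unpredicted; the undefined-metric
  # warnings are part of the contract
  cv <- suppressWarnings(
    crossValidate(ds$x, ds$y, tinyConfig(),
                  trainConfig(epochs = 2L, batchSize = 16L, seed = 6L),
                  k = 5L))
  expect_length(cv$confusions, 5L)
  for (cm in cv$confusions) {
    expect_equal(dim(cm), c(6L, 6L))
    # one test fold: ~108/5 samples, each class within +-1 of 18/5
    expect_gte(sum(cm), 18L)
    expect_lte(sum(cm), 24L)
  }
  # the five test folds cover the dataset exactly once
  expect_equal(Reduce(`+`, lapply(cv$confusions, sum)), length(ds$y))
  expect_named(cv$summary, c("metric", "mean", "sd"))
  expect_true(all(c("TPR", "TNR", "fbeta") %in% cv$summary$metric))
})
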