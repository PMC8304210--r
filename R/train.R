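# Training protocol: stratified k-fold splits, imbalance-aware oversampling,
# flip/rotation augmentation, and from-scratch SGD training of the compact
# classifier.

#' TrainConfig: training hyperparameters
#'
#' Defaults follow the published recipe: SGD with momentum 0.9, initial
#' learning rate 5e-3 divided by 5 every 10 epochs, dropout 0.5. Epoch count
#' (30) and batch size (32) are this package's defaults and are recorded in
#' the run log.
#'
#' @slot optimizer character, only \code{"sgd"}.
#' @slot momentum numeric momentum coefficient.
#' @slot initialLr numeric initial learning rate.
#' @slot lrDecayFactor learning-rate divisor.
#' @slot lrDecayEvery epochs between divisions.
#' @slot epochs maximum number of epochs.
#' @slot batchSize minibatch size.
#' @slot seed integer seed for all training randomness.
#'
#' @export
setClass("TrainConfig",
  representation(optimizer = "character", momentum = "numeric",
                 initialLr = "numeric", lrDecayFactor = "numeric",
                 lrDecayEvery = "integer", epochs = "integer",
                 batchSize = "integer", seed = "integer"),
  validity = function(object) {
    if (object@optimizer != "sgd") return("only the sgd optimizer is supported")
    if (object@initialLr <= 0) return("initialLr must be positive")
    if (object@epochs < 1L || object@batchSize < 1L)
      return("epochs and batchSize must be >= 1")
    TRUE
  })

#' Create a TrainConfig
#'
#' @param momentum SGD momentum (default 0.9).
#' @param initialLr initial learning rate (default 5e-3).
#' @param lrDecayFactor divide the rate by this factor (default 5).
#' @param lrDecayEvery every this many epochs (default 10).
#' @param epochs maximum epochs (default 30).
#' @param batchSize minibatch size (default 32).
#' @param seed RNG seed (default 1).
#' @return A \linkS4class{TrainConfig}.
#' @examples
#' tc <- trainConfig(epochs = 5L)
#' learningRateAt(tc, 0:11)
#' @export
trainConfig <- function(momentum = 0.9, initialLr = 5e-3, lrDecayFactor = 5,
                        lrDecayEvery = 10L, epochs = 30L, batchSize = 32L,
                        seed = 1L) {
  new("TrainConfig", optimizer = "sgd", momentum = momentum,
      initialLr = initialLr, lrDecayFactor = lrDecayFactor,
      lrDecayEvery = as.integer(lrDecayEvery), epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), seed = as.integer(seed))
}

#' Learning rate at a (0-based) epoch
#'
#' lr(e) = initialLr / lrDecayFactor^floor(e / lrDecayEvery).
#'
#' @param tc a \linkS4class{TrainConfig}.
#' @param epoch integer vector of 0-based epochs.
#' @return Numeric vector of learning rates.
#' @export
learningRateAt <- function(tc, epoch) {
  tc@initialLr / tc@lrDecayFactor^(epoch %/% tc@lrDecayEvery)
}

#' Stratified k-fold split with per-round train/validation/test roles
#'
#' Assigns every sample to one of k folds so that each fold holds
#' approximately 1/k of every class (within one sample). Round r (1..k) uses
#' fold r as the test set, the next fold cyclically as validation, and the
#' remaining k - 2 folds for training, so the k rounds have pairwise different
#' test folds covering the data exactly once.
#'
#' @param labels per-sample class labels (factor or character).
#' @param k number of folds (default 5).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return List with \code{foldOfSample} (integer 1..k per sample) and
#'   \code{roundRoles} (data.frame: round, testFold, valFold, and a
#'   comma-separated trainFolds column).
#' @examples
#' labels <- rep(LEUKOCYTE_CLASSES, each = 10)
#' fs <- stratifiedKFold(labels, k = 5, seed = 1)
#' table(fs$foldOfSample, labels)
#' @export
stratifiedKFold <- function(labels, k = 5L, seed = 1L) {
  labels <- as.character(labels)
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small) > 0L)
    stop(sprintf("class '%s' has fewer than k = %d samples", small[1], k))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  rounds <- data.frame(
    round = seq_len(k),
    testFold = seq_len(k),
    valFold = seq_len(k) %% k + 1L)
  rounds$trainFolds <- vapply(seq_len(k), function(r) {
    paste(setdiff(seq_len(k), c(rounds$testFold[r], rounds$valFold[r])),
          collapse = ",")
  }, character(1))
  list(foldOfSample = fold, roundRoles = rounds, k = k)
}

#' Oversample minority classes to the majority frequency
#'
#' Returns a shuffled index vector in which every class appears as often as
#' the largest class: majority-class indices once each, minority classes
#' resampled with replacement. A balanced input therefore yields a plain
#' permutation. Uses the current RNG state.
#'
#' @param labels per-sample class labels.
#' @return Integer index vector of length nClasses * majoritySize.
#' @examples
#' set.seed(1)
#' idx <- oversampleMinority(c("a", "a", "a", "b"))
#' table(c("a", "a", "a", "b")[idx])
#' @export
oversampleMinority <- function(labels) {
  labels <- as.character(labels)
  counts <- table(labels)
  m <- max(counts)
  out <- unlist(lapply(names(counts), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) == m) idx else idx[sample.int(length(idx), m, replace = TRUE)]
  }), use.names = FALSE)
  out[sample.int(length(out))]
}

#' Random flip / right-angle rotation augmentation
#'
#' Applies a horizontal flip, a vertical flip and a rotation by a multiple of
#' 90 degrees (the label is unchanged; right angles avoid interpolation
#' artifacts and border fill). Draws missing choices from the current RNG
#' state, so a fixed seed reproduces the augmented sequence.
#'
#' @param crop a \linkS4class{CellCrop} or a square h x h x 3 array.
#' @param flipH,flipV logical; drawn at random when NULL.
#' @param rot rotation in degrees, one of 0, 90, 180, 270; drawn when NULL.
#' @return Object of the same kind as \code{crop}.
#' @examples
#' a <- array(seq_len(4 * 4 * 3), c(4, 4, 3))
#' identical(augmentCrop(a, FALSE, FALSE, 0), a)
#' @export
augmentCrop <- function(crop, flipH = NULL, flipV = NULL, rot = NULL) {
  px <- if (is(crop, "CellCrop")) crop@pixels else crop
  if (is.null(flipH)) flipH <- runif(1) < 0.5
  if (is.null(flipV)) flipV <- runif(1) < 0.5
  if (is.null(rot)) rot <- sample(c(0, 90, 180, 270), 1)
  stopifnot(rot %in% c(0, 90, 180, 270))
  if (flipH) px <- px[, dim(px)[2]:1, , drop = FALSE]
  if (flipV) px <- px[dim(px)[1]:1, , , drop = FALSE]
  if (rot > 0) {
    if (dim(px)[1] != dim(px)[2])
      stop("rotation requires a square crop")
    for (i in seq_len(rot / 90))   # 90 deg clockwise: transpose + flip cols
      px <- aperm(px, c(2, 1, 3))[, dim(px)[1]:1, , drop = FALSE]
  }
  if (is(crop, "CellCrop")) {
    crop@pixels <- px
    crop
  } else px
}

.labelsToInt <- function(y, nClasses) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), LEUKOCYTE_CLASSES)
    if (length(bad) > 0L) stop(sprintf("unknown class label '%s'", bad[1]))
    return(match(y, LEUKOCYTE_CLASSES))
  }
  y <- as.integer(y)
  stopifnot(all(y >= 1L & y <= nClasses))
  y
}

#' Train the compact classifier from scratch
#'
#' SGD with momentum under the configured learning-rate schedule. Each epoch
#' (optionally) oversamples minority classes to the majority frequency and
#' pushes every presented sample through a random flip/rotation. Dropout is
#' active only during training; validation accuracy is computed in
#' deterministic evaluation mode after every epoch and the best-validation
#' checkpoint (ties: earliest epoch) is restored into the returned model.
#'
#' @param config a \linkS4class{CompactNetConfig}.
#' @param tc a \linkS4class{TrainConfig}.
#' @param train list with \code{x} (integer array h x w x 3 x n, values 0-255)
#'   and \code{y} (labels: class names or integers 1..nClasses).
#' @param val like \code{train}; used for checkpoint selection.
#' @param oversample balance classes by resampling each epoch (default TRUE).
#' @param augment apply random flip/rotation each epoch (default TRUE).
#' @param targetValAcc optional early-stopping threshold on validation
#'   accuracy.
#' @param verbose print per-epoch progress.
#' @return List with \code{model} (\linkS4class{CompactNet}, best checkpoint),
#'   \code{log} (data.frame: epoch, lr, trainLoss, valAcc), \code{bestEpoch}
#'   and \code{bestValAcc}.
#' @export
trainModel <- function(config, tc, train, val, oversample = TRUE,
                       augment = TRUE, targetValAcc = NULL, verbose = FALSE) {
  stopifnot(is(config, "CompactNetConfig"), is(tc, "TrainConfig"))
  set.seed(tc@seed)
  x <- .cropsToArray(train$x)
  yTrain <- .labelsToInt(train$y, config@nClasses)
  xv <- .cropsToArray(val$x)
  yVal <- .labelsToInt(val$y, config@nClasses)
  # input normalization from the training set (subsampled for speed)
  pick <- seq_len(min(dim(x)[4], 64L))
  sub <- x[, , , pick, drop = FALSE] / 255
  inputNorm <- list(
    mean = vapply(1:3, function(c) mean(sub[, , c, ]), numeric(1)),
    sd = pmax(vapply(1:3, function(c) sd(sub[, , c, ]), numeric(1)), 1e-3))
  model <- buildModel(config, seed = tc@seed, inputNorm = inputNorm)
  ptr <- .modelPtr(model)
  ds <- .makeDataset(x)
  dsVal <- .makeDataset(xv)
  # variance-calibrate the FC layers on a probe batch (initialization only)
  .cn_calibrate_fc(ptr, ds, seq_len(min(dim(x)[4], 32L)))
  model@state$params <- .cn_get_params(ptr)
  n <- dim(x)[4]
  bestAcc <- -Inf; bestEpoch <- NA_integer_; bestParams <- NULL
  log <- vector("list", tc@epochs)
  for (e in seq_len(tc@epochs) - 1L) {
    lr <- learningRateAt(tc, e)
    order <- if (oversample) oversampleMinority(yTrain) else
      sample.int(n)
    aug <- if (augment) sample(0:7, length(order), replace = TRUE) else
      rep(0L, length(order))
    dropSeed <- sample.int(.Machine$integer.max, 1L)
    loss <- .cn_train_epoch(ptr, ds, order, yTrain[order] - 1L, aug,
                            lr, tc@momentum, tc@batchSize, dropSeed)
    probs <- .cn_predict(ptr, dsVal, seq_len(dim(xv)[4]))
    acc <- mean(max.col(probs, ties.method = "first") == yVal)
    log[[e + 1L]] <- data.frame(epoch = e, lr = lr, trainLoss = loss,
                                valAcc = acc)
    if (verbose)
      message(sprintf("epoch %d: lr %.2e, loss %.4f, val acc %.4f",
                      e, lr, loss, acc))
    if (acc > bestAcc) {
      bestAcc <- acc; bestEpoch <- e; bestParams <- .cn_get_params(ptr)
    }
    if (!is.null(targetValAcc) && bestAcc >= targetValAcc) break
  }
  .cn_set_params(ptr, bestParams)
  model@state$params <- bestParams
  list(model = model, log = do.call(rbind, log[!vapply(log, is.null, TRUE)]),
       bestEpoch = bestEpoch, bestValAcc = bestAcc)
}

#' One SGD-momentum step (reference update rule)
#'
#' The package's update convention: v' = momentum * v + grad;
#' w' = w - lr * v'. Exposed for verification against hand arithmetic.
#'
#' @param w,v current weight and velocity.
#' @param grad gradient at w.
#' @param lr,momentum step size and momentum coefficient.
#' @return Numeric vector c(w', v').
#' @examples
#' sgdStep(w = 1, v = 0, grad = 2, lr = 0.1, momentum = 0.9)
#' @export
sgdStep <- function(w, v, grad, lr, momentum) {
  .cn_sgd_step(w, v, grad, lr, momentum)
}

#' Run the full k-fold protocol on a labeled crop dataset
#'
#' For each round: split per \code{\link{stratifiedKFold}}, train on the
#' training folds, select by validation accuracy, evaluate on the test fold.
#' Returns per-round confusion matrices and the mean and standard deviation of
#' the support-weighted metrics across rounds (the usual cross-validated
#' reporting format).
#'
#' @param x integer crop array h x w x 3 x n.
#' @param y labels (class names or integers 1..6).
#' @param config a \linkS4class{CompactNetConfig}.
#' @param tc a \linkS4class{TrainConfig}.
#' @param k folds (default 5).
#' @param rounds which rounds to run (default all k).
#' @param ... passed to \code{\link{trainModel}}.
#' @return List with \code{confusions} (list of 6 x 6 matrices),
#'   \code{metrics} (data.frame of weighted metrics per round), and
#'   \code{summary} (mean and sd per metric).
#' @export
crossValidate <- function(x, y, config, tc, k = 5L,
                          rounds = seq_len(k), ...) {
  x <- .cropsToArray(x)
  yInt <- .labelsToInt(y, config@nClasses)
  fs <- stratifiedKFold(yInt, k = k, seed = tc@seed)
  confusions <- list(); metricRows <- list()
  for (r in rounds) {
    roles <- fs$roundRoles[r, ]
    testIdx <- which(fs$foldOfSample == roles$testFold)
    valIdx <- which(fs$foldOfSample == roles$valFold)
    trainIdx <- setdiff(seq_along(yInt), c(testIdx, valIdx))
    fit <- trainModel(config, tc,
                      train = list(x = x[, , , trainIdx, drop = FALSE],
                                   y = yInt[trainIdx]),
                      val = list(x = x[, , , valIdx, drop = FALSE],
                                 y = yInt[valIdx]), ...)
    pred <- predictClasses(fit$model, x[, , , testIdx, drop = FALSE])
    truth <- factor(LEUKOCYTE_CLASSES[yInt[testIdx]],
                    levels = LEUKOCYTE_CLASSES)
    cm <- confusionMatrix6(truth, pred)
    confusions[[length(confusions) + 1L]] <- cm
    ms <- metricsFromConfusion(cm)
    metricRows[[length(metricRows) + 1L]] <-
      cbind(data.frame(round = r), as.data.frame(as.list(ms$weighted)))
  }
  metrics <- do.call(rbind, metricRows)
  num <- metrics[, setdiff(names(metrics), "round"), drop = FALSE]
  list(confusions = confusions, metrics = metrics,
       summary = data.frame(metric = names(num),
                            mean = vapply(num, mean, numeric(1)),
                            sd = vapply(num, sd, numeric(1))))
}
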