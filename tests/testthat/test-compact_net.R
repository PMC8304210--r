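# Architecture accounting, construction, SE attention and inference
# contracts of the compact classifier.

test_that("per-layer accounting matches hand arithmetic", {
  acct <- modelAccount(compactNetConfig())
  pl <- acct$perLayer
  # first conv block: 3*3*3*64 + 64 bias + 2*64 scale/shift
  expect_equal(pl$params[pl$layer == "block0_conv"], 1920)
  # first fully-connected layer: 12544*512 + 512
  expect_equal(pl$params[pl$layer == "fc0"], 6423040)
  # SE bottleneck: 256*16 + 16 + 16*256 + 256
  expect_equal(pl$params[pl$layer == "se"], 8464)
  expect_equal(acct$nParameters, sum(pl$params))

  # conv MACs at each conv's own output resolution
  expect_equal(pl$macs[pl$layer == "block0_conv"], 86704128)
  expect_equal(pl$macs[pl$layer == "block1_conv"], 924844032)
  expect_equal(pl$macs[pl$layer == "block2_conv"], 231211008)
  expect_equal(pl$macs[pl$layer == "block3_conv"], 115605504)
  expect_equal(sum(pl$macs[grepl("conv", pl$layer)]), 1358364672)
  expect_equal(pl$macs[pl$layer == "se"], 8192)
  expect_gt(countMacs(compactNetConfig(), includeElementwise = TRUE),
            countMacs(compactNetConfig()))
})

test_that("canonical feature-map geometry follows the published column", {
  fm <- featureMapSizes(compactNetConfig())
  expect_equal(fm$poolSide, c(112L, 56L, 14L, 7L))
  expect_equal(fm$channels, c(64L, 128L, 256L, 256L))
  expect_equal(fm$convSide, c(224L, 112L, 28L, 14L))
})

test_that("closed-form parameter count equals tensor enumeration", {
  for (variant in c("noSE", "twoBlock", "threeBlock")) {
    cfg <- ablationConfig(variant, inputSize = 64L)
    net <- buildModel(cfg, seed = 1)
    expect_equal(numParameters(net), countParameters(cfg))
  }
  # removing the SE module removes exactly its 8,464 parameters
  expect_equal(countParameters(compactNetConfig()) -
                 countParameters(ablationConfig("noSE")), 8464)
})

test_that("incompatible SE ratio is rejected", {
  expect_error(compactNetConfig(blockChannels = c(8L, 12L),
                                blockStrides = c(1L, 1L), seRatio = 16L),
               "divisible")
})

test_that("SE attention gate matches hand computation", {
  # identical constant channels share attention uniformly under softmax
  f <- matrix(3, 4, 10)
  w <- attr(seForward(f, diag(4), 0, diag(4), 0), "weights")
  expect_equal(w, rep(0.25, 4), tolerance = 1e-6)

  # two-channel toy with identity weights: softmax(relu(c(1, 0)))
  f <- matrix(c(1, 0), 2, 8)
  out <- seForward(f, diag(2), 0, diag(2), 0)
  w <- attr(out, "weights")
  expect_equal(w, exp(c(1, 0)) / sum(exp(c(1, 0))), tolerance = 1e-4)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  expect_equal(out[1, 1], 1 * w[1], tolerance = 1e-6)

  # softmax weights form a probability vector for random inputs
  set.seed(1)
  for (i in 1:10) {
    f <- matrix(rnorm(8 * 25), 8, 25)
    W1 <- matrix(rnorm(16), 2, 8); W2 <- matrix(rnorm(16), 8, 2)
    w <- attr(seForward(f, W1, rnorm(2), W2, rnorm(8)), "weights")
    expect_equal(sum(w), 1, tolerance = 1e-6)
    expect_true(all(w >= 0))
    wS <- attr(seForward(f, W1, rnorm(2), W2, rnorm(8), gate = "sigmoid"),
               "weights")
    expect_true(all(wS > 0 & wS < 1))
  }

  # array input keeps its shape
  a <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  out <- seForward(a, diag(4), 0, diag(4), 0)
  expect_equal(dim(out), dim(a))
})

test_that("inference is a deterministic softmax over six classes", {
  cfg <- tinyConfig()
  net <- buildModel(cfg, seed = 2)
  x <- array(sample(0:255, 32 * 32 * 3 * 3, TRUE), c(32, 32, 3, 3))
  p1 <- predictProbs(net, x)
  expect_equal(dim(p1), c(3L, 6L))
  expect_equal(unname(rowSums(p1)), rep(1, 3), tolerance = 1e-6)
  expect_identical(p1, predictProbs(net, x))   # bitwise reproducible

  # zeroed final layer forces uniform probabilities
  pars <- getParams(net)
  pars$fc1_w[] <- 0; pars$fc1_b[] <- 0
  setParams(net, pars)
  expect_equal(unname(as.vector(predictProbs(net, x))),
               rep(1 / 6, 18), tolerance = 1e-7)

  expect_error(predictProbs(net, array(0L, c(16, 16, 3, 1))), "expects")
  expect_error(predictProbs(net, x, evalMode = FALSE), "not supported")
})

test_that("ablation variants build and infer with re-derived FC geometry", {
  x <- array(sample(0:255, 64 * 64 * 3, TRUE), c(64, 64, 3, 1))
  for (variant in c("canonical", "noSE", "noDropout", "twoBlock",
                    "threeBlock")) {
    cfg <- ablationConfig(variant, inputSize = 64L)
    net <- buildModel(cfg, seed = 3)
    p <- predictProbs(net, x)
    expect_equal(dim(p), c(1L, 6L))
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
})

test_that("backpropagation matches finite-difference gradients", {
  # dropout off so the training-mode loss is the deterministic eval loss
  cfg <- compactNetConfig(blockChannels = c(4L, 6L), blockStrides = c(1L, 1L),
                          seRatio = 2L, fc0Width = 10L, inputSize = 16L,
                          useDropout = FALSE)
  net <- buildModel(cfg, seed = 4)
  set.seed(5)
  x <- array(sample(0:255, 16 * 16 * 3, TRUE), c(16, 16, 3, 1))
  label <- 3L
  lossAt <- function(params) {
    setParams(net, params)
    unname(-log(predictProbs(net, x)[1, label]))
  }
  p0 <- getParams(net)
  # implied gradient from one momentum-free SGD step
  lr <- 1e-3
  ds <- aplScreen:::.makeDataset(x)
  ptr <- aplScreen:::.modelPtr(net)
  aplScreen:::.cn_train_epoch(ptr, ds, 1L, label - 1L, 0L, lr, 0, 1L, 1L)
  p1 <- aplScreen:::.cn_get_params(ptr)
  h <- 5e-3
  for (nm in c("block0_conv_w", "block1_bn_gamma", "se_w2", "fc0_w",
               "fc1_b")) {
    set.seed(match(nm, names(p0)))
    i <- sample(length(p0[[nm]]), 1)
    gImpl <- (p0[[nm]][i] - p1[[nm]][i]) / lr
    pp <- p0; pp[[nm]][i] <- pp[[nm]][i] + h
    lp <- lossAt(pp)
    pp[[nm]][i] <- pp[[nm]][i] - 2 * h
    lm <- lossAt(pp)
    gNum <- (lp - lm) / (2 * h)
    expect_equal(gImpl, gNum, tolerance = 0.05,
                 label = sprintf("gradient of %s", nm))
  }
})

test_that("checkpoints round-trip through disk", {
  cfg <- tinyConfig()
  net <- buildModel(cfg, seed = 6)
  x <- array(sample(0:255, 32 * 32 * 3 * 2, TRUE), c(32, 32, 3, 2))
  p <- predictProbs(net, x)
  tmp <- withr::local_tempfile(fileext = ".rds")
  saveModel(net, tmp)
  restored <- loadModel(tmp)
  expect_identical(predictProbs(restored, x), p)
})
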