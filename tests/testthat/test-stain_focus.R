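# Color statistics, normalization, stain deconvolution, binarization and
# bounding-box extraction.

test_that("color statistics match direct per-pixel arithmetic", {
  gray <- array(128L, c(64, 64, 3))
  cs <- computeColorStats(gray, space = "rgb")
  expect_equal(cs@mean, rep(128, 3))
  expect_equal(cs@sd, rep(0, 3))

  img <- randomImage(32, 32, seed = 5)
  cs1 <- computeColorStats(img, space = "rgb")
  cs2 <- computeColorStats(img, space = "rgb")
  expect_identical(cs1@mean, cs2@mean)   # deterministic

  # independent brute-force sums
  for (c in 1:3) {
    v <- as.numeric(img[, , c])
    expect_equal(cs1@mean[c], sum(v) / length(v), tolerance = 1e-9)
    expect_equal(cs1@sd[c], sqrt(sum((v - mean(v))^2) / length(v)),
                 tolerance = 1e-9)
  }
  expect_error(computeColorStats(img, space = "hsv"))
})

test_that("color normalization matches reference statistics and degenerates safely", {
  img <- randomImage(48, 48, seed = 7)

  # identity: normalizing to an image's own stats moves nothing beyond
  # quantization
  for (space in c("rgb", "lab")) {
    ref <- computeColorStats(img, space = space)
    out <- normalizeColor(img, ref)
    expect_lte(max(abs(out - img)), 1)
  }

  # constant image takes the reference mean exactly (zero-spread rule)
  flat <- array(77L, c(32, 32, 3))
  ref <- colorStats(c(100, 120, 140), c(10, 10, 10), "rgb")
  out <- normalizeColor(flat, ref)
  expect_equal(unique(as.vector(out[, , 1])), 100)
  expect_equal(unique(as.vector(out[, , 2])), 120)
  expect_equal(unique(as.vector(out[, , 3])), 140)

  # statistics of the output match the requested reference
  out <- normalizeColor(img, ref)
  cs <- computeColorStats(out, space = "rgb")
  expect_true(all(abs(cs@mean - ref@mean) < 1))
  expect_true(all(abs(cs@sd - ref@sd) < 1))

  # idempotence: a second pass changes at most one intensity level
  for (space in c("rgb", "lab")) {
    refS <- computeColorStats(randomImage(32, 32, 11), space = space)
    once <- normalizeColor(img, refS)
    twice <- normalizeColor(once, refS)
    expect_lte(max(abs(twice - once)), 1)
  }
})

test_that("deconvolution inverts the Beer-Lambert forward model", {
  sm <- defaultStainModel()

  # pure background has zero density
  bg <- array(255L, c(64, 64, 3))
  maps <- deconvolveStains(bg, sm)
  expect_lt(max(methyleneBlue(maps)), 1e-6)
  expect_lt(max(eosin(maps)), 1e-6)

  # known concentrations round-trip exactly in the continuous domain
  I <- beerLambertForward(matrix(0.7, 2, 2), matrix(0.2, 2, 2), sm)
  maps <- deconvolveStains(I, sm)
  expect_lt(max(abs(methyleneBlue(maps) - 0.7)), 1e-6)
  expect_lt(max(abs(eosin(maps) - 0.2)), 1e-6)

  # a pure methylene-blue pixel at unit density
  I <- beerLambertForward(matrix(1, 1, 1), matrix(0, 1, 1), sm)
  maps <- deconvolveStains(I, sm)
  expect_lt(abs(methyleneBlue(maps) - 1), 1e-6)
  expect_lt(abs(eosin(maps)), 1e-6)

  # near-parallel stain vectors are rejected by name: outright dependence
  # fails at construction, marginal near-parallelism at deconvolution
  expect_error(stainModel(rbind(c(0.6, 0.7, 0.3), c(0.6000001, 0.7, 0.3))),
               "dependent")
  v1 <- c(0.6, 0.7, 0.3)
  v2 <- v1 + 1e-4 * c(0.7, -0.6, 0)
  expect_error(deconvolveStains(bg, stainModel(rbind(v1, v2))),
               "parallel|singular")
})

test_that("continuous round trip is exact across the concentration domain", {
  sm <- defaultStainModel()
  set.seed(42)
  for (i in 1:100) {
    mb <- matrix(runif(4, 0, 3), 2, 2)
    eo <- matrix(runif(4, 0, 3), 2, 2)
    maps <- deconvolveStains(beerLambertForward(mb, eo, sm), sm)
    expect_lt(max(abs(methyleneBlue(maps) - mb)), 1e-6)
    expect_lt(max(abs(eosin(maps) - eo)), 1e-6)
  }
})

test_that("stain vectors can be re-estimated from single-stain fields", {
  sm <- defaultStainModel()
  set.seed(3)
  mb <- matrix(runif(64 * 64, 0.2, 1.5), 64, 64)
  I <- beerLambertForward(mb, matrix(0, 64, 64), sm)
  Iq <- array(as.integer(round(I)), dim(I))
  v <- estimateStainVectors(Iq)
  expect_lt(max(abs(v - stainVectors(sm)[1, ])), 0.01)
  expect_error(estimateStainVectors(array(255L, c(8, 8, 3))), "OD floor")
})

test_that("binarization thresholds the density map with area filtering", {
  expect_equal(sum(binarizeLeukocyteMap(matrix(0, 64, 64))), 0)

  m <- matrix(0, 80, 80)
  m[31:50, 31:50] <- 2
  mask <- binarizeLeukocyteMap(m, minArea = 50)
  expect_equal(which(mask), which(m > 0))   # exactly the square
  expect_equal(sum(binarizeLeukocyteMap(m, minArea = 500)), 0)

  # fixed threshold override
  mask <- binarizeLeukocyteMap(m, method = "fixed", threshold = 1,
                               minArea = 50)
  expect_equal(sum(mask), 400)
  expect_error(binarizeLeukocyteMap(m, method = "fixed"), "threshold")
})

test_that("bounding boxes agree with a brute-force flood-fill oracle", {
  expect_equal(nrow(extractCellBoxes(matrix(FALSE, 10, 10), minArea = 1)), 0)

  # two disjoint rectangles give exactly their bounds
  m <- matrix(FALSE, 60, 60)
  m[5:14, 3:10] <- TRUE
  m[40:49, 30:44] <- TRUE
  b <- extractCellBoxes(m, minArea = 1)
  expect_equal(b$x0, c(2L, 29L))
  expect_equal(b$y0, c(4L, 39L))
  expect_equal(b$width, c(8L, 15L))
  expect_equal(b$height, c(10L, 10L))
  expect_equal(b$area_px, c(80L, 150L))

  # property: exact agreement with the independent oracle on random masks
  for (seed in 1:100) {
    set.seed(seed)
    m <- matrix(runif(64 * 64) < 0.25, 64, 64)
    got <- extractCellBoxes(m, minArea = 1)
    want <- bruteForceBoxes(m, minArea = 1)
    expect_equal(got, want)
  }
})

test_that("crops are square, background-padded and resized to the target", {
  img <- randomImage(64, 64, seed = 9)

  # whole-image box at the output size is returned unchanged
  full <- data.frame(x0 = 0L, y0 = 0L, width = 64L, height = 64L,
                     area_px = 64L * 64L)
  crops <- cropCells(img, full, padFrac = 0, outSize = 64)
  expect_identical(pixels(crops[[1]]), array(as.integer(img), dim(img)))

  # 50 x 100 box becomes a centered square before resizing
  img2 <- randomImage(128, 128, seed = 10)
  img2[1, 1, ] <- c(7L, 8L, 9L)   # not the mode; background is the modal color
  box <- data.frame(x0 = 10L, y0 = 10L, width = 50L, height = 100L,
                    area_px = 100L)
  crops <- cropCells(img2, box, padFrac = 0, outSize = 224)
  expect_equal(dim(pixels(crops[[1]])), c(224L, 224L, 3L))

  expect_equal(cropCells(img, full[0, ]), list())
  bad <- data.frame(x0 = 40L, y0 = 0L, width = 60L, height = 10L,
                    area_px = 10L)
  expect_error(cropCells(img, bad), "outside")
})

test_that("focusing recovers planted leukocytes and ignores red-cell fields", {
  sm <- cached("smear_seed3", generateSmear(smearRecipe(seed = 3L)))
  res <- focusLeukocytes(sm$image)
  gt <- sm$groundTruth
  best <- vapply(seq_len(nrow(gt)), function(i) {
    if (nrow(res$boxes) == 0) return(0)
    max(vapply(seq_len(nrow(res$boxes)),
               function(j) boxIoU(gt[i, ], res$boxes[j, ]), numeric(1)))
  }, numeric(1))
  expect_gte(sum(best >= 0.5), nrow(gt) - 1)   # at least 9 of 10
  expect_equal(dim(pixels(res$crops[[1]])), c(224L, 224L, 3L))

  redOnly <- generateSmear(smearRecipe(nLeukocytes = 0L, nRedCells = 50L,
                                       seed = 4L))
  expect_equal(nrow(focusLeukocytes(redOnly$image)$boxes), 0L)
})

test_that("field images and boxes survive a disk round trip", {
  sm <- cached("smear_seed3", generateSmear(smearRecipe(seed = 3L)))
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "field.png")
  writeSmearImage(sm$image, p)
  back <- readSmearImage(p)
  expect_identical(pixels(back), pixels(sm$image))
  expect_equal(sourceId(back), "field")

  bp <- file.path(tmp, "boxes.csv")
  writeBoxesCsv(sm$groundTruth[, 1:5], bp, sourceId = "field",
                label = sm$groundTruth$label)
  df <- readBoxesCsv(bp)
  expect_equal(df$x0, sm$groundTruth$x0)
  expect_equal(df$label, sm$groundTruth$label)
})
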