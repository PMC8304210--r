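# The synthetic smear generator: determinism, ground truth consistency and
# class separability.

test_that("recipes validate their inputs", {
  expect_error(smearRecipe(classMix = rep(0.2, 6)), "summing")
  expect_error(smearRecipe(nLeukocytes = -1L))
  expect_s4_class(smearRecipe(), "SmearRecipe")
})

test_that("identical recipe and seed give bitwise-identical fields", {
  r <- smearRecipe(nLeukocytes = 4L, nRedCells = 25L, seed = 17L)
  a <- generateSmear(r)
  b <- generateSmear(r)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(a$groundTruth, b$groundTruth)
  # another seed gives a different field
  c <- generateSmear(smearRecipe(nLeukocytes = 4L, nRedCells = 25L,
                                 seed = 18L))
  expect_false(identical(pixels(a$image), pixels(c$image)))
})

test_that("ground truth matches the rendered content", {
  sm <- cached("smear_seed3", generateSmear(smearRecipe(seed = 3L)))
  gt <- sm$groundTruth
  expect_equal(nrow(gt), 10L)
  expect_true(all(gt$label %in% LEUKOCYTE_CLASSES))
  d <- dim(pixels(sm$image))
  expect_true(all(gt$x0 >= 0 & gt$x0 + gt$width <= d[2]))
  expect_true(all(gt$y0 >= 0 & gt$y0 + gt$height <= d[1]))
  expect_true(all(gt$area_px >= 400))   # every planted cell is segmentable
})

test_that("a field without leukocytes yields no focusing detections", {
  sm <- generateSmear(smearRecipe(nLeukocytes = 0L, nRedCells = 60L,
                                  seed = 23L))
  expect_equal(nrow(sm$groundTruth), 0L)
  expect_equal(nrow(focusLeukocytes(sm$image)$boxes), 0L)
})

test_that("noise-free deconvolution recovers the nominal densities", {
  sm <- generateSmear(smearRecipe(noiseSd = 0, seed = 5L))
  maps <- deconvolveStains(sm$image)
  expect_lt(max(abs(methyleneBlue(maps) - sm$densities$methyleneBlue)), 0.05)
  expect_lt(max(abs(eosin(maps) - sm$densities$eosin)), 0.05)
})

test_that("overlap is impossible by default and an explicit opt-in", {
  sm <- cached("smear_seed3", generateSmear(smearRecipe(seed = 3L)))
  cp <- sm$cellParams
  for (i in seq_len(nrow(cp) - 1)) {
    d2 <- (cp$y[-(1:i)] - cp$y[i])^2 + (cp$x[-(1:i)] - cp$x[i])^2
    expect_true(all(d2 > (cp$radius[-(1:i)] + cp$radius[i])^2))
  }
  # an impossible packing fails with advice rather than looping forever
  expect_error(
    generateSmear(smearRecipe(imageSize = c(128L, 128L), nLeukocytes = 12L,
                              nRedCells = 0L, seed = 1L)),
    "reduce")
  # the same packing is allowed when overlap is explicitly enabled
  sm2 <- generateSmear(smearRecipe(imageSize = c(128L, 128L),
                                   nLeukocytes = 6L, nRedCells = 0L,
                                   allowOverlap = TRUE, seed = 1L))
  expect_equal(nrow(sm2$groundTruth), 6L)
})

test_that("crop datasets are balanced, labeled and deterministic", {
  ds <- generateCellDataset(nPerClass = 3, seed = 31, imageSize = 96L)
  expect_equal(dim(ds$x), c(96L, 96L, 3L, 18L))
  expect_equal(as.integer(table(ds$y)), rep(3L, 6))
  ds2 <- generateCellDataset(nPerClass = 3, seed = 31, imageSize = 96L)
  expect_identical(ds$x, ds2$x)
  expect_identical(ds$y, ds2$y)

  # an explicit class-size vector is honored (an imbalanced clinical-style
  # distribution at reduced scale)
  sizes <- c(10L, 11L, 10L, 9L, 6L, 23L)
  dsI <- generateCellDataset(seed = 32, classSizes = sizes, imageSize = 64L)
  expect_equal(as.integer(table(dsI$y)), sizes)
})

test_that("class signatures separate under a nearest-centroid baseline", {
  ds <- cached("sep64", generateCellDataset(nPerClass = 40, seed = 33,
                                            imageSize = 64L))
  expect_gte(nearestCentroidAccuracy(ds$x, ds$y), 0.8)
})
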