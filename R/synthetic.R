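# Synthetic Romanowsky-type smear generator. Cells are composed as
# methylene-blue / eosin density fields (red cells: pale eosin disks with
# central pallor; leukocytes: blue-dense nuclei plus class-specific granule
# and nucleus signatures) and rendered to RGB through the same Beer-Lambert
# forward model the deconvolution stage inverts, so ground-truth densities,
# boxes and labels are known exactly.

# density caps keep the 8-bit dynamic range informative: with the default
# stain vectors the darkest channel stays above ~16/255, so quantization
# perturbs recovered densities by well under 0.05
.MB_MAX_DENSITY <- 2.0
.EO_MAX_DENSITY <- 1.4
.GT_DENSITY <- 0.3   # methylene-blue level defining the ground-truth extent

#' Create a smear recipe
#'
#' Defaults define the package's reference synthetic study conditions: a
#' 384 x 384 field with 10 non-overlapping leukocytes of uniformly mixed
#' class, 60 red cells, the default stain model and Gaussian pixel noise of
#' sd 2 (8-bit units).
#'
#' @param imageSize integer (height, width), default c(384, 384).
#' @param nLeukocytes leukocytes to plant (default 10).
#' @param nRedCells red cells to plant (default 60).
#' @param classMix 6 class probabilities (default uniform).
#' @param stains a \linkS4class{StainModel}.
#' @param noiseSd Gaussian pixel noise sd in 8-bit units (default 2).
#' @param allowOverlap allow overlapping cells (default FALSE; overlap is the
#'   documented failure mode of the focusing stage).
#' @param seed integer seed (default 1); identical recipe + seed gives a
#'   bitwise-identical image.
#' @return A \linkS4class{SmearRecipe}.
#' @examples
#' smearRecipe(nLeukocytes = 5, seed = 42)
#' @export
smearRecipe <- function(imageSize = c(384L, 384L), nLeukocytes = 10L,
                        nRedCells = 60L, classMix = rep(1 / 6, 6),
                        stains = defaultStainModel(), noiseSd = 2,
                        allowOverlap = FALSE, seed = 1L) {
  new("SmearRecipe", imageSize = as.integer(imageSize),
      nLeukocytes = as.integer(nLeukocytes),
      nRedCells = as.integer(nRedCells), classMix = classMix,
      stainModel = stains, noiseSd = noiseSd,
      allowOverlap = allowOverlap, seed = as.integer(seed))
}

# add an anti-aliased disk to a density matrix (in place semantics via return)
.addDisk <- function(dens, cy, cx, r, value) {
  h <- nrow(dens); w <- ncol(dens)
  i0 <- max(1L, floor(cy - r - 1)); i1 <- min(h, ceiling(cy + r + 1))
  j0 <- max(1L, floor(cx - r - 1)); j1 <- min(w, ceiling(cx + r + 1))
  if (i0 > i1 || j0 > j1) return(dens)
  yy <- i0:i1; xx <- j0:j1
  d <- sqrt(outer((yy - cy)^2, (xx - cx)^2, "+"))
  wgt <- pmin(pmax(r - d + 0.5, 0), 1)
  dens[yy, xx] <- dens[yy, xx] + value * wgt
  dens
}

# disk with a disk-shaped notch (kidney nucleus)
.addKidney <- function(dens, cy, cx, r, value, notchFrac = 0.75,
                       notchDist = 0.8, angle = 0) {
  h <- nrow(dens); w <- ncol(dens)
  i0 <- max(1L, floor(cy - r - 1)); i1 <- min(h, ceiling(cy + r + 1))
  j0 <- max(1L, floor(cx - r - 1)); j1 <- min(w, ceiling(cx + r + 1))
  if (i0 > i1 || j0 > j1) return(dens)
  yy <- i0:i1; xx <- j0:j1
  ny <- cy + notchDist * r * sin(angle)
  nx <- cx + notchDist * r * cos(angle)
  d <- sqrt(outer((yy - cy)^2, (xx - cx)^2, "+"))
  dn <- sqrt(outer((yy - ny)^2, (xx - nx)^2, "+"))
  wgt <- pmin(pmax(r - d + 0.5, 0), 1) *
    pmin(pmax(dn - notchFrac * r + 0.5, 0), 1)
  dens[yy, xx] <- dens[yy, xx] + value * wgt
  dens
}

# thick anti-aliased line segment (Auer-rod motif)
.addRod <- function(dens, y1, x1, y2, x2, halfWidth, value) {
  h <- nrow(dens); w <- ncol(dens)
  i0 <- max(1L, floor(min(y1, y2) - halfWidth - 1))
  i1 <- min(h, ceiling(max(y1, y2) + halfWidth + 1))
  j0 <- max(1L, floor(min(x1, x2) - halfWidth - 1))
  j1 <- min(w, ceiling(max(x1, x2) + halfWidth + 1))
  if (i0 > i1 || j0 > j1) return(dens)
  yy <- i0:i1; xx <- j0:j1
  vy <- y2 - y1; vx <- x2 - x1
  len2 <- vy^2 + vx^2
  Y <- matrix(yy, length(yy), length(xx))
  X <- matrix(xx, length(yy), length(xx), byrow = TRUE)
  t <- pmin(pmax(((Y - y1) * vy + (X - x1) * vx) / len2, 0), 1)
  d <- sqrt((Y - (y1 + t * vy))^2 + (X - (x1 + t * vx))^2)
  wgt <- pmin(pmax(halfWidth - d + 0.5, 0), 1)
  dens[yy, xx] <- dens[yy, xx] + value * wgt
  dens
}

# red cell: pale eosin disk with central pallor
.addRedCell <- function(mb, eo, cy, cx, r) {
  h <- nrow(eo); w <- ncol(eo)
  i0 <- max(1L, floor(cy - r - 1)); i1 <- min(h, ceiling(cy + r + 1))
  j0 <- max(1L, floor(cx - r - 1)); j1 <- min(w, ceiling(cx + r + 1))
  yy <- i0:i1; xx <- j0:j1
  d <- sqrt(outer((yy - cy)^2, (xx - cx)^2, "+"))
  rim <- pmin(pmax(r - d + 0.5, 0), 1)
  pallor <- 0.45 + 0.55 * pmin(d / r, 1)^2
  eo[yy, xx] <- eo[yy, xx] + 0.35 * rim * pallor
  mb[yy, xx] <- mb[yy, xx] + 0.01 * rim
  list(mb = mb, eo = eo)
}

# Render one leukocyte of the given class into mb/eo density matrices at
# center (cy, cx) with body radius R. All sub-feature sizes are relative to R
# so the same signatures serve field cells and large single-cell crops.
# Returns the updated maps.
.addLeukocyte <- function(mb, eo, class, cy, cx, R) {
  jit <- function(s) runif(1, -s, s) * R
  switch(class,
    lymphocyte = {
      # scant cytoplasm, big round dense nucleus
      eo <- .addDisk(eo, cy, cx, R, 0.03)
      mb <- .addDisk(mb, cy, cx, R, 0.15)
      mb <- .addDisk(mb, cy + jit(0.04), cx + jit(0.04), 0.80 * R, 2.0)
    },
    neutrophil = {
      eo <- .addDisk(eo, cy, cx, R, 0.40)  # pink cytoplasm
      mb <- .addDisk(mb, cy, cx, R, 0.08)
      nl <- sample(3:5, 1)
      rl <- 0.34 * R
      dcent <- min(0.9 * rl / sin(pi / nl), 0.5 * R)
      a0 <- runif(1, 0, 2 * pi)
      for (l in seq_len(nl)) {
        a <- a0 + 2 * pi * (l - 1) / nl
        mb <- .addDisk(mb, cy + dcent * sin(a), cx + dcent * cos(a), rl, 1.4)
      }
    },
    monocyte = {
      eo <- .addDisk(eo, cy, cx, R, 0.04)
      mb <- .addDisk(mb, cy, cx, R, 0.28)  # gray-blue cytoplasm
      mb <- .addKidney(mb, cy + jit(0.03), cx + jit(0.03), 0.75 * R, 1.3,
                       notchFrac = 0.7, notchDist = 0.85,
                       angle = runif(1, 0, 2 * pi))
    },
    eosinophil = {
      eo <- .addDisk(eo, cy, cx, R, 0.25)
      mb <- .addDisk(mb, cy, cx, R, 0.08)
      a <- runif(1, 0, 2 * pi)
      for (s in c(-1, 1))   # bilobed nucleus, lobes overlapping
        mb <- .addDisk(mb, cy + s * 0.33 * R * sin(a),
                       cx + s * 0.33 * R * cos(a), 0.40 * R, 1.5)
      for (g in seq_len(65)) {   # coarse bright eosin granules
        ga <- runif(1, 0, 2 * pi); gd <- runif(1, 0.25, 0.92) * R
        eo <- .addDisk(eo, cy + gd * sin(ga), cx + gd * cos(ga),
                       runif(1, 0.060, 0.100) * R, 1.5)
      }
    },
    basophil = {
      eo <- .addDisk(eo, cy, cx, R, 0.05)
      mb <- .addDisk(mb, cy, cx, R, 0.25)
      mb <- .addDisk(mb, cy + jit(0.04), cx + jit(0.04), 0.55 * R, 1.4)
      for (g in seq_len(70)) {   # dense dark-blue granules obscure the cell
        ga <- runif(1, 0, 2 * pi); gd <- runif(1, 0, 0.85) * R
        mb <- .addDisk(mb, cy + gd * sin(ga), cx + gd * cos(ga),
                       runif(1, 0.065, 0.105) * R, 1.8)
      }
    },
    promyelocyte = {
      # abnormal promyelocyte: large cell, eccentric kidney/bilobed nucleus,
      # heavy azurophilic (purple) granulation and rod-like inclusions
      eo <- .addDisk(eo, cy, cx, R, 0.18)
      mb <- .addDisk(mb, cy, cx, R, 0.12)
      na <- runif(1, 0, 2 * pi)
      mb <- .addKidney(mb, cy + 0.18 * R * sin(na), cx + 0.18 * R * cos(na),
                       0.72 * R, 1.7, notchFrac = 0.65, notchDist = 0.9,
                       angle = na + pi)
      for (g in seq_len(60)) {
        ga <- runif(1, 0, 2 * pi); gd <- runif(1, 0, 0.82) * R
        gy <- cy + gd * sin(ga); gx <- cx + gd * cos(ga)
        gr <- runif(1, 0.045, 0.080) * R
        mb <- .addDisk(mb, gy, gx, gr, 0.9)
        eo <- .addDisk(eo, gy, gx, gr, 0.70)
      }
      for (rod in seq_len(sample(1:2, 1))) {
        ra <- runif(1, 0, 2 * pi); rl <- 0.45 * R
        ry <- cy + jit(0.25); rx <- cx + jit(0.25)
        mb <- .addRod(mb, ry - rl * sin(ra), rx - rl * cos(ra),
                      ry + rl * sin(ra), rx + rl * cos(ra),
                      0.045 * R, 2.2)
        eo <- .addRod(eo, ry - rl * sin(ra), rx - rl * cos(ra),
                      ry + rl * sin(ra), rx + rl * cos(ra),
                      0.045 * R, 0.6)
      }
    },
    stop(sprintf("unknown leukocyte class '%s'", class)))
  list(mb = mb, eo = eo)
}

# rejection-sampled non-overlapping placement
.placeCells <- function(h, w, radii, allowOverlap, margin = 2) {
  n <- length(radii)
  ys <- numeric(n); xs <- numeric(n)
  placed <- 0L
  tries <- 0L
  cap <- 400L * max(n, 1L)
  while (placed < n) {
    tries <- tries + 1L
    if (tries > cap)
      stop("could not place all cells without overlap; ",
           "reduce cell counts or image density")
    r <- radii[placed + 1L]
    cy <- runif(1, r + margin, h - r - margin)
    cx <- runif(1, r + margin, w - r - margin)
    ok <- allowOverlap || placed == 0L ||
      all((ys[seq_len(placed)] - cy)^2 + (xs[seq_len(placed)] - cx)^2 >
            (radii[seq_len(placed)] + r + margin)^2)
    if (ok) {
      placed <- placed + 1L
      ys[placed] <- cy; xs[placed] <- cx
    }
  }
  list(y = ys, x = xs)
}

#' Generate a synthetic stained-smear field with ground truth
#'
#' Plants non-overlapping leukocytes (classes drawn from the recipe's mix)
#' and red cells, renders the stain density fields to RGB via the recipe's
#' Beer-Lambert stain model, adds Gaussian pixel noise and quantizes to 8
#' bits. Ground-truth boxes delimit each leukocyte's methylene-blue-dense
#' extent (density > 0.3), the same signal the focusing stage segments.
#'
#' @param recipe a \linkS4class{SmearRecipe}.
#' @return List with \code{image} (\linkS4class{SmearImage}),
#'   \code{groundTruth} (data.frame: x0, y0, width, height, area_px, label)
#'   and \code{cellParams} (data.frame of generative per-cell parameters).
#' @examples
#' sm <- generateSmear(smearRecipe(nLeukocytes = 3, nRedCells = 20, seed = 2))
#' sm$groundTruth
#' @export
generateSmear <- function(recipe = smearRecipe()) {
  stopifnot(is(recipe, "SmearRecipe"))
  validObject(recipe)
  set.seed(recipe@seed)
  h <- recipe@imageSize[1]; w <- recipe@imageSize[2]
  nL <- recipe@nLeukocytes; nR <- recipe@nRedCells
  classes <- if (nL > 0)
    sample(LEUKOCYTE_CLASSES, nL, replace = TRUE, prob = recipe@classMix)
  else character(0)
  radL <- runif(nL, 24, 32) * ifelse(classes == "promyelocyte", 1.25, 1)
  radR <- runif(nR, 8, 11)
  pos <- .placeCells(h, w, c(radL, radR), recipe@allowOverlap)
  mb <- matrix(0, h, w); eo <- matrix(0, h, w)
  gt <- vector("list", nL)
  for (i in seq_len(nL)) {
    before <- mb
    maps <- .addLeukocyte(mb, eo, classes[i], pos$y[i], pos$x[i], radL[i])
    mb <- maps$mb; eo <- maps$eo
    added <- mb - before
    gt[[i]] <- .densityBox(added, .GT_DENSITY, classes[i])
  }
  for (i in seq_len(nR)) {
    maps <- .addRedCell(mb, eo, pos$y[nL + i], pos$x[nL + i], radR[i])
    mb <- maps$mb; eo <- maps$eo
  }
  mb <- pmin(mb, .MB_MAX_DENSITY); eo <- pmin(eo, .EO_MAX_DENSITY)
  inten <- beerLambertForward(mb, eo, recipe@stainModel)
  if (recipe@noiseSd > 0)
    inten <- inten + rnorm(length(inten), sd = recipe@noiseSd)
  arr <- array(as.integer(round(pmin(pmax(inten, 0), 255))), dim(inten))
  gtDf <- if (nL > 0) do.call(rbind, gt) else
    data.frame(x0 = integer(), y0 = integer(), width = integer(),
               height = integer(), area_px = integer(), label = character())
  rownames(gtDf) <- NULL
  list(image = SmearImage(arr, sprintf("synthetic_seed%d", recipe@seed)),
       groundTruth = gtDf,
       cellParams = data.frame(
         label = c(classes, rep("red_cell", nR)),
         y = pos$y, x = pos$x, radius = c(radL, radR)),
       densities = list(methyleneBlue = mb, eosin = eo))
}

.densityBox <- function(dens, threshold, label) {
  idx <- which(dens > threshold)
  if (length(idx) == 0L)
    return(data.frame(x0 = NA_integer_, y0 = NA_integer_, width = 0L,
                      height = 0L, area_px = 0L, label = label))
  h <- nrow(dens)
  rows <- (idx - 1L) %% h
  cols <- (idx - 1L) %/% h
  data.frame(x0 = min(cols), y0 = min(rows),
             width = max(cols) - min(cols) + 1L,
             height = max(rows) - min(rows) + 1L,
             area_px = length(idx), label = label)
}

#' Generate a labeled single-cell crop dataset
#'
#' Renders centered single leukocytes of each class (plus a few peripheral red
#' cells) into classifier-ready square crops, balanced at \code{nPerClass} per
#' class or following an explicit per-class size vector (e.g. an imbalanced
#' clinical distribution). Deterministic for a given seed.
#'
#' @param nPerClass crops per class when \code{classSizes} is NULL.
#' @param seed integer seed.
#' @param classSizes optional integer 6-vector of per-class counts (order
#'   \code{LEUKOCYTE_CLASSES}), overriding \code{nPerClass}.
#' @param imageSize square crop size (default 224, the classifier input).
#' @param noiseSd Gaussian pixel noise sd (default 2).
#' @param stains a \linkS4class{StainModel}.
#' @return List with \code{x} (integer array imageSize x imageSize x 3 x n)
#'   and \code{y} (factor of class labels, levels \code{LEUKOCYTE_CLASSES}).
#' @examples
#' ds <- generateCellDataset(nPerClass = 2, seed = 1, imageSize = 64)
#' table(ds$y)
#' @export
generateCellDataset <- function(nPerClass = 100L, seed = 1L,
                                classSizes = NULL, imageSize = 224L,
                                noiseSd = 2, stains = defaultStainModel()) {
  if (is.null(classSizes)) classSizes <- rep(as.integer(nPerClass), 6L)
  stopifnot(length(classSizes) == 6L, all(classSizes >= 1L))
  set.seed(seed)
  n <- sum(classSizes)
  # shuffle the label sequence up front so class blocks are not ordered
  # (rendering directly in shuffled order avoids copying the pixel array)
  labels <- sample(rep(LEUKOCYTE_CLASSES, classSizes))
  x <- array(0L, c(imageSize, imageSize, 3L, n))
  for (i in seq_len(n))
    x[, , , i] <- .renderSingleCell(labels[i], imageSize, noiseSd, stains)
  list(x = x, y = factor(labels, levels = LEUKOCYTE_CLASSES))
}

.renderSingleCell <- function(class, size, noiseSd, stains) {
  mb <- matrix(0, size, size); eo <- matrix(0, size, size)
  R <- runif(1, 0.30, 0.38) * size *
    (if (class == "promyelocyte") 1.2 else 1)
  cy <- size / 2 + runif(1, -0.03, 0.03) * size
  cx <- size / 2 + runif(1, -0.03, 0.03) * size
  # a few peripheral red cells for context
  for (k in seq_len(3)) {
    a <- runif(1, 0, 2 * pi)
    d <- runif(1, 0.44, 0.52) * size
    maps <- .addRedCell(mb, eo, cy + d * sin(a), cx + d * cos(a),
                        runif(1, 0.04, 0.06) * size)
    mb <- maps$mb; eo <- maps$eo
  }
  maps <- .addLeukocyte(mb, eo, class, cy, cx, R)
  mb <- pmin(maps$mb, .MB_MAX_DENSITY); eo <- pmin(maps$eo, .EO_MAX_DENSITY)
  inten <- beerLambertForward(mb, eo, stains)
  if (noiseSd > 0) inten <- inten + rnorm(length(inten), sd = noiseSd)
  array(as.integer(round(pmin(pmax(inten, 0), 255))), dim(inten))
}
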