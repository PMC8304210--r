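# Leukocyte focusing: binarize the methylene-blue density map, find
# 8-connected components, emit bounding boxes and classifier-ready crops.

#' Binarize a methylene-blue density map
#'
#' Thresholds the density map (Otsu by default, or a fixed threshold), applies
#' morphological opening and hole filling, and removes components smaller than
#' \code{minArea}. A map whose maximum density does not exceed
#' \code{minDensity} yields an empty mask: Otsu on a signal-free map would
#' otherwise split noise into spurious foreground.
#'
#' @param mbMap non-negative height x width density matrix (from
#'   \code{\link{deconvolveStains}}).
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param threshold fixed threshold (required when \code{method = "fixed"}).
#' @param minArea smallest component size kept, in pixels (default 400).
#' @param minDensity density floor below which nothing is foreground
#'   (default 0.2); also a lower bound on the Otsu threshold.
#' @param openingSize diameter of the opening brush (odd, default 3).
#' @return Logical height x width matrix.
#' @examples
#' m <- matrix(0, 64, 64); m[20:39, 20:39] <- 2
#' mask <- binarizeLeukocyteMap(m, minArea = 50)
#' sum(mask)
#' @export
binarizeLeukocyteMap <- function(mbMap, method = c("otsu", "fixed"),
                                 threshold = NULL, minArea = 400,
                                 minDensity = 0.2, openingSize = 3) {
  method <- match.arg(method)
  stopifnot(is.matrix(mbMap))
  if (min(mbMap) < 0) stop("density map must be non-negative")
  mx <- max(mbMap)
  if (!is.finite(mx) || mx <= minDensity)
    return(matrix(FALSE, nrow(mbMap), ncol(mbMap)))
  th <- if (method == "fixed") {
    if (is.null(threshold)) stop("method 'fixed' requires a threshold")
    threshold
  } else {
    EBImage::otsu(EBImage::Image(mbMap / mx), range = c(0, 1)) * mx
  }
  th <- max(th, minDensity)
  mask <- mbMap > th
  if (!any(mask)) return(mask)
  img <- EBImage::Image(mask * 1)
  img <- EBImage::opening(img, EBImage::makeBrush(openingSize, "disc"))
  img <- EBImage::fillHull(img)
  mask <- matrix(as.numeric(img) > 0.5, nrow(mbMap), ncol(mbMap))
  .dropSmallComponents(mask, minArea)
}

.dropSmallComponents <- function(mask, minArea) {
  if (!any(mask) || minArea <= 1) return(mask)
  lab <- .label_components_8(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minArea)
  matrix(lab %in% keep & mask, nrow(mask), ncol(mask))
}

#' Bounding boxes of 8-connected mask components
#'
#' One box per 8-connected foreground component with pixel count at least
#' \code{minArea}. Boxes use 0-based, half-open pixel coordinates
#' ([x0, x0 + width) horizontally, [y0, y0 + height) vertically, x = column,
#' y = row) and are sorted by (y0, x0).
#'
#' @param mask logical height x width matrix.
#' @param minArea smallest component pixel count kept (default 400).
#' @return data.frame with columns x0, y0, width, height, area_px.
#' @examples
#' m <- matrix(FALSE, 64, 64); m[5:14, 3:10] <- TRUE
#' extractCellBoxes(m, minArea = 10)
#' @export
extractCellBoxes <- function(mask, minArea = 400) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  empty <- data.frame(x0 = integer(), y0 = integer(), width = integer(),
                      height = integer(), area_px = integer())
  if (!any(mask)) return(empty)
  lab <- .label_components_8(mask)
  idx <- which(lab > 0L)
  labv <- lab[idx]
  h <- nrow(mask)
  rows <- (idx - 1L) %% h          # 0-based row (y)
  cols <- (idx - 1L) %/% h         # 0-based col (x)
  area <- tabulate(labv)
  keep <- which(area >= minArea)
  if (length(keep) == 0L) return(empty)
  y0 <- tapply(rows, labv, min)[as.character(keep)]
  y1 <- tapply(rows, labv, max)[as.character(keep)]
  x0 <- tapply(cols, labv, min)[as.character(keep)]
  x1 <- tapply(cols, labv, max)[as.character(keep)]
  boxes <- data.frame(x0 = as.integer(x0), y0 = as.integer(y0),
                      width = as.integer(x1 - x0 + 1L),
                      height = as.integer(y1 - y0 + 1L),
                      area_px = as.integer(area[keep]))
  boxes <- boxes[order(boxes$y0, boxes$x0), , drop = FALSE]
  rownames(boxes) <- NULL
  boxes
}

# per-channel modal 8-bit color of an image array
.modalColor <- function(px) {
  vapply(1:3, function(c) {
    which.max(tabulate(as.integer(px[, , c]) + 1L, 256L)) - 1L
  }, integer(1))
}

#' Extract fixed-size classifier crops from bounding boxes
#'
#' Each box is expanded by \code{padFrac} on every side, clamped to the image,
#' padded to a square with the image's modal background color (so cells are
#' never stretched anisotropically) and resized to
#' \code{outSize} x \code{outSize}.
#'
#' @param image a \linkS4class{SmearImage} or height x width x 3 array.
#' @param boxes data.frame as returned by \code{\link{extractCellBoxes}}.
#' @param padFrac fractional margin added per side (default 0.15).
#' @param outSize output spatial size (default 224, the classifier input).
#' @return List of \linkS4class{CellCrop} objects.
#' @export
cropCells <- function(image, boxes, padFrac = 0.15, outSize = 224) {
  pm <- if (is(image, "SmearImage")) image@pixels else image
  srcId <- if (is(image, "SmearImage")) image@sourceId else "field"
  h <- dim(pm)[1]; w <- dim(pm)[2]
  if (nrow(boxes) == 0L) return(list())
  bad <- boxes$x0 < 0 | boxes$y0 < 0 |
    boxes$x0 + boxes$width > w | boxes$y0 + boxes$height > h
  if (any(bad))
    stop(sprintf("box %d lies outside the %d x %d image", which(bad)[1], h, w))
  bg <- .modalColor(pm)
  lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, , drop = FALSE]
    padx <- round(padFrac * b$width); pady <- round(padFrac * b$height)
    x0 <- max(0L, b$x0 - padx); x1 <- min(w, b$x0 + b$width + padx)
    y0 <- max(0L, b$y0 - pady); y1 <- min(h, b$y0 + b$height + pady)
    rw <- x1 - x0; rh <- y1 - y0
    side <- max(rw, rh)
    canvas <- array(rep(bg, each = side * side), c(side, side, 3))
    oy <- (side - rh) %/% 2; ox <- (side - rw) %/% 2
    canvas[(oy + 1):(oy + rh), (ox + 1):(ox + rw), ] <-
      pm[(y0 + 1):y1, (x0 + 1):x1, ]
    out <- .resizeRgb(canvas, outSize)
    new("CellCrop", pixels = out, originBox = boxes[i, , drop = FALSE],
        sourceId = srcId)
  })
}

.resizeRgb <- function(arr, outSize) {
  if (dim(arr)[1] == outSize && dim(arr)[2] == outSize) {
    storage.mode(arr) <- "integer"
    return(arr)
  }
  img <- EBImage::Image(arr / 255, colormode = "Color")
  img <- EBImage::resize(img, w = outSize, h = outSize)
  out <- as.array(img) * 255
  out <- array(as.integer(round(pmin(pmax(out, 0), 255))),
               c(outSize, outSize, 3))
  out
}

#' Locate and crop leukocytes in a field image
#'
#' Convenience wrapper for the full focusing stage: optional color
#' normalization, stain deconvolution, binarization of the methylene-blue map,
#' bounding boxes and fixed-size crops.
#'
#' @param image a \linkS4class{SmearImage} or height x width x 3 array.
#' @param stains a \linkS4class{StainModel}.
#' @param reference optional \linkS4class{ColorStats} for normalization
#'   (NULL skips normalization).
#' @param minArea,minDensity,openingSize,method,threshold passed to
#'   \code{\link{binarizeLeukocyteMap}} / \code{\link{extractCellBoxes}}.
#' @param padFrac,outSize passed to \code{\link{cropCells}}.
#' @return List with elements \code{boxes} (data.frame), \code{crops}
#'   (list of \linkS4class{CellCrop}), \code{maps}
#'   (\linkS4class{StainMaps}) and \code{mask}.
#' @examples
#' sm <- generateSmear(smearRecipe(nLeukocytes = 2, nRedCells = 10, seed = 7))
#' res <- focusLeukocytes(sm$image)
#' nrow(res$boxes)
#' @export
focusLeukocytes <- function(image, stains = defaultStainModel(),
                            reference = NULL, method = "otsu",
                            threshold = NULL, minArea = 400,
                            minDensity = 0.2, openingSize = 3,
                            padFrac = 0.15, outSize = 224) {
  if (!is.null(reference)) image <- normalizeColor(image, reference)
  maps <- deconvolveStains(image, stains)
  mask <- binarizeLeukocyteMap(maps@methyleneBlue, method = method,
                               threshold = threshold, minArea = minArea,
                               minDensity = minDensity,
                               openingSize = openingSize)
  boxes <- extractCellBoxes(mask, minArea = minArea)
  crops <- cropCells(image, boxes, padFrac = padFrac, outSize = outSize)
  list(boxes = boxes, crops = crops, maps = maps, mask = mask)
}

#' Read a field image from disk
#'
#' Reads PNG/TIFF/JPEG via EBImage and returns a \linkS4class{SmearImage}
#' (8-bit RGB).
#'
#' @param path image file path.
#' @param sourceId identifier; defaults to the file name without extension.
#' @return A \linkS4class{SmearImage}.
#' @export
readSmearImage <- function(path, sourceId = NULL) {
  img <- EBImage::readImage(path)
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3]
  a <- aperm(a, c(2, 1, 3))    # EBImage stores x (width) first
  arr <- array(as.integer(round(pmin(pmax(a, 0), 1) * 255)), dim(a))
  if (is.null(sourceId))
    sourceId <- sub("\\.[^.]*$", "", basename(path))
  SmearImage(arr, sourceId)
}

#' Write a SmearImage or CellCrop to disk
#'
#' @param image a \linkS4class{SmearImage} or \linkS4class{CellCrop}.
#' @param path output file path; format follows the extension (png/tiff/jpeg).
#' @return Invisibly, \code{path}.
#' @export
writeSmearImage <- function(image, path) {
  px <- pixels(image)
  a <- aperm(px / 255, c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Write bounding boxes as CSV
#'
#' Columns: source_id, x0, y0, width, height, area_px. A versioned schema
#' comment is written as the first line.
#'
#' @param boxes data.frame from \code{\link{extractCellBoxes}}.
#' @param path output CSV path.
#' @param sourceId field identifier recorded per row.
#' @param label optional per-box class labels (adds a label column).
#' @return Invisibly, \code{path}.
#' @export
writeBoxesCsv <- function(boxes, path, sourceId = "field", label = NULL) {
  df <- cbind(data.frame(source_id = rep(sourceId, length.out = nrow(boxes))),
              boxes)
  if (!is.null(label)) df$label <- label
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# aplScreen box schema v1", con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a boxes CSV written by \code{\link{writeBoxesCsv}}
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readBoxesCsv <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Write cell crops as PNG files
#'
#' Files are named \code{<sourceId>_<index>.png}.
#'
#' @param crops list of \linkS4class{CellCrop}.
#' @param dir output directory (created if missing).
#' @return Character vector of file paths, invisibly.
#' @export
writeCellCrops <- function(crops, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(crops), function(i) {
    p <- file.path(dir, sprintf("%s_%d.png", sourceId(crops[[i]]), i))
    writeSmearImage(crops[[i]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Intersection-over-union of two boxes
#'
#' Boxes are lists/rows with x0, y0, width, height in half-open pixel
#' coordinates.
#'
#' @param a,b boxes (one-row data.frames or lists).
#' @return IoU in [0, 1].
#' @export
boxIoU <- function(a, b) {
  ix <- max(0, min(a$x0 + a$width, b$x0 + b$width) - max(a$x0, b$x0))
  iy <- max(0, min(a$y0 + a$height, b$y0 + b$height) - max(a$y0, b$y0))
  inter <- ix * iy
  uni <- a$width * a$height + b$width * b$height - inter
  if (uni <= 0) return(0)
  inter / uni
}
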