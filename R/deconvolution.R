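# Beer-Lambert color deconvolution into methylene-blue and eosin densities.
#
# Optical density per channel: OD_c = -log((I_c + eps) / I0), eps = 1/255,
# I0 = 255 for 8-bit images. With stain matrix V (2 x 3, unit rows), a pixel's
# densities solve OD = t(V) %*% conc in the least-squares sense; negatives are
# clipped. The forward synthesis used by the generator and the tests,
# I = I0 * exp(-t(V) %*% conc) - eps, is the exact inverse, so noise-free
# round trips recover densities to machine precision.

.OD_EPS <- 1 / 255

#' Default methylene-blue / eosin stain model
#'
#' Unit-normalized optical-density color vectors for a Romanowsky-type stain:
#' methylene blue approximately (0.644, 0.717, 0.267) and eosin approximately
#' (0.093, 0.954, 0.283), with background intensity I0 = 255. Both are
#' configurable via \code{\link{stainModel}} or estimable from pure-stain
#' fields via \code{\link{estimateStainVectors}}.
#'
#' @return A \linkS4class{StainModel}.
#' @examples
#' defaultStainModel()
#' @export
defaultStainModel <- function() {
  stainModel(rbind(c(0.644, 0.717, 0.267),
                   c(0.093, 0.954, 0.283)))
}

#' Per-pixel optical density of an RGB image
#'
#' @param image a \linkS4class{SmearImage} or height x width x 3 array,
#'   values in [0, 255].
#' @param i0 background transmitted intensity.
#' @return A 3 x N matrix of optical densities (N = pixels).
#' @keywords internal
.opticalDensity <- function(image, i0) {
  pm <- .pixelMatrix(image)
  list(od = -log((pm$m + .OD_EPS) / i0), dim = pm$dim)
}

#' Deconvolve an RGB field into stain density maps
#'
#' Converts the image to optical density and solves, per pixel, the
#' least-squares system OD = t(V) c for the two stain concentrations,
#' clipping negative values to zero.
#'
#' @param image a \linkS4class{SmearImage} or height x width x 3 array.
#' @param stains a \linkS4class{StainModel}; default
#'   \code{\link{defaultStainModel}()}.
#' @return A \linkS4class{StainMaps} object with \code{methyleneBlue} and
#'   \code{eosin} density matrices of the image's spatial shape.
#' @examples
#' img <- array(255L, c(64, 64, 3))  # pure background
#' maps <- deconvolveStains(img)
#' max(methyleneBlue(maps))
#' @export
deconvolveStains <- function(image, stains = defaultStainModel()) {
  stopifnot(is(stains, "StainModel"))
  v <- stains@vectors
  gram <- v %*% t(v)
  if (abs(det(gram)) < 1e-8 || crossprodNorm(v) < 1e-3)
    stop("stain vectors are singular or near-parallel; deconvolution is ill-posed")
  odd <- .opticalDensity(image, stains@backgroundIntensity)
  solver <- solve(gram, v)          # 2 x 3: conc = solver %*% OD
  conc <- solver %*% odd$od
  conc[conc < 0] <- 0
  h <- odd$dim[1]; w <- odd$dim[2]
  new("StainMaps",
      methyleneBlue = matrix(conc[1, ], h, w),
      eosin = matrix(conc[2, ], h, w))
}

#' Beer-Lambert forward synthesis from stain densities
#'
#' Renders continuous RGB intensities from per-pixel methylene-blue and eosin
#' densities: I = I0 * exp(-t(V) c) - eps, the exact inverse of the density
#' estimator in \code{\link{deconvolveStains}}.
#'
#' @param mb,eo height x width matrices of non-negative stain densities.
#' @param stains a \linkS4class{StainModel}.
#' @return A numeric (not quantized) height x width x 3 array.
#' @examples
#' I <- beerLambertForward(matrix(1, 2, 2), matrix(0, 2, 2))
#' @export
beerLambertForward <- function(mb, eo, stains = defaultStainModel()) {
  stopifnot(identical(dim(mb), dim(eo)))
  v <- stains@vectors
  i0 <- stains@backgroundIntensity
  conc <- rbind(as.vector(mb), as.vector(eo))
  inten <- i0 * exp(-t(v) %*% conc) - .OD_EPS   # 3 x N
  array(as.vector(t(inten)), c(dim(mb), 3))
}

#' Estimate a stain vector from a field of one pure stain
#'
#' Takes the pixels whose optical-density magnitude exceeds a floor and
#' returns the unit-normalized mean optical-density direction. Run once per
#' stain on single-stain control fields to build a custom
#' \code{\link{stainModel}}.
#'
#' @param image a \linkS4class{SmearImage} or height x width x 3 array showing
#'   a single stain.
#' @param i0 background intensity (default 255).
#' @param minOd minimum OD magnitude for a pixel to contribute (default 0.15).
#' @return Unit numeric 3-vector.
#' @export
estimateStainVectors <- function(image, i0 = 255, minOd = 0.15) {
  odd <- .opticalDensity(image, i0)
  mag <- sqrt(colSums(odd$od^2))
  keep <- mag > minOd
  if (!any(keep))
    stop("no stained pixels above the OD floor; cannot estimate a stain vector")
  v <- rowMeans(odd$od[, keep, drop = FALSE])
  v / sqrt(sum(v^2))
}
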