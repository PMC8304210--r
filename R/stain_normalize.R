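# Color statistics and Reinhard-style stain-appearance normalization.
#
# The default working space is Reinhard's l-alpha-beta: RGB -> LMS (3x3),
# log10, then the decorrelating rotation. Mean/sd matching in that space is
# the standard recipe for transferring stain appearance between fields.

.rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                     0.1967, 0.7244, 0.0782,
                     0.0241, 0.1288, 0.8444),
                   nrow = 3, byrow = TRUE)
.lms2rgb <- solve(.rgb2lms)
.lms2lab <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), nrow = 3, byrow = TRUE)
.lab2lms <- solve(.lms2lab)
.LOG_EPS <- 1e-6

# pixels: 3 x N matrix in [0,1] -> 3 x N l-alpha-beta
.rgbToLab <- function(px) {
  lms <- pmax(.rgb2lms %*% px, .LOG_EPS)
  .lms2lab %*% log10(lms)
}

.labToRgb <- function(lab) {
  lms <- 10^(.lab2lms %*% lab)
  .lms2rgb %*% lms
}

.pixelMatrix <- function(image) {
  px <- if (is(image, "SmearImage")) image@pixels else image
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("expected a height x width x 3 pixel array")
  d <- dim(px)
  m <- matrix(as.numeric(px), d[1] * d[2], 3)
  list(m = t(m), dim = d)
}

#' Per-channel color statistics of a field image
#'
#' Computes the channel means and standard deviations of an RGB image in the
#' requested working space. These statistics drive
#' \code{\link{normalizeColor}}.
#'
#' @param image a \linkS4class{SmearImage} or a height x width x 3 array with
#'   values in [0, 255].
#' @param space \code{"lab"} (Reinhard l-alpha-beta, default) or \code{"rgb"}.
#' @return A \linkS4class{ColorStats} object.
#' @examples
#' img <- array(128L, c(64, 64, 3))
#' computeColorStats(img, space = "rgb")
#' @export
computeColorStats <- function(image, space = c("lab", "rgb")) {
  space <- match.arg(space)
  pm <- .pixelMatrix(image)
  x <- if (space == "lab") .rgbToLab(pm$m / 255) else pm$m
  n <- ncol(x)
  mu <- rowMeans(x)
  va <- rowSums((x - mu)^2) / n   # population sd, matches the normalizer
  new("ColorStats", mean = unname(mu), sd = unname(sqrt(va)), space = space)
}

#' Construct ColorStats directly
#'
#' @param mean,sd numeric 3-vectors.
#' @param space \code{"lab"} or \code{"rgb"}.
#' @return A \linkS4class{ColorStats} object.
#' @export
colorStats <- function(mean, sd, space = c("lab", "rgb")) {
  space <- match.arg(space)
  new("ColorStats", mean = as.numeric(mean), sd = as.numeric(sd),
      space = space)
}

#' Reinhard-style color normalization against reference statistics
#'
#' Linearly transforms every channel (in the reference's working space) so its
#' mean and standard deviation match the reference, then converts back to
#' 8-bit RGB, clipping to [0, 255]. A source channel with zero spread cannot
#' be rescaled; it is set to the reference mean (degenerate rule).
#'
#' @param image a \linkS4class{SmearImage} or height x width x 3 array.
#' @param reference a \linkS4class{ColorStats}, e.g. from
#'   \code{\link{computeColorStats}} on a reference field.
#' @return An object of the same kind as \code{image} with normalized pixels.
#' @examples
#' img <- array(sample(0:255, 64 * 64 * 3, TRUE), c(64, 64, 3))
#' ref <- colorStats(c(100, 120, 140), c(10, 10, 10), "rgb")
#' out <- normalizeColor(img, ref)
#' @export
normalizeColor <- function(image, reference) {
  stopifnot(is(reference, "ColorStats"))
  if (any(!is.finite(reference@mean)) || any(!is.finite(reference@sd)))
    stop("reference statistics must be finite")
  pm <- .pixelMatrix(image)
  lab <- reference@space == "lab"
  x <- if (lab) .rgbToLab(pm$m / 255) else pm$m
  n <- ncol(x)
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / n)
  for (c in 1:3) {
    if (sdv[c] < 1e-12) {
      x[c, ] <- reference@mean[c]
    } else {
      x[c, ] <- (x[c, ] - mu[c]) * (reference@sd[c] / sdv[c]) +
        reference@mean[c]
    }
  }
  out <- if (lab) .labToRgb(x) * 255 else x
  out <- round(pmin(pmax(out, 0), 255))
  arr <- array(as.integer(t(out)), pm$dim)
  if (is(image, "SmearImage")) SmearImage(arr, image@sourceId) else arr
}
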