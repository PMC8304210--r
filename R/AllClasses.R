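#' SmearImage: an RGB microscopy field
#'
#' Holds an 8-bit RGB field image as an integer array of dimension
#' height x width x 3 with values in [0, 255], plus a source identifier.
#'
#' @slot pixels integer array, height x width x 3, values 0-255.
#' @slot sourceId character scalar identifying the field.
#'
#' @export
setClass("SmearImage",
  representation(pixels = "array", sourceId = "character"),
  validity = function(object) {
    p <- object@pixels
    d <- dim(p)
    if (length(d) != 3L || d[3] != 3L)
      return("pixels must be a height x width x 3 array")
    if (d[1] < 64L || d[2] < 64L)
      return("field images must be at least 64 x 64 pixels")
    if (anyNA(p) || min(p) < 0 || max(p) > 255)
      return("pixel values must lie in [0, 255]")
    if (length(object@sourceId) != 1L)
      return("sourceId must be a single string")
    TRUE
  })

#' Construct a SmearImage
#'
#' @param pixels numeric or integer array height x width x 3, values 0-255.
#' @param sourceId identifier string.
#' @return A \linkS4class{SmearImage}.
#' @examples
#' img <- SmearImage(array(128L, c(64, 64, 3)), "example")
#' dim(pixels(img))
#' @export
SmearImage <- function(pixels, sourceId = "field") {
  storage.mode(pixels) <- "integer"
  new("SmearImage", pixels = pixels, sourceId = as.character(sourceId))
}

#' StainModel: stain vectors and background intensity for deconvolution
#'
#' A 2 x 3 matrix of unit optical-density color vectors (row 1 methylene blue,
#' row 2 eosin) and the background transmitted intensity I0.
#'
#' @slot vectors 2 x 3 numeric matrix, rows unit-norm.
#' @slot backgroundIntensity positive scalar I0 (default 255).
#'
#' @export
setClass("StainModel",
  representation(vectors = "matrix", backgroundIntensity = "numeric"),
  validity = function(object) {
    v <- object@vectors
    if (!all(dim(v) == c(2L, 3L)))
      return("vectors must be a 2 x 3 matrix (rows: methylene blue, eosin)")
    nrm <- sqrt(rowSums(v^2))
    if (any(abs(nrm - 1) > 1e-6))
      return("each stain vector must have unit Euclidean norm (within 1e-6)")
    cp <- crossprodNorm(v)
    if (cp < 1e-6)
      return("stain vectors are linearly dependent")
    if (length(object@backgroundIntensity) != 1L ||
        object@backgroundIntensity <= 0)
      return("backgroundIntensity must be a positive scalar")
    TRUE
  })

# norm of the 3D cross product of the two stain rows (0 iff parallel)
crossprodNorm <- function(v) {
  a <- v[1, ]; b <- v[2, ]
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  sqrt(sum(cr^2))
}

#' Construct a StainModel
#'
#' Rows are normalized to unit length.
#'
#' @param vectors 2 x 3 matrix of optical-density color vectors
#'   (rows: methylene blue, eosin).
#' @param backgroundIntensity transmitted background intensity I0.
#' @return A \linkS4class{StainModel}.
#' @examples
#' stainModel(rbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11)))
#' @export
stainModel <- function(vectors, backgroundIntensity = 255) {
  vectors <- as.matrix(vectors)
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("stain vectors must be nonzero")
  vectors <- vectors / nrm
  rownames(vectors) <- c("methylene_blue", "eosin")
  colnames(vectors) <- c("R", "G", "B")
  new("StainModel", vectors = vectors,
      backgroundIntensity = backgroundIntensity)
}

#' ColorStats: per-channel mean and standard deviation
#'
#' @slot mean numeric 3-vector of channel means.
#' @slot sd numeric 3-vector of channel standard deviations (>= 0).
#' @slot space character, \code{"lab"} (Reinhard l-alpha-beta) or \code{"rgb"}.
#'
#' @export
setClass("ColorStats",
  representation(mean = "numeric", sd = "numeric", space = "character"),
  validity = function(object) {
    if (length(object@mean) != 3L || length(object@sd) != 3L)
      return("mean and sd must be 3-vectors")
    if (any(object@sd < 0)) return("sd components must be >= 0")
    if (!object@space %in% c("lab", "rgb"))
      return("space must be 'lab' or 'rgb'")
    TRUE
  })

#' StainMaps: per-stain density maps
#'
#' @slot methyleneBlue non-negative height x width matrix of densities.
#' @slot eosin non-negative height x width matrix of densities.
#'
#' @export
setClass("StainMaps",
  representation(methyleneBlue = "matrix", eosin = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@methyleneBlue), dim(object@eosin)))
      return("stain maps must share the same spatial shape")
    if (min(object@methyleneBlue) < 0 || min(object@eosin) < 0)
      return("densities must be non-negative")
    TRUE
  })

#' CellCrop: a fixed-size classifier-ready cell image
#'
#' @slot pixels integer array outSize x outSize x 3 (default 224).
#' @slot originBox one-row data.frame with the source bounding box
#'   (columns x0, y0, width, height, area_px; 0-based, half-open).
#' @slot sourceId identifier of the originating field.
#'
#' @export
setClass("CellCrop",
  representation(pixels = "array", originBox = "data.frame",
                 sourceId = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[1] != d[2] || d[3] != 3L)
      return("crop pixels must be a square size x size x 3 array")
    if (min(object@pixels) < 0 || max(object@pixels) > 255)
      return("pixel values must lie in [0, 255]")
    TRUE
  })

#' CompactNetConfig: architecture description of the compact classifier
#'
#' The canonical configuration has four conv blocks (64, 128, 256, 256
#' channels; conv strides 1, 1, 2, 1; each block = 3x3 conv, channel
#' normalization, ReLU, 3x3/2 max pool), a squeeze-and-excitation channel
#' attention module (ratio 16) on the final feature map, and two
#' fully-connected layers (512, then one logit per class), with dropout 0.5
#' after each fully-connected layer. Input is a 224 x 224 x 3 crop.
#'
#' @slot blockChannels integer vector of conv output channels per block.
#' @slot blockStrides integer vector of conv strides (1 or 2) per block.
#' @slot useSE logical, include the channel-attention module.
#' @slot seRatio integer compression ratio of the SE bottleneck.
#' @slot gate character, \code{"softmax"} or \code{"sigmoid"} SE gate.
#' @slot useDropout logical, apply dropout after the FC layers in training.
#' @slot dropoutRate numeric dropout probability.
#' @slot fc0Width integer width of the first fully-connected layer.
#' @slot nClasses integer number of output classes.
#' @slot inputSize integer input spatial size (square).
#'
#' @export
setClass("CompactNetConfig",
  representation(blockChannels = "integer", blockStrides = "integer",
                 useSE = "logical", seRatio = "integer", gate = "character",
                 useDropout = "logical", dropoutRate = "numeric",
                 fc0Width = "integer", nClasses = "integer",
                 inputSize = "integer"),
  validity = function(object) {
    if (length(object@blockChannels) < 1L)
      return("at least one conv block is required")
    if (length(object@blockChannels) != length(object@blockStrides))
      return("blockChannels and blockStrides must have equal length")
    if (!all(object@blockStrides %in% c(1L, 2L)))
      return("conv strides must be 1 or 2")
    if (!object@gate %in% c("softmax", "sigmoid"))
      return("gate must be 'softmax' or 'sigmoid'")
    if (object@useSE) {
      cFinal <- object@blockChannels[length(object@blockChannels)]
      if (cFinal %% object@seRatio != 0L)
        return(sprintf(
          "final channel count %d is not divisible by the SE ratio %d",
          cFinal, object@seRatio))
    }
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
      return("dropoutRate must lie in [0, 1)")
    sizes <- featureMapSideLengths(object@inputSize, object@blockStrides)
    if (any(sizes < 1L))
      return("input size too small for the requested number of blocks")
    TRUE
  })

#' CompactNet: an instantiated compact classifier
#'
#' Wraps the native network state (an external pointer) together with its
#' configuration. The pointer is rebuilt transparently from the stored
#' parameter list after deserialization.
#'
#' @slot config a \linkS4class{CompactNetConfig}.
#' @slot state environment holding the native pointer, the parameter list and
#'   the input normalization constants.
#'
#' @export
setClass("CompactNet",
  representation(config = "CompactNetConfig", state = "environment"))

#' CBCPanel: complete blood count inputs for risk stratification
#'
#' @slot wbc white-blood-cell count, x10^9/L.
#' @slot platelets platelet count, x10^9/L.
#'
#' @export
setClass("CBCPanel",
  representation(wbc = "numeric", platelets = "numeric"),
  validity = function(object) {
    if (length(object@wbc) != 1L || length(object@platelets) != 1L)
      return("wbc and platelets must be scalars")
    if (!is.finite(object@wbc) || !is.finite(object@platelets))
      return("wbc and platelets must be finite")
    if (object@wbc < 0 || object@platelets < 0)
      return("counts must be non-negative")
    TRUE
  })

#' Construct a CBCPanel
#'
#' @param wbc white-blood-cell count, x10^9/L.
#' @param platelets platelet count, x10^9/L.
#' @return A \linkS4class{CBCPanel}.
#' @examples
#' cbcPanel(wbc = 2.1, platelets = 63)
#' @export
cbcPanel <- function(wbc, platelets) {
  new("CBCPanel", wbc = as.numeric(wbc), platelets = as.numeric(platelets))
}

#' DiagnosticOpinion: advisory screening result
#'
#' @slot suspectedApl logical flag.
#' @slot risk character, one of \code{"low"}, \code{"intermediate"},
#'   \code{"high"}.
#' @slot potentialTreatment advisory treatment string (empty when not
#'   suspected).
#' @slot evidence list with the cell count summary behind the opinion.
#' @slot note fixed not-for-clinical-use disclaimer plus any run notes.
#'
#' @export
setClass("DiagnosticOpinion",
  representation(suspectedApl = "logical", risk = "character",
                 potentialTreatment = "character", evidence = "list",
                 note = "character"),
  validity = function(object) {
    if (!object@risk %in% c("low", "intermediate", "high"))
      return("risk must be low, intermediate or high")
    if (object@suspectedApl && !nzchar(object@potentialTreatment))
      return("a suspected-APL opinion must carry a treatment string")
    if (!object@suspectedApl && nzchar(object@potentialTreatment))
      return("treatment must be empty when APL is not suspected")
    TRUE
  })

#' SmearRecipe: parameters of the synthetic smear generator
#'
#' @slot imageSize integer (height, width) of the field.
#' @slot nLeukocytes integer number of leukocytes to plant.
#' @slot nRedCells integer number of red cells to plant.
#' @slot classMix numeric 6-vector of class probabilities (sums to 1).
#' @slot stainModel the \linkS4class{StainModel} used for Beer-Lambert
#'   rendering.
#' @slot noiseSd Gaussian pixel noise standard deviation, 8-bit units.
#' @slot allowOverlap logical; if TRUE cells may overlap (demonstrates the
#'   known failure mode of the focusing stage; default FALSE).
#' @slot seed integer seed controlling all randomness of the recipe.
#'
#' @export
setClass("SmearRecipe",
  representation(imageSize = "integer", nLeukocytes = "integer",
                 nRedCells = "integer", classMix = "numeric",
                 stainModel = "StainModel", noiseSd = "numeric",
                 allowOverlap = "logical", seed = "integer"),
  validity = function(object) {
    if (length(object@imageSize) != 2L || any(object@imageSize < 64L))
      return("imageSize must be two integers >= 64")
    if (object@nLeukocytes < 0L || object@nRedCells < 0L)
      return("cell counts must be >= 0")
    if (length(object@classMix) != 6L ||
        abs(sum(object@classMix) - 1) > 1e-9 || any(object@classMix < 0))
      return("classMix must be 6 non-negative probabilities summing to 1")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    TRUE
  })
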