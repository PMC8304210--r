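#' @name accessors
#' @title Accessors for aplScreen classes
#' @param object an aplScreen S4 object.
#' @return The slot value (see each method).
NULL

#' @describeIn accessors pixel array of a SmearImage or CellCrop.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @describeIn accessors source identifier.
#' @export
setGeneric("sourceId", function(object) standardGeneric("sourceId"))

#' @describeIn accessors 2 x 3 stain optical-density matrix.
#' @export
setGeneric("stainVectors", function(object) standardGeneric("stainVectors"))

#' @describeIn accessors background transmitted intensity I0.
#' @export
setGeneric("backgroundIntensity",
           function(object) standardGeneric("backgroundIntensity"))

#' @describeIn accessors methylene-blue density map of StainMaps.
#' @export
setGeneric("methyleneBlue", function(object) standardGeneric("methyleneBlue"))

#' @describeIn accessors eosin density map of StainMaps.
#' @export
setGeneric("eosin", function(object) standardGeneric("eosin"))

#' @describeIn accessors risk tag of a DiagnosticOpinion.
#' @export
setGeneric("risk", function(object) standardGeneric("risk"))

#' @describeIn accessors suspected-APL flag of a DiagnosticOpinion.
#' @export
setGeneric("suspectedApl", function(object) standardGeneric("suspectedApl"))

#' @describeIn accessors advisory treatment string of a DiagnosticOpinion.
#' @export
setGeneric("potentialTreatment",
           function(object) standardGeneric("potentialTreatment"))

setMethod("pixels", "SmearImage", function(object) object@pixels)
setMethod("pixels", "CellCrop", function(object) object@pixels)
setMethod("sourceId", "SmearImage", function(object) object@sourceId)
setMethod("sourceId", "CellCrop", function(object) object@sourceId)
setMethod("stainVectors", "StainModel", function(object) object@vectors)
setMethod("backgroundIntensity", "StainModel",
          function(object) object@backgroundIntensity)
setMethod("methyleneBlue", "StainMaps", function(object) object@methyleneBlue)
setMethod("eosin", "StainMaps", function(object) object@eosin)
setMethod("risk", "DiagnosticOpinion", function(object) object@risk)
setMethod("suspectedApl", "DiagnosticOpinion",
          function(object) object@suspectedApl)
setMethod("potentialTreatment", "DiagnosticOpinion",
          function(object) object@potentialTreatment)

setMethod("show", "SmearImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SmearImage '%s': %d x %d RGB field\n",
              object@sourceId, d[1], d[2]))
})

setMethod("show", "StainModel", function(object) {
  cat(sprintf("StainModel (I0 = %g)\n", object@backgroundIntensity))
  print(round(object@vectors, 4))
})

setMethod("show", "StainMaps", function(object) {
  d <- dim(object@methyleneBlue)
  cat(sprintf(
    "StainMaps %d x %d; max density mb = %.3f, eo = %.3f\n",
    d[1], d[2], max(object@methyleneBlue), max(object@eosin)))
})

setMethod("show", "CellCrop", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CellCrop %d x %d from '%s' (box %d,%d %dx%d)\n",
              d[1], d[2], object@sourceId,
              object@originBox$x0, object@originBox$y0,
              object@originBox$width, object@originBox$height))
})

setMethod("show", "CompactNetConfig", function(object) {
  cat("CompactNetConfig\n")
  cat("  blocks:  ", paste(object@blockChannels, collapse = ", "),
      " (strides ", paste(object@blockStrides, collapse = ", "), ")\n",
      sep = "")
  cat(sprintf("  SE:      %s (ratio %d, gate %s)\n",
              ifelse(object@useSE, "yes", "no"), object@seRatio, object@gate))
  cat(sprintf("  dropout: %s (rate %.2f)\n",
              ifelse(object@useDropout, "yes", "no"), object@dropoutRate))
  cat(sprintf("  FC:      %d -> %d; input %d x %d x 3\n",
              object@fc0Width, object@nClasses,
              object@inputSize, object@inputSize))
})

setMethod("show", "CompactNet", function(object) {
  acct <- modelAccount(object@config)
  cat(sprintf("CompactNet: %s parameters, %s MACs per input\n",
              format(acct$nParameters, big.mark = ","),
              format(acct$macCount, big.mark = ",")))
  show(object@config)
})

setMethod("show", "CBCPanel", function(object) {
  cat(sprintf("CBCPanel: WBC %.1f x10^9/L, platelets %.1f x10^9/L\n",
              object@wbc, object@platelets))
})

setMethod("show", "DiagnosticOpinion", function(object) {
  cat("DiagnosticOpinion\n")
  cat(sprintf("  suspected APL: %s\n", object@suspectedApl))
  cat(sprintf("  risk:          %s\n", object@risk))
  if (nzchar(object@potentialTreatment))
    cat(sprintf("  treatment:     %s\n", object@potentialTreatment))
  cat(sprintf("  note: %s\n", object@note[1]))
})

setMethod("show", "SmearRecipe", function(object) {
  cat(sprintf(
    "SmearRecipe %d x %d: %d leukocytes, %d red cells, noise sd %.1f, seed %d\n",
    object@imageSize[1], object@imageSize[2], object@nLeukocytes,
    object@nRedCells, object@noiseSd, object@seed))
})
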