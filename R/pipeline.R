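# End-to-end orchestration: focusing -> classification -> diagnostic opinion,
# with reproducible configuration and standard-format outputs.

#' Create a run configuration
#'
#' A nested, YAML-round-trippable list of stage parameters. Every pipeline run
#' writes the fully resolved configuration beside its outputs.
#'
#' @param seed global seed (default 1).
#' @param outputDir output directory or NA for no file output.
#' @param logLevel \code{"info"} or \code{"quiet"}.
#' @param focus named list overriding focusing parameters (minArea,
#'   minDensity, openingSize, padFrac, outSize, method, threshold).
#' @param diagnosis named list overriding diagnosis parameters
#'   (minPromyelocytes).
#' @param normalizeToReference logical: normalize each field to the reference
#'   color statistics before deconvolution (default FALSE; enable when fields
#'   come from heterogeneous staining batches).
#' @return A list of class \code{"RunConfig"}.
#' @examples
#' cfg <- runConfig(seed = 7)
#' cfg$focus$minArea
#' @export
runConfig <- function(seed = 1L, outputDir = NA_character_,
                      logLevel = "info",
                      focus = list(), diagnosis = list(),
                      normalizeToReference = FALSE) {
  base <- list(
    version = 1L,
    seed = as.integer(seed),
    outputDir = outputDir,
    logLevel = logLevel,
    normalizeToReference = normalizeToReference,
    focus = list(minArea = 400L, minDensity = 0.2, openingSize = 3L,
                 padFrac = 0.15, outSize = 224L, method = "otsu",
                 threshold = NA_real_),
    diagnosis = list(minPromyelocytes = 1L))
  base$focus[names(focus)] <- focus
  base$diagnosis[names(diagnosis)] <- diagnosis
  structure(base, class = c("RunConfig", "list"))
}

#' Write / read a run configuration as YAML
#'
#' @param config a \code{\link{runConfig}} list.
#' @param path YAML file path.
#' @return \code{writeRunConfig}: the path, invisibly; \code{readRunConfig}:
#'   the configuration.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  structure(yaml::read_yaml(path), class = c("RunConfig", "list"))
}

#' Reference color statistics for normalization
#'
#' Statistics of a deterministic reference synthetic field, usable as the
#' normalization target when fields come from heterogeneous staining batches.
#'
#' @param space \code{"lab"} or \code{"rgb"}.
#' @return A \linkS4class{ColorStats}.
#' @export
defaultReferenceStats <- function(space = c("lab", "rgb")) {
  space <- match.arg(space)
  sm <- generateSmear(smearRecipe(seed = 20210711L))
  computeColorStats(sm$image, space = space)
}

#' Read a directory-per-class labeled image tree
#'
#' Expects one subdirectory per class (the layout of the public single-cell
#' leukocyte datasets). Unknown directory names are rejected unless a mapping
#' from directory name to canonical class is supplied.
#'
#' @param root dataset root directory.
#' @param mapping optional named character vector: names are directory names,
#'   values canonical classes in \code{LEUKOCYTE_CLASSES}.
#' @param extensions image file extensions to accept.
#' @return data.frame manifest with columns \code{path} and \code{label}.
#' @export
readClassTree <- function(root, mapping = NULL,
                          extensions = c("png", "tiff", "tif", "jpg",
                                         "jpeg")) {
  if (!dir.exists(root)) stop(sprintf("directory '%s' does not exist", root))
  dirs <- list.dirs(root, recursive = FALSE, full.names = TRUE)
  if (length(dirs) == 0L) stop(sprintf("'%s' contains no class directories", root))
  rows <- lapply(dirs, function(d) {
    nm <- basename(d)
    label <- if (nm %in% LEUKOCYTE_CLASSES) nm
    else if (!is.null(mapping) && nm %in% names(mapping)) {
      cl <- unname(mapping[nm])
      if (!cl %in% LEUKOCYTE_CLASSES)
        stop(sprintf("mapping for '%s' targets unknown class '%s'", nm, cl))
      cl
    } else stop(sprintf(
      "unknown class directory '%s' (supply a mapping to canonical classes)",
      nm))
    pat <- paste0("\\.(", paste(extensions, collapse = "|"), ")$")
    files <- list.files(d, pattern = pat, ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) return(NULL)
    data.frame(path = files, label = label)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop(sprintf("no image files found under '%s'", root))
  rownames(out) <- NULL
  out
}

#' Run the three-stage pipeline on field images
#'
#' Per field: (optional) color normalization, stain deconvolution,
#' binarization of the methylene-blue map, bounding boxes, fixed-size crops,
#' classification. Classified counts are aggregated into a cell count summary;
#' the CBC panel is stratified into a risk level; and an advisory opinion is
#' rendered. Evaluation is deterministic: the same inputs, model and
#' configuration give identical outputs.
#'
#' @param fields character vector of image paths, or a list of
#'   \linkS4class{SmearImage} objects.
#' @param model a trained \linkS4class{CompactNet}.
#' @param cbc a \linkS4class{CBCPanel}.
#' @param config a \code{\link{runConfig}} list.
#' @param stains a \linkS4class{StainModel}.
#' @param reference optional \linkS4class{ColorStats} used when
#'   \code{config$normalizeToReference} is TRUE (default:
#'   \code{\link{defaultReferenceStats}}).
#' @return List with \code{opinion} (\linkS4class{DiagnosticOpinion}),
#'   \code{predictions} (data.frame: source_id, cell index, box, predicted
#'   class and per-class probabilities) and \code{summary} (the cell count
#'   summary). When \code{config$outputDir} is set, predictions CSV, opinion
#'   JSON, the resolved YAML config and a run log are written there.
#' @export
runPipeline <- function(fields, model, cbc, config = runConfig(),
                        stains = defaultStainModel(), reference = NULL) {
  stopifnot(is(model, "CompactNet"), is(cbc, "CBCPanel"))
  fc <- config$focus
  if (isTRUE(config$normalizeToReference) && is.null(reference))
    reference <- defaultReferenceStats()
  logLines <- c(sprintf("aplScreen pipeline run, seed %d", config$seed),
                sprintf("R %s, aplScreen %s", getRversion(),
                        as.character(utils::packageVersion("aplScreen"))))
  predRows <- list()
  skipped <- 0L
  for (f in seq_along(fields)) {
    img <- tryCatch({
      if (is.character(fields)) readSmearImage(fields[f]) else fields[[f]]
    }, error = function(e) e)
    if (inherits(img, "error")) {
      warning(sprintf("skipping unreadable field %s", fields[f]))
      logLines <- c(logLines, sprintf("WARN unreadable field: %s", fields[f]))
      skipped <- skipped + 1L
      next
    }
    res <- focusLeukocytes(
      img, stains = stains,
      reference = if (isTRUE(config$normalizeToReference)) reference else NULL,
      method = fc$method,
      threshold = if (is.na(fc$threshold)) NULL else fc$threshold,
      minArea = fc$minArea, minDensity = fc$minDensity,
      openingSize = fc$openingSize, padFrac = fc$padFrac,
      outSize = fc$outSize)
    if (nrow(res$boxes) == 0L) next
    probs <- predictProbs(model, res$crops)
    pred <- LEUKOCYTE_CLASSES[max.col(probs, ties.method = "first")]
    df <- cbind(data.frame(source_id = sourceId(img),
                           cell = seq_len(nrow(res$boxes))),
                res$boxes,
                data.frame(predicted = pred))
    predRows[[length(predRows) + 1L]] <- cbind(df, as.data.frame(probs))
  }
  predictions <- if (length(predRows) > 0) do.call(rbind, predRows) else
    data.frame()
  counts <- vapply(LEUKOCYTE_CLASSES, function(cl) {
    if (nrow(predictions) == 0L) 0L else
      sum(predictions$predicted == cl)
  }, integer(1))
  summary <- cellCountSummary(counts, nFields = length(fields))
  riskLevel <- stratifyRisk(cbc)
  note <- if (summary$total == 0L) "no leukocytes found" else NULL
  opinion <- renderOpinion(summary, riskLevel,
                           minPromyelocytes = config$diagnosis$minPromyelocytes,
                           note = note)
  logLines <- c(logLines,
                sprintf("fields: %d (%d skipped), cells: %d",
                        length(fields), skipped, summary$total),
                sprintf("risk: %s, suspected APL: %s", riskLevel,
                        opinion@suspectedApl))
  if (!is.na(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    writePredictionsCsv(predictions,
                        file.path(config$outputDir, "predictions.csv"))
    writeOpinion(opinion, file.path(config$outputDir, "opinion.json"))
    writeRunConfig(config, file.path(config$outputDir, "config.yaml"))
    writeLines(logLines, file.path(config$outputDir, "run.log"))
  }
  list(opinion = opinion, predictions = predictions, summary = summary)
}

#' Write per-cell predictions as CSV
#'
#' @param predictions data.frame from \code{\link{runPipeline}}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writePredictionsCsv <- function(predictions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# aplScreen predictions schema v1", con)
  write.csv(predictions, con, row.names = FALSE)
  invisible(path)
}
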