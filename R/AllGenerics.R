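#' @name ramanoid-accessors
#' @title Accessors for ramanoid classes
#' @description Read-only accessors for the S4 containers:
#' \code{wavenumbers()} returns the Raman-shift axis (cm-1);
#' \code{intensities()} the raw intensity block of a cube;
#' \code{cubeMeta()} the sample annotation of a cube as a list;
#' \code{spectraMatrix()} the channels x spectra intensity matrix;
#' \code{spectraLabels()} the per-spectrum annotation;
#' \code{pcaScores()}, \code{pcaLoadings()}, \code{varExplained()} the PCA
#' fields; \code{foldAccuracies()}, \code{confusionMatrix()},
#' \code{perClassMetrics()}, \code{pcImportance()},
#' \code{borutaDecisions()} the classification-report fields.
#' @param x an object of the documented class.
#' @return The slot value described above.
NULL

#' @rdname ramanoid-accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))
#' @rdname ramanoid-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname ramanoid-accessors
#' @export
setGeneric("cubeMeta", function(x) standardGeneric("cubeMeta"))
#' @rdname ramanoid-accessors
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))
#' @rdname ramanoid-accessors
#' @export
setGeneric("spectraLabels", function(x) standardGeneric("spectraLabels"))
#' @rdname ramanoid-accessors
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))
#' @rdname ramanoid-accessors
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))
#' @rdname ramanoid-accessors
#' @export
setGeneric("varExplained", function(x) standardGeneric("varExplained"))
#' @rdname ramanoid-accessors
#' @export
setGeneric("foldAccuracies", function(x) standardGeneric("foldAccuracies"))
#' @rdname ramanoid-accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
#' @rdname ramanoid-accessors
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))
#' @rdname ramanoid-accessors
#' @export
setGeneric("pcImportance", function(x) standardGeneric("pcImportance"))
#' @rdname ramanoid-accessors
#' @export
setGeneric("borutaDecisions", function(x) standardGeneric("borutaDecisions"))

#' @rdname ramanoid-accessors
setMethod("wavenumbers", "RamanCube", function(x) x@wavenumber)
#' @rdname ramanoid-accessors
setMethod("wavenumbers", "RamanSpectra", function(x)
  SummarizedExperiment::rowData(x)$wavenumber)
#' @rdname ramanoid-accessors
setMethod("wavenumbers", "RamanPCA", function(x) x@wavenumber)
#' @rdname ramanoid-accessors
setMethod("intensities", "RamanCube", function(x) x@intensities)
#' @rdname ramanoid-accessors
setMethod("cubeMeta", "RamanCube", function(x)
  list(line = x@line, organoid_id = x@organoidId,
       stage_weeks = x@stageWeeks, fov_id = x@fovId, pitch_um = x@pitchUm))
#' @rdname ramanoid-accessors
setMethod("spectraMatrix", "RamanSpectra", function(x)
  SummarizedExperiment::assay(x, "intensity"))
#' @rdname ramanoid-accessors
setMethod("spectraLabels", "RamanSpectra", function(x)
  SummarizedExperiment::colData(x))
#' @rdname ramanoid-accessors
setMethod("pcaScores", "RamanPCA", function(x) x@scores)
#' @rdname ramanoid-accessors
setMethod("pcaLoadings", "RamanPCA", function(x) x@loadings)
#' @rdname ramanoid-accessors
setMethod("varExplained", "RamanPCA", function(x) x@varExplained)
#' @rdname ramanoid-accessors
setMethod("foldAccuracies", "StageClassification", function(x)
  x@foldAccuracies)
#' @rdname ramanoid-accessors
setMethod("confusionMatrix", "StageClassification", function(x) x@confusion)
#' @rdname ramanoid-accessors
setMethod("perClassMetrics", "StageClassification", function(x) x@perClass)
#' @rdname ramanoid-accessors
setMethod("pcImportance", "StageClassification", function(x) x@importances)
#' @rdname ramanoid-accessors
setMethod("borutaDecisions", "StageClassification", function(x) x@boruta)

setMethod("show", "StudyDesign", function(object) {
  stages <- vapply(object@profiles, function(p) p$stage_weeks, integer(1))
  lines <- vapply(object@profiles, function(p) p$line, character(1))
  cat("StudyDesign:", length(object@profiles), "group profile(s)",
      sprintf("(stages %s; lines %s)\n",
              paste(unique(stages), collapse = "/"),
              paste(unique(lines), collapse = "/")))
  cat(sprintf("  %d organoid(s)/group x %d FOV(s)/organoid, FOV %dx%d px, %d channels\n",
              object@organoidsPerStage, object@fovsPerOrganoid,
              object@fovHeight, object@fovWidth, object@nChannels))
  cat(sprintf("  effectScale %.2f, noiseSd %.3g, cosmicRayRate %.3g, seed %d\n",
              object@effectScale, object@noiseSd, object@cosmicRayRate,
              object@seed))
})

setMethod("show", "RamanCube", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("RamanCube %dx%d px x %d channels (%.0f-%.0f cm-1)\n",
              d[1], d[2], d[3], min(object@wavenumber),
              max(object@wavenumber)))
  cat(sprintf("  line %s, organoid %s, stage %d wk, FOV %s, pitch %.2g um\n",
              object@line, object@organoidId, object@stageWeeks,
              object@fovId, object@pitchUm))
})

setMethod("show", "RamanPCA", function(object) {
  cat(sprintf("RamanPCA: %d components x %d channels, %d spectra\n",
              nrow(object@loadings), ncol(object@loadings),
              nrow(object@scores)))
  cat(sprintf("  cumulative variance explained: %.1f%%\n",
              100 * sum(object@varExplained)))
})

setMethod("show", "StageClassification", function(object) {
  cat(sprintf("StageClassification: %d classes\n", nrow(object@confusion)))
  if (length(object@foldAccuracies))
    cat(sprintf("  CV accuracy %.2f%% +/- %.2f%% over %d folds\n",
                100 * mean(object@foldAccuracies),
                100 * sd(object@foldAccuracies),
                length(object@foldAccuracies)))
  if (length(object@boruta))
    cat("  relevance:", sum(object@boruta == "confirmed"), "confirmed /",
        sum(object@boruta == "tentative"), "tentative /",
        sum(object@boruta == "rejected"), "rejected\n")
})
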