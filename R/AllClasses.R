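#' Band components of the synthetic Raman signal
#'
#' A band component is one vibrational line: a named peak with a center (in
#' Raman shift, cm-1), a half-width at half-maximum (cm-1) and a line shape
#' (Lorentzian, the natural shape of Raman lines, or Gaussian).
#' `bandComponents()` builds the component table; `defaultBands()` returns
#' the seven biomarker bands used throughout: nucleic-acid ring breathing
#' (788 cm-1), glycogen (850 cm-1), polysaccharide C-C stretch (940 cm-1),
#' phenylalanine (1004 cm-1), amide III protein (1350 cm-1), lipid CH2
#' scissoring (1440 cm-1) and amide I protein (1650 cm-1).
#'
#' @param name character vector of band names.
#' @param center numeric vector of band centers (cm-1).
#' @param width numeric vector of half-widths at half-maximum (cm-1).
#' @param shape character, \code{"lorentzian"} or \code{"gaussian"}, recycled.
#' @return A data.frame with columns \code{name}, \code{center},
#'   \code{width}, \code{shape}.
#' @examples
#' defaultBands()
#' @export
bandComponents <- function(name, center, width, shape = "lorentzian") {
  stopifnot(length(name) == length(center), length(center) == length(width))
  if (any(width <= 0)) stop("band width must be > 0")
  shape <- rep_len(match.arg(shape, c("lorentzian", "gaussian"),
                             several.ok = TRUE), length(name))
  data.frame(name = as.character(name), center = as.numeric(center),
             width = as.numeric(width), shape = shape,
             stringsAsFactors = FALSE)
}

#' @rdname bandComponents
#' @export
defaultBands <- function() {
  bandComponents(
    name   = c("nucleic_acids", "glycogen", "polysaccharide",
               "phenylalanine", "amide_III", "lipid_CH2", "amide_I"),
    center = c(788, 850, 940, 1004, 1350, 1440, 1650),
    width  = c(8, 10, 10, 6, 14, 12, 14))
}

#' Study design for synthetic organoid Raman acquisitions
#'
#' Describes a simulated acquisition campaign: one stage profile per
#' (maturation stage, cell line) group, the number of organoids per group
#' and fields of view (FOVs) per organoid, the FOV raster size and spectral
#' channel count, and the generative nuisance parameters (noise, polynomial
#' autofluorescence baseline, cosmic-ray rate, multiplicative organoid/FOV
#' random effects, and an optional class-independent broad nuisance
#' component).
#'
#' @slot profiles list of stage profiles; each a list with elements
#'   \code{stage_weeks} (integer), \code{line} (character) and
#'   \code{concentrations} (named nonnegative numeric, one entry per band
#'   in \code{bands}).
#' @slot bands data.frame of band components (see [bandComponents()]).
#' @slot organoidsPerStage,fovsPerOrganoid integer counts (>= 1).
#' @slot fovHeight,fovWidth FOV raster size in pixels.
#' @slot nChannels number of raw spectral channels.
#' @slot effectScale multiplier (>= 0) on between-group amplitude
#'   differences; 0 collapses all groups onto the mean profile (null model).
#' @slot noiseSd per-channel Gaussian noise SD (intensity units).
#' @slot baselineCoeffMean,baselineCoeffSd mean and SD of the 6 polynomial
#'   baseline coefficients (degree <= 5), drawn per pixel spectrum.
#' @slot cosmicRayRate expected cosmic-ray spikes per spectrum (Poisson).
#' @slot organoidSd,fovSd SDs (log scale) of the multiplicative log-normal
#'   organoid- and FOV-level intensity effects.
#' @slot nuisanceSd SD of a per-spectrum random amplitude on a fixed broad
#'   spectral hump, independent of group; models substrate background that
#'   dominates the leading variance direction.
#' @slot compositionSd log-scale SD of a per-pixel, per-band log-normal
#'   jitter on the band amplitudes; models local biochemical
#'   heterogeneity between pixels (different cells and cytoplasm mixes),
#'   which varies the relative band composition independently of group.
#' @slot pitchUm pixel pitch in micrometers.
#' @slot seed integer seed from which all per-cube streams are derived.
#' @export
setClass("StudyDesign", representation(
  profiles = "list", bands = "data.frame",
  organoidsPerStage = "integer", fovsPerOrganoid = "integer",
  fovHeight = "integer", fovWidth = "integer", nChannels = "integer",
  effectScale = "numeric", noiseSd = "numeric",
  baselineCoeffMean = "numeric", baselineCoeffSd = "numeric",
  cosmicRayRate = "numeric", organoidSd = "numeric", fovSd = "numeric",
  nuisanceSd = "numeric", compositionSd = "numeric",
  pitchUm = "numeric", seed = "integer"))

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (length(object@profiles) < 1) msg <- c(msg, "need >= 1 stage profile")
  for (p in object@profiles) {
    if (!all(c("stage_weeks", "line", "concentrations") %in% names(p)))
      msg <- c(msg, "each profile needs stage_weeks, line, concentrations")
    else if (any(p$concentrations < 0))
      msg <- c(msg, "band amplitudes must be >= 0")
  }
  counts <- c(object@organoidsPerStage, object@fovsPerOrganoid,
              object@fovHeight, object@fovWidth)
  if (any(counts < 1L)) msg <- c(msg, "counts and dimensions must be >= 1")
  if (object@nChannels < 2L) msg <- c(msg, "nChannels must be >= 2")
  sds <- c(object@effectScale, object@noiseSd, object@baselineCoeffSd,
           object@cosmicRayRate, object@organoidSd, object@fovSd,
           object@nuisanceSd, object@compositionSd)
  if (any(sds < 0)) msg <- c(msg, "scales, SDs and rates must be >= 0")
  if (length(object@baselineCoeffMean) > 6L)
    msg <- c(msg, "baseline polynomial degree must be <= 5")
  if (length(msg)) msg else TRUE
})

#' One hyperspectral Raman field of view
#'
#' Holds the H x W x C intensity block of one field of view (FOV), the
#' wavenumber axis (cm-1, strictly increasing, length C), and the sample
#' annotation (cell line, organoid id, maturation stage in weeks, FOV id,
#' pixel pitch in micrometers).
#'
#' @slot intensities 3-dimensional numeric array, H x W x C, nonnegative.
#' @slot wavenumber numeric length C, strictly increasing (cm-1).
#' @slot line,organoidId,fovId character scalars.
#' @slot stageWeeks integer scalar.
#' @slot pitchUm numeric scalar (micrometers).
#' @export
setClass("RamanCube", representation(
  intensities = "array", wavenumber = "numeric",
  line = "character", organoidId = "character", stageWeeks = "integer",
  fovId = "character", pitchUm = "numeric"))

setValidity("RamanCube", function(object) {
  d <- dim(object@intensities)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "intensities must be a 3-d array")
  else {
    if (d[3] != length(object@wavenumber))
      msg <- c(msg, "wavenumber length must equal the channel dimension")
    if (d[1] < 1L || d[2] < 1L) msg <- c(msg, "H and W must be >= 1")
  }
  if (length(object@wavenumber) < 2L ||
      any(diff(object@wavenumber) <= 0))
    msg <- c(msg, "wavenumber axis must be strictly increasing, length >= 2")
  if (length(msg)) msg else TRUE
})

#' Preprocessed Raman spectra with sample labels
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"intensity"}
#' (channels x spectra), \code{rowData} column \code{wavenumber} (cm-1) and
#' \code{colData} columns \code{stage_weeks}, \code{line}, \code{organoid_id}
#' and \code{fov_id}. This is the flat table handed to PCA and
#' classification; columns are individual (binned) pixel spectra.
#'
#' @export
setClass("RamanSpectra", contains = "SummarizedExperiment")

setValidity("RamanSpectra", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  if (!"wavenumber" %in% names(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData column 'wavenumber' is required")
  else {
    wn <- SummarizedExperiment::rowData(object)$wavenumber
    if (any(diff(wn) <= 0)) msg <- c(msg, "wavenumber must be increasing")
  }
  need <- c("stage_weeks", "line", "organoid_id", "fov_id")
  if (!all(need %in% names(SummarizedExperiment::colData(object))))
    msg <- c(msg, paste("colData needs columns:",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Principal component model of a spectrum table
#'
#' Centered (covariance) PCA of the spectra: the mean spectrum, unit-norm
#' loading vectors (components x channels), per-spectrum scores
#' (spectra x components) and explained-variance fractions. Loading signs
#' follow a fixed convention: each loading is flipped so that its
#' largest-magnitude element is positive.
#'
#' @slot center mean spectrum (length C).
#' @slot loadings k x C matrix, orthonormal rows.
#' @slot scores N x k matrix.
#' @slot varExplained length-k fractions, nonincreasing, in [0, 1].
#' @slot wavenumber axis of the fitted channels (cm-1).
#' @slot labels \code{DataFrame} of per-spectrum annotation.
#' @export
setClass("RamanPCA", representation(
  center = "numeric", loadings = "matrix", scores = "matrix",
  varExplained = "numeric", wavenumber = "numeric", labels = "DataFrame"))

setValidity("RamanPCA", function(object) {
  msg <- character()
  k <- nrow(object@loadings)
  if (ncol(object@loadings) != length(object@center))
    msg <- c(msg, "loadings/center channel mismatch")
  if (ncol(object@scores) != k) msg <- c(msg, "scores/loadings mismatch")
  if (length(object@varExplained) != k)
    msg <- c(msg, "varExplained length mismatch")
  if (any(object@varExplained < -1e-8 | object@varExplained > 1 + 1e-8))
    msg <- c(msg, "explained fractions must lie in [0, 1]")
  if (any(diff(object@varExplained) > 1e-8))
    msg <- c(msg, "explained fractions must be nonincreasing")
  if (length(msg)) msg else TRUE
})

#' Classification report for stage / line prediction
#'
#' Bundles the cross-validated fold accuracies, the hold-out confusion
#' matrix (rows = true class, columns = predicted class), per-class
#' precision / recall / F1, the impurity-based per-feature importances
#' (normalized to sum 1) and, when run, the shadow-feature relevance
#' decisions (confirmed / tentative / rejected per feature).
#'
#' @slot foldAccuracies numeric vector of per-fold accuracies in [0, 1].
#' @slot confusion integer K x K matrix, true x predicted.
#' @slot perClass data.frame with precision, recall, f1 per class.
#' @slot importances named nonnegative numeric summing to 1.
#' @slot boruta named character vector (may be empty) with values
#'   \code{"confirmed"}, \code{"tentative"} or \code{"rejected"}.
#' @slot config list of the settings used (trees, folds, seed, features).
#' @export
setClass("StageClassification", representation(
  foldAccuracies = "numeric", confusion = "matrix", perClass = "data.frame",
  importances = "numeric", boruta = "character", config = "list"))

setValidity("StageClassification", function(object) {
  msg <- character()
  if (any(object@foldAccuracies < 0 | object@foldAccuracies > 1))
    msg <- c(msg, "fold accuracies must lie in [0, 1]")
  if (length(object@importances) &&
      (any(object@importances < 0) ||
       abs(sum(object@importances) - 1) > 1e-8))
    msg <- c(msg, "importances must be >= 0 and sum to 1")
  if (nrow(object@confusion) && ncol(object@confusion) &&
      nrow(object@confusion) != ncol(object@confusion))
    msg <- c(msg, "confusion matrix must be square")
  if (length(msg)) msg else TRUE
})
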