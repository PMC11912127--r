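#' Run a full analysis experiment into an output directory
#'
#' End-to-end orchestration: synthetic generation + preprocessing
#' (streamed), PCA, random-forest classification with cross-validation,
#' band-trend quantification and separability analysis, with every
#' artifact written to \code{outDir}:
#' \itemize{
#'   \item \code{design.json}, \code{manifest.json} (config, package
#'     version, seed),
#'   \item \code{spectra.csv} (labels + channel columns),
#'   \item \code{pca_loadings.csv}, \code{pca_summary.json},
#'   \item \code{classification.json}, \code{confusion.csv},
#'   \item \code{bands.csv} (per-band group summaries and tests),
#'   \item \code{separability.json}, \code{distances.csv}.
#' }
#' Reruns with the same design and seed reproduce every number.
#'
#' @param design a \linkS4class{StudyDesign} or a preset name for
#'   [ramanPreset()].
#' @param outDir output directory (created if missing).
#' @param labelColumn class label to predict (default
#'   \code{"stage_weeks"}; use \code{"line"} for the cell-line
#'   comparison).
#' @param pcIndices PC features for the classifier (default \code{1:25}).
#' @param nComponents components fitted by the PCA (default 25).
#' @param k cross-validation folds.
#' @param nTrees forest size.
#' @param boruta run shadow-feature selection.
#' @param separabilityPCs components for the centroid-distance analysis.
#' @param bands band table for the trend analysis.
#' @param config a [preprocessConfig()].
#' @param seed integer seed for every stochastic stage.
#' @param writeSpectra logical; write the (possibly large) spectra CSV.
#' @return invisibly, a list with the in-memory results
#'   (\code{spectra}, \code{pca}, \code{classification}, \code{bands},
#'   \code{separability}, \code{outDir}).
#' @export
runExperiment <- function(design, outDir, labelColumn = "stage_weeks",
                          pcIndices = 1:25, nComponents = max(pcIndices),
                          k = 10L, nTrees = 50L, boruta = FALSE,
                          separabilityPCs = c(1, 2, 4),
                          bands = defaultBands(),
                          config = preprocessConfig(), seed = 1L,
                          writeSpectra = TRUE) {
  if (is.character(design)) design <- ramanPreset(design, seed = seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeDesignJson(design, file.path(outDir, "design.json"))

  spectra <- preprocessStudy(design, config)
  if (writeSpectra) writeSpectraCsv(spectra, file.path(outDir,
                                                       "spectra.csv"))

  pca <- fitPCA(spectra, nComponents = nComponents)
  utils::write.csv(
    data.frame(wavenumber = wavenumbers(pca), t(pcaLoadings(pca))),
    file.path(outDir, "pca_loadings.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_components = nComponents,
         var_explained = varExplained(pca),
         n_spectra = nrow(pcaScores(pca))),
    file.path(outDir, "pca_summary.json"), auto_unbox = TRUE, digits = NA)

  cls <- classifyStages(pca, labelColumn = labelColumn,
                        pcIndices = pcIndices, nTrees = nTrees, k = k,
                        boruta = boruta, seed = seed)
  jsonlite::write_json(
    list(label = labelColumn, pc_indices = pcIndices,
         fold_accuracies = foldAccuracies(cls),
         accuracy_mean = mean(foldAccuracies(cls)),
         accuracy_sd = sd(foldAccuracies(cls)),
         per_class = perClassMetrics(cls),
         importances = as.list(pcImportance(cls)),
         boruta = as.list(borutaDecisions(cls))),
    file.path(outDir, "classification.json"), auto_unbox = TRUE,
    digits = NA)
  utils::write.csv(confusionMatrix(cls),
                   file.path(outDir, "confusion.csv"))

  groupBy <- if (labelColumn == "line") "line" else "stage_weeks"
  bt <- bandTrendAnalysis(spectra, bands = bands, groupBy = groupBy)
  bandRows <- do.call(rbind, lapply(names(bt), function(nm) {
    g <- bt[[nm]]$groups
    g$band <- nm
    t <- bt[[nm]]$tests
    t$band <- nm
    merge(g, t, by = "band")
  }))
  utils::write.csv(bandRows, file.path(outDir, "bands.csv"),
                   row.names = FALSE)

  sep <- separabilityAnalysis(pca, groupBy = groupBy,
                              pcIndices = separabilityPCs)
  jsonlite::write_json(
    list(pc_indices = sep$pcIndices, threshold = sep$threshold,
         centroids = as.data.frame(sep$centroids),
         distances = as.data.frame(sep$distances),
         intervals = sep$intervals),
    file.path(outDir, "separability.json"), auto_unbox = TRUE,
    digits = NA)
  utils::write.csv(sep$distances, file.path(outDir, "distances.csv"))

  jsonlite::write_json(
    list(package = "ramanoid",
         version = as.character(utils::packageVersion("ramanoid")),
         seed = seed, label_column = labelColumn,
         pc_indices = pcIndices, k_folds = k, n_trees = nTrees,
         preprocess = unclass(config),
         n_spectra = ncol(spectra),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(spectra = spectra, pca = pca, classification = cls,
                 bands = bt, separability = sep, outDir = outDir))
}
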