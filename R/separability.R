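#' Euclidean distances between group centroids in PC space
#'
#' Computes the per-group mean of the selected score columns and the
#' pairwise Euclidean distances between those centroids; the distances
#' quantify how well maturation stages separate in the reduced space.
#'
#' @param scores spectra x components score matrix.
#' @param labels group label per row.
#' @param pcIndices 1-based columns to use (default: all); the stage
#'   analysis focuses on the most discriminative components, e.g.
#'   PC1/PC2/PC4.
#' @return list with \code{centroids} (group x component matrix) and
#'   \code{distances} (symmetric group x group matrix).
#' @export
centroidDistances <- function(scores, labels, pcIndices = NULL) {
  scores <- as.matrix(scores)
  if (!is.null(pcIndices)) scores <- selectComponents(scores, pcIndices)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) stop("need at least 2 groups")
  if (any(table(labels) == 0L)) labels <- droplevels(labels)
  cen <- do.call(rbind, lapply(levels(labels), function(g)
    colMeans(scores[labels == g, , drop = FALSE])))
  rownames(cen) <- levels(labels)
  list(centroids = cen, distances = as.matrix(stats::dist(cen)))
}

#' Minimum detectable maturation interval per adjacent stage pair
#'
#' Extrapolates the smallest time interval at which two stages would
#' remain separable, assuming centroid distance grows linearly with the
#' time gap: for an adjacent pair at \eqn{t_a < t_b} with centroid
#' distance \eqn{d}, \eqn{\Delta t_{min} = threshold \cdot (t_b - t_a) /
#' d}. The threshold defaults to 0.85, the distance of the weakest
#' still-separable pair in the four-stage analysis. A zero distance is
#' reported as non-separable rather than a number.
#'
#' @param distances symmetric group x group distance matrix whose
#'   dimnames (or order) correspond to \code{stageWeeks}.
#' @param stageWeeks numeric stage ages in weeks, ordered, one per group.
#' @param threshold separability threshold in score-distance units.
#' @return data.frame with one row per adjacent pair: \code{from_weeks},
#'   \code{to_weeks}, \code{distance}, \code{separable},
#'   \code{min_interval_weeks} (NA when non-separable).
#' @export
minDetectableInterval <- function(distances, stageWeeks,
                                  threshold = 0.85) {
  if (threshold <= 0) stop("threshold must be > 0")
  stageWeeks <- as.numeric(stageWeeks)
  if (is.unsorted(stageWeeks, strictly = TRUE))
    stop("stageWeeks must be strictly increasing")
  if (nrow(distances) != length(stageWeeks))
    stop("distance matrix and stageWeeks size mismatch")
  n <- length(stageWeeks)
  out <- data.frame(from_weeks = stageWeeks[-n], to_weeks = stageWeeks[-1L],
                    distance = NA_real_, separable = NA,
                    min_interval_weeks = NA_real_)
  for (i in seq_len(n - 1L)) {
    d <- distances[i, i + 1L]
    out$distance[i] <- d
    out$separable[i] <- d > 0
    out$min_interval_weeks[i] <- if (d > 0)
      threshold * (stageWeeks[i + 1L] - stageWeeks[i]) / d else NA_real_
  }
  out
}

#' Separability analysis of a PCA model
#'
#' Convenience wrapper: group centroids and distances on the selected
#' components, plus the minimum detectable interval per adjacent stage
#' pair when grouping by stage.
#'
#' @param pca a \linkS4class{RamanPCA}.
#' @param groupBy label column (default \code{"stage_weeks"}).
#' @param pcIndices components used (default \code{c(1, 2, 4)}, the most
#'   discriminative set in the four-stage analysis).
#' @param threshold separability threshold (default 0.85).
#' @return list with \code{pcIndices}, \code{threshold},
#'   \code{centroids}, \code{distances} and (stage grouping only)
#'   \code{intervals}.
#' @export
separabilityAnalysis <- function(pca, groupBy = "stage_weeks",
                                 pcIndices = c(1, 2, 4),
                                 threshold = 0.85) {
  labels <- pca@labels[[groupBy]]
  cd <- centroidDistances(pca@scores, labels, pcIndices)
  res <- list(pcIndices = as.integer(pcIndices), threshold = threshold,
              centroids = cd$centroids, distances = cd$distances)
  if (groupBy == "stage_weeks")
    res$intervals <- minDetectableInterval(
      cd$distances, sort(unique(as.numeric(as.character(labels)))),
      threshold)
  res
}
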