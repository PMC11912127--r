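#' Importance-weighted sum of PCA loadings
#'
#' Linear combination of loading vectors weighted by the classifier's
#' feature importances, \eqn{W(\nu) = \sum_j w_j \, L_j(\nu)}. This
#' spectral signature emphasizes the wavenumber regions that drive the
#' classification, pointing at the discriminating biomarker bands.
#'
#' @param model a \linkS4class{RamanPCA}.
#' @param importances numeric weights, aligned with
#'   \code{componentIndices}.
#' @param componentIndices 1-based components to combine (default: the
#'   first \code{length(importances)}).
#' @return numeric signature vector over channels.
#' @export
weightedLoadingSum <- function(model, importances,
                               componentIndices = seq_along(importances)) {
  componentIndices <- as.integer(componentIndices)
  if (length(importances) != length(componentIndices))
    stop("importances and componentIndices length mismatch")
  if (any(componentIndices < 1L) ||
      any(componentIndices > nrow(model@loadings)))
    stop("component index out of range")
  as.vector(crossprod(model@loadings[componentIndices, , drop = FALSE],
                      importances))
}

.trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)

#' Trapezoidal band area of a spectrum
#'
#' Integrates the spectrum over the window \code{center +/- halfwidth}
#' (cm-1). Spectra entering this quantification are already
#' baseline-corrected, so no local chord is subtracted.
#'
#' @param x numeric spectrum.
#' @param axis wavenumber axis (cm-1).
#' @param center band center (cm-1).
#' @param halfwidth window half-width (cm-1, default 10).
#' @return the trapezoidal integral (intensity * cm-1).
#' @export
integrateBand <- function(x, axis, center, halfwidth = 10) {
  if (center - halfwidth < min(axis) || center + halfwidth > max(axis))
    stop("band window [", center - halfwidth, ", ", center + halfwidth,
         "] falls outside the axis")
  idx <- which(axis >= center - halfwidth & axis <= center + halfwidth)
  if (length(idx) < 2L) stop("band window contains fewer than 2 channels")
  .trapz(axis[idx], x[idx])
}

#' Mann-Whitney rank test for a two-group location difference
#'
#' Returns the U statistic (with midrank ties) and the two-sided p-value:
#' the exact rank-sum distribution for small tie-free samples (both
#' groups <= 20), the normal approximation with tie correction otherwise.
#'
#' @param a,b numeric vectors (both nonempty).
#' @return list with \code{U} and \code{p}.
#' @export
mannWhitneyTest <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0L
  small <- length(a) <= 20L && length(b) <= 20L
  wt <- suppressWarnings(wilcox.test(a, b, exact = small && !ties,
                                     correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Band-area trends across maturation stages or cell lines
#'
#' For every band, computes the trapezoidal area of each spectrum,
#' summarizes the areas per group (n, median, quartiles), and runs
#' Mann-Whitney tests between groups: consecutive pairs when grouping by
#' stage (the natural ordering in weeks), all pairs when grouping by
#' line. Significance is flagged at the raw p < 0.05 level by default;
#' Benjamini-Hochberg adjustment is available.
#'
#' @param spectra a \linkS4class{RamanSpectra}.
#' @param bands band table with columns \code{name}, \code{center} (and
#'   optionally \code{halfwidth}); defaults to [defaultBands()].
#' @param groupBy \code{"stage_weeks"} or \code{"line"}.
#' @param halfwidth default window half-width (cm-1) for bands without
#'   their own.
#' @param adjust \code{"none"} (default, raw p-values) or \code{"BH"}.
#' @param alpha significance level (default 0.05).
#' @return named list (one element per band) of lists with \code{band},
#'   \code{areas} (per-spectrum, with group), \code{groups} (summary
#'   data.frame) and \code{tests} (data.frame with U, p, significant).
#' @export
bandTrendAnalysis <- function(spectra, bands = defaultBands(),
                              groupBy = c("stage_weeks", "line"),
                              halfwidth = 10, adjust = c("none", "BH"),
                              alpha = 0.05) {
  groupBy <- match.arg(groupBy)
  adjust <- match.arg(adjust)
  labels <- spectraLabels(spectra)
  if (!groupBy %in% names(labels)) stop("unknown grouping key: ", groupBy)
  grp <- labels[[groupBy]]
  lev <- if (groupBy == "stage_weeks") sort(unique(grp)) else
    sort(unique(as.character(grp)))
  if (length(lev) < 2L) stop("need at least 2 groups")
  pairs <- if (groupBy == "stage_weeks")
    cbind(lev[-length(lev)], lev[-1L]) else t(utils::combn(lev, 2L))
  axis <- wavenumbers(spectra)
  mat <- spectraMatrix(spectra)
  hw <- if ("halfwidth" %in% names(bands)) bands$halfwidth else
    rep_len(halfwidth, nrow(bands))

  out <- list()
  for (b in seq_len(nrow(bands))) {
    idx <- which(axis >= bands$center[b] - hw[b] &
                   axis <= bands$center[b] + hw[b])
    if (length(idx) < 2L)
      stop("band ", bands$name[b], " window has fewer than 2 channels")
    areas <- apply(mat[idx, , drop = FALSE], 2L, .trapz, x = axis[idx])
    groups <- do.call(rbind, lapply(lev, function(g) {
      v <- areas[grp == g]
      data.frame(group = g, n = length(v), median = median(v),
                 q1 = unname(quantile(v, 0.25)),
                 q3 = unname(quantile(v, 0.75)))
    }))
    tests <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      mw <- mannWhitneyTest(areas[grp == pairs[i, 1L]],
                            areas[grp == pairs[i, 2L]])
      data.frame(group_a = pairs[i, 1L], group_b = pairs[i, 2L],
                 U = mw$U, p = mw$p)
    }))
    tests$p_adjusted <- if (adjust == "BH")
      stats::p.adjust(tests$p, "BH") else tests$p
    tests$significant <- tests$p_adjusted < alpha
    out[[bands$name[b]]] <- list(
      band = bands[b, , drop = FALSE],
      areas = data.frame(group = grp, area = unname(areas)),
      groups = groups, tests = tests)
  }
  out
}
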