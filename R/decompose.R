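#' Principal component analysis of a spectrum table
#'
#' Centered covariance PCA (rows are already normalized by preprocessing,
#' so no per-channel rescaling is applied). Scores are the centered
#' spectra projected on the loadings; explained-variance fractions are the
#' covariance eigenvalues divided by the total variance. Each loading is
#' sign-flipped so its largest-magnitude element is positive, making
#' downstream weighted loading sums reproducible.
#'
#' @param spectra a \linkS4class{RamanSpectra}.
#' @param nComponents number of components to keep
#'   (<= min(spectra, channels)); the stage analyses use 25.
#' @return a \linkS4class{RamanPCA}.
#' @export
fitPCA <- function(spectra, nComponents = 25L) {
  X <- t(spectraMatrix(spectra))            # spectra x channels
  k <- as.integer(nComponents)
  if (k < 1L || k > min(dim(X)))
    stop("nComponents must be in [1, min(spectra, channels)]")
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  loadings <- t(pc$rotation)                 # k x C
  scores <- pc$x
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[j, ]))
    if (loadings[j, i] < 0) {
      loadings[j, ] <- -loadings[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(loadings) <- list(paste0("PC", seq_len(k)), rownames(spectra))
  dimnames(scores) <- list(colnames(spectra), paste0("PC", seq_len(k)))
  new("RamanPCA", center = as.vector(pc$center), loadings = loadings,
      scores = scores,
      varExplained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
      wavenumber = wavenumbers(spectra),
      labels = spectraLabels(spectra))
}

#' Project spectra onto a fitted PCA model
#'
#' Centers the spectra with the model's mean spectrum and projects them on
#' the loadings; used for held-out data.
#'
#' @param model a \linkS4class{RamanPCA}.
#' @param spectra a \linkS4class{RamanSpectra} on the same channel axis.
#' @return spectra x components score matrix.
#' @export
projectSpectra <- function(model, spectra) {
  X <- t(spectraMatrix(spectra))
  if (ncol(X) != length(model@center) ||
      !isTRUE(all.equal(wavenumbers(spectra), model@wavenumber)))
    stop("channel axis mismatch between model and spectra")
  sc <- sweep(X, 2L, model@center, `-`) %*% t(model@loadings)
  colnames(sc) <- rownames(model@loadings)
  sc
}

#' Select principal components by 1-based index
#'
#' Returns the requested score columns in the requested order; supports
#' exclusion of PC1 (e.g. \code{2:20} for the cell-line comparison, where
#' the leading component carries substrate background rather than
#' biological signal).
#'
#' @param x a \linkS4class{RamanPCA} or a score matrix.
#' @param indices 1-based component indices (e.g. \code{c(1, 2, 4)} or
#'   \code{2:20}).
#' @return score matrix with \code{length(indices)} columns.
#' @export
selectComponents <- function(x, indices) {
  sc <- if (is(x, "RamanPCA")) x@scores else as.matrix(x)
  indices <- as.integer(indices)
  if (any(indices < 1L) || any(indices > ncol(sc)))
    stop("component index out of range (model has ", ncol(sc),
         " components)")
  sc[, indices, drop = FALSE]
}
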