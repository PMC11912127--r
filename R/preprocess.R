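#' Preprocessing configuration
#'
#' Bundles every constant of the spectral preprocessing chain: fingerprint
#' window (600-1800 cm-1), Hampel despiking window half-width (3 channels)
#' and threshold (3 robust SDs), Savitzky-Golay window (9) and polynomial
#' order (5), iterative baseline polynomial order (12) and iteration count
#' (100), spatial bin factor (5), and the normalization order and scope.
#'
#' The two normalization steps (per-spectrum z-score and Frobenius-norm
#' scaling) can run in either order and the Frobenius step can act per
#' spectrum or per FOV block; the default is z-score first, then Frobenius,
#' both per spectrum.
#'
#' @param fingerprintLo,fingerprintHi fingerprint bounds (cm-1), closed
#'   interval.
#' @param hampelHalfwidth despiking window half-width in channels.
#' @param hampelNsigma robust-SD threshold.
#' @param sgWindow,sgPolyorder Savitzky-Golay window (odd) and order.
#' @param baselineOrder,baselineIterations modified-polyfit degree and
#'   iteration count.
#' @param binFactor spatial bin edge length in pixels.
#' @param normalizationOrder \code{"zscore_then_frobenius"} or
#'   \code{"frobenius_then_zscore"}.
#' @param normalizationScope \code{"spectrum"} or \code{"fov"} (Frobenius
#'   step only; the z-score is always per spectrum).
#' @return a validated list of class \code{"PreprocessConfig"}.
#' @export
preprocessConfig <- function(fingerprintLo = 600, fingerprintHi = 1800,
                             hampelHalfwidth = 3L, hampelNsigma = 3,
                             sgWindow = 9L, sgPolyorder = 5L,
                             baselineOrder = 12L,
                             baselineIterations = 100L,
                             binFactor = 5L,
                             normalizationOrder = c("zscore_then_frobenius",
                                                    "frobenius_then_zscore"),
                             normalizationScope = c("spectrum", "fov")) {
  if (fingerprintLo >= fingerprintHi) stop("fingerprintLo must be < hi")
  if (sgWindow %% 2L != 1L || sgWindow <= sgPolyorder)
    stop("sgWindow must be odd and > sgPolyorder")
  if (binFactor < 1L) stop("binFactor must be >= 1")
  if (baselineOrder < 1L || baselineIterations < 1L)
    stop("baselineOrder and baselineIterations must be >= 1")
  if (hampelHalfwidth < 1L || hampelNsigma <= 0)
    stop("invalid Hampel parameters")
  structure(list(
    fingerprintLo = fingerprintLo, fingerprintHi = fingerprintHi,
    hampelHalfwidth = as.integer(hampelHalfwidth),
    hampelNsigma = hampelNsigma,
    sgWindow = as.integer(sgWindow), sgPolyorder = as.integer(sgPolyorder),
    baselineOrder = as.integer(baselineOrder),
    baselineIterations = as.integer(baselineIterations),
    binFactor = as.integer(binFactor),
    normalizationOrder = match.arg(normalizationOrder),
    normalizationScope = match.arg(normalizationScope)),
    class = "PreprocessConfig")
}

#' Extract the fingerprint region of a cube
#'
#' Keeps exactly the channels whose wavenumber lies in the closed interval
#' \code{[lo, hi]}; the axis and intensity block are sliced consistently.
#' The 600-1800 cm-1 region concentrates the biomolecular signatures; on
#' the default 1340-channel axis it retains 870 channels.
#'
#' @param cube a \linkS4class{RamanCube}.
#' @param lo,hi interval bounds in cm-1.
#' @return the sliced \linkS4class{RamanCube}.
#' @export
extractFingerprint <- function(cube, lo = 600, hi = 1800) {
  idx <- which(cube@wavenumber >= lo & cube@wavenumber <= hi)
  if (!length(idx))
    stop("no channel falls inside [", lo, ", ", hi, "] cm-1")
  initialize(cube, intensities = cube@intensities[, , idx, drop = FALSE],
             wavenumber = cube@wavenumber[idx])
}

#' Hampel despiking of a spectrum
#'
#' Sliding-window robust outlier replacement: for each channel, the median
#' and scaled MAD (1.4826 * MAD) of the window of \code{2*halfwidth + 1}
#' channels (truncated at the spectrum edges) are computed; the value is
#' replaced by the window median iff it deviates from it by more than
#' \code{nsigma} robust SDs. Removes single-channel cosmic-ray artifacts
#' while leaving genuine Raman bands intact.
#'
#' @param x numeric spectrum (length >= 2) or channels-by-spectra matrix.
#' @param halfwidth window half-width in channels (default 3).
#' @param nsigma threshold in robust SDs (default 3).
#' @return despiked spectrum (or matrix) of the same shape.
#' @export
removeCosmicRays <- function(x, halfwidth = 3L, nsigma = 3) {
  if (is.matrix(x))
    return(.hampel_despike_mat(x, as.integer(halfwidth), nsigma))
  if (length(x) < 2L) stop("spectrum must have at least 2 channels")
  as.vector(.hampel_despike_mat(matrix(x, ncol = 1L),
                                as.integer(halfwidth), nsigma))
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing (window 9, order 5 by
#' default); exact on polynomials up to the filter order, so peak shapes
#' are preserved. Edges are handled by fitting the polynomial on the
#' truncated terminal windows.
#'
#' @param x numeric spectrum.
#' @param window odd window length, > \code{polyorder}.
#' @param polyorder polynomial order.
#' @return smoothed spectrum.
#' @export
sgSmooth <- function(x, window = 9L, polyorder = 5L) {
  if (window %% 2L != 1L || window <= polyorder)
    stop("window must be odd and > polyorder")
  if (length(x) < window) stop("spectrum shorter than the SG window")
  as.vector(signal::sgolayfilt(x, p = polyorder, n = window))
}

# Vectorized SG over the columns of a channels x spectra matrix, using the
# same coefficient matrix and edge scheme as signal::sgolayfilt.
.sgSmoothMat <- function(Y, window = 9L, polyorder = 5L) {
  C <- nrow(Y)
  if (C < window) stop("spectra shorter than the SG window")
  F <- unclass(signal::sgolay(p = polyorder, n = window))
  hw <- (window - 1L) %/% 2L
  out <- matrix(0, C, ncol(Y))
  int <- (hw + 1L):(C - hw)
  ctr <- F[hw + 1L, ]
  for (j in seq_len(window))
    out[int, ] <- out[int, ] + ctr[j] * Y[int + (j - hw - 1L), , drop = FALSE]
  out[seq_len(hw), ] <- F[seq_len(hw), ] %*% Y[seq_len(window), , drop = FALSE]
  out[(C - hw + 1L):C, ] <- F[(hw + 2L):window, ] %*%
    Y[(C - window + 1L):C, , drop = FALSE]
  out
}

# Orthonormal polynomial basis of the given degree on the axis mapped
# affinely to [-1, 1]; degree-12 fits on raw cm-1 values are numerically
# ill-conditioned, this basis is mathematically the same fit.
.polyBasisQ <- function(axis, order) {
  if (length(axis) <= order)
    stop("need more channels than the polynomial order")
  z <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  qr.Q(qr(outer(z, 0:order, `^`)))
}

#' Iterative polynomial baseline subtraction
#'
#' Modified polynomial fitting for autofluorescence removal: a polynomial
#' of the given order is least-squares fitted to the working spectrum and
#' the working spectrum is clipped to the pointwise minimum of itself and
#' the fit; iterating drives the fit under the Raman peaks and onto the
#' slowly varying background. The final fit is the baseline.
#'
#' @param x numeric spectrum.
#' @param axis wavenumber axis (same length).
#' @param order polynomial degree (default 12).
#' @param iterations number of fit-and-clip passes (default 100).
#' @return list with elements \code{corrected} (x minus baseline) and
#'   \code{baseline}.
#' @export
baselineSubtract <- function(x, axis, order = 12L, iterations = 100L) {
  if (length(x) != length(axis)) stop("spectrum/axis length mismatch")
  Q <- .polyBasisQ(axis, order)
  B <- .modpoly_baseline_mat(matrix(x, ncol = 1L), Q,
                             as.integer(iterations))
  list(corrected = x - as.vector(B), baseline = as.vector(B))
}

#' Spatial binning of a cube
#'
#' Averages non-overlapping \code{factor x factor} pixel blocks per
#' channel (e.g. 50 x 50 to 10 x 10 at factor 5), trading spatial
#' resolution for signal-to-noise. Dimensions must be divisible by the
#' factor; there is no silent cropping.
#'
#' @param cube a \linkS4class{RamanCube}.
#' @param factor bin edge length in pixels.
#' @return the binned \linkS4class{RamanCube} (pitch scaled accordingly).
#' @export
binSpatial <- function(cube, factor = 5L) {
  d <- dim(cube@intensities)
  factor <- as.integer(factor)
  if (d[1] %% factor != 0L || d[2] %% factor != 0L)
    stop("FOV dimensions (", d[1], "x", d[2],
         ") are not divisible by the bin factor ", factor)
  H2 <- d[1] %/% factor; W2 <- d[2] %/% factor
  Y <- matrix(cube@intensities, d[1] * d[2], d[3])
  B <- t(.binMatrix(d[1], d[2], factor)) %*% Y
  initialize(cube, intensities = array(B, dim = c(H2, W2, d[3])),
             pitchUm = cube@pitchUm * factor)
}

# npix x nbin block-mean aggregation matrix for an H x W raster.
.binMatrix <- function(H, W, f) {
  H2 <- H %/% f; W2 <- W %/% f
  px <- seq_len(H * W)
  h <- (px - 1L) %% H; w <- (px - 1L) %/% H
  blk <- (h %/% f) + H2 * (w %/% f)        # 0-based block index
  P <- matrix(0, H * W, H2 * W2)
  P[cbind(px, blk + 1L)] <- 1 / f^2
  P
}

#' Per-spectrum z-score standardization
#'
#' Centers a spectrum to mean 0 and scales it to unit SD across channels,
#' so that relative spectral features can be compared across acquisitions.
#'
#' @param x numeric spectrum with positive channel SD.
#' @return standardized spectrum.
#' @export
zscoreSpectrum <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate spectrum: zero channel variance")
  (x - mean(x)) / s
}

#' Frobenius normalization
#'
#' Divides a spectrum (or a spectra block) by its Frobenius norm - the
#' Euclidean norm for a single spectrum - removing global intensity scale
#' differences between acquisitions.
#'
#' @param x numeric vector or matrix with nonzero norm.
#' @return x scaled to unit Frobenius norm.
#' @export
frobeniusNormalize <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (!is.finite(nrm) || nrm == 0) stop("zero block cannot be normalized")
  x / nrm
}

# Normalize the columns (spectra) of Y per the config.
.normalizeBlock <- function(Y, config) {
  zs <- function(Y) {
    cm <- colMeans(Y)
    csd <- sqrt(pmax(colMeans(Y^2) - cm^2, 0) * nrow(Y) / (nrow(Y) - 1))
    if (any(csd == 0))
      stop("degenerate spectrum: zero channel variance")
    sweep(sweep(Y, 2L, cm, `-`), 2L, csd, `/`)
  }
  fro <- function(Y) {
    if (config$normalizationScope == "fov") {
      nrm <- sqrt(sum(Y^2))
      if (nrm == 0) stop("zero block cannot be normalized")
      Y / nrm
    } else {
      nrm <- sqrt(colSums(Y^2))
      if (any(nrm == 0)) stop("zero block cannot be normalized")
      sweep(Y, 2L, nrm, `/`)
    }
  }
  if (config$normalizationOrder == "zscore_then_frobenius") fro(zs(Y))
  else zs(fro(Y))
}

# Full chain for one cube; returns the channels x binned-spectra matrix
# and the sliced axis.
.preprocessCubeMatrix <- function(cube, config) {
  idx <- which(cube@wavenumber >= config$fingerprintLo &
                 cube@wavenumber <= config$fingerprintHi)
  if (!length(idx)) stop("no channel in the fingerprint interval")
  d <- dim(cube@intensities)
  Y <- t(matrix(cube@intensities, d[1] * d[2], d[3]))[idx, , drop = FALSE]
  axis <- cube@wavenumber[idx]
  Y <- .hampel_despike_mat(Y, config$hampelHalfwidth, config$hampelNsigma)
  Y <- .sgSmoothMat(Y, config$sgWindow, config$sgPolyorder)
  Q <- .polyBasisQ(axis, config$baselineOrder)
  rawScale <- max(abs(Y))
  Y <- Y - .modpoly_baseline_mat(Y, Q, config$baselineIterations)
  # spectra that are pure baseline collapse to numerical fuzz here
  resid <- apply(abs(Y), 2L, max)
  if (any(resid <= 1e-10 * (rawScale + 1e-300)))
    stop("degenerate spectrum: no signal left after baseline subtraction")
  if (config$binFactor > 1L) {
    if (d[1] %% config$binFactor != 0L || d[2] %% config$binFactor != 0L)
      stop("FOV dimensions not divisible by the bin factor")
    Y <- Y %*% .binMatrix(d[1], d[2], config$binFactor)
  }
  list(matrix = .normalizeBlock(Y, config), axis = axis)
}

#' Preprocess one field of view
#'
#' Runs the chain fingerprint extraction -> Hampel despiking ->
#' Savitzky-Golay smoothing -> iterative polynomial baseline subtraction
#' (all per pixel spectrum) -> spatial binning -> normalization, and
#' returns the binned spectra as a \linkS4class{RamanSpectra} table with
#' the cube's annotation replicated per spectrum.
#'
#' @param cube a \linkS4class{RamanCube}.
#' @param config a [preprocessConfig()].
#' @return a \linkS4class{RamanSpectra}.
#' @export
preprocessCube <- function(cube, config = preprocessConfig()) {
  res <- tryCatch(.preprocessCubeMatrix(cube, config), error = function(e)
    stop("preprocessing failed for cube ", cube@organoidId, "/",
         cube@fovId, ": ", conditionMessage(e), call. = FALSE))
  n <- ncol(res$matrix)
  .makeRamanSpectra(res$matrix, res$axis, data.frame(
    stage_weeks = rep.int(cube@stageWeeks, n),
    line = rep.int(cube@line, n),
    organoid_id = rep.int(cube@organoidId, n),
    fov_id = rep.int(paste(cube@organoidId, cube@fovId, sep = ":"), n),
    stringsAsFactors = FALSE))
}

.makeRamanSpectra <- function(mat, axis, labels) {
  rownames(mat) <- sprintf("wn_%.2f", axis)
  colnames(mat) <- sprintf("s%05d", seq_len(ncol(mat)))
  cd <- S4Vectors::DataFrame(labels)
  rownames(cd) <- colnames(mat)
  rd <- S4Vectors::DataFrame(wavenumber = axis)
  rownames(rd) <- rownames(mat)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = mat), rowData = rd, colData = cd)
  new("RamanSpectra", se)
}

#' Preprocess a list of cubes into one spectrum table
#'
#' All cubes must share one wavenumber axis; their binned spectra are
#' stacked column-wise with per-spectrum labels.
#'
#' @param cubes list of \linkS4class{RamanCube}.
#' @param config a [preprocessConfig()].
#' @return a \linkS4class{RamanSpectra}.
#' @export
preprocessCubes <- function(cubes, config = preprocessConfig()) {
  if (!length(cubes)) stop("no cubes supplied")
  ax <- cubes[[1L]]@wavenumber
  for (cb in cubes)
    if (!isTRUE(all.equal(cb@wavenumber, ax)))
      stop("all cubes must share one wavenumber axis")
  parts <- lapply(cubes, preprocessCube, config = config)
  do.call(.combineSpectra, parts)
}

.combineSpectra <- function(...) {
  parts <- list(...)
  mat <- do.call(cbind, lapply(parts, spectraMatrix))
  labels <- do.call(rbind, lapply(parts, function(p)
    as.data.frame(spectraLabels(p))))
  .makeRamanSpectra(mat, wavenumbers(parts[[1L]]), labels)
}

#' Generate and preprocess a synthetic study, streaming cube by cube
#'
#' Equivalent to \code{preprocessCubes(synthStudy(design), config)} but
#' never holds more than one raw cube in memory, which matters for
#' full-size designs (a 50 x 50 x 1340 cube is ~27 MB; a four-stage
#' campaign has 72 of them).
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param config a [preprocessConfig()].
#' @return a \linkS4class{RamanSpectra}.
#' @export
preprocessStudy <- function(design, config = preprocessConfig()) {
  validObject(design)
  parts <- list()
  for (gi in seq_along(design@profiles))
    for (oi in seq_len(design@organoidsPerStage))
      for (fi in seq_len(design@fovsPerOrganoid)) {
        cube <- synthCube(design, gi, oi, fi)
        parts[[length(parts) + 1L]] <- preprocessCube(cube, config)
      }
  do.call(.combineSpectra, parts)
}
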