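#' Wavenumber axis of the spectrometer
#'
#' Builds the linear Raman-shift axis. For the default 1340-channel
#' detector the axis is \eqn{\nu_k = 600 + (k - 235) \cdot 1200/869} cm-1
#' for \eqn{k = 0, \dots, 1339}, so that exactly 870 channels fall in the
#' 600-1800 cm-1 fingerprint region. For other channel counts the same
#' spectral span is sampled uniformly.
#'
#' @param nChannels number of channels (>= 2); default 1340.
#' @return strictly increasing numeric vector of wavenumbers (cm-1).
#' @examples
#' ax <- makeWavenumberAxis()
#' sum(ax >= 600 & ax <= 1800)  # 870
#' @export
makeWavenumberAxis <- function(nChannels = 1340L) {
  nChannels <- as.integer(nChannels)
  if (is.na(nChannels) || nChannels < 2L)
    stop("nChannels must be an integer >= 2")
  step <- 1200 / 869
  if (nChannels == 1340L) return(600 + (0:1339 - 235) * step)
  lo <- 600 - 235 * step
  hi <- 600 + (1339 - 235) * step
  seq(lo, hi, length.out = nChannels)
}

# Order-insensitive 32-bit seed derivation for per-cube RNG streams.
.deriveSeed <- function(seed, ...) {
  m <- 2147483647           # 2^31 - 1
  h <- (as.numeric(seed) %% m)
  for (k in c(...)) h <- (h * 48271 + as.numeric(k) + 1) %% m
  as.integer(h)
}

# Unit-height peak shape on the axis; width is HWHM in cm-1.
.peakShape <- function(axis, center, width, shape = "lorentzian") {
  if (shape == "lorentzian") width^2 / ((axis - center)^2 + width^2)
  else exp(-log(2) * ((axis - center) / width)^2)
}

# Band profile matrix: one column per band, unit height.
.bandBasis <- function(axis, bands) {
  vapply(seq_len(nrow(bands)), function(b)
    .peakShape(axis, bands$center[b], bands$width[b], bands$shape[b]),
    numeric(length(axis)))
}

# Amplitudes of group `gi` after applying effectScale to the deviation
# from the across-group mean profile.
.effectiveAmplitudes <- function(design, gi) {
  amps <- vapply(design@profiles, function(p)
    p$concentrations[design@bands$name], numeric(nrow(design@bands)))
  ctr <- rowMeans(amps)
  pmax(ctr + design@effectScale * (amps[, gi] - ctr), 0)
}

# Raw polynomial baseline basis on the axis mapped to [-1, 1].
.baselineBasis <- function(axis, degree) {
  z <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  outer(z, 0:degree, `^`)
}

# Fixed broad hump used as the class-independent nuisance component.
.nuisanceShape <- function(axis)
  exp(-log(2) * ((axis - 1200) / 250)^2)

#' Construct a synthetic study design
#'
#' @param profiles list of group profiles (see \linkS4class{StudyDesign}).
#' @param bands band component table (see [bandComponents()]).
#' @param organoidsPerStage,fovsPerOrganoid counts per group / organoid.
#' @param fovHeight,fovWidth FOV raster size in pixels.
#' @param nChannels raw spectral channel count.
#' @param effectScale multiplier on between-group amplitude differences.
#' @param noiseSd Gaussian channel noise SD.
#' @param baselineCoeffMean,baselineCoeffSd mean / SD of the degree-<=5
#'   polynomial baseline coefficients (drawn per pixel spectrum).
#' @param cosmicRayRate expected spikes per spectrum.
#' @param organoidSd,fovSd log-scale SDs of the multiplicative random
#'   effects shared by all pixels of an organoid / FOV.
#' @param nuisanceSd SD of the class-independent broad-hump amplitude.
#' @param compositionSd log-scale SD of the per-pixel, per-band
#'   log-normal amplitude jitter (local biochemical heterogeneity).
#' @param pitchUm pixel pitch (micrometers).
#' @param seed integer master seed.
#' @return A validated \linkS4class{StudyDesign}.
#' @examples
#' d <- ramanPreset("pgp1-4stage")
#' d
#' @export
studyDesign <- function(profiles, bands = defaultBands(),
                        organoidsPerStage = 3L, fovsPerOrganoid = 6L,
                        fovHeight = 50L, fovWidth = 50L,
                        nChannels = 1340L, effectScale = 1,
                        noiseSd = 0.05,
                        baselineCoeffMean = c(4, -1.5, 0.8, 0.4, 0, 0),
                        baselineCoeffSd = 0.25,
                        cosmicRayRate = 0.03, organoidSd = 0.1,
                        fovSd = 0.05, nuisanceSd = 0, compositionSd = 0,
                        pitchUm = 1.5, seed = 1L) {
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    miss <- setdiff(bands$name, names(p$concentrations))
    if (length(miss))
      stop("profile ", i, " lacks amplitudes for: ",
           paste(miss, collapse = ", "))
  }
  new("StudyDesign", profiles = profiles, bands = bands,
      organoidsPerStage = as.integer(organoidsPerStage),
      fovsPerOrganoid = as.integer(fovsPerOrganoid),
      fovHeight = as.integer(fovHeight), fovWidth = as.integer(fovWidth),
      nChannels = as.integer(nChannels), effectScale = effectScale,
      noiseSd = noiseSd, baselineCoeffMean = baselineCoeffMean,
      baselineCoeffSd = baselineCoeffSd, cosmicRayRate = cosmicRayRate,
      organoidSd = organoidSd, fovSd = fovSd, nuisanceSd = nuisanceSd,
      compositionSd = compositionSd, pitchUm = pitchUm,
      seed = as.integer(seed))
}

#' Simulate one raw Raman spectrum
#'
#' Sum of band peaks (amplitudes from the stage profile), a low-order
#' polynomial autofluorescence baseline, Gaussian channel noise, and
#' Poisson-count single-channel cosmic-ray spikes with amplitude uniform
#' in \code{[20, 200] * noiseSd}; the result is clipped at zero. Uses the
#' current RNG state; seed it for reproducibility.
#'
#' @param concentrations named nonnegative amplitudes, one per band.
#' @param bands band component table.
#' @param axis wavenumber axis (cm-1).
#' @param baselineCoeffs polynomial coefficients (length <= 6, constant
#'   first) on the axis mapped affinely to [-1, 1].
#' @param noiseSd Gaussian noise SD (>= 0).
#' @param cosmicRayRate expected spike count (Poisson mean).
#' @return numeric spectrum, length \code{length(axis)}, nonnegative.
#' @examples
#' set.seed(1)
#' ax <- makeWavenumberAxis(300)
#' y <- synthSpectrum(c(glycogen = 1), defaultBands()[2, ], ax,
#'                    baselineCoeffs = 0, noiseSd = 0.05)
#' @export
synthSpectrum <- function(concentrations, bands, axis,
                          baselineCoeffs = 0, noiseSd = 0,
                          cosmicRayRate = 0) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (length(baselineCoeffs) > 6L)
    stop("baseline polynomial degree must be <= 5")
  amp <- concentrations[bands$name]
  if (anyNA(amp)) stop("missing band amplitudes")
  y <- as.vector(.bandBasis(axis, bands) %*% amp)
  if (any(baselineCoeffs != 0))
    y <- y + as.vector(.baselineBasis(axis, length(baselineCoeffs) - 1L)
                       %*% baselineCoeffs)
  if (noiseSd > 0) y <- y + rnorm(length(axis), 0, noiseSd)
  if (cosmicRayRate > 0) {
    n <- rpois(1L, cosmicRayRate)
    if (n > 0) {
      ch <- sample.int(length(axis), n, replace = TRUE)
      y[ch] <- y[ch] + runif(n, 20, 200) * noiseSd
    }
  }
  pmax(y, 0)
}

#' Simulate one hyperspectral FOV cube
#'
#' All pixel spectra of the cube share one organoid-level and one FOV-level
#' multiplicative log-normal intensity effect; each pixel gets its own
#' baseline coefficients, noise and cosmic rays. Output is deterministic
#' given the design seed and the three indices.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param stageIndex,organoidIndex,fovIndex 1-based indices into the design.
#' @return A \linkS4class{RamanCube}.
#' @examples
#' d <- ramanPreset("pgp1-4stage", fovHeight = 10, fovWidth = 10,
#'                  nChannels = 200)
#' synthCube(d, 1, 1, 1)
#' @export
synthCube <- function(design, stageIndex, organoidIndex, fovIndex) {
  G <- length(design@profiles)
  if (stageIndex < 1 || stageIndex > G ||
      organoidIndex < 1 || organoidIndex > design@organoidsPerStage ||
      fovIndex < 1 || fovIndex > design@fovsPerOrganoid)
    stop("index out of range for this design")
  axis <- makeWavenumberAxis(design@nChannels)
  C <- length(axis); npix <- design@fovHeight * design@fovWidth
  prof <- design@profiles[[stageIndex]]

  set.seed(.deriveSeed(design@seed, stageIndex, organoidIndex))
  gOrg <- if (design@organoidSd > 0) rlnorm(1, 0, design@organoidSd) else 1

  set.seed(.deriveSeed(design@seed, stageIndex, organoidIndex, fovIndex))
  gFov <- if (design@fovSd > 0) rlnorm(1, 0, design@fovSd) else 1

  amps <- .effectiveAmplitudes(design, stageIndex)
  BB <- .bandBasis(axis, design@bands)
  if (design@compositionSd > 0) {
    nb <- length(amps)
    A <- amps * exp(matrix(rnorm(nb * npix, 0, design@compositionSd),
                           nb, npix))
    Y <- BB %*% A
  } else {
    Y <- matrix(as.vector(BB %*% amps), C, npix)
  }

  nb <- length(design@baselineCoeffMean)
  if (nb > 0 && (any(design@baselineCoeffMean != 0) ||
                 design@baselineCoeffSd > 0)) {
    coeffs <- matrix(rnorm(nb * npix, design@baselineCoeffMean,
                           design@baselineCoeffSd), nb, npix)
    Y <- Y + .baselineBasis(axis, nb - 1L) %*% coeffs
  }
  if (design@nuisanceSd > 0)
    Y <- Y + outer(.nuisanceShape(axis),
                   rnorm(npix, 0, design@nuisanceSd))
  if (design@noiseSd > 0)
    Y <- Y + matrix(rnorm(C * npix, 0, design@noiseSd), C, npix)
  if (design@cosmicRayRate > 0) {
    ns <- rpois(npix, design@cosmicRayRate)
    tot <- sum(ns)
    if (tot > 0) {
      px <- rep.int(seq_len(npix), ns)
      ch <- sample.int(C, tot, replace = TRUE)
      Y[cbind(ch, px)] <- Y[cbind(ch, px)] +
        runif(tot, 20, 200) * design@noiseSd
    }
  }
  Y <- pmax(gOrg * gFov * Y, 0)

  new("RamanCube",
      intensities = array(t(Y), dim = c(design@fovHeight, design@fovWidth,
                                        C)),
      wavenumber = axis, line = prof$line,
      organoidId = sprintf("%s_wk%02d_org%d", prof$line, prof$stage_weeks,
                           organoidIndex),
      stageWeeks = as.integer(prof$stage_weeks),
      fovId = sprintf("fov%02d", fovIndex), pitchUm = design@pitchUm)
}

#' Simulate a full acquisition campaign
#'
#' Generates every cube of the design (groups x organoids x FOVs) with
#' correct metadata. For large designs prefer [preprocessStudy()], which
#' streams cubes through preprocessing without holding them all in memory.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @return list of \linkS4class{RamanCube}.
#' @examples
#' d <- ramanPreset("pgp1-4stage", fovHeight = 5, fovWidth = 5,
#'                  nChannels = 150, fovsPerOrganoid = 1,
#'                  organoidsPerStage = 1)
#' length(synthStudy(d))  # 4
#' @export
synthStudy <- function(design) {
  validObject(design)
  out <- list()
  for (gi in seq_along(design@profiles))
    for (oi in seq_len(design@organoidsPerStage))
      for (fi in seq_len(design@fovsPerOrganoid))
        out[[length(out) + 1L]] <- synthCube(design, gi, oi, fi)
  out
}
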