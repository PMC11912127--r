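# Shared fixtures: small designs and spectra built in code.

# Two-group profile pair with a single differential band (glycogen)
# unless full = TRUE, in which case the preset amplitude table is used.
tinyProfiles <- function(delta = 0.4) {
  bn <- defaultBands()$name
  base <- c(0.8, 0.5, 0.5, 0.6, 0.7, 0.7, 0.8)
  hi <- base
  hi[2] <- base[2] + delta
  list(list(stage_weeks = 6L, line = "PGP1",
            concentrations = stats::setNames(base, bn)),
       list(stage_weeks = 12L, line = "PGP1",
            concentrations = stats::setNames(hi, bn)))
}

# Small, fast design: ~143 fingerprint channels, 4 binned spectra per FOV.
tinyDesign <- function(profiles = tinyProfiles(), ...) {
  defaults <- list(profiles = profiles, nChannels = 220L,
                   fovHeight = 10L, fovWidth = 10L,
                   organoidsPerStage = 1L, fovsPerOrganoid = 2L,
                   noiseSd = 0.05, cosmicRayRate = 0.02, seed = 42L)
  do.call(studyDesign, utils::modifyList(defaults, list(...)))
}

# Independent brute-force Hampel oracle: per-channel window median and
# scaled MAD, recomputed directly.
hampelOracle <- function(x, halfwidth, nsigma) {
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    win <- x[max(1, i - halfwidth):min(n, i + halfwidth)]
    m <- median(win)
    sigma <- 1.4826 * median(abs(win - m))
    if (abs(x[i] - m) > nsigma * sigma) out[i] <- m
  }
  out
}

# Exact Mann-Whitney p by exhaustive enumeration of group assignments.
mwEnumOracle <- function(a, b) {
  uStat <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  obs <- uStat(a, b)
  pool <- c(a, b)
  n1 <- length(a)
  combos <- utils::combn(length(pool), n1)
  u <- apply(combos, 2L, function(ix) uStat(pool[ix], pool[-ix]))
  m <- n1 * (length(pool) - n1) / 2
  # two-sided: arrangements at least as extreme (as far from the mean)
  mean(abs(u - m) >= abs(obs - m) - 1e-9)
}
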