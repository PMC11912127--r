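test_that("fingerprint extraction keeps the closed 600-1800 interval", {
  d <- tinyDesign()
  cb <- synthCube(d, 1, 1, 1)
  fp <- extractFingerprint(cb)
  expect_true(all(wavenumbers(fp) >= 600 & wavenumbers(fp) <= 1800))
  expect_equal(dim(intensities(fp))[3], length(wavenumbers(fp)))

  inside <- extractFingerprint(fp)       # axis already inside -> unchanged
  expect_identical(intensities(inside), intensities(fp))
  expect_error(extractFingerprint(cb, lo = 1e5, hi = 2e5), "no channel")
})

test_that("Hampel despiking matches a brute-force sliding-window oracle", {
  const <- rep(2, 101)
  spiked <- const
  spiked[50] <- 102
  out <- removeCosmicRays(spiked)
  expect_equal(out[50], 2)
  expect_equal(out[-50], const[-50])
  expect_equal(removeCosmicRays(const), const)

  set.seed(3)
  for (hw in c(2L, 3L, 5L)) {
    x <- cumsum(rnorm(200)) + rnorm(200)
    x[sample(200, 5)] <- x[sample(200, 5)] + 40
    expect_equal(removeCosmicRays(x, hw, 3), hampelOracle(x, hw, 3))
  }
})

test_that("despiking removes injected rays and spares clean channels", {
  d <- tinyDesign()
  bands <- d@bands
  amps <- d@profiles[[1]]$concentrations
  ax <- makeWavenumberAxis(300)
  noise <- 0.05
  ax <- makeWavenumberAxis()                 # native channel spacing
  set.seed(9)
  nSpiked <- 0; nCaught <- 0; nCleanDistorted <- 0; nClean <- 0
  for (i in 1:1000) {
    y <- synthSpectrum(amps, bands, ax,
                       baselineCoeffs = c(4, -1, 0.5), noiseSd = noise)
    k <- sample(length(ax), 2)
    spike <- runif(2, 20, 200) * noise
    ys <- y; ys[k] <- ys[k] + spike
    out <- removeCosmicRays(ys)
    nSpiked <- nSpiked + 2
    nCaught <- nCaught + sum(abs(out[k] - ys[k]) > spike / 2)
    nClean <- nClean + length(ax) - 2
    # clean channels must keep their value to within noise scale: any
    # replacement the filter makes there stays a sub-noise correction
    nCleanDistorted <- nCleanDistorted +
      sum(abs(out[-k] - ys[-k]) > 3 * noise)
  }
  expect_gte(nCaught / nSpiked, 0.99)
  expect_lt(nCleanDistorted / nClean, 0.01)
})

test_that("Savitzky-Golay smoothing is exact on polynomials and denoises", {
  x <- seq(0, 1, length.out = 200)
  y <- 3 - 2 * x + 5 * x^3 - 4 * x^5
  expect_equal(sgSmooth(y), y, tolerance = 1e-10)
  expect_equal(sgSmooth(rep(1.5, 50)), rep(1.5, 50))
  expect_error(sgSmooth(y, window = 8), "odd")

  set.seed(5)
  noise <- rnorm(870)
  expect_lt(var(sgSmooth(noise)), var(noise))
})

test_that("the vectorized SG path equals sgolayfilt channel-by-channel", {
  set.seed(11)
  Y <- matrix(rnorm(150 * 8), 150, 8)
  fast <- ramanoid:::.sgSmoothMat(Y, 9L, 5L)
  slow <- apply(Y, 2, sgSmooth)
  expect_equal(fast, slow, tolerance = 1e-10)
})

test_that("iterative baseline fitting nulls polynomials and recovers peaks", {
  ax <- makeWavenumberAxis(500)
  z <- 2 * (ax - min(ax)) / diff(range(ax)) - 1
  poly12 <- as.vector(outer(z, 0:12, `^`) %*% rnorm(13))
  res <- baselineSubtract(poly12, ax)
  expect_lt(max(abs(res$corrected)), 1e-6 * diff(range(poly12)))
  expect_lt(sum(res$corrected^2), 1e-8 * sum(poly12^2))

  res0 <- baselineSubtract(rep(0, 500), ax)
  expect_equal(res0$corrected, rep(0, 500))
  expect_equal(res0$baseline, rep(0, 500))

  h <- 2
  peak <- h * 10^2 / ((ax - 1100)^2 + 10^2)      # Lorentzian, HWHM 10
  base3 <- 5 + 0.5 * z - 0.8 * z^2 + 0.3 * z^3
  rec <- baselineSubtract(peak + base3, ax)
  expect_lt(abs(max(rec$corrected) - h) / h, 0.1)
  expect_error(baselineSubtract(rep(1, 10), ax[1:10], order = 12), "order")
})

test_that("spatial binning averages blocks and refuses ragged rasters", {
  d <- tinyDesign()
  cb <- synthCube(d, 1, 1, 1)                     # 10 x 10
  b <- binSpatial(cb, 5)
  expect_equal(dim(intensities(b))[1:2], c(2L, 2L))
  # block mean check against direct averaging for one channel
  ch <- 17
  expect_equal(intensities(b)[1, 1, ch],
               mean(intensities(cb)[1:5, 1:5, ch]))

  const <- cb
  methods::slot(const, "intensities") <-
    array(3.25, dim = dim(intensities(cb)))
  expect_equal(unique(as.vector(intensities(binSpatial(const, 5)))), 3.25)

  d7 <- tinyDesign(fovHeight = 7L, fovWidth = 7L)
  expect_error(binSpatial(synthCube(d7, 1, 1, 1), 5), "divisible")
})

test_that("z-score and Frobenius normalizations have their defining properties", {
  set.seed(13)
  x <- rnorm(100)
  z <- zscoreSpectrum(x)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_equal(zscoreSpectrum(3 * x + 7), z, tolerance = 1e-10)
  expect_error(zscoreSpectrum(rep(2, 10)), "degenerate")

  f <- frobeniusNormalize(x)
  expect_equal(sqrt(sum(f^2)), 1, tolerance = 1e-12)
  expect_equal(frobeniusNormalize(5 * x), f, tolerance = 1e-12)
  M <- matrix(rnorm(40), 8, 5)
  expect_equal(sqrt(sum(frobeniusNormalize(M)^2)), 1, tolerance = 1e-12)
  expect_error(frobeniusNormalize(rep(0, 4)), "zero")
})

test_that("the pipeline stacks labeled unit-norm spectra deterministically", {
  d <- tinyDesign(organoidsPerStage = 2L)
  sp <- preprocessStudy(d)
  expect_s4_class(sp, "RamanSpectra")
  expect_equal(ncol(sp), 2 * 2 * 2 * 4)     # stages x orgs x fovs x bins
  expect_equal(unname(colSums(spectraMatrix(sp)^2)),
               rep(1, ncol(sp)), tolerance = 1e-10)
  expect_equal(sort(unique(spectraLabels(sp)$stage_weeks)), c(6L, 12L))

  sp2 <- preprocessStudy(d)
  expect_identical(spectraMatrix(sp), spectraMatrix(sp2))

  # permutation over cubes only reorders the rows
  cubes <- synthStudy(d)
  a <- preprocessCubes(cubes)
  b <- preprocessCubes(rev(cubes))
  key <- function(s) {
    m <- spectraMatrix(s)
    m[, order(spectraLabels(s)$fov_id, m[1, ]), drop = FALSE]
  }
  expect_equal(unname(key(a)), unname(key(b)), tolerance = 1e-12)
})

test_that("degenerate all-flat cubes are rejected with context", {
  d0 <- tinyDesign(noiseSd = 0, baselineCoeffSd = 0, cosmicRayRate = 0,
                   organoidSd = 0, fovSd = 0,
                   baselineCoeffMean = c(2, 0, 0, 0, 0, 0),
                   profiles = lapply(tinyProfiles(), function(p) {
                     p$concentrations[] <- 0
                     p
                   }))
  cb <- synthCube(d0, 1, 1, 1)   # constant baseline only -> flat spectra
  expect_error(preprocessCube(cb), "degenerate|zero")
})

test_that("both normalization orders and scopes are honoured", {
  d <- tinyDesign()
  cb <- synthCube(d, 1, 1, 1)
  fov <- preprocessCube(cb, preprocessConfig(
    normalizationOrder = "frobenius_then_zscore",
    normalizationScope = "fov"))
  m <- spectraMatrix(fov)
  # z-score is the outer step: per-spectrum mean 0, SD 1
  expect_equal(unname(colMeans(m)), rep(0, ncol(m)), tolerance = 1e-10)
  expect_equal(apply(m, 2, sd), rep(1, ncol(m)), tolerance = 1e-10,
               ignore_attr = TRUE)
})
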