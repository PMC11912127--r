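test_that("cube text serialization round-trips", {
  d <- tinyDesign()
  cb <- synthCube(d, 1, 1, 1)
  path <- file.path(tempdir(), "cube1")
  writeCube(cb, path)
  back <- readCube(path)
  expect_equal(intensities(back), intensities(cb), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(wavenumbers(back), wavenumbers(cb), tolerance = 1e-12)
  expect_equal(cubeMeta(back), cubeMeta(cb))
  unlink(path, recursive = TRUE)
})

test_that("runExperiment writes every artifact and is reproducible", {
  d <- tinyDesign(fovsPerOrganoid = 3L, fovHeight = 20L, fovWidth = 20L)
  out1 <- file.path(tempdir(), "run1")
  out2 <- file.path(tempdir(), "run2")
  r1 <- runExperiment(d, out1, nComponents = 8, pcIndices = 1:8,
                      k = 5, seed = 3)
  r2 <- runExperiment(d, out2, nComponents = 8, pcIndices = 1:8,
                      k = 5, seed = 3)

  artifacts <- c("design.json", "manifest.json", "spectra.csv",
                 "pca_loadings.csv", "pca_summary.json",
                 "classification.json", "confusion.csv", "bands.csv",
                 "separability.json", "distances.csv")
  for (f in artifacts) expect_true(file.exists(file.path(out1, f)),
                                   info = f)

  expect_identical(foldAccuracies(r1$classification),
                   foldAccuracies(r2$classification))
  expect_identical(spectraMatrix(r1$spectra), spectraMatrix(r2$spectra))

  man <- jsonlite::read_json(file.path(out1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 3)
  expect_equal(man$n_spectra, ncol(r1$spectra))
  cls <- jsonlite::read_json(file.path(out1, "classification.json"),
                             simplifyVector = TRUE)
  expect_equal(cls$accuracy_mean, mean(foldAccuracies(r1$classification)))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("presets encode the study geometries", {
  p4 <- ramanPreset("pgp1-4stage")
  expect_length(p4@profiles, 4)
  expect_equal(p4@organoidsPerStage, 3L)
  expect_equal(p4@fovsPerOrganoid, 6L)
  expect_equal(c(p4@fovHeight, p4@fovWidth), c(50L, 50L))
  expect_equal(p4@nChannels, 1340L)
  # glycogen rises, nucleic acids fall across the four stages
  gly <- vapply(p4@profiles, function(p) p$concentrations[["glycogen"]],
                numeric(1))
  nuc <- vapply(p4@profiles,
                function(p) p$concentrations[["nucleic_acids"]],
                numeric(1))
  expect_true(all(diff(gly) > 0))
  expect_true(all(diff(nuc) < 0))

  h2 <- ramanPreset("h1-2stage")
  expect_length(h2@profiles, 2)
  expect_equal(h2@organoidsPerStage, 2L)
  expect_equal(h2@fovsPerOrganoid, 8L)

  lc <- ramanPreset("line-comparison")
  expect_length(lc@profiles, 4)
  expect_setequal(vapply(lc@profiles, function(p) p$line, character(1)),
                  c("PGP1", "H1"))
  expect_gt(lc@nuisanceSd, 0)

  ov <- ramanPreset("pgp1-4stage", fovHeight = 10L, seed = 9L)
  expect_equal(ov@fovHeight, 10L)
  expect_equal(ov@seed, 9L)
})

test_that("the shipped band config matches the built-in defaults", {
  f <- system.file("extdata", "default_bands.json", package = "ramanoid")
  b <- readBandsJson(f)
  expect_equal(b$name, defaultBands()$name)
  expect_equal(b$center, defaultBands()$center)
  expect_equal(b$width, defaultBands()$width)
  expect_equal(b$halfwidth, rep(10, 7))
})

test_that("design JSON serialization captures every field", {
  d <- tinyDesign()
  f <- tempfile(fileext = ".json")
  writeDesignJson(d, f)
  x <- jsonlite::read_json(f, simplifyVector = FALSE)
  expect_equal(x$n_channels, d@nChannels)
  expect_equal(x$seed, d@seed)
  expect_equal(length(x$profiles), length(d@profiles))
  expect_equal(x$profiles[[1]]$concentrations$glycogen,
               unname(d@profiles[[1]]$concentrations["glycogen"]))
  unlink(f)
})
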