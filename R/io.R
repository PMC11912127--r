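#' Write / read a hyperspectral cube as plain text
#'
#' Serializes a \linkS4class{RamanCube} into a directory holding
#' \code{meta.json} (annotation, raster size), \code{wavenumber.csv} (the
#' axis) and \code{intensities.csv} (pixels x channels, pixel index
#' running down the rows column-major over the raster). The round trip is
#' lossless to numeric text precision.
#'
#' @param cube a \linkS4class{RamanCube}.
#' @param path directory to create/fill.
#' @return \code{path}, invisibly.
#' @export
writeCube <- function(cube, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(cube@intensities)
  meta <- c(cubeMeta(cube), list(height = d[1], width = d[2],
                                 channels = d[3]))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(wavenumber_cm1 = cube@wavenumber),
            file.path(path, "wavenumber.csv"), row.names = FALSE)
  utils::write.table(matrix(cube@intensities, d[1] * d[2], d[3]),
                     file.path(path, "intensities.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeCube
#' @export
readCube <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  wn <- read.csv(file.path(path, "wavenumber.csv"))$wavenumber_cm1
  Y <- as.matrix(read.csv(file.path(path, "intensities.csv"),
                          header = FALSE))
  new("RamanCube",
      intensities = array(as.numeric(Y),
                          dim = c(meta$height, meta$width, meta$channels)),
      wavenumber = wn, line = meta$line, organoidId = meta$organoid_id,
      stageWeeks = as.integer(meta$stage_weeks), fovId = meta$fov_id,
      pitchUm = meta$pitch_um)
}

#' Write a spectrum table as CSV
#'
#' Label columns first, then one column per channel named by wavenumber.
#'
#' @param spectra a \linkS4class{RamanSpectra}.
#' @param file output CSV path.
#' @return \code{file}, invisibly.
#' @export
writeSpectraCsv <- function(spectra, file) {
  df <- cbind(as.data.frame(spectraLabels(spectra)),
              as.data.frame(t(spectraMatrix(spectra))))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read band definitions from a JSON config
#'
#' Reads a JSON array of band objects (\code{name}, \code{center},
#' \code{width}, optional \code{shape} and integration \code{halfwidth})
#' into the band table used across the package. The seven default
#' biomarker bands ship as
#' \code{system.file("extdata", "default_bands.json", package =
#' "ramanoid")}.
#'
#' @param file path to the JSON band config.
#' @return data.frame as from [bandComponents()], with a
#'   \code{halfwidth} column when present in the config.
#' @export
readBandsJson <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  out <- bandComponents(x$name, x$center, x$width,
                        if (is.null(x$shape)) "lorentzian" else x$shape)
  if (!is.null(x$halfwidth)) out$halfwidth <- x$halfwidth
  out
}

#' Serialize a study design to JSON
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param file output JSON path.
#' @return \code{file}, invisibly.
#' @export
writeDesignJson <- function(design, file) {
  x <- list(
    profiles = lapply(design@profiles, function(p)
      list(stage_weeks = p$stage_weeks, line = p$line,
           concentrations = as.list(p$concentrations))),
    bands = design@bands,
    organoids_per_stage = design@organoidsPerStage,
    fovs_per_organoid = design@fovsPerOrganoid,
    fov_height = design@fovHeight, fov_width = design@fovWidth,
    n_channels = design@nChannels, effect_scale = design@effectScale,
    noise_sd = design@noiseSd,
    baseline_coeff_mean = design@baselineCoeffMean,
    baseline_coeff_sd = design@baselineCoeffSd,
    cosmic_ray_rate = design@cosmicRayRate,
    organoid_sd = design@organoidSd, fov_sd = design@fovSd,
    nuisance_sd = design@nuisanceSd,
    composition_sd = design@compositionSd, pitch_um = design@pitchUm,
    seed = design@seed)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
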