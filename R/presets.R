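# Frozen amplitude tables (arbitrary intensity units) encoding the
# qualitative maturation trends: nucleic-acid and protein bands decrease
# with age, glycogen and polysaccharide increase, phenylalanine is stable.
# Band order: nucleic_acids, glycogen, polysaccharide, phenylalanine,
# amide_III, lipid_CH2, amide_I.
.presetAmplitudes <- list(
  pgp1 = list(
    `6`  = c(1.200, 0.250, 0.300, 0.30, 0.600, 0.35, 1.300),
    `12` = c(1.010, 0.410, 0.304, 0.30, 0.570, 0.35, 1.100),
    `16` = c(0.440, 0.890, 0.316, 0.30, 0.480, 0.35, 0.500),
    `20` = c(0.250, 1.050, 0.320, 0.30, 0.450, 0.35, 0.300)),
  h1 = list(
    `16` = c(0.65, 0.70, 0.55, 0.60, 0.75, 0.78, 0.72),
    `20` = c(0.50, 0.90, 0.70, 0.60, 0.63, 0.82, 0.62)))

.makeProfile <- function(stage, line, amps, bandNames) {
  list(stage_weeks = as.integer(stage), line = line,
       concentrations = stats::setNames(amps, bandNames))
}

#' Frozen synthetic study presets
#'
#' Three ready-made designs mirroring the three organoid experiments:
#' \describe{
#'   \item{\code{"pgp1-4stage"}}{4 maturation stages (6/12/16/20 weeks) x
#'     3 organoids x 6 FOVs of 50 x 50 px, PGP1 amplitude profiles with
#'     monotone glycogen increase and nucleic-acid / protein decrease.}
#'   \item{\code{"h1-2stage"}}{2 stages (16/20 weeks) x 2 organoids x
#'     8 FOVs, H1 profiles (nucleic-acid and amide-III decrease,
#'     polysaccharide increase).}
#'   \item{\code{"line-comparison"}}{PGP1 vs H1 at 16 and 20 weeks (one
#'     organoid per line and stage, 6 FOVs each), with line-dependent
#'     glycogen / lipid / nucleic-acid amplitudes plus a strong
#'     line-independent broad nuisance component that loads on the
#'     leading principal component.}
#' }
#' Amplitudes, noise and design sizes are frozen; \code{...} overrides
#' any [studyDesign()] argument (tests use it to shrink rasters).
#'
#' @param name preset name.
#' @param ... overrides passed to [studyDesign()].
#' @return a \linkS4class{StudyDesign}.
#' @examples
#' ramanPreset("h1-2stage", fovHeight = 10, fovWidth = 10)
#' @export
ramanPreset <- function(name = c("pgp1-4stage", "h1-2stage",
                                 "line-comparison"), ...) {
  name <- match.arg(name)
  bn <- defaultBands()$name
  args <- switch(name,
    "pgp1-4stage" = list(
      profiles = lapply(names(.presetAmplitudes$pgp1), function(s)
        .makeProfile(s, "PGP1", .presetAmplitudes$pgp1[[s]], bn)),
      organoidsPerStage = 3L, fovsPerOrganoid = 6L,
      compositionSd = 0.5),
    "h1-2stage" = list(
      profiles = lapply(names(.presetAmplitudes$h1), function(s)
        .makeProfile(s, "H1", .presetAmplitudes$h1[[s]], bn)),
      organoidsPerStage = 2L, fovsPerOrganoid = 8L,
      compositionSd = 0.15),
    "line-comparison" = list(
      profiles = c(
        lapply(c("16", "20"), function(s)
          .makeProfile(s, "PGP1", .presetAmplitudes$pgp1[[s]], bn)),
        lapply(c("16", "20"), function(s) {
          a <- .presetAmplitudes$h1[[s]]
          # accentuate the line contrast in the discriminating bands
          a[1] <- a[1] * 1.40   # nucleic acids
          a[2] <- a[2] * 0.65   # glycogen
          a[6] <- a[6] * 0.80   # lipid CH2
          a[7] <- a[7] * 1.12   # amide I
          .makeProfile(s, "H1", a, bn)
        })),
      organoidsPerStage = 1L, fovsPerOrganoid = 6L,
      nuisanceSd = 0.8, compositionSd = 0.15))
  do.call(studyDesign, utils::modifyList(args, list(...)))
}
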