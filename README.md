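# ramanoid

Label-free Raman micro-spectroscopy can stage the maturation of 3D
cortical organoids without fixing, sectioning or labelling them: as
organoids mature, nucleic-acid and protein Raman bands fade while
glycogen and polysaccharide bands grow. `ramanoid` is an R package for
analysts working with hyperspectral Raman cubes (H × W pixels × C
spectral channels per field of view) who want to turn raw acquisitions
into a maturation-stage classifier and interpretable biomarker
statements — plus a synthetic-cube generator that reproduces the
statistical structure of such acquisitions, so the entire pipeline is
testable end-to-end without instrument data.

## The method

For each field of view the chain is:

1. **Fingerprint extraction**: keep 600 ≤ ν ≤ 1800 cm⁻¹ (870 of 1340
   channels on the default axis).
2. **Hampel despiking** per pixel spectrum (window half-width 3,
   3 robust SDs, σ̂ = 1.4826·MAD) to remove cosmic-ray spikes.
3. **Savitzky–Golay smoothing** (window 9, order 5).
4. **Iterative polynomial baseline subtraction** (degree 12, 100
   fit-and-clip iterations) to remove autofluorescence.
5. **5 × 5 spatial binning** (50 × 50 → 10 × 10 spectra).
6. **z-score + Frobenius normalization** per spectrum.

The normalized spectra x(ν) are decomposed by centered PCA; a random
forest (50 trees) classifies maturation stage (or cell line) from
selected PC scores, evaluated by stratified k-fold cross-validation
(mean ± SD over folds) and a stratified 70/30 hold-out split (confusion
matrix, precision/recall/F1). Interpretation uses the
importance-weighted loading sum

  W(ν) = Σⱼ wⱼ Lⱼ(ν),

with wⱼ the forest's normalized impurity importances and Lⱼ the PCA
loadings, plus trapezoidal band areas over ±10 cm⁻¹ windows around the
biomarker bands (788 nucleic acids, 850 glycogen, 940 polysaccharide,
1004 phenylalanine, 1350 amide III, 1440 lipid CH₂, 1650 cm⁻¹ amide I)
compared across groups by two-sided Mann–Whitney tests. Separability is
quantified by Euclidean distances between group centroids in PC space,
extrapolated to a minimum detectable time interval Δt_min = θ·Δt/d
(threshold θ = 0.85). A Boruta-style shadow-feature scheme classifies
PC relevance as confirmed / tentative / rejected.

## Worked example

A reduced two-stage study (16 vs 20 weeks, 20 × 20 px FOVs for speed):

```r
library(ramanoid)

design  <- ramanPreset("h1-2stage", fovHeight = 20L, fovWidth = 20L,
                       seed = 7L)
spectra <- preprocessStudy(design)   # generate + full preprocessing
spectra
#> class: RamanSpectra
#> dim: 870 512
#> assays(1): intensity
#> colData names(4): stage_weeks line organoid_id fov_id

pca <- fitPCA(spectra, nComponents = 15)
report <- classifyStages(pca, pcIndices = 1:15, k = 10, seed = 7)
report
#> StageClassification: 2 classes
#>   CV accuracy 100.00% +/- 0.00% over 10 folds
confusionMatrix(report)
#>     predicted
#> true 16 20
#>   16 77  0
#>   20  0 77
```

512 binned spectra (2 stages × 2 organoids × 8 FOVs × 16 bins) are
classified perfectly: the injected stage contrast is far larger than
the residual noise after binning. Band quantification recovers the
injected biochemistry — the glycogen band area rises between the two
stages, and the Mann–Whitney test flags the shift:

```r
trends <- bandTrendAnalysis(spectra)
trends$glycogen$groups
#>   group   n   median       q1       q3
#> 1    16 256 1.608876 1.566239 1.650569
#> 2    20 256 2.181392 2.146939 2.238696
trends$glycogen$tests
#>   group_a group_b U            p   significant
#> 1      16      20 0 2.452568e-85        TRUE
```

Centroid separability in PC space, with the minimum time interval at
which the two stages would remain distinguishable under the linear
distance–time model (the 0.85 threshold is a score-space reference
distance; on synthetic scores its absolute scale is arbitrary):

```r
separabilityAnalysis(pca, pcIndices = c(1, 2, 3))$intervals
#>   from_weeks to_weeks  distance separable min_interval_weeks
#> 1         16       20 0.2181494      TRUE           15.58565
```

The full-size presets are `ramanPreset("pgp1-4stage")` (4 stages × 3
organoids × 6 FOVs of 50 × 50 px), `"h1-2stage"` and
`"line-comparison"`; `runExperiment(design, outDir)` runs everything
and writes spectra, PCA, classification report, band trends,
separability and a reproducibility manifest to disk.

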