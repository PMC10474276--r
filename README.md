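# rcmorph

Objective 3-D quantification of rotator-cuff (RC) muscle size, relative
contribution and fatty infiltration from **partial-coverage** shoulder
segmentation label maps.

Clinical shoulder MRI captures only the lateral portion of the scapula and
RC musculature, and how much varies between scans. Volumetric muscle
measures are therefore incomparable across patients unless the captured
range is normalized. `rcmorph` is aimed at musculoskeletal imaging
researchers working with labelled segmentations (e.g. from an automated
segmentation model): it turns a partial label map into
location-normalized, demographically referenced muscle metrics.

## Method

1. **Scapula-length prediction.** At the sagittal slice of peak scapular
   cross-sectional area (searched in the lateral half of the captured
   extent), four morphometrics are measured: PD (mm, distance from the
   most lateral scapular point to the peak slice), PC (mm², the peak CSA),
   and VB/HB (mm, vertical/horizontal bounding-box extents at that slice).
   Total scapula length `L` is predicted by OLS regression
   `L = β₀ + β₁·PD + β₂·PC + β₃·VB + β₄·HB`, which converts captured
   extent into percent coverage.
2. **Cumulative volume curves** for each region on the integer grid
   p = 1..100 (% of predicted length, measured medially from the most
   lateral scapular voxel, linearly interpolated between slices).
3. **Per-muscle metrics at location p** (fat = intramuscular fat of that
   muscle):

   - normalized muscle size(p) = (muscle(p) + fat(p)) / scapula(p)
   - relative contribution(p) = (muscle(p) + fat(p)) / Σ₄ (muscle(p) + fat(p)) × 100
   - fatty infiltration(p) = fat(p) / (muscle(p) + fat(p)) × 100

4. **Cohort analyses:** partial-vs-full-coverage correlation tables
   (Shapiro-Wilk-gated Pearson/Spearman), scapula-normalization
   correlation sweeps, two-way sex × age ANOVA (Type III, partial η²,
   Bonferroni post-hoc), and a sex × age-bin normative reference database
   yielding per-scan z-scores.

A rigid registration utility (principal-axes initialization + Dice-overlap
pattern search, nearest-neighbour label resampling) aligns full-coverage
CT-derived maps to partial MRI-derived ones, and a phantom generator
produces synthetic shoulders and cohorts with exactly known ground truth
for validation. See the methods vignette
(`vignettes/rcmorph-methods.Rmd`) for design rationale.

## Worked example

Build a small synthetic cohort, fit the length model, and run the full
per-scan pipeline:

```r
library(rcmorph)

specs <- lapply(1:10, function(i) {
  set.seed(i)
  L <- rnorm(1, 146, 15)
  phantom_spec(length_mm = L, peak_frac = runif(1, 0.25, 0.35),
               peak_csa_mm2 = 450 * (L / 150)^2 * runif(1, 0.9, 1.1),
               scapula_height_mm = 20 * L / 150, coverage = 0.75, seed = i)
})
phantoms <- lapply(specs, generate_phantom)
morpho <- do.call(rbind, lapply(phantoms, function(ph)
  as.data.frame(measure_lateral_morphometrics(ph$volume))))
morpho$length_mm <- vapply(phantoms, function(ph) ph$truth$true_length_mm, 1)

model <- fit_length_model(morpho[1:7, ])
evaluate_length_model(model, morpho[8:10, ])
#> Length-model evaluation (n = 3)
#>   mean absolute error: 1.41% (SD 1.43%)
#>   signed error range: -0.79% to 3.05%

compute_scan_metrics(phantoms[[1]]$volume, model)
#> scan_metrics: predicted length 135.9 mm, coverage 75.1%
#>   at p = 30:
#>     supraspinatus  size 0.981, contribution 24.0%, FI 5.2%
#>     infraspinatus  size 1.349, contribution 32.9%, FI 5.2%
#>     teres_minor    size 0.294, contribution 7.2%, FI 5.8%
#>     subscapularis  size 1.471, contribution 35.9%, FI 5.4%
```

The evaluation reports per-scan signed percent errors of predicted versus
true scapula length. The scan metrics show, per muscle at 30% of the
scapula: its size normalized by scapula volume, its share of the
four-muscle RC unit, and its fat fraction — here ≈ 5%, this phantom's
generating fat fraction.

Scans on disk go through `read_label_volume("scan.nii.gz", schema,
laterality)` with an `roi_schema` describing the label integers (default:
the 11-region shoulder schema). A thin command-line front end with
`measure`, `fit-length`, `predict-length`, `metrics`, `register` and
`phantom` subcommands is installed at `inst/cli/rcmorph.R`.

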