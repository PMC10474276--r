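---
title: "Quantifying rotator-cuff morphology from partial-coverage label maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rotator-cuff morphology from partial-coverage label maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcmorph)
```

## The measurement problem

Clinical shoulder MRI is acquired sagittally and captures only the lateral
portion of the scapula and rotator-cuff (RC) musculature — how much varies
from scan to scan. Volumetric muscle measures (size, atrophy, fatty
infiltration) computed on such scans are therefore not comparable across
patients unless the captured extent is normalized. `rcmorph` implements a
location-normalization pipeline for segmentation label maps:

1. **Scapula-length prediction.** Four morphometric measures of the lateral
   scapula are taken at the slice of peak scapular cross-sectional area
   (CSA): the sagittal distance from the most lateral scapular point to the
   peak slice (PD, mm), the peak CSA itself (PC, mm²), and the vertical and
   horizontal extents of the scapula's bounding box in that slice (VB, HB,
   mm). An ordinary least-squares regression of total scapula length on
   (PD, PC, VB, HB) turns a partial scan into a *percent coverage* of the
   full scapula.
2. **Cumulative volume curves.** Each region's cumulative volume is
   expressed on an integer percent grid p = 1..100 of the predicted length,
   measured medially from the most lateral scapular voxel, with linear
   interpolation of the cumulative curve between slice boundaries.
3. **Three per-muscle metrics at location p.**
   *Normalized muscle size* = (muscle + intramuscular fat volume) /
   scapula volume (dimensionless; intramuscular fat is included so the
   compartment, not lean tissue alone, is sized);
   *relative contribution* = a muscle's share of the four-muscle RC unit
   volume (%); *fatty infiltration* (FI) = fat / (muscle + fat) (%).
4. **Cohort statistics.** Partial-vs-full-coverage correlation tables,
   normality-gated correlation, two-way sex × age ANOVA with partial
   η², and a normative sex × age-bin reference database yielding per-scan
   z-scores.

A rigid registration utility aligns a full-coverage (CT-derived) label map
to a partial (MRI-derived) one, and a phantom generator produces synthetic
shoulders with exactly known ground truth, which is how the pipeline is
validated in the absence of clinical data.

## Conventions and their rationale

**Canonical orientation.** The first array axis is sagittal and, after
canonicalization, slice 1 is the most lateral captured slice. Left
shoulders are mirrored along the sagittal axis at read time so left and
right scans pool into one geometry. The in-plane axes are untouched by
mirroring; the bounding-box measures are symmetric under it.

**Peak-CSA search window.** The peak is sought only within the lateral
half of the *captured* scapular extent. The scapula can have a second,
more medial CSA maximum, which partial scans cannot rely on. Using the
captured extent (rather than the unknown full length) is the only option
available at measurement time; its corollary is that on very shallow
truncations (coverage below roughly twice the peak's location fraction)
the detected peak may not be the anatomical one. PD is measured
slice-centre to slice-centre with no sub-slice interpolation; CSA ties
break to the most lateral slice, which is deterministic and biases PD
consistently downward rather than randomly.

**All four predictors are kept.** In practice only PD and PC carry most of
the signal; VB and HB are retained in the deployed model because the full
four-variable regression is the reference specification. `fit_length_model`
accepts a `predictors` argument for a PD + PC sensitivity model.
An intercept is included (standard OLS practice; a zero-morphometrics
scapula is not a meaningful extrapolation target either way).

**Clamping.** A predicted length below the captured extent would imply
more than 100% coverage; `predict()` clamps such predictions up to the
extent and flags them. This situation does not arise in realistic
geometry but the contract must be total.

**Depth accounting.** Depth runs from the most lateral *scapular* voxel.
Muscle tissue lateral to that origin (possible for some insertions) is
folded into the first percent bin rather than dropped, so no captured
volume is lost. Values beyond the captured coverage are `NA`, never
extrapolated. Volumes are reported in ml.

**Fatty-infiltration denominator.** FI is fat over the muscle *boundary*
volume (muscle + intramuscular fat), so FI is bounded in [0, 100] and a
fully infiltrated compartment scores 100%.

## Rigid registration

Inputs are label maps, so an intensity metric is meaningless; the
objective is the Dice overlap of the alignment ROI's binary masks
(default: scapula), directly expressing "least difference between the two
label maps". Initialization aligns mask centroids and principal axes;
because a truncated shape's centroid is offset along its long axis, each
start also sweeps coarse shifts along the fixed first principal axis. All
four proper sign combinations of the principal axes are refined — a
truncated, nearly symmetric shape can score deceptively well flipped — by
a multi-scale coordinate pattern search (steps halved from 8° / 8 mm to
0.25° / 0.25 mm). Pattern search was chosen over simplex methods because
the Dice objective is piecewise constant: simplexes stall on its plateaus,
while fixed-step coordinate moves escape them. Labels are resampled by
nearest neighbour only; label identities are never blended. The procedure
is deterministic; the `seed` argument exists for interface stability.
Recovery accuracy on phantoms is within 1° and one voxel for perturbations
up to 20° / 20 mm.

## Statistical choices

**Normality-gated correlation.** Pearson is used when both series pass
Shapiro-Wilk at α = 0.05, otherwise Spearman. The same α gates every use.

**Type III sums of squares** are used for the sex × age ANOVA (computed on
sum-to-zero contrasts via `car::Anova`), matching the convention of
mainstream point-and-click statistical software on unbalanced designs;
Type II is available as an option. Partial η² = SS_effect /
(SS_effect + SS_error). The sex × age interaction is included and
reported: with two sexes and six age bins the 12-cell model leaves
n − 12 residual degrees of freedom, consistent with F(5, 158) on a cohort
of 170 with two scans excluded for insufficient coverage. Post-hoc
comparisons are all pairwise age-bin tests (pooled across sex) and the sex
pair, Bonferroni-adjusted with the divisor equal to the number of pairwise
tests. Empty design cells make Type III effects inestimable and raise an
error rather than silently re-parameterizing.

**Analysis coverage.** The default working location is p* = 30% of the
scapula, where partial metrics correlate strongly with full-coverage
metrics and which nearly all clinical scans achieve; a 40% companion
analysis is a one-argument change. Scans below the threshold are flagged,
not dropped.

**Age bins.** Six bins: 15–29, 30–39, 40–49, 50–59, 60–69, 70–89 years.
Ages outside [15, 89] are outside the reference population and error on
z-scoring. Reference cells need n ≥ 2 and SD > 0 to be usable.

## The phantom generator

`generate_phantom()` rasterizes an idealized geometric shoulder — it
reproduces the *measurement problem*, not scapular anatomy:

- The scapular CSA profile rises linearly from a lateral base value to a
  single peak (default at 30% of length) and tapers medially, guaranteeing
  the lateral search window's assumption. A pathological medial-peak mode
  (`peak_frac > 0.5`) exists to probe the window's behaviour.
- Cross-sections are axis-aligned rectangles in disjoint row bands. The
  scapula's per-slice widths use nearest rounding (areas within one voxel
  row of the analytic target); muscle compartments use error-diffusion
  rounding so cumulative volume tracks the target to under one voxel
  column (well within the 2% volume contract).
- Intramuscular fat is assigned i.i.d. within each compartment at the
  specified fraction. Real FI is spatially clustered, especially
  laterally; the i.i.d. default makes exact binomial accounting possible,
  and slice-wise area noise (`area_noise_sd`) provides cohorts whose
  medial volume carries independent information.
- Truncation keeps the lateral fraction of the scapular extent, after
  ground truth (per-ROI full volumes and cumulative volume at every 1% of
  true length) is recorded from the untruncated rasterization by direct
  voxel counting.

`generate_cohort()` adds demographic structure: per-cell (sex × age-bin)
sample sizes, sex-specific scapula length (mean 152/140 mm, SD 12 mm,
around the mid-140s mm population average), baseline normalized sizes
(0.8, 1.0, 0.25, 1.1 for supraspinatus, infraspinatus, teres minor,
subscapularis — plausible lateral-30% values with the subscapularis and
infraspinatus dominant and teres minor small), baseline fat fractions of
5% (healthy adults average below 10%), multiplicative age slopes per bin
step and sex factors, and a muscle-scapula volume coupling ρ: muscle
volume follows scapula volume through `V_m ∝ V_s^ρ` with log-normal noise
scaled by √(1 − ρ²), so ρ = 1 gives exact proportionality and ρ = 0
independence (default 0.9). Coverage is drawn uniformly from 35–60%,
emulating the clinical coverage distribution in which most scans reach
30–40% and fewer than half reach 50%.

One consequence of the ρ-coupling deserves emphasis: for ρ < 1,
normalized size `V_m / V_s` retains a residual dependence on scapula
volume (an allometric leak), so a sex difference in scapula length
induces a small systematic sex difference in normalized size even with
the sex effect set to 1. Null-calibration simulations therefore specify
sex-equal length means — that *is* the null condition for the metric —
and the default sex-dimorphic lengths are kept for realistic cohorts.

**What passing phantom tests does and does not show.** The phantoms have
rectangular cross-sections, sharp boundaries, no segmentation error, and
(by default) unclustered fat. Passing tests demonstrates that the
numerical machinery — orientation handling, CSA profiling, regression,
interpolation, the three metric definitions, the ANOVA and z-scoring — is
correct and internally consistent, and that the pipeline's discretization
error is small at clinical voxel sizes. It does not certify accuracy on
real anatomy, segmentation-noise robustness, or the clinical validity of
the 30% threshold.

## Numerical details

- Cumulative curves are interpolated linearly between slice-boundary
  values; at 1 mm in-plane / ≤ 6 mm sagittal spacing the interpolation
  error is below one slice's volume by construction, and halving voxel
  size changes the metrics by well under 1%.
- The captured extent counts whole slices (`n × spacing`); PD is a
  slice-centre distance (`(k − 1) × spacing`). Both conventions are exact
  for the discrete objects actually measured.
- OLS fitting requires n ≥ predictors + 2 and a full-rank design; exact
  collinearity errors out rather than silently dropping a predictor.
- Shapiro-Wilk requires 3 ≤ n ≤ 5000; correlation requires n ≥ 4 pairs
  and non-constant series. In cohort-level correlation tables a constant
  series (e.g. relative contributions in an exactly proportional cohort)
  yields an `NA` row rather than an error.
- Reference databases and length models serialize to plain JSON with
  units recorded.

## Problem sizes used in the validation suite

The test suite validates each property at sizes where the check is
informative yet quick: 20 randomized phantoms for voxel-count oracle
equivalence; 100 seeds at n = 33 (the reference training size) for
regression coverage; 10 random perturbations for registration recovery;
50 seeded cohorts of 8 scans for the coverage-monotonicity sign test;
1000 metric-level null cohorts for ANOVA type-I calibration and 200 for
power at 14 scans per cell; 500 leave-one-out draws for z-score
calibration. `scripts/acceptance.R` re-runs the same pipeline end to end
at comparable sizes and reports the headline numbers.

## Known limitations

- The scapula-length model is fit to phantom or user-supplied training
  pairs; no clinical reference model ships with the package.
- The captured-extent interpretation of the peak-search window can
  misplace the peak on scans with coverage below about twice the peak's
  location fraction; such scans are usually below the 30% analysis
  threshold anyway and arrive flagged.
- Dice-based rigid registration assumes the alignment ROI is present and
  reasonably overlapping in both volumes; it does not handle deformable
  mismatch.
- The ANOVA is a fixed-effects factorial on one metric at one coverage;
  longitudinal or covariate-adjusted normative modelling is out of scope.
- Phantom realism is deliberately limited (see above); conclusions about
  real scans require real data.
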