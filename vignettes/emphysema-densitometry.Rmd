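---
title: "Quantifying emphysema on chest CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying emphysema on chest CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungdens)
```

## The measurement

Pulmonary emphysema destroys alveolar walls and replaces tissue with air,
which lowers X-ray attenuation. On inspiratory volumetric chest CT this is
measurable: a lung voxel whose density is **at or below -950 Hounsfield
units (HU)** is conventionally assigned to emphysema. `lungdens`
implements this density-mask analysis for cohorts where emphysema is a
secondary, developing lesion — the motivating application is cystic
fibrosis (CF), where emphysema emerges in adolescence alongside
bronchiectasis and mucus plugging — together with the statistics used to
relate emphysema burden to lung function and age.

From a segmented lung the package reports:

* **LV** — segmented lung volume (ml): lung voxel count times voxel volume.
* **EV** — emphysema volume (ml): voxels with HU ≤ threshold.
* **EI** — emphysema index EV/LV, stored as a fraction, displayed in percent.
* **MLD** — mean lung density (HU).
* **15th percentile (perc15)** — the HU value below which 15% of lung
  voxels fall; it decreases as emphysema accumulates and is more robust
  than MLD when dense lesions (mucus, consolidation) coexist with
  emphysema.
* **LW** — lung weight (g), from the linear water–air mixture model: a
  voxel at HU *h* has mass density `max(0, (h + 1000)/1000)` g/ml. The
  clamp at -1000 HU keeps noise-driven values physical. This formula is a
  reconstruction — the clinical software this emulates does not publish
  its mass model — and is documented as such.

Three numerical conventions matter and are fixed deliberately:

1. **The threshold comparison is inclusive** (HU ≤ -950). Implementations
   differ on this; a voxel at exactly -950 HU counts as emphysema here.
2. **perc15 uses the inverse empirical CDF without interpolation**: the
   smallest observed HU value *h* such that the fraction of lung voxels
   strictly below *h* is at least 0.15. With 15 voxels at -1000 HU and 85
   at -800 HU, perc15 is -800 exactly. If no observed value qualifies
   (a constant lung) the maximum lung HU is returned.
3. **MLD and perc15 are computed over the full lung mask**, before any
   exclusion mask is subtracted. Exclusions model the manual correction
   step that removes cysts, sacculations and bronchiectatic airways from
   the *emphysema* mask — they change EV and EI only.

The density histogram uses 1 HU bins over [-1024, 200] HU by default; the
bin width is an assumption (the reference analysis does not state one),
and perc15 recomputed from the 1 HU histogram agrees with the raw-value
perc15 to within one bin.

## Segmentation

The analysis needs lungs, and central-airway air must not masquerade as
emphysema. The segmentation is a classical, fully deterministic
threshold/region-growing/closing design; every parameter is recorded in
the result (`params_used`) for reproducibility:

* **Body**: largest 26-connected component above -200 HU, holes filled
  slice-wise. Exterior air is then used to check scanner calibration: the
  mean HU outside the body (excluding the bottom 15% of image rows, where
  the patient table sits) should be -1000 ± 6 HU. The tolerance is a
  typical scanner QA band; the region definition is our reconstruction of
  an "extracorporal air control" and is configurable.
* **Airways**: 6-connected region growing from a trachea seed (auto-detected
  as a round, 50–500 mm², low-HU component in the top third of slices, or
  supplied manually), with the threshold relaxed from -990 HU in 10 HU
  steps. If the grown volume jumps by more than 20 ml between steps the
  growth has leaked into parenchyma and the last pre-leak tree is kept.
  The **whole** grown tree is excluded from the lung, so airway lumen air
  never counts as emphysema.
* **Lungs**: in-body voxels below -500 HU minus the airway tree;
  26-connected components of at least 50 ml (at most two) are kept, closed
  with a 2 mm ball to reincorporate vessels and septa, and labelled
  right = 1 / left = 2 by centre-of-mass column (patient supine). Touching
  lungs are split by eroding until two cores appear and growing the cores
  back through the component (breadth-first, geodesic distance; on convex
  lung shapes this matches Euclidean assignment, and equidistant voxels go
  to the right lung for determinism).

Defaults (-500 HU air threshold, 2 mm closing, 50 ml minimum volume,
20 ml leak step) are standard values in the CT-densitometry literature and
all overridable. Intrapulmonary vessels closed into the mask are counted
in LV; the airway tree is not. Cyst lumina are part of the lung (they are
intrapulmonary lesions) — in phantom ground truth they are included in the
lung mask, which is what makes the exclusion-mask workflow testable.

## Cohort statistics

The statistical layer reproduces a standard cross-sectional design:

* **Group comparisons** (`compare_groups`): Student's t-test when both
  groups pass Shapiro–Wilk at 0.05, otherwise Wilcoxon rank-sum;
  summaries are mean ± SD or median (range) accordingly.
* **Correlation matrix** (`correlation_matrix`): each densitometry metric
  (LV, LW, EV, EI, MLD, perc15) against each lung-function metric (FEV1,
  FEV1%, VC, FEV1/VC, RV, TLC, RV/TLC). Spearman's rank correlation is
  used whenever either variable is EI or a percent-predicted value,
  Pearson otherwise; this single rule is applied uniformly because the
  source analysis states it but does not enumerate pairs. Significance is
  flagged at the Bonferroni-corrected threshold α/m with m the number of
  lung-function tests per metric (7 by default, recomputed if the lists
  change). Spearman p-values use the t approximation for n ≥ 10 and exact
  permutation enumeration below; ties get average ranks.
* **Variance explained** truncates rather than rounds (100·0.66² = 43.56 →
  43), matching how such values are conventionally printed.
* **Age regression** (`fit_age_regression`): ordinary least squares with
  the closed-form t-based confidence band for the mean response. For EI
  the regression operates in percent units, so slopes read as %EI/year —
  a slope of 0.35 means one additional EI percentage point per ~3 years.
* **Onset age** (`ci_band_intersection`): the published notion of the
  "intersection of the 95% confidence limits" of the diseased and control
  regressions is not given an explicit rule in the source; we
  operationalise it as the **first age at which the diseased lower band
  reaches the control upper band** (bisection to 0.1 year). If the bands
  never separate the result is NA; if they are already separate at the
  range minimum that age is returned with a flag.
* **Slope comparison** (`compare_slopes`): group×age interaction in a
  pooled model (ANCOVA) rather than a z-test on separate fits, using the
  pooled residual variance.

## What the synthetic generators emulate

No clinical data ship with the package; two seeded generators make every
stage testable end to end.

### Digital chest phantom

`generate_phantom()` builds a soft-tissue body ellipsoid (+40 HU) in
-1000 HU air, two lung ellipsoids (-850 HU), a blind-ending
trachea/main-bronchus tube, optional thin-walled cysts (walls distinguish
them from wall-less emphysematous bullae), and emphysematous lesions at
-980 HU. Lesions are 2–8 mm spheres placed under a pattern prior —
subpleural (weighted to the lung surface), bronchovascular (weighted
toward, but guarded away from, the airway axis), centrilobular
(mid-parenchyma), or diffuse (voxel-wise) — until the designed fraction of
lung voxels is exceeded, then trimmed back by seeded random removal so the
ground-truth mask holds exactly `round(fraction × n_lung)` voxels. The
recorded design value is this achieved fraction; it differs from the
requested fraction by at most one voxel's worth (~3·10⁻⁵ at the default
64³ grid). Gaussian HU noise is added last; ground-truth masks are
noise-free by construction.

The phantom exercises thresholding, connectivity, leak detection and
exclusion arithmetic. It does **not** emulate CT texture, partial-volume
boundaries, reconstruction kernels, motion, or realistic airway-tree
branching — so passing phantom suites demonstrates correctness of the
computational pipeline, not clinical segmentation performance.

### Synthetic cohort

`generate_cohort()` draws 41 CF and 21 control subjects. CF ages follow
7 + Gamma(shape 1.7, scale 9.4) truncated at 66 (median ≈ 20 years,
clinic-like right skew); control ages 4 + 64·Beta(1.55, 1.95) (median ≈ 30).
EI in percent follows a group line in age — slope 0.35 %/year (CF) versus
0.04 %/year (control) — plus Gaussian noise, floored at 0.

Two calibrations are built into the defaults and were fixed once, at
design time:

* **Onset geometry.** The intercepts (-2.21 CF, 0.5 control) and residual
  SDs (1.2 and 1.1 %EI) are chosen so that the *expected* 95% confidence
  bands of the two regressions first separate at ≈ 13 years
  (`design_onset_age()` solves this analytically from the design lines and
  expected age moments). Realized cohorts scatter around this designed
  crossing; wider noise moves separation later.
* **Rank correlation.** FEV1% is linked to EI through a Gaussian copula:
  the normal scores of the EI ranks are blended with fresh noise at
  correlation ρ = 2·sin(π·ρₛ/6), which yields an expected Spearman
  coefficient of ρₛ (-0.66 by default), then mapped through a gamma
  marginal (mean 46, SD 30 %predicted in CF). This closed form replaces a
  Monte-Carlo noise search and is verified by simulation in the test
  suite.

The other variables carry the sign structure of the clinical correlation
table: TLC and RV/TLC increase with EI in CF (hyperinflation), RV =
RV/TLC·TLC and VC = TLC − RV keep the physiological identities exact,
perc15 decreases and lung weight increases with disease, and CT lung
volume is TLC·1000 − 400 ml + noise (dead space and breath-hold offset),
giving a pooled LV–TLC Pearson r above 0.9. PFT columns are set missing
for 2 CF and 6 control subjects, matching the published PFT subgroup
sizes (39/15).

The residual EI noise is measurement-scale, far below the population SD a
real CF cohort shows (≈ 7.5 %EI): the generator reproduces the mean age
structure, orderings and correlation signs, **not** population
heterogeneity. Quantities that depend on that heterogeneity (group SDs,
absolute EV/EI distributions) are therefore not comparable to clinical
values, and the test suite does not assert them.

## Problem sizes and tolerances

The validation suite uses 64³ phantoms at 3 mm spacing for pipeline
checks (≈ 23 000 lung voxels), 36³ phantoms for the brute-force oracle
comparison (production vectorised code versus a naive per-voxel triple
loop; integer counts must match exactly, floating-point panel values to
1e-9 relative), and 200 replicate cohorts for the statistical recovery
checks (slope-CI coverage ≥ 90%, slope-difference p < 0.001 in ≥ 95% of
replicates, mean Spearman within ±0.05 of target, onset-age median within
±3 years of the designed crossing). EI recovery through the full
segmentation pipeline is required to within 0.02 of the designed fraction
for fractions up to 0.20 and noise up to 7 HU; the dominant error source
is boundary voxels, since the -980/-850/-950 margins put per-voxel
misclassification beyond 4 noise SDs.

## Known limitations

* DICOM series are not read in this build; convert to NIfTI or MetaImage
  first. Rescale handling therefore lives upstream.
* No resampling, registration or kernel harmonisation: all masks must
  share the CT grid, and densitometry is computed on native voxels.
* No lobe segmentation, no fissures, no machine-learned segmentation; the
  per-lung split is left/right only.
* No expiratory air-trapping analysis (the -860 to -950 HU band) and no
  texture-based emphysema subtyping; pattern labels exist only in the
  phantom generator's priors.
* The phantom's geometry is ellipsoidal and its noise white Gaussian;
  claims about real-scanner robustness require real data.
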