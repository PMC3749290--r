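# lungdens

Quantitative emphysema densitometry for volumetric chest CT.

Emphysema replaces lung tissue with air and lowers CT attenuation. On
inspiratory CT, lung voxels with density **at or below -950 Hounsfield
units (HU)** are assigned to emphysema (the "density mask"). From a
segmented lung, `lungdens` computes the standard densitometric panel —

* **LV** lung volume (ml), **EV** emphysema volume (ml),
* **EI** = EV/LV, the emphysema index,
* **MLD** mean lung density (HU),
* **perc15**, the 15th percentile of the lung density histogram (HU),
* **LW** lung weight (g) via the linear water–air density model,

— with exclusion-mask correction (so cysts and bronchiectatic airways do
not inflate EI), minimum-intensity-projection rendering, and the cohort
statistics used to relate emphysema to lung function and age in diseases
such as cystic fibrosis (CF): t/Wilcoxon group comparisons,
Bonferroni-corrected Pearson/Spearman correlation matrices against
spirometry and plethysmography (FEV1%, RV, TLC, RV/TLC, ...), age
regression with 95% confidence bands, the band-separation onset age, and
slope comparison via the group×age interaction.

The package is aimed at imaging researchers who want a reproducible,
fully-tested reference implementation of density-mask analysis. Because
no clinical data ship with it, it includes seeded synthetic generators
with exact ground truth: 3D chest phantoms (body/lung/airway/emphysema/
cyst compartments at realistic HU) and CF-versus-control cohorts with the
statistical structure of a real study (EI–age slopes 0.35 vs 0.04 %/year,
Spearman(EI, FEV1%) ≈ -0.66, onset ≈ 13 years).

## Worked example

```r
library(lungdens)

# a 64^3 phantom with a designed 10% emphysema fraction and 3 HU noise
ph  <- generate_phantom(phantom_spec(emphysema_fraction = 0.10,
                                     noise_sd = 3, seed = 1))
seg <- segment_lungs(ph$volume)
seg
#> <segmentation_result> right lung 307 ml, left lung 308 ml, airway 20 ml

emph   <- compute_density_mask(ph$volume, seg$lung_mask, threshold = -950)
report <- compute_report(ph$volume, seg$lung_mask, emph)
report
#> <densitometry_report> scope: whole (threshold -950 HU)
#>   LV 615 ml | EV 61 ml | EI 9.9%
#>   MLD -862.8 HU | 15th percentile -855 HU | LW 84 g
```

The pipeline recovers the designed 10% fraction as EI = 9.9% (the
difference is a handful of segmentation boundary voxels); MLD sits
between the parenchymal -850 HU and the emphysematous -980 HU, and perc15
reflects the low-attenuation tail.

```r
# a synthetic cohort: 41 CF vs 21 control subjects
sim  <- generate_cohort(cohort_spec(seed = 1))
cf   <- subset(sim$table, group == "CF")
ctrl <- subset(sim$table, group == "control")

fit_cf   <- fit_age_regression(cf$age,   100 * cf$EI)    # EI in %
fit_ctrl <- fit_age_regression(ctrl$age, 100 * ctrl$EI)
fit_cf
#> <regression_band> y = -2.405 + 0.3556 * age (n = 41, residual SD 0.971, 95% CI)
fit_ctrl
#> <regression_band> y = 0.8628 + 0.03962 * age (n = 21, residual SD 1.1, 95% CI)

ci_band_intersection(fit_cf, fit_ctrl, range(sim$table$age))$age
#> [1] 14

compare_groups(sim$table, "EI")
#> <group_comparison> EI: CF 0.0368 (0-0.112) (n=41) vs control 0.0212 (0-0.0411)
#>   (n=21); wilcoxon test p = 0.000677
```

This realisation recovers the generator's design: slopes 0.356 vs 0.040
%EI/year against the designed 0.35/0.04, and the 95% confidence bands of
the two regressions first separate at 14.0 years against a designed
crossing of 13. `correlation_matrix(sim$table, group = "CF")` produces
the per-pair Pearson/Spearman table with Bonferroni flags at 0.05/7, and
`plot_age_regression(sim$table)` draws the dot plot with CI bands
(requires ggplot2).

A thin command-line wrapper over these functions lives at
`inst/scripts/lungdens.R` (subcommands `simulate-phantom`,
`simulate-cohort`, `segment`, `densito`, `cohort`, `run-all`).

## Documentation

The methods vignette (`vignettes/emphysema-densitometry.Rmd`) documents
the measurement model, the segmentation design and its parameters, the
statistical conventions (inclusive threshold, perc15 rule, truncated
variance explained, onset-age operationalisation), what the synthetic
generators do and do not emulate, and known limitations. Function-level
documentation is in the roxygen comments under `R/`.
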