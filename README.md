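# relaxomap

Quantitative T1/T2 relaxometry mapping, multi-atlas parcellation and
inter-center agreement statistics for preclinical brain MRI — with a fully
synthetic digital phantom, so the entire pipeline is testable end to end
without any scanner data.

## The problem

Relaxation times T1 and T2 are tissue-specific, quantitative MR biomarkers.
Estimating them regionally in the rodent brain takes three steps: fit a
signal model voxel-per-voxel to a series of weighted images, parcellate the
brain into regions, and average the fitted values per region.  When several
imaging centers pool data, every step becomes a potential source of
disagreement — different scanners, different fitting software, different
segmentation implementations.  `relaxomap` implements those steps together
with the statistics used to quantify each source of disagreement, plus a
simulation layer that generates multicenter-like data with known ground
truth.

## Models

For an inversion-recovery series with inversion times TI (magnitude data,
no phase), each voxel is fitted with the three-parameter model

    s(TI) = | A (1 − B exp(−TI / T1)) |

where a free inversion factor B (ideally 2) absorbs imperfect inversion
and incomplete recovery over TR.  A multi-echo T2 series is fitted with
the two-parameter mono-exponential

    s(TE) = A exp(−TE / T2)

Two interchangeable optimizer backends (Levenberg-Marquardt and
Nelder-Mead simplex) minimize the same per-voxel sum of squares; fitted
values outside (0, 3000] ms for T1 or (0, 300] ms for T2 are discarded.
Parcellations are fused from several co-registered atlas label volumes by
a per-voxel maximum-probability (plurality) vote, and compared by Dice
overlap and parcel volume.  Agreement between centers, fitting pipelines,
segmentation pipelines or repeated scans is reported with Bland-Altman
limits (mean ± 2 SD), regression to identity with R², symmetric mean
percent error, and exact Mann-Whitney / Wilcoxon signed-rank tests gated
by Shapiro-Wilk normality.  See `vignette("relaxometry-pipeline")` for the
methods in detail.

## Worked example

```r
library(relaxomap)

# 1. phantom with ground truth
spec <- phantom_spec(grid_shape = c(32, 32, 16), seed = 1)
phantom <- make_label_phantom(spec)
truth <- truth_maps(phantom, spec)

# 2. simulate a 7-point inversion-recovery acquisition at peak SNR 50
series <- simulate_ir_series(truth$t1_ms, truth$proton_density,
                             noise_sigma = 20, seed = 1)

# 3. fit the T1 map voxel-per-voxel (Levenberg-Marquardt)
t1_map <- fit_t1_map(series, fit_options("LEAST_SQUARES_LM"))
#> <parameter_map> IR_T1, 32x32x16 grid, 6495/16384 valid voxels

# 4. regional statistics
stats <- region_means(t1_map, phantom)
head(stats[, 1:5], 4)
#>   label_id            region_name n_valid_voxels  mean_ms     sd_ms
#> 1        1 3rd and 4th ventricles             64 2770.517 133.80943
#> 2        2             Amygdala L            236 1802.681  91.53313
#> 3        3             Amygdala R            246 1811.990 103.08292
#> 4        4      Caudate-putamen L            246 1753.027  93.85473

# 5. does a second center agree? (same phantom, different gain/bias/noise)
series_c2 <- apply_center_effect(series,
  center_effect(gain = 1.1, bias_field_amplitude = 0.08,
                noise_sigma = 10, seed = 2))
stats_c2 <- region_means(fit_t1_map(series_c2), phantom)
agreement_report(stats$mean_ms, stats_c2$mean_ms)
#> <agreement_report> n = 29 pairs (alpha = 0.01, nonparametric primary)
#>   Bland-Altman: mean diff 0.1415, limits [-13.4, 13.68]
#>   regression:   y = 0.9885x + 21.6 (R2 = 0.9996)
#>   mean % error: 0.206%   Mann-Whitney p = 0.889   Wilcoxon p = 0.243
```

Reading the output: the ventricle region (CSF truth 2800 ms) averages
2770 ms over its 64 valid voxels; tissue regions land within ~1% of their
truth.  The second center's gain and smooth bias field leave the fitted
relaxation times nearly untouched (decay fitting is scale invariant), so
the two "centers" agree to 0.21% mean error, the regression hugs the
identity line and neither rank test approaches the α = 0.01 significance
level.

A whole study — subjects × centers × scans × fitting pipelines × atlas
sets — runs from one YAML configuration:

```r
cfg <- default_study_config()
cfg$master_seed <- 42
run_study(cfg, "study_out/")   # CSV reports + manifest + log
```

A thin command-line wrapper with `simulate`, `fit-t1`, `fit-t2`, `fuse`,
`dice`, `stats` and `run-study` subcommands is installed at
`system.file("cli", "relaxo.R", package = "relaxomap")`.

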