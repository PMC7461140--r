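# spectromed

Mediation analysis linking mid-infrared (ATR-FTIR) spectral features of
tissue-culture-derived plants to DNA sequence variation through methylation
change.

## The problem

Plants regenerated in vitro accumulate DNA sequence variants and altered
cytosine methylation. One way to probe the biochemistry behind this is to
treat an integrated infrared band absorbance (a proxy for compounds such as
β-glucans, cellulose or methyl-donor metabolites) as the predictor X, a
methylation-derived quantity (demethylation of CHG cytosine contexts,
`chg_dmv`, percent) as the mediator M, and the sequence-variation
percentage `sv` as the outcome Y. `spectromed` is for researchers running
exactly this kind of spectroscopy-to-genotype analysis: it provides the
spectral preprocessing, the mediation machinery, the time-moderated
extension, and a window-wise screen over the whole spectrum, plus seeded
synthetic generators so every stage can be validated against known truth.

The core model is the product-of-coefficients decomposition from three OLS
fits —

```
m = i1 + a·x          y = i2 + c'·x + b·m          y = i3 + c·x
```

— with indirect effect `ab` (percentile bootstrap CI), the exact identity
`c = c' + ab`, variance accounted for `VAF = 100·ab/c`, Goodman test
`Z = ab / sqrt(b²s_a² + a²s_b² − s_a²s_b²)`, and, in the moderated model,
conditional indirect effects `θ(w) = (a1 + a3·w)(b1 + b2·w)` with
analytically solved Johnson–Neyman significance regions.

The package ships the 35-regenerant barley dataset the methods were
developed on (`regenerant_data()`): per-plant integrated absorbances over
710–690 and 1010–940 cm⁻¹, metAFLP demethylation and sequence-variation
percentages, and culture time (21/28/35 days) across nine trials.

## Worked example

```r
library(spectromed)

reg <- regenerant_data()
fit <- mediate_simple(reg, f1010_940, chg_dmv, sv,
                      boot = boot_config(n_boot = 5000, seed = 1))
fit
#> Simple mediation: f1010_940 -> chg_dmv -> sv  (n = 35)
#> # A tibble: 5 × 7
#>   term    estimate std.error statistic  p.value conf.low conf.high
#>   <chr>      <dbl>     <dbl>     <dbl>    <dbl>    <dbl>     <dbl>
#> 1 a         -15.6      6.11      -2.55 1.57e- 2   NA           NA
#> 2 b          -8.24     0.852     -9.67 5.18e-11   NA           NA
#> 3 c_prime    51.3     32.7        1.57 1.27e- 1   NA           NA
#> 4 c         180.      58.3        3.08 4.18e- 3   NA           NA
#> 5 ie        128.      NA          2.48 1.33e- 2    0.369      284.
#> Indirect effect a*b = 128.2254, 95% percentile bootstrap CI [0.3695, 283.8686]
#> VAF = 71.4%; Goodman z = 2.475 (p = 0.0133)
```

Reading: a unit increase in the 1010–940 cm⁻¹ integrated absorbance lowers
CHG demethylation (`a = -15.6`), lower CHG demethylation lowers sequence
variation (`b = -8.24`), and their product — the mediated effect,
`ab ≈ 128` — accounts for 71.4% of the total effect `c ≈ 180`. The
bootstrap CI excludes zero, so the mediation is supported.

Moderation by culture time, with the combined absorbance as predictor:

```r
mm <- mediate_moderated(reg, f_combined, chg_dmv, sv, time_days,
                        boot = boot_config(n_boot = 5000, seed = 1))
conditional_indirect(mm, c(21, 28, 35))
#> # A tibble: 3 × 7
#>       w estimate    se statistic p.value conf.low conf.high
#>   <dbl>    <dbl> <dbl>     <dbl>   <dbl>    <dbl>     <dbl>
#> 1    21   345.   152.      2.28   0.0229    12.6      634.
#> 2    28    46.3   31.9     1.45   0.146     -8.29     113.
#> 3    35     8.07  28.1     0.287  0.774    -44.7       70.0

johnson_neyman(mm, "a")
#> Johnson-Neyman region, a path, alpha = 0.05
#>   boundary at w = 30.1568
#>   boundary at w = 46.3294 (outside observed range)
```

The mediated effect is strong early (significant at 21 days) and fades
with culture time; the Johnson–Neyman boundary puts the significance limit
of the spectral-feature-to-demethylation path at about 30 days.

Other entry points: `scan_mediation()` runs the mediation in every
10 cm⁻¹ window of a spectral cohort; `deconvolve_peaks()` resolves
overlapping bands into Gaussian components; `simulate_spectra()` /
`simulate_mediation()` generate seeded synthetic data;
`tidy()`, `glance()` and `autoplot()` work on every fitted object. The
vignette (`vignettes/spectral-mediation.Rmd`) documents the models,
conventions and numerical choices.

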