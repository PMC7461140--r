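---
title: "Linking infrared spectral features to DNA sequence variation by mediation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking infrared spectral features to DNA sequence variation by mediation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(spectromed)
library(dplyr)
```

## The scientific setting

Plants regenerated through in vitro tissue culture accumulate DNA sequence
changes and altered cytosine methylation relative to their donor. One
mechanistic hypothesis is that culture stress perturbs biochemical pools
(cell-wall glucans, cellulose, methyl-donor metabolites), that these
perturbations drive demethylation — particularly at CHG cytosine contexts —
and that demethylated sites are the substrate on which sequence variants
arise. None of the biochemical players is measured directly; instead, a
mid-infrared (ATR-FTIR) spectrum of powdered leaf tissue acts as a cheap,
comprehensive biochemical fingerprint, and methylation-sensitive AFLP
(metAFLP) markers quantify demethylation (`chg_dmv`, percent) and sequence
variation (`sv`, percent) per regenerant.

`spectromed` implements the full analysis chain for this design:

1. **spectral preprocessing** — baseline correction, area normalization,
   band integration, fixed-width fragmentation, Gaussian deconvolution;
2. **simple mediation** — integrated band absorbance X, mediator M
   (CHG demethylation), outcome Y (sequence variation), with bootstrap
   confidence intervals for the indirect effect;
3. **moderated mediation** — culture duration (21/28/35 days) moderating
   the X-to-M and M-to-Y paths, with conditional indirect effects and
   Johnson–Neyman regions;
4. **a window-wise screen** — mediation re-run in every 10 cm⁻¹ fragment
   of the spectrum to locate mediating spectral regions;
5. **synthetic generators** for both spectra and mediation datasets, so
   every stage is testable against known ground truth.

The bundled dataset (`regenerant_data()`) contains the 35 barley
regenerants the methods were developed on: two integrated band absorbances
(710–690 and 1010–940 cm⁻¹, plus their sum), the metAFLP characteristics
and the culture time, across nine culture trials.

## The mediation model

For a predictor x, mediator m and outcome y, three ordinary least-squares
regressions define the standard product-of-coefficients decomposition:

\[
m = i_1 + a x, \qquad
y = i_2 + c' x + b m, \qquad
y = i_3 + c x .
\]

The indirect (mediated) effect is \(ab\), the direct effect is \(c'\), and
under OLS the decomposition \(c = c' + ab\) is exact — the package asserts
this identity to 1e-8 on every fit it tests. Mediation strength is
summarized as the *variance accounted for*, \(\mathrm{VAF} = 100\,ab/c\)
(values above 80% are conventionally read as full mediation), and the
partially/completely standardized indirect effects
(\(ab/\mathrm{SD}(y)\) and \(ab\,\mathrm{SD}(x)/\mathrm{SD}(y)\), sample
SDs with the n−1 denominator).

Interval estimation for \(ab\) uses a seeded case-resampling bootstrap
(default 5000 draws, 95% percentile interval; a bias-corrected variant is
available via `boot_config(type = "bc")`). Percentile is the default
because it is the convention for indirect effects and makes no symmetry
assumption; the original analyses' resampling seeds are unknowable, so CI
endpoints are reproducible only qualitatively (sign, exclusion of zero),
and the package treats them that way in its tests. Internally the
bootstrap is vectorized: each resample is a multinomial weight vector, and
all path estimates are recovered from weighted first and second moments in
one matrix product — algebraically identical to refitting OLS per resample
(unit-tested against literal `lm` refits), but fast enough for
thousand-replicate validity studies.

Normal-theory significance of \(ab\) uses the Goodman statistic

\[
Z = \frac{ab}{\sqrt{b^2 s_a^2 + a^2 s_b^2 - s_a^2 s_b^2}},
\]

with the Sobel denominator \(\sqrt{b^2 s_a^2 + a^2 s_b^2}\) as an
automatic, flagged fallback when the Goodman denominator is non-positive
(the subtracted term can dominate when both paths are weak relative to
their errors). Where the denominator is valid, \(|Z_{Goodman}| \ge
|Z_{Sobel}|\) by construction. Standard errors are classical OLS
throughout; that is what reproduces the reference results on the bundled
data.

```{r}
reg <- regenerant_data()
fit <- mediate_simple(reg, f1010_940, chg_dmv, sv,
                      boot = boot_config(n_boot = 5000, seed = 1))
glance(fit) |> select(a, b, c_prime, c, ie, vaf, goodman_z, goodman_p)
```

## Moderated mediation and Johnson–Neyman regions

Culture duration w (days) may change both how strongly a spectral feature
drives demethylation and how strongly demethylation translates into
sequence variants. The default moderated model therefore carries raw
(uncentred) interactions on the a and b paths only:

\[
m = i_1 + a_1 x + a_2 w + a_3 x w, \qquad
y = i_2 + c'_1 x + c_2 w + b_1 m + b_2 m w .
\]

Products are deliberately not mean-centred so the coefficients stay on the
reported scale. With n = 35 this yields the characteristic residual
degrees of freedom 31 (mediator model) and 30 (outcome model). A variant
with the direct path moderated as well (`moderate = c("a","b","cprime")`)
is available; it costs one further outcome degree of freedom. The
highest-order interaction in each model is tested by the R²-change F test
between nested fits (`interaction_f_test()`).

The conditional indirect effect at moderator value w is the exact algebra
\(\theta(w) = (a_1 + a_3 w)(b_1 + b_2 w)\); its uncertainty is assessed by
case-resampling bootstrap of the whole two-model system (the product of
two conditional slopes has no convenient finite-sample distribution, so
the delta method is reserved for single paths).

The Johnson–Neyman technique asks for which w a single conditional path
\(\beta_{main} + \beta_{int} w\) is distinguishable from zero:
\(|\theta(w)| = t_{crit}\,\mathrm{SE}(\theta(w))\) with
\(\mathrm{Var}(\theta(w)) = v_{11} + 2w\,v_{13} + w^2 v_{33}\) from the
coefficient covariance. Squaring gives a quadratic in w, solved in closed
form; a fine-grid scan is used as an independent oracle in the tests.
Boundaries outside the observed moderator range are reported and flagged
rather than hidden, since extrapolated significance statements are not
meaningful.

```{r}
mm <- mediate_moderated(reg, f_combined, chg_dmv, sv, time_days,
                        boot = boot_config(n_boot = 5000, seed = 1))
glance(mm)
conditional_indirect(mm, c(21, 28, 35)) |> select(w, estimate, conf.low, conf.high)
johnson_neyman(mm, "a")$boundaries
```

**Aggregate summary convention.** For a moderated model there is no single
canonical "overall indirect effect". `modmed_summary()` reports the
main-effect product \(a_1 b_1\) as the aggregate indirect effect, the sum
\(a_1 b_1 + c'\) as the corresponding total, and
\(\mathrm{VAF} = 100\,a_1 b_1/(a_1 b_1 + c')\). This convention is stated
rather than argued for: with raw (uncentred) products, \(a_1\) and
\(b_1\) are the conditional paths at w = 0, and their product summarizes
the path system in a single scale-consistent number that reproduces the
reference analysis of the bundled data. The per-w conditional effects are
the scientifically interpretable quantities and are always reported
alongside.

## Spectral preprocessing choices

- **Baseline**: instrument vendors apply proprietary corrections; the
  package replaces them with a documented anchor-window procedure —
  subtract the line (or piecewise-linear curve) through the mean
  absorbance of user-chosen anchor windows, with constant extrapolation
  beyond the outermost anchors. One anchor degenerates to an offset
  subtraction.
- **Area normalization** (`normalize_area()`, default 1800–900 cm⁻¹)
  divides the whole spectrum by one factor so the reference-window
  integral is 1, removing global intensity differences (ATR contact
  pressure, sample amount). It is idempotent and makes spectra that
  differ by a global factor identical.
- **Integration** (`integrate_band()`) is the trapezoid rule on the
  native grid with linear interpolation at the window edges: standard,
  deterministic, exactly additive over adjacent windows, and agnostic to
  the high-to-low storage orientation of mid-IR spectra.
- **Order of operations**: band integrals are computed on the
  area-normalized spectrum (normalize-then-integrate). Integrating first
  and normalizing the resulting areas would differ only by the global
  factor and is available by composing the functions the other way.
- **Fragmentation** (`fragment_spectrum()`) tiles from the
  high-wavenumber end in fixed 10 cm⁻¹ steps; a final narrower window at
  the low end is kept and flagged `partial` so the tiling always covers
  the range exactly once.
- **Deconvolution** (`deconvolve_peaks()`) fits a sum of Gaussians by
  Levenberg–Marquardt least squares. Heights and widths enter through
  their absolute values, making non-negativity a parameterization rather
  than a constraint; the budget is 10000 function evaluations with
  relative-RSS convergence 1e-10; non-convergence is a flag, not an
  error; and the returned fit is never worse than the starting point
  (the start is returned if the optimizer somehow ends higher). Good
  initial centres matter — in practice they come from visible shoulders,
  and the fitted peaks are returned sorted by descending centre.

## The window-wise screen

`scan_mediation()` integrates every fragment for every sample and feeds
each window's areas into the identical mediation code path used by
`mediate_simple()` (a single-window scan is bitwise equal to a direct
call). Each window's bootstrap seed is `bitwXor(master_seed, window_index)`,
so results are independent of evaluation order and individually
reproducible. Two decision rules are computed: the default flags windows
whose bootstrap CI excludes zero; `sig_bh` applies Benjamini–Hochberg
across the ~360 windows of a full-range scan to the Goodman p values. The
uncorrected per-window rule is also available (`rule = "raw"`) because a
screening analysis without multiplicity control is a common historical
practice that users may need to reproduce — but the BH column is always
reported so the cost of that choice is visible. Zero-variance windows
(possible in flat spectral regions) are skipped with a warning.

## What the synthetic generators emulate — and what they do not

`simulate_spectra()` draws spectra as a sum of Gaussian bands at twelve
default centres between 1153 and 670 cm⁻¹, plus optional linear drift and
Gaussian noise on the 4000–400 cm⁻¹, 4 cm⁻¹ grid. The default heights and
widths were chosen once for realism: strong broad polysaccharide bands
near 1036–1069 cm⁻¹, and a weak narrow low-frequency cluster whose
area relative to the 1010–940 region (about 1:30) matches the bundled
data's two integrated absorbances. Drift defaults to zero because the
template represents an already baseline-corrected measurement; it can be
switched on to exercise `baseline_correct()`. A latent per-sample factor
can drive selected peak heights linearly (`effect_map`), which is how a
"compound that also drives methylation" is planted in screening
simulations; the linkage is kept linear (no clamping) so planted
correlations are exactly 1 in the noiseless case.

`simulate_mediation()` draws the predictor uniformly over the observed
absorbance range 0.02–0.06 (a fixture-resampling mode exists for power
studies on realistic predictor spacing), applies the two-equation model
with Gaussian residuals, and emits the result in the regenerant-table
schema so it flows through the same I/O validation as real data. Default
paths mirror the fitted values on the bundled data; the intercepts are
placed so the emitted percentages stay positive in the bulk of the
distribution.

Features of the real data that the generators deliberately do **not**
emulate: the strongly skewed outcome distribution (three regenerants in
one trial carry sequence variation near 14% against a background near
2–4%), the discreteness of metAFLP-derived percentages, between-trial
correlation structure, and ATR-specific artifacts (penetration-depth
wavelength dependence, water-vapor lines). Passing the synthetic validity
suite therefore demonstrates correctness of the estimators under the
stated Gaussian model — coverage, type-I error, parameter recovery — not
robustness to those real-data features.

## Numerical and degenerate-input policy

- Rank-deficient designs raise an error naming the aliased columns;
  nothing is silently dropped. A fully noiseless mediator stage is the
  canonical example: it makes the mediator collinear with the predictor
  and the outcome model unidentifiable.
- Zero-variance variables, out-of-range windows, non-positive
  normalization integrals and a zero total effect (undefined VAF) are
  typed errors.
- Bootstrap resamples that are internally degenerate (zero predictor
  variance after resampling — vanishingly rare for n ≥ 10) are dropped as
  `NA` rather than propagated.
- Quantiles for percentile intervals use the `stats::quantile()` default
  (type 7); with thousands of draws the choice is immaterial relative to
  resampling noise.
- Printed-table validation tolerances: 1e-4 (inclusive) for the
  absorbance sum, because independently rounded 4-decimal columns can
  disagree by exactly one unit in the last place, and 5e-3 for the
  demethylation sum.

## Validation design and problem sizes

The package's acceptance suite recomputes every desk-scale quantity from
the bundled table deterministically, and validates the stochastic
machinery at these sizes, chosen as the package's validation design:
bootstrap coverage over 1000 replicates of n = 500 with 1000 resamples
each (nominal 95%, accepted band 93–97%); type-I error of the
indirect-effect CI over 500 replicates of n = 200 under a null a path
(accepted band 3–7%); Johnson–Neyman boundaries against a 0.01-step grid
oracle; and the windowed screen on a 1200–800 cm⁻¹ cohort of 60 samples —
150 seeds for planted-band recovery and false-positive accounting, 60
seeds for the all-null BH check.

## Known limitations

- Band-centre localization under noise has intrinsic limits: with the
  default template, bands at 5–6% of the spectrum maximum that overlap
  within one width (the 719/710/701 triplet, and the broad 1104/1153
  pair) cannot reliably be localized to 2 cm⁻¹ once noise reaches 1% of
  the spectrum maximum — at that level the per-point SNR on the weak
  bands is about 5. At 0.1% noise (still far above a modern instrument's
  floor) all twelve centres recover within 2 cm⁻¹ in every tested seed.
- Integrated absorbances of magnitude ~0.001 printed to four decimals
  carry ~5% rounding uncertainty, which propagates into any regression
  slope computed from them; conclusions that depend on such weak bands
  should be drawn from the unrounded spectra.
- JCAMP-DX input is not implemented; spectra are exchanged as two-column
  CSV.
- The moderated-mediation bootstrap resamples cases; for designs with few
  distinct moderator values and small n, stratified resampling (not
  implemented) could be preferable.
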