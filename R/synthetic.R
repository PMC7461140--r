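#' Default Gaussian band set for synthetic plant-leaf spectra
#'
#' Twelve bands at the component positions typically resolved in the
#' 1200--600 cm-1 fingerprint region of dried leaf tissue (polysaccharide
#' ring/C-O stretches near 1153--1036, the deoxyribose-associated 960,
#' glycosidic 896, and the narrow low-frequency cluster 719/710/701/670).
#' Heights (relative absorbance) and widths are plausible for
#' area-normalized leaf spectra: broad, strong polysaccharide bands up
#' around 1050 cm-1 and weak, narrow bands below 850 cm-1.
#'
#' @return A [gaussian_peaks()] tibble with 12 rows.
#' @export
default_peaks <- function() {
  gaussian_peaks(
    center = c(1153, 1104, 1069, 1036, 991, 960, 896, 825, 719, 710, 701, 670),
    height = c(0.40, 0.55, 0.95, 1.00, 0.25, 0.18, 0.12, 0.10,
               0.060, 0.060, 0.050, 0.080),
    fwhm   = c(45, 40, 38, 32, 22, 20, 20, 14, 10, 9, 10, 14)
  )
}

#' Template describing how synthetic spectra are generated
#'
#' A synthetic spectrum is a sum of Gaussian bands on an evenly spaced
#' wavenumber grid, plus an optional linear baseline drift and Gaussian
#' noise. The defaults emulate a baseline-corrected ATR-FTIR measurement of
#' powdered leaf tissue recorded from 4000 to 400 cm-1 at 4 cm-1
#' resolution: `baseline_slope = 0` (drift is opt-in, for exercising
#' [baseline_correct()]) and `noise_sd = 0.005` absorbance units
#' (a high signal-to-noise instrument after scan averaging).
#'
#' @param peaks A [gaussian_peaks()] table (default [default_peaks()]).
#' @param baseline_slope Linear drift in AU per cm-1 (applied as
#'   `slope * (wavenumber - min(grid))`).
#' @param noise_sd Standard deviation of additive Gaussian noise (AU).
#' @param grid `c(start, stop, step)` in cm-1; spectra are emitted high to
#'   low wavenumber.
#' @return A list of class `"spectrum_template"`.
#' @export
spectrum_template <- function(peaks = default_peaks(), baseline_slope = 0,
                              noise_sd = 0.005, grid = c(4000, 400, 4)) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (grid[3] <= 0) abort("Grid step must be positive.")
  structure(list(peaks = as_tibble(peaks), baseline_slope = baseline_slope,
                 noise_sd = noise_sd, grid = as.numeric(grid)),
            class = "spectrum_template")
}

template_grid <- function(template) {
  g <- template$grid
  seq(max(g[1], g[2]), min(g[1], g[2]), by = -abs(g[3]))
}

#' Simulate spectra with a known latent driver
#'
#' Draws `n` spectra from a [spectrum_template()]. Each sample has a latent
#' standard-normal factor; `effect_map` ties selected peak heights linearly
#' to that factor (`height_i = height + slope * factor_i`, kept linear so
#' planted linkages are exactly recoverable), which is how a
#' concentration-varying compound enters the synthetic cohort. The latent
#' factors are returned as ground truth for screening simulations.
#'
#' @param template A [spectrum_template()].
#' @param n Number of spectra.
#' @param effect_map Optional data frame with columns `center` and `slope`;
#'   `center` must match template peak centres exactly.
#' @param seed RNG seed.
#' @return A list with `spectra` (named list of [ir_spectrum()]) and
#'   `factors` (tibble with `sample` and `factor`).
#' @export
simulate_spectra <- function(template, n, effect_map = NULL, seed = 1) {
  stopifnot(inherits(template, "spectrum_template"), n >= 1)
  wn <- template_grid(template)
  set.seed(seed)
  factors <- rnorm(n)
  slopes <- numeric(nrow(template$peaks))
  if (!is.null(effect_map)) {
    effect_map <- as_tibble(effect_map)
    pos <- match(effect_map$center, template$peaks$center)
    if (anyNA(pos)) {
      abort("`effect_map$center` must match template peak centres.")
    }
    slopes[pos] <- effect_map$slope
  }
  drift <- template$baseline_slope * (wn - min(wn))
  spectra <- lapply(seq_len(n), function(i) {
    h <- template$peaks$height + slopes * factors[i]
    ab <- gaussian_sum(wn, template$peaks$center, h, template$peaks$fwhm) + drift
    if (template$noise_sd > 0) {
      ab <- ab + rnorm(length(wn), sd = template$noise_sd)
    }
    ir_spectrum(wn, ab, steps = "synthetic")
  })
  names(spectra) <- paste0("sample_", seq_len(n))
  list(spectra = spectra,
       factors = tibble(sample = names(spectra), factor = factors))
}

#' Ground truth for a synthetic mediation design
#'
#' Defines the data-generating model
#' `m = intercept_m + (a + a3*w) x + e_m`,
#' `y = intercept_y + c_prime*x + (b + b2*w) m + e_y`,
#' with Gaussian residuals and the culture-time moderator `w` drawn from
#' `time_levels`. The default path coefficients and residual scales mirror
#' the fitted values on the bundled barley dataset (a = -15.57, b = -8.24,
#' c' = 51.35, residual standard deviations 0.3 and 1.3, unmoderated), with
#' intercepts placed so the emitted percentages stay positive in the bulk
#' of the distribution.
#'
#' @param a,b,c_prime Path coefficients.
#' @param a3,b2 Moderation slopes on the a and b paths (0 for unmoderated).
#' @param intercept_m,intercept_y Model intercepts.
#' @param sd_m,sd_y Residual standard deviations (>= 0).
#' @param time_levels Multiset of moderator levels; sampled with
#'   replacement unless its length equals `n`, in which case it is used
#'   as given.
#' @param n Sample size (>= 4).
#' @param seed RNG seed.
#' @param x_range Range of the uniform predictor, default the observed
#'   integrated-absorbance range 0.02--0.06.
#' @return A list of class `"mediation_truth"`.
#' @export
mediation_truth <- function(a = -15.57, b = -8.24, c_prime = 51.35,
                            a3 = 0, b2 = 0,
                            intercept_m = 1.5, intercept_y = 14,
                            sd_m = 0.3, sd_y = 1.3,
                            time_levels = c(21, 28, 35),
                            n = 35, seed = 1, x_range = c(0.02, 0.06)) {
  if (sd_m < 0 || sd_y < 0) abort("Residual standard deviations must be >= 0.")
  if (n < 4) abort("`n` must be >= 4.")
  structure(list(a = a, b = b, c_prime = c_prime, a3 = a3, b2 = b2,
                 intercept_m = intercept_m, intercept_y = intercept_y,
                 sd_m = sd_m, sd_y = sd_y, time_levels = time_levels,
                 n = as.integer(n), seed = as.integer(seed),
                 x_range = x_range),
            class = "mediation_truth")
}

#' Simulate a mediation dataset in the regenerant-table schema
#'
#' Draws a dataset from a [mediation_truth()] and emits it in the schema of
#' [regenerant_data()]: the predictor becomes the combined integrated
#' absorbance (split 3:97 between the 710--690 and 1010--940 windows, the
#' proportion observed in the real data), the mediator becomes `chg_dmv`
#' (with a constant CG-context component so `dmv = cg_dmv + chg_dmv`
#' exactly), the outcome becomes `sv`, and the moderator `time_days`.
#' Synthetic trial labels `S1, S2, ...` index the time level. Fully
#' deterministic under a fixed seed.
#'
#' @param truth A [mediation_truth()].
#' @param x_source `"uniform"` (default) draws the predictor uniformly over
#'   `truth$x_range`; `"resample_fixture"` resamples the bundled dataset's
#'   observed combined absorbances, for power studies on realistic
#'   predictor spacing.
#' @return A tibble in the [regenerant_data()] schema with `n` rows.
#' @examples
#' d <- simulate_mediation(mediation_truth(n = 50, seed = 7))
#' glance(mediate_simple(d, f_combined, chg_dmv, sv,
#'                       boot = boot_config(n_boot = 500, seed = 7)))
#' @export
simulate_mediation <- function(truth, x_source = c("uniform", "resample_fixture")) {
  stopifnot(inherits(truth, "mediation_truth"))
  x_source <- match.arg(x_source)
  n <- truth$n
  set.seed(truth$seed)
  x <- if (x_source == "uniform") {
    runif(n, truth$x_range[1], truth$x_range[2])
  } else {
    sample(regenerant_data()$f_combined, n, replace = TRUE)
  }
  w <- if (length(truth$time_levels) == n) {
    as.numeric(truth$time_levels)
  } else {
    as.numeric(sample(truth$time_levels, n, replace = TRUE))
  }
  m <- truth$intercept_m + (truth$a + truth$a3 * w) * x +
    rnorm(n, sd = truth$sd_m)
  y <- truth$intercept_y + truth$c_prime * x + (truth$b + truth$b2 * w) * m +
    rnorm(n, sd = truth$sd_y)
  f710 <- 0.03 * x
  cg <- rep(0.46, n)
  tibble(
    sample_no = seq_len(n),
    trial = paste0("S", match(w, sort(unique(w)))),
    f710_690 = f710,
    f1010_940 = x - f710,
    f_combined = x,
    dmv = cg + m,
    cg_dmv = cg,
    chg_dmv = m,
    sv = y,
    time_days = w
  )
}
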