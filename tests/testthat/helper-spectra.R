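# analytic single-Gaussian spectrum on a grid (high-to-low orientation)
gauss_spectrum <- function(center, height, fwhm, from = 2000, to = 400, by = 4,
                           extra = function(wn) 0) {
  wn <- seq(from, to, by = -by)
  ab <- height * exp(-4 * log(2) * (wn - center)^2 / fwhm^2) + extra(wn)
  ir_spectrum(wn, ab)
}

# closed-form area of a Gaussian band: h * fwhm * sqrt(pi / (4 log 2))
gauss_area <- function(height, fwhm) height * fwhm * sqrt(pi / (4 * log(2)))

# flat-spectrum cohort whose integral over [lo, hi] equals `values` per sample
constant_spectra <- function(values, lo, hi, by = 1) {
  lapply(values, function(v) {
    wn <- seq(hi, lo, by = -by)
    ir_spectrum(wn, rep(v / (hi - lo), length(wn)))
  })
}
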