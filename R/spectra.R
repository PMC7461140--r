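#' Construct an infrared spectrum
#'
#' A spectrum is a two-column tibble (`wavenumber` in cm-1, `absorbance` in
#' absorbance units) on a strictly monotonic, evenly spaced wavenumber grid
#' (4 cm-1 for the instrument settings emulated here; any constant step is
#' accepted). Mid-infrared spectra are conventionally stored from high to
#' low wavenumber; both orientations are accepted and preserved. Processing
#' steps applied by [baseline_correct()] and [normalize_area()] are recorded
#' in the `"steps"` attribute for provenance.
#'
#' @param wavenumber Numeric vector of wavenumbers (cm-1), length >= 2,
#'   strictly monotonic with constant spacing (relative tolerance 1e-6).
#' @param absorbance Numeric vector of finite absorbances, same length.
#' @param steps Character vector of processing-step tags already applied.
#' @return A tibble of class `"ir_spectrum"`.
#' @examples
#' s <- ir_spectrum(seq(4000, 400, by = -4), rexp(901))
#' spectrum_steps(s)
#' @export
ir_spectrum <- function(wavenumber, absorbance, steps = character()) {
  if (length(wavenumber) != length(absorbance) || length(wavenumber) < 2) {
    abort("`wavenumber` and `absorbance` must have equal length >= 2.")
  }
  if (!all(is.finite(wavenumber)) || !all(is.finite(absorbance))) {
    abort("Spectrum values must be finite.")
  }
  dw <- diff(wavenumber)
  if (any(dw == 0) || length(unique(sign(dw))) != 1) {
    abort("`wavenumber` must be strictly monotonic.")
  }
  if (max(abs(dw - dw[1])) > 1e-6 * abs(dw[1])) {
    abort("`wavenumber` spacing must be constant (relative tolerance 1e-6).")
  }
  out <- tibble(wavenumber = as.numeric(wavenumber),
                absorbance = as.numeric(absorbance))
  attr(out, "steps") <- as.character(steps)
  class(out) <- c("ir_spectrum", class(out))
  out
}

#' @rdname ir_spectrum
#' @param x An `ir_spectrum`.
#' @export
spectrum_steps <- function(x) {
  stopifnot(inherits(x, "ir_spectrum"))
  attr(x, "steps") %||% character()
}

add_step <- function(x, tag) {
  attr(x, "steps") <- c(spectrum_steps(x), tag)
  x
}

replace_absorbance <- function(x, absorbance) {
  steps <- spectrum_steps(x)
  ir_spectrum(x$wavenumber, absorbance, steps = steps)
}

#' Define a wavenumber band window
#'
#' @param lo,hi Window bounds in cm-1, `lo < hi`. Windows are closed
#'   intervals; integration includes both endpoints by linear interpolation
#'   when they fall between grid points.
#' @return A one-row tibble with columns `lo` and `hi`.
#' @export
band_window <- function(lo, hi) {
  if (any(lo >= hi)) abort("Band window requires lo < hi.")
  tibble(lo = as.numeric(lo), hi = as.numeric(hi))
}

check_window_in_range <- function(spectrum, lo, hi) {
  rng <- range(spectrum$wavenumber)
  if (lo < rng[1] - 1e-9 || hi > rng[2] + 1e-9) {
    abort(sprintf("Window [%g, %g] cm-1 outside spectrum range [%g, %g].",
                  lo, hi, rng[1], rng[2]),
          class = "spectromed_range_error")
  }
}

#' Baseline-correct a spectrum through anchor windows
#'
#' Subtracts a baseline interpolated through the mean absorbance of each
#' anchor window, evaluated at the window centre: a constant offset for one
#' anchor, a straight line for two, piecewise linear (with constant
#' extrapolation beyond the outermost anchors) for more. This documented
#' procedure replaces instrument-vendor baseline correction; after it, the
#' mean absorbance within each anchor window is approximately zero.
#'
#' @param spectrum An [ir_spectrum()].
#' @param anchors A data frame of anchor windows ([band_window()] rows),
#'   all inside the spectrum range.
#' @return The corrected spectrum, with a `"baseline"` step tag appended.
#' @export
baseline_correct <- function(spectrum, anchors) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  anchors <- as_tibble(anchors)
  if (nrow(anchors) < 1) abort("At least one anchor window is required.")
  for (i in seq_len(nrow(anchors))) {
    check_window_in_range(spectrum, anchors$lo[i], anchors$hi[i])
  }
  centers <- (anchors$lo + anchors$hi) / 2
  means <- vapply(seq_len(nrow(anchors)), function(i) {
    sel <- spectrum$wavenumber >= anchors$lo[i] - 1e-9 &
      spectrum$wavenumber <= anchors$hi[i] + 1e-9
    mean(spectrum$absorbance[sel])
  }, numeric(1))
  if (nrow(anchors) == 1) {
    base <- rep(means, nrow(spectrum))
  } else {
    ord <- order(centers)
    base <- approx(centers[ord], means[ord], xout = spectrum$wavenumber,
                   rule = 2)$y
  }
  add_step(replace_absorbance(spectrum, spectrum$absorbance - base), "baseline")
}

#' Area-normalize a spectrum over a reference window
#'
#' Rescales the whole spectrum by a single factor so that its trapezoidal
#' integral over the reference window equals 1. The default window,
#' 1800--900 cm-1, is the fingerprint region conventionally used for plant
#' tissue spectra. Normalization is idempotent and removes any global
#' multiplicative difference between spectra (e.g. contact pressure or
#' sample amount in ATR measurements).
#'
#' @param spectrum An [ir_spectrum()].
#' @param window Reference window, default `band_window(900, 1800)`.
#' @return The scaled spectrum with a `"normalize_area"` step tag.
#' @export
normalize_area <- function(spectrum, window = band_window(900, 1800)) {
  area <- integrate_band(spectrum, window)
  if (!is.finite(area) || area <= 0) {
    abort("Window integral must be positive for area normalization.",
          class = "spectromed_normalization_error")
  }
  add_step(replace_absorbance(spectrum, spectrum$absorbance / area),
           "normalize_area")
}

#' Integrate absorbance over a band window
#'
#' Trapezoidal integral of absorbance over `[lo, hi]` on the native grid,
#' with the window endpoints included by linear interpolation when they fall
#' between grid points. Orientation-agnostic: spectra stored high-to-low
#' give the same (non-negative for non-negative spectra) area as low-to-high.
#' The integral is additive over adjacent windows.
#'
#' @param spectrum An [ir_spectrum()].
#' @param window A [band_window()] (or data frame with `lo`, `hi`); must lie
#'   within the spectrum range.
#' @return The integrated area (absorbance units times cm-1).
#' @export
integrate_band <- function(spectrum, window) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  window <- as_tibble(window)
  stopifnot(nrow(window) == 1)
  lo <- window$lo
  hi <- window$hi
  if (lo >= hi) abort("Band window requires lo < hi.")
  check_window_in_range(spectrum, lo, hi)
  wn <- spectrum$wavenumber
  ab <- spectrum$absorbance
  if (wn[1] > wn[length(wn)]) {
    wn <- rev(wn)
    ab <- rev(ab)
  }
  inside <- wn > lo & wn < hi
  xs <- c(lo, wn[inside], hi)
  ys <- c(approx(wn, ab, xout = lo)$y, ab[inside], approx(wn, ab, xout = hi)$y)
  sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
}

#' Integrate one or more windows across a collection of spectra
#'
#' @param spectra A list of [ir_spectrum()] objects, optionally named; all
#'   must share one wavenumber grid.
#' @param windows A data frame of windows (`lo`, `hi`), e.g. several
#'   [band_window()] rows bound together or the output of
#'   [fragment_spectrum()].
#' @return A long tibble with columns `sample`, `lo`, `hi`, `area`.
#' @export
integrate_bands <- function(spectra, windows) {
  check_common_grid(spectra)
  windows <- as_tibble(windows)
  ids <- names(spectra) %||% as.character(seq_along(spectra))
  if (is.null(names(spectra))) ids <- as.character(seq_along(spectra))
  purrr::map2_dfr(spectra, ids, function(sp, id) {
    tibble(sample = id, lo = windows$lo, hi = windows$hi,
           area = vapply(seq_len(nrow(windows)), function(i)
             integrate_band(sp, windows[i, ]), numeric(1)))
  })
}

check_common_grid <- function(spectra) {
  if (length(spectra) < 1) abort("Need at least one spectrum.")
  ref <- spectra[[1]]$wavenumber
  same <- vapply(spectra, function(s)
    length(s$wavenumber) == length(ref) && all(abs(s$wavenumber - ref) < 1e-9),
    logical(1))
  if (!all(same)) {
    abort("All spectra must share a common wavenumber grid.",
          class = "spectromed_alignment_error")
  }
  invisible(ref)
}

#' Fragment a spectrum range into fixed-width windows
#'
#' Tiles the spectrum range with contiguous, non-overlapping windows of the
#' given width, starting from the high-wavenumber end. A final narrower
#' window at the low end is retained and flagged `partial`. Together the
#' windows cover the range exactly once.
#'
#' @param spectrum An [ir_spectrum()], or a numeric length-2 range in cm-1.
#' @param width Window width in cm-1 (default 10).
#' @return A tibble with columns `window` (index from the high end), `lo`,
#'   `hi`, `partial`.
#' @export
fragment_spectrum <- function(spectrum, width = 10) {
  if (width <= 0) abort("`width` must be positive.")
  rng <- if (inherits(spectrum, "ir_spectrum")) {
    range(spectrum$wavenumber)
  } else {
    range(as.numeric(spectrum))
  }
  span <- diff(rng)
  if (width > span) {
    warn("`width` exceeds the spectrum span; returning a single window.")
    return(tibble(window = 1L, lo = rng[1], hi = rng[2], partial = TRUE))
  }
  n_full <- floor(span / width + 1e-9)
  hi <- rng[2] - (seq_len(n_full) - 1) * width
  lo <- hi - width
  partial <- rep(FALSE, n_full)
  if (lo[n_full] > rng[1] + 1e-9) {
    hi <- c(hi, lo[n_full])
    lo <- c(lo, rng[1])
    partial <- c(partial, TRUE)
  }
  tibble(window = seq_along(hi), lo = lo, hi = hi, partial = partial)
}

#' Read / write a spectrum as two-column CSV
#'
#' The on-disk format is a CSV with columns `wavenumber` and `absorbance`;
#' a header row is optional on input and always written on output.
#'
#' @param path File path.
#' @return `read_spectrum()` returns an [ir_spectrum()];
#'   `write_spectrum()` returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  d <- utils::read.csv(path, header = has_header,
                       col.names = c("wavenumber", "absorbance"))
  ir_spectrum(d$wavenumber, d$absorbance)
}

#' @rdname read_spectrum
#' @param spectrum An [ir_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  readr::write_csv(tibble(wavenumber = spectrum$wavenumber,
                          absorbance = spectrum$absorbance),
                   path, progress = FALSE)
  invisible(path)
}
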