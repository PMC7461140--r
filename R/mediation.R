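#' Bootstrap configuration
#'
#' @param n_boot Number of case resamples (default 5000, the conventional
#'   default for indirect-effect confidence intervals).
#' @param seed RNG seed; mandatory so every bootstrap is reproducible.
#' @param level Confidence level in (0, 1), default 0.95.
#' @param type `"percentile"` (default) or `"bc"` (bias-corrected).
#' @return A list of class `"boot_config"`.
#' @export
boot_config <- function(n_boot = 5000, seed = 1, level = 0.95,
                        type = c("percentile", "bc")) {
  type <- match.arg(type)
  if (n_boot < 1) abort("`n_boot` must be >= 1.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  structure(list(n_boot = as.integer(n_boot), seed = as.integer(seed),
                 level = level, type = type),
            class = "boot_config")
}

# n_boot x n matrix of multinomial resampling counts (each row sums to n);
# algebraically identical to case resampling, but lets every bootstrap path
# estimate come from one matrix product over weighted moments.
boot_weights <- function(n, n_boot, seed) {
  set.seed(seed)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  id <- rep(seq_len(n_boot), each = n)
  cnt <- tabulate((id - 1L) * as.integer(n) + idx, nbins = n * n_boot)
  matrix(cnt, nrow = n_boot, ncol = n, byrow = TRUE)
}

# bootstrap draws of the mediation paths from weighted first/second moments
boot_mediation_draws <- function(x, m, y, n_boot, seed) {
  n <- length(x)
  W <- boot_weights(n, n_boot, seed)
  Mom <- (W %*% cbind(x, m, y, x * x, x * m, m * m, x * y, m * y)) / n
  mx <- Mom[, 1]; mm <- Mom[, 2]; my <- Mom[, 3]
  vx <- Mom[, 4] - mx^2
  cxm <- Mom[, 5] - mx * mm
  vm <- Mom[, 6] - mm^2
  cxy <- Mom[, 7] - mx * my
  cmy <- Mom[, 8] - mm * my
  det <- vm * vx - cxm^2
  ok <- vx > 1e-300 & det > 1e-300
  a <- ifelse(ok, cxm / vx, NA_real_)
  b <- ifelse(ok, (cmy * vx - cxy * cxm) / det, NA_real_)
  c_tot <- ifelse(ok, cxy / vx, NA_real_)
  tibble(a = a, b = b, c = c_tot, ie = a * b, c_prime = c_tot - a * b)
}

boot_ci <- function(draws, estimate, level, type) {
  draws <- draws[is.finite(draws)]
  alpha <- 1 - level
  if (type == "percentile") {
    ci <- unname(quantile(draws, c(alpha / 2, 1 - alpha / 2)))
  } else {
    z0 <- qnorm(mean(draws < estimate))
    probs <- pnorm(2 * z0 + qnorm(c(alpha / 2, 1 - alpha / 2)))
    ci <- unname(quantile(draws, probs))
  }
  ci
}

#' Sobel and Goodman tests of an indirect effect
#'
#' Normal-theory tests of the product-of-coefficients indirect effect
#' `a * b`. The Goodman variant subtracts the product of squared standard
#' errors inside the square root,
#' `z = a*b / sqrt(b^2 se_a^2 + a^2 se_b^2 - se_a^2 se_b^2)`,
#' which makes it (weakly) more liberal than Sobel's
#' `sqrt(b^2 se_a^2 + a^2 se_b^2)`. When the Goodman denominator is not
#' positive the Sobel denominator is used instead and the result is flagged
#' via `method = "sobel_fallback"`.
#'
#' @param a,b Path estimates (predictor-to-mediator, mediator-to-outcome).
#' @param se_a,se_b Their standard errors (> 0).
#' @return A one-row tibble: `z`, `p.value` (two-sided normal), `method`.
#' @export
goodman_test <- function(a, b, se_a, se_b) {
  if (se_a <= 0 || se_b <= 0) abort("Standard errors must be positive.")
  denom2 <- b^2 * se_a^2 + a^2 * se_b^2 - se_a^2 * se_b^2
  if (denom2 > 0) {
    z <- a * b / sqrt(denom2)
    method <- "goodman"
  } else {
    z <- a * b / sqrt(b^2 * se_a^2 + a^2 * se_b^2)
    method <- "sobel_fallback"
  }
  tibble(z = z, p.value = 2 * pnorm(-abs(z)), method = method)
}

#' @rdname goodman_test
#' @export
sobel_test <- function(a, b, se_a, se_b) {
  if (se_a <= 0 || se_b <= 0) abort("Standard errors must be positive.")
  z <- a * b / sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  tibble(z = z, p.value = 2 * pnorm(-abs(z)), method = "sobel")
}

#' Variance accounted for by mediation
#'
#' `100 * ie / total`: the indirect effect as a percentage of the total
#' effect. Values above 80 percent are conventionally read as full
#' mediation.
#'
#' @param ie Indirect effect.
#' @param total Total effect (non-zero).
#' @return Percentage.
#' @export
vaf <- function(ie, total) {
  if (any(total == 0)) {
    abort("VAF is undefined for a zero total effect.",
          class = "spectromed_domain_error")
  }
  100 * ie / total
}

#' Cohen's f-squared effect size from a squared multiple correlation
#'
#' @param r2 Squared multiple correlation in `[0, 1)`.
#' @return `r2 / (1 - r2)`.
#' @export
cohen_f2 <- function(r2) {
  if (any(r2 < 0) || any(r2 >= 1)) {
    abort("`r2` must lie in [0, 1).", class = "spectromed_domain_error")
  }
  r2 / (1 - r2)
}

resolve_column <- function(data, quo, arg) {
  idx <- tidyselect::eval_select(quo, data)
  if (length(idx) != 1) {
    abort(sprintf("`%s` must select exactly one column.", arg))
  }
  names(idx)
}

#' Simple mediation with bootstrap indirect-effect confidence interval
#'
#' Fits the three ordinary least-squares regressions of a single-mediator
#' model -- `m ~ x` (path `a`), `y ~ x + m` (paths `c'` and `b`) and
#' `y ~ x` (total effect `c`) -- and reports the product-of-coefficients
#' indirect effect `ie = a * b` with a seeded case-resampling bootstrap
#' confidence interval, partially and completely standardized indirect
#' effects, the variance accounted for (VAF), and Sobel/Goodman tests.
#' For OLS the effect decomposition `c = c' + a*b` holds exactly.
#'
#' @param data A data frame with one row per sample.
#' @param predictor,mediator,outcome Columns (bare names or strings) holding
#'   x, m and y.
#' @param boot A [boot_config()].
#' @return An object of class `"simple_mediation"`. [tidy()] gives the path
#'   table, [glance()] a one-row summary mirroring the conventional report
#'   layout (R-squared, c', a, b, c, IE, CI bounds, VAF, Goodman test),
#'   [autoplot()] the bootstrap distribution of the indirect effect.
#' @examples
#' fit <- mediate_simple(regenerant_data(), f1010_940, chg_dmv, sv,
#'                       boot = boot_config(n_boot = 1000, seed = 42))
#' glance(fit)
#' @export
mediate_simple <- function(data, predictor, mediator, outcome,
                           boot = boot_config()) {
  xn <- resolve_column(data, rlang::enquo(predictor), "predictor")
  mn <- resolve_column(data, rlang::enquo(mediator), "mediator")
  yn <- resolve_column(data, rlang::enquo(outcome), "outcome")
  mediate_vectors(data[[xn]], data[[mn]], data[[yn]], boot,
                  vars = c(x = xn, m = mn, y = yn))
}

# core implementation shared verbatim by mediate_simple() and the windowed
# scan, so a single-window scan is bitwise identical to a direct call
mediate_vectors <- function(x, m, y, boot, vars = c(x = "x", m = "m", y = "y")) {
  stopifnot(inherits(boot, "boot_config"))
  n <- length(x)
  if (n < 10) abort("Mediation requires at least 10 complete cases.")
  if (length(m) != n || length(y) != n) abort("x, m, y must have equal length.")
  if (!all(is.finite(x)) || !all(is.finite(m)) || !all(is.finite(y))) {
    abort("x, m, y must be finite.")
  }
  if (sd(x) == 0 || sd(m) == 0 || sd(y) == 0) {
    abort("Degenerate (zero-variance) variable in mediation model.",
          class = "spectromed_variance_error")
  }
  d <- tibble(x = x, m = m, y = y)
  fit_a <- fit_ols(d, m ~ x)
  fit_y <- fit_ols(d, y ~ x + m)
  fit_c <- fit_ols(d, y ~ x)
  a <- unname(fit_a$coefficients["x"]); se_a <- unname(fit_a$se["x"])
  b <- unname(fit_y$coefficients["m"]); se_b <- unname(fit_y$se["m"])
  c_prime <- unname(fit_y$coefficients["x"])
  c_tot <- unname(fit_c$coefficients["x"])
  ie <- a * b
  draws <- boot_mediation_draws(x, m, y, boot$n_boot, boot$seed)
  ci <- boot_ci(draws$ie, ie, boot$level, boot$type)
  gd <- goodman_test(a, b, se_a, se_b)
  sb <- sobel_test(a, b, se_a, se_b)
  out <- list(
    paths = tibble(
      term = c("a", "b", "c_prime", "c"),
      estimate = c(a, b, c_prime, c_tot),
      std.error = c(se_a, se_b, unname(fit_y$se["x"]), unname(fit_c$se["x"]))),
    ie = ie,
    ie_ci = ci,
    ie_partially_std = ie / sd(y),
    ie_completely_std = ie * sd(x) / sd(y),
    vaf = vaf(ie, c_tot),
    goodman = gd,
    sobel = sb,
    fits = list(mediator = fit_a, outcome = fit_y, total = fit_c),
    boot = boot,
    boot_draws = draws$ie,
    vars = vars,
    n = n
  )
  class(out) <- "simple_mediation"
  out
}

#' @export
print.simple_mediation <- function(x, ...) {
  v <- x$vars
  cat(sprintf("Simple mediation: %s -> %s -> %s  (n = %d)\n",
              v[["x"]], v[["m"]], v[["y"]], x$n))
  print(tidy(x))
  cat(sprintf("Indirect effect a*b = %.4f, %d%% %s bootstrap CI [%.4f, %.4f]\n",
              x$ie, round(100 * x$boot$level), x$boot$type,
              x$ie_ci[1], x$ie_ci[2]))
  cat(sprintf("VAF = %.1f%%; Goodman z = %.3f (p = %.4f)\n",
              x$vaf, x$goodman$z, x$goodman$p.value))
  invisible(x)
}

#' @export
tidy.simple_mediation <- function(x, ...) {
  paths <- dplyr::mutate(x$paths,
                         statistic = .data$estimate / .data$std.error)
  dfs <- c(x$fits$mediator$df_resid, x$fits$outcome$df_resid,
           x$fits$outcome$df_resid, x$fits$total$df_resid)
  paths$p.value <- 2 * pt(-abs(paths$statistic), df = dfs)
  ie_row <- tibble(term = "ie", estimate = x$ie, std.error = NA_real_,
                   statistic = x$goodman$z, p.value = x$goodman$p.value,
                   conf.low = x$ie_ci[1], conf.high = x$ie_ci[2])
  dplyr::bind_rows(
    dplyr::mutate(paths, conf.low = NA_real_, conf.high = NA_real_),
    ie_row)
}

#' @export
glance.simple_mediation <- function(x, ...) {
  p <- setNames(x$paths$estimate, x$paths$term)
  tibble(
    r.squared = x$fits$outcome$r2,
    c_prime = unname(p["c_prime"]), a = unname(p["a"]), b = unname(p["b"]),
    c = unname(p["c"]), ie = x$ie,
    ci_lower = x$ie_ci[1], ci_upper = x$ie_ci[2],
    ie_partially_std = x$ie_partially_std,
    ie_completely_std = x$ie_completely_std,
    vaf = x$vaf,
    goodman_z = x$goodman$z, goodman_p = x$goodman$p.value,
    r.squared_mediator = x$fits$mediator$r2,
    r.squared_total = x$fits$total$r2,
    nobs = x$n, n_boot = x$boot$n_boot
  )
}

#' @export
autoplot.simple_mediation <- function(object, bins = 60, ...) {
  d <- tibble(ie = object$boot_draws[is.finite(object$boot_draws)])
  ggplot2::ggplot(d, ggplot2::aes(.data$ie)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$ie, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$ie_ci, linetype = 2) +
    ggplot2::labs(x = "Bootstrap indirect effect (a*b)", y = "Count",
                  title = sprintf("Indirect effect %.3f, %d%% CI [%.3f, %.3f]",
                                  object$ie, round(100 * object$boot$level),
                                  object$ie_ci[1], object$ie_ci[2]))
}
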