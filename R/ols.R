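#' Fit an ordinary least-squares regression
#'
#' Thin, validated wrapper around [stats::lm()] that exposes everything the
#' mediation machinery needs in one object: coefficients with classical
#' standard errors, the full coefficient covariance, R-squared, the overall
#' F statistic and degrees of freedom. Rank deficiency is an error (naming
#' the aliased columns) rather than silent coefficient dropping.
#'
#' @param data A data frame.
#' @param formula A model formula; an intercept is included unless removed
#'   explicitly.
#' @return An object of class `"ols_fit"` with elements `coefficients`
#'   (named vector), `se`, `vcov`, `r2`, `f_stat`, `df_model`, `df_resid`,
#'   `n`, `sigma`, `terms` and the underlying `lm` fit.
#' @examples
#' fit_ols(regenerant_data(), sv ~ f1010_940)
#' @export
fit_ols <- function(data, formula) {
  mm <- model.matrix(formula, data = data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    abort(paste0("Design matrix is rank deficient; aliased column(s): ",
                 paste(bad, collapse = ", ")),
          class = "spectromed_singular_error")
  }
  n <- nrow(mm)
  if (n <= ncol(mm)) {
    abort("More coefficients than observations.",
          class = "spectromed_singular_error")
  }
  fit <- lm(formula, data = data)
  s <- summary(fit)
  fstat <- if (is.null(s$fstatistic)) c(NA_real_, 0, fit$df.residual) else s$fstatistic
  out <- list(
    coefficients = coef(fit),
    se = s$coefficients[, "Std. Error"],
    vcov = vcov(fit),
    r2 = s$r.squared,
    f_stat = unname(fstat[1]),
    df_model = unname(fstat[2]),
    df_resid = df.residual(fit),
    n = n,
    sigma = s$sigma,
    terms = colnames(mm),
    fit = fit
  )
  class(out) <- "ols_fit"
  out
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, R^2 = %.4f, F(%g, %g) = %.4g\n",
              x$n, x$r2, x$df_model, x$df_resid, x$f_stat))
  print(tidy(x), ...)
  invisible(x)
}

#' @export
tidy.ols_fit <- function(x, ...) {
  est <- x$coefficients
  se <- x$se
  stat <- est / se
  tibble(term = names(est), estimate = unname(est), std.error = unname(se),
         statistic = unname(stat),
         p.value = 2 * pt(-abs(unname(stat)), df = x$df_resid))
}

#' @export
glance.ols_fit <- function(x, ...) {
  tibble(r.squared = x$r2, statistic = x$f_stat, df = x$df_model,
         df.residual = x$df_resid, nobs = x$n, sigma = x$sigma,
         p.value = if (x$df_model > 0)
           pf_upper(x$f_stat, x$df_model, x$df_resid) else NA_real_)
}

pf_upper <- function(f, df1, df2) stats::pf(f, df1, df2, lower.tail = FALSE)

#' F test for the highest-order term between nested OLS fits
#'
#' Compares a reduced and a full model fitted to the same response by the
#' R-squared-change F test:
#' `F = ((R2_full - R2_reduced)/df1) / ((1 - R2_full)/df2)`.
#' Used to test the highest-order (interaction) term of a moderated model.
#'
#' @param fit_reduced,fit_full [fit_ols()] objects; the reduced model's
#'   terms must be a subset of the full model's.
#' @return A one-row tibble with `f_stat`, `df1`, `df2`, `delta_r2`, `p.value`.
#' @export
interaction_f_test <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "ols_fit"), inherits(fit_full, "ols_fit"))
  if (!all(fit_reduced$terms %in% fit_full$terms)) {
    abort("Models are not nested: reduced terms are not a subset of full terms.",
          class = "spectromed_nesting_error")
  }
  if (fit_reduced$n != fit_full$n) {
    abort("Models were fitted to different numbers of observations.",
          class = "spectromed_nesting_error")
  }
  df1 <- length(fit_full$terms) - length(fit_reduced$terms)
  df2 <- fit_full$df_resid
  delta_r2 <- fit_full$r2 - fit_reduced$r2
  f_stat <- if (df1 == 0) 0 else (delta_r2 / df1) / ((1 - fit_full$r2) / df2)
  tibble(f_stat = f_stat, df1 = df1, df2 = df2, delta_r2 = delta_r2,
         p.value = if (df1 == 0) 1 else pf_upper(f_stat, df1, df2))
}
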