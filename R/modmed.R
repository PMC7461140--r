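#' Moderated mediation with a continuous moderator
#'
#' Fits the two regressions of a first-stage-and-second-stage moderated
#' mediation model with raw (uncentred) product terms:
#' the mediator model `m ~ x + w + x:w` (coefficients `a1`, `a2_w`, `a3_xw`)
#' and the outcome model `y ~ x + w + m + m:w` (`c1_prime`, `c2_w`, `b1`,
#' `b2_mw`). Which paths carry an interaction is controlled by `moderate`;
#' the default moderates the predictor-to-mediator (`"a"`) and
#' mediator-to-outcome (`"b"`) paths but not the direct path, which for
#' n = 35 yields the characteristic residual degrees of freedom 31
#' (mediator model) and 30 (outcome model). The conditional indirect effect
#' at moderator value w is `(a1 + a3*w) * (b1 + b2*w)`.
#'
#' @param data A data frame with one row per sample.
#' @param predictor,mediator,outcome,moderator Columns (bare names or
#'   strings) holding x, m, y and w.
#' @param moderate Character subset of `c("a", "b", "cprime")`; at least one.
#' @param boot Default [boot_config()] used by downstream summaries.
#' @return An object of class `"moderated_mediation"` with elements
#'   `mediator_model` and `outcome_model` ([fit_ols()] objects), the
#'   reduced (interaction-free) fits, the model frame, and metadata.
#' @examples
#' fit <- mediate_moderated(regenerant_data(), f_combined, chg_dmv, sv, time_days)
#' tidy(fit)
#' conditional_indirect(fit, c(21, 28, 35))
#' @export
mediate_moderated <- function(data, predictor, mediator, outcome, moderator,
                              moderate = c("a", "b"),
                              boot = boot_config()) {
  if (length(moderate) < 1 || !all(moderate %in% c("a", "b", "cprime"))) {
    abort('`moderate` must be a non-empty subset of c("a", "b", "cprime").')
  }
  xn <- resolve_column(data, rlang::enquo(predictor), "predictor")
  mn <- resolve_column(data, rlang::enquo(mediator), "mediator")
  yn <- resolve_column(data, rlang::enquo(outcome), "outcome")
  wn <- resolve_column(data, rlang::enquo(moderator), "moderator")
  d <- tibble(x = data[[xn]], m = data[[mn]], y = data[[yn]], w = data[[wn]])
  if (nrow(d) < 15) abort("Moderated mediation requires at least 15 cases.")
  if (!all(vapply(d, function(v) all(is.finite(v)), logical(1)))) {
    abort("All model variables must be finite.")
  }
  if (length(unique(d$w)) < 2) {
    abort("Moderator must take at least 2 distinct values.",
          class = "spectromed_singular_error")
  }
  f_med <- if ("a" %in% moderate) m ~ x + w + x:w else m ~ x + w
  out_terms <- c("x", "w", "m",
                 if ("b" %in% moderate) "m:w",
                 if ("cprime" %in% moderate) "x:w")
  f_out <- stats::reformulate(out_terms, response = "y")
  fit <- list(
    mediator_model = fit_ols(d, f_med),
    outcome_model = fit_ols(d, f_out),
    mediator_reduced = fit_ols(d, m ~ x + w),
    outcome_reduced = fit_ols(d, y ~ x + w + m),
    moderate = moderate,
    model_frame = d,
    vars = c(x = xn, m = mn, y = yn, w = wn),
    w_range = range(d$w),
    n = nrow(d),
    boot = boot
  )
  class(fit) <- "moderated_mediation"
  fit
}

# interaction terms may be labelled either v1:v2 or v2:v1 by terms()
interaction_term <- function(nms, v1, v2) {
  hit <- nms %in% c(paste0(v1, ":", v2), paste0(v2, ":", v1))
  if (any(hit)) nms[which(hit)[1]] else NA_character_
}

# first- and second-stage slope/interaction coefficients (0 when unmoderated)
modmed_paths <- function(fit) {
  cm <- fit$mediator_model$coefficients
  co <- fit$outcome_model$coefficients
  xw_m <- interaction_term(names(cm), "x", "w")
  mw_o <- interaction_term(names(co), "m", "w")
  list(a1 = unname(cm["x"]),
       a3 = if (is.na(xw_m)) 0 else unname(cm[xw_m]),
       b1 = unname(co["m"]),
       b2 = if (is.na(mw_o)) 0 else unname(co[mw_o]),
       c_prime = unname(co["x"]))
}

#' @export
print.moderated_mediation <- function(x, ...) {
  v <- x$vars
  cat(sprintf("Moderated mediation: %s -> %s -> %s, moderated by %s on path(s) %s\n",
              v[["x"]], v[["m"]], v[["y"]], v[["w"]],
              paste(x$moderate, collapse = ", ")))
  cat(sprintf("n = %d; outcome R^2 = %.4f, F(%g, %g) = %.2f\n",
              x$n, x$outcome_model$r2, x$outcome_model$df_model,
              x$outcome_model$df_resid, x$outcome_model$f_stat))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.moderated_mediation <- function(x, conf.level = 0.95, ...) {
  one <- function(fit, model) {
    tt <- tidy(fit)
    tcrit <- qt(1 - (1 - conf.level) / 2, df = fit$df_resid)
    dplyr::mutate(tt, model = model,
                  conf.low = .data$estimate - tcrit * .data$std.error,
                  conf.high = .data$estimate + tcrit * .data$std.error,
                  .before = 1)
  }
  dplyr::bind_rows(one(x$mediator_model, "mediator"),
                   one(x$outcome_model, "outcome"))[
    , c("model", "term", "estimate", "std.error", "statistic", "p.value",
        "conf.low", "conf.high")]
}

#' @export
glance.moderated_mediation <- function(x, ...) {
  o <- x$outcome_model
  m <- x$mediator_model
  tibble(r.squared = o$r2, statistic = o$f_stat, df = o$df_model,
         df.residual = o$df_resid,
         p.value = pf_upper(o$f_stat, o$df_model, o$df_resid),
         r.squared_mediator = m$r2, nobs = x$n)
}

#' Conditional indirect effect at given moderator values
#'
#' Evaluates `theta(w) = (a1 + a3*w) * (b1 + b2*w)` on the fitted
#' coefficients (deterministic), with a seeded case-resampling bootstrap for
#' the standard error and percentile confidence interval of the product.
#'
#' @param fit A [mediate_moderated()] object.
#' @param w Moderator values at which to evaluate the effect.
#' @param boot A [boot_config()]; defaults to the one stored in `fit`.
#'   `NULL` skips the bootstrap (point estimates only).
#' @return A tibble with one row per `w`: `w`, `estimate`, `se`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high` (the last five `NA`
#'   when `boot` is `NULL`).
#' @export
conditional_indirect <- function(fit, w, boot = fit$boot) {
  stopifnot(inherits(fit, "moderated_mediation"))
  p <- modmed_paths(fit)
  theta <- (p$a1 + p$a3 * w) * (p$b1 + p$b2 * w)
  if (is.null(boot)) {
    return(tibble(w = w, estimate = theta, se = NA_real_,
                  statistic = NA_real_, p.value = NA_real_,
                  conf.low = NA_real_, conf.high = NA_real_))
  }
  draws <- boot_conditional_draws(fit, w, boot)
  se <- apply(draws, 2, stats::sd, na.rm = TRUE)
  alpha <- 1 - boot$level
  ci <- t(vapply(seq_along(w), function(j)
    boot_ci(draws[, j], theta[j], boot$level, boot$type), numeric(2)))
  z <- theta / se
  tibble(w = w, estimate = theta, se = se, statistic = z,
         p.value = 2 * pnorm(-abs(z)),
         conf.low = ci[, 1], conf.high = ci[, 2])
}

# n_boot x length(w) draws of theta(w) by refitting both models per resample
boot_conditional_draws <- function(fit, w, boot) {
  d <- fit$model_frame
  n <- nrow(d)
  Xm <- model.matrix(fit$mediator_model$fit)
  Xo <- model.matrix(fit$outcome_model$fit)
  im <- match("x", colnames(Xm))
  im3 <- match(interaction_term(colnames(Xm), "x", "w"), colnames(Xm))
  io <- match("m", colnames(Xo))
  io2 <- match(interaction_term(colnames(Xo), "m", "w"), colnames(Xo))
  set.seed(boot$seed)
  draws <- matrix(NA_real_, boot$n_boot, length(w))
  for (r in seq_len(boot$n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    cm <- tryCatch(stats::.lm.fit(Xm[idx, , drop = FALSE], d$m[idx])$coefficients,
                   error = function(e) NULL)
    co <- tryCatch(stats::.lm.fit(Xo[idx, , drop = FALSE], d$y[idx])$coefficients,
                   error = function(e) NULL)
    if (is.null(cm) || is.null(co) || anyNA(cm) || anyNA(co)) next
    a1 <- cm[im]; a3 <- if (is.na(im3)) 0 else cm[im3]
    b1 <- co[io]; b2 <- if (is.na(io2)) 0 else co[io2]
    draws[r, ] <- (a1 + a3 * w) * (b1 + b2 * w)
  }
  draws
}

#' Johnson-Neyman regions of significance for a moderated path
#'
#' Finds the moderator values at which the conditional path
#' `theta(w) = beta_main + beta_int * w` stops being distinguishable from
#' zero: the boundaries solve `|theta(w)| / SE(theta(w)) = t_crit`, where
#' `Var(theta(w)) = Var(beta_main) + 2 w Cov + w^2 Var(beta_int)` and
#' `t_crit` is the two-sided critical t value at `alpha` on the model's
#' residual degrees of freedom. The condition is a quadratic in w and is
#' solved analytically; boundaries are reported relative to the observed
#' moderator range, with out-of-range boundaries flagged rather than
#' hidden.
#'
#' @param fit A [mediate_moderated()] object.
#' @param path `"a"` (predictor-to-mediator, from the mediator model) or
#'   `"b"` (mediator-to-outcome, from the outcome model); the path must be
#'   moderated in `fit`.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `"jn_region"`: boundaries, the observed
#'   moderator range, and a `regions` tibble giving significance over each
#'   sub-interval of the range. [autoplot()] draws the conditional effect
#'   with its confidence band and shades the significant region.
#' @export
johnson_neyman <- function(fit, path = c("a", "b"), alpha = 0.05) {
  stopifnot(inherits(fit, "moderated_mediation"))
  path <- match.arg(path)
  if (path == "a") {
    if (!"a" %in% fit$moderate) abort("The a path is not moderated in this fit.")
    model <- fit$mediator_model
    main <- "x"
    int <- interaction_term(names(model$coefficients), "x", "w")
  } else {
    if (!"b" %in% fit$moderate) abort("The b path is not moderated in this fit.")
    model <- fit$outcome_model
    main <- "m"
    int <- interaction_term(names(model$coefficients), "m", "w")
  }
  beta1 <- unname(model$coefficients[main])
  beta3 <- unname(model$coefficients[int])
  V <- model$vcov
  v11 <- V[main, main]; v13 <- V[main, int]; v33 <- V[int, int]
  tcrit <- qt(1 - alpha / 2, df = model$df_resid)
  # |theta(w)| = tcrit * SE(theta(w))  <=>  A w^2 + B w + C = 0
  A <- beta3^2 - tcrit^2 * v33
  B <- 2 * beta1 * beta3 - 2 * tcrit^2 * v13
  C <- beta1^2 - tcrit^2 * v11
  disc <- B^2 - 4 * A * C
  boundaries <- if (abs(A) < 1e-300) {
    if (abs(B) < 1e-300) numeric() else -C / B
  } else if (disc < 0) {
    numeric()
  } else {
    sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  }
  rng <- fit$w_range
  in_range <- boundaries >= rng[1] & boundaries <= rng[2]
  theta_t <- function(w) {
    (beta1 + beta3 * w) / sqrt(v11 + 2 * w * v13 + w^2 * v33)
  }
  cuts <- sort(unique(c(rng, boundaries[in_range])))
  mids <- (head(cuts, -1) + cuts[-1]) / 2
  regions <- tibble(lo = head(cuts, -1), hi = cuts[-1],
                    significant = abs(theta_t(mids)) > tcrit)
  out <- list(path = path, alpha = alpha, t_crit = tcrit,
              boundaries = boundaries, in_range = in_range,
              w_range = rng, regions = regions,
              beta_main = beta1, beta_int = beta3,
              vcov = c(v11 = v11, v13 = v13, v33 = v33),
              df = model$df_resid)
  class(out) <- "jn_region"
  out
}

#' @export
print.jn_region <- function(x, ...) {
  cat(sprintf("Johnson-Neyman region, %s path, alpha = %g\n", x$path, x$alpha))
  if (length(x$boundaries) == 0) {
    cat("No real boundary: the conditional effect is uniformly",
        if (x$regions$significant[1]) "significant" else "non-significant",
        "over the observed range.\n")
  } else {
    for (i in seq_along(x$boundaries)) {
      cat(sprintf("  boundary at w = %.4f%s\n", x$boundaries[i],
                  if (x$in_range[i]) "" else " (outside observed range)"))
    }
  }
  print(x$regions)
  invisible(x)
}

#' @export
tidy.jn_region <- function(x, ...) x$regions

#' @export
autoplot.jn_region <- function(object, expand = 0.15, ...) {
  rng <- object$w_range
  pad <- expand * diff(rng)
  w <- seq(rng[1] - pad, rng[2] + pad, length.out = 400)
  v <- object$vcov
  theta <- object$beta_main + object$beta_int * w
  se <- sqrt(v["v11"] + 2 * w * v["v13"] + w^2 * v["v33"])
  d <- tibble(w = w, theta = theta,
              lo = theta - object$t_crit * se, hi = theta + object$t_crit * se)
  sig <- dplyr::filter(object$regions, .data$significant)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$w, .data$theta))
  if (nrow(sig) > 0) {
    p <- p + ggplot2::geom_rect(
      data = sig, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
      ymin = -Inf, ymax = Inf, fill = "steelblue", alpha = 0.15)
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$boundaries[object$in_range],
                        colour = "firebrick", linetype = 3) +
    ggplot2::labs(x = "Moderator value", y = "Conditional effect",
                  title = sprintf("Johnson-Neyman region (%s path)", object$path))
}

#' Summary table for a moderated mediation
#'
#' Conditional indirect effects at chosen moderator values (with bootstrap
#' intervals), plus an aggregate mediation summary computed from the
#' main-effect coefficients: aggregate indirect effect `a1 * b1`, total
#' `a1 * b1 + c'`, `VAF = 100 * ie / (ie + c')`, and a Goodman test on
#' `a1`, `b1` and their standard errors.
#'
#' @param fit A [mediate_moderated()] object.
#' @param w_values Moderator values (default the culture-time design points
#'   21, 28, 35 days); must lie within the observed moderator range.
#' @param boot A [boot_config()]; defaults to the one stored in `fit`.
#' @return An object of class `"modmed_summary"` with tibbles `conditional`
#'   and `aggregate`.
#' @export
modmed_summary <- function(fit, w_values = c(21, 28, 35), boot = fit$boot) {
  stopifnot(inherits(fit, "moderated_mediation"))
  if (length(w_values) == 0) abort("`w_values` must not be empty.")
  if (any(w_values < fit$w_range[1]) || any(w_values > fit$w_range[2])) {
    abort("All `w_values` must lie within the observed moderator range.")
  }
  p <- modmed_paths(fit)
  cond <- conditional_indirect(fit, w_values, boot)
  se_a1 <- unname(fit$mediator_model$se["x"])
  se_b1 <- unname(fit$outcome_model$se["m"])
  gd <- goodman_test(p$a1, p$b1, se_a1, se_b1)
  ie <- p$a1 * p$b1
  total <- ie + p$c_prime
  aggregate <- tibble(ie = ie, c_prime = p$c_prime, total = total,
                      vaf = vaf(ie, total),
                      goodman_z = gd$z, goodman_p = gd$p.value)
  out <- list(conditional = cond, aggregate = aggregate,
              w_values = w_values, vars = fit$vars)
  class(out) <- "modmed_summary"
  out
}

#' @export
print.modmed_summary <- function(x, ...) {
  cat("Conditional indirect effects:\n")
  print(x$conditional)
  cat("\nAggregate (main-effect) summary:\n")
  print(x$aggregate)
  invisible(x)
}
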