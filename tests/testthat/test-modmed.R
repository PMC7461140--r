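barley_modmed <- function() {
  mediate_moderated(regenerant_data(), f_combined, chg_dmv, sv, time_days,
                    boot = boot_config(n_boot = 500, seed = 7))
}

test_that("moderated fits on the barley data reproduce the published model", {
  fit <- barley_modmed()
  cm <- fit$mediator_model$coefficients
  expect_equal(unname(cm["x"]), -94.60, tolerance = 0.01)
  expect_equal(unname(cm["x:w"]), 2.759, tolerance = 0.01)
  expect_equal(fit$outcome_model$r2, 0.90, tolerance = 0.02)
  expect_equal(fit$outcome_model$f_stat, 66.25, tolerance = 0.02)
  # characteristic degrees of freedom for n = 35 under the default paths
  expect_equal(fit$outcome_model$df_resid, 30)
  expect_equal(fit$mediator_model$df_resid, 31)
  expect_equal(fit$outcome_model$df_model, 4)
})

test_that("the direct path can also be moderated, shifting the outcome df", {
  d <- regenerant_data()
  fit <- mediate_moderated(d, f_combined, chg_dmv, sv, time_days,
                           moderate = c("a", "b", "cprime"))
  expect_equal(fit$outcome_model$df_resid, 35 - 6)
  expect_error(
    mediate_moderated(dplyr::mutate(d, time_days = 28), f_combined,
                      chg_dmv, sv, time_days),
    class = "spectromed_singular_error")
  expect_error(
    mediate_moderated(d, f_combined, chg_dmv, sv, time_days,
                      moderate = "z"), "moderate")
})

test_that("highest-order interaction tests match the published F statistics", {
  fit <- barley_modmed()
  a_test <- interaction_f_test(fit$mediator_reduced, fit$mediator_model)
  expect_equal(a_test$f_stat, 9.89, tolerance = 0.02)
  expect_equal(a_test$delta_r2, 0.1848, tolerance = 0.02)
  expect_equal(c(a_test$df1, a_test$df2), c(1, 31))
  b_test <- interaction_f_test(fit$outcome_reduced, fit$outcome_model)
  expect_equal(b_test$f_stat, 28.32, tolerance = 0.02)
  expect_equal(c(b_test$df1, b_test$df2), c(1, 30))
})

test_that("conditional indirect effects are exact algebra on the coefficients", {
  fit <- barley_modmed()
  cm <- fit$mediator_model$coefficients
  co <- fit$outcome_model$coefficients
  w <- c(17.3, 21, 28, 31.11, 35)
  theta <- (unname(cm["x"]) + unname(cm[grep(":", names(cm))]) * w) *
    (unname(co["m"]) + unname(co[grep(":", names(co))]) * w)
  got <- conditional_indirect(fit, w, boot = NULL)
  expect_equal(got$estimate, theta, tolerance = 1e-12)

  # published point estimates at the design times
  est <- conditional_indirect(fit, c(21, 28), boot = NULL)$estimate
  expect_equal(est[1], 344.99, tolerance = 0.01)
  expect_equal(est[2], 46.28, tolerance = 0.02)

  # bootstrap intervals: significant at 21 days only, deterministic in the seed
  ci <- conditional_indirect(fit, c(21, 28, 35))
  expect_gt(ci$conf.low[1], 0)
  expect_lt(ci$conf.low[2], 0)
  expect_lt(ci$conf.low[3], 0)
  ci2 <- conditional_indirect(fit, c(21, 28, 35))
  expect_identical(ci$conf.low, ci2$conf.low)
})

test_that("Johnson-Neyman boundaries match a fine grid oracle and the record", {
  fit <- barley_modmed()
  grid_oracle <- function(model, main, int) {
    b1 <- unname(model$coefficients[main]); b3 <- unname(model$coefficients[int])
    V <- model$vcov
    tcrit <- qt(0.975, model$df_resid)
    w <- seq(15, 40, by = 0.01)
    tval <- abs(b1 + b3 * w) /
      sqrt(V[main, main] + 2 * w * V[main, int] + w^2 * V[int, int])
    w[which(diff(sign(tval - tcrit)) != 0)]  # last grid point before a crossing
  }
  int_of <- function(model) names(model$coefficients)[grep(":", names(model$coefficients))]
  jn_a <- johnson_neyman(fit, "a")
  cross_a <- grid_oracle(fit$mediator_model, "x", int_of(fit$mediator_model))
  for (b in jn_a$boundaries[jn_a$boundaries > 15 & jn_a$boundaries < 40]) {
    expect_lt(min(abs(b - cross_a)), 0.011)
  }
  jn_b <- johnson_neyman(fit, "b")
  cross_b <- grid_oracle(fit$outcome_model, "m", int_of(fit$outcome_model))
  for (b in jn_b$boundaries[jn_b$boundaries > 15 & jn_b$boundaries < 40]) {
    expect_lt(min(abs(b - cross_b)), 0.011)
  }

  # published significance limits: ~30 days (a path), ~28 days (b path)
  expect_equal(jn_a$boundaries[jn_a$in_range], 30, tolerance = 1 / 30)
  expect_equal(jn_b$boundaries[jn_b$in_range], 28, tolerance = 1 / 28)
  expect_true(jn_a$regions$significant[1])   # significant below the boundary
  expect_false(jn_a$regions$significant[2])
})

test_that("the moderated-mediation summary reports the aggregate decomposition", {
  fit <- barley_modmed()
  s <- modmed_summary(fit, boot = boot_config(n_boot = 500, seed = 11))
  # aggregate ie = a1*b1 and VAF = ie/(ie + c') against the published values
  expect_equal(s$aggregate$ie, 2804.153, tolerance = 0.005)
  expect_equal(s$aggregate$vaf, 98.57, tolerance = 0.005)
  expect_equal(s$aggregate$goodman_z, 3.29, tolerance = 0.01)
  expect_equal(nrow(s$conditional), 3)
  expect_error(modmed_summary(fit, w_values = numeric()), "empty")
  expect_error(modmed_summary(fit, w_values = 50), "range")
})

test_that("unmoderated truth yields near-constant conditional effects", {
  truth <- mediation_truth(n = 300, seed = 31)   # a3 = b2 = 0
  sim <- simulate_mediation(truth)
  fit <- mediate_moderated(sim, f_combined, chg_dmv, sv, time_days,
                           boot = boot_config(n_boot = 400, seed = 31))
  ce <- conditional_indirect(fit, c(21, 28, 35))
  spread <- diff(range(ce$estimate))
  expect_lt(spread, 3 * max(ce$se))
  # and interaction estimates are within their own 95% CI of zero
  tt <- tidy(fit)
  ints <- tt[grepl(":", tt$term), ]
  expect_true(all(ints$conf.low < 0 & ints$conf.high > 0))
})

test_that("moderated paths are recovered from synthetic data", {
  truth_paths <- c(a1 = -94.6, a3 = 2.76, b1 = -29.6, b2 = 0.963)
  rel_err <- matrix(NA_real_, 20, 4, dimnames = list(NULL, names(truth_paths)))
  for (r in 1:20) {
    sim <- simulate_mediation(mediation_truth(
      a = truth_paths["a1"], a3 = truth_paths["a3"],
      b = truth_paths["b1"], b2 = truth_paths["b2"],
      c_prime = 40.6, intercept_m = 4.07, intercept_y = 31.3,
      sd_m = 0.3, sd_y = 1.3, n = 500, seed = 1000 + r))
    fit <- mediate_moderated(sim, f_combined, chg_dmv, sv, time_days)
    p <- spectromed:::modmed_paths(fit)
    est <- c(p$a1, p$a3, p$b1, p$b2)
    rel_err[r, ] <- abs(est - truth_paths) / abs(truth_paths)
  }
  expect_true(all(apply(rel_err, 2, stats::median) <= 0.10))
})
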