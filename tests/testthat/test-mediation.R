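fast_boot <- boot_config(n_boot = 500, seed = 99)

test_that("simple mediation on the barley data reproduces the published paths", {
  d <- regenerant_data()
  fit <- mediate_simple(d, f1010_940, chg_dmv, sv, boot = fast_boot)
  g <- glance(fit)
  expect_equal(g$a, -15.57, tolerance = 0.01)
  expect_equal(g$b, -8.24, tolerance = 0.01)
  expect_equal(g$c_prime, 51.35, tolerance = 0.01)
  expect_equal(g$ie, 128.28, tolerance = 0.01)
  expect_equal(g$vaf, 71.4, tolerance = 0.001)

  # weak-band model: the completely standardized indirect effect
  fit710 <- mediate_simple(d, f710_690, chg_dmv, sv, boot = fast_boot)
  expect_equal(glance(fit710)$ie_completely_std, -0.299, tolerance = 0.01)
})

test_that("effect decomposition c = c' + a*b holds exactly under OLS", {
  d <- regenerant_data()
  for (x in c("f710_690", "f1010_940", "f_combined")) {
    g <- glance(mediate_simple(d, !!x, chg_dmv, sv, boot = fast_boot))
    expect_equal(g$c, g$c_prime + g$a * g$b, tolerance = 1e-8)
  }
  for (seed in 1:5) {
    sim <- simulate_mediation(mediation_truth(n = 40, seed = seed))
    g <- glance(mediate_simple(sim, f_combined, chg_dmv, sv, boot = fast_boot))
    expect_equal(g$c, g$c_prime + g$a * g$b, tolerance = 1e-8)
  }
})

test_that("Goodman test matches its formula, with Sobel fallback and ordering", {
  d <- regenerant_data()
  fit <- mediate_simple(d, f1010_940, chg_dmv, sv, boot = fast_boot)
  expect_equal(fit$goodman$z, 2.47, tolerance = 0.05 / 2.47)
  expect_equal(fit$goodman$p.value, 0.01, tolerance = 0.5)

  # extended-precision formula oracle
  a <- 1.37; b <- -0.52; se_a <- 0.41; se_b <- 0.13
  z_oracle <- (a * b) / sqrt(b^2 * se_a^2 + a^2 * se_b^2 - se_a^2 * se_b^2)
  expect_equal(goodman_test(a, b, se_a, se_b)$z, z_oracle, tolerance = 1e-12)

  # null a path
  g0 <- goodman_test(0, b, se_a, se_b)
  expect_equal(g0$z, 0)
  expect_equal(g0$p.value, 1)

  # fallback when the Goodman denominator is nonpositive
  gf <- goodman_test(0.1, 0.1, 1, 1)
  expect_equal(gf$method, "sobel_fallback")
  expect_equal(gf$z, sobel_test(0.1, 0.1, 1, 1)$z)

  # |z_Goodman| >= |z_Sobel| whenever Goodman's denominator is positive
  set.seed(5)
  for (i in 1:50) {
    a <- rnorm(1); b <- rnorm(1)
    se_a <- runif(1, 0.01, 0.3); se_b <- runif(1, 0.01, 0.3)
    if (b^2 * se_a^2 + a^2 * se_b^2 - se_a^2 * se_b^2 > 0) {
      expect_gte(abs(goodman_test(a, b, se_a, se_b)$z),
                 abs(sobel_test(a, b, se_a, se_b)$z))
    }
  }
})

test_that("VAF and Cohen's f2 follow their definitions", {
  expect_equal(vaf(128.28, 179.63), 71.4, tolerance = 0.1 / 71.4)
  expect_error(vaf(1, 0), class = "spectromed_domain_error")

  # full mediation: y depends on x only through m, so VAF = 100%
  set.seed(3)
  n <- 30
  x <- rnorm(n)
  m <- 2 * x + rnorm(n)
  d <- tibble::tibble(x = x, m = m, y = 3 * m)
  g <- glance(suppressWarnings(mediate_simple(d, x, m, y, boot = fast_boot)))
  expect_equal(g$c_prime, 0, tolerance = 1e-8)
  expect_equal(g$vaf, 100, tolerance = 1e-8)

  expect_equal(cohen_f2(0.1), 1 / 9, tolerance = 1e-12)
  expect_equal(cohen_f2(0), 0)
  expect_equal(cohen_f2(0.5), 1)
  expect_error(cohen_f2(1), class = "spectromed_domain_error")
})

test_that("bootstrap is deterministic under a seed and draws match a refit oracle", {
  d <- regenerant_data()
  b1 <- mediate_simple(d, f1010_940, chg_dmv, sv,
                       boot = boot_config(n_boot = 300, seed = 42))
  b2 <- mediate_simple(d, f1010_940, chg_dmv, sv,
                       boot = boot_config(n_boot = 300, seed = 42))
  expect_identical(b1$ie_ci, b2$ie_ci)
  expect_identical(b1$boot_draws, b2$boot_draws)
  b3 <- mediate_simple(d, f1010_940, chg_dmv, sv,
                       boot = boot_config(n_boot = 300, seed = 43))
  expect_false(identical(b1$ie_ci, b3$ie_ci))

  # weighted-moment draws equal literal case-resampled lm refits
  x <- d$f1010_940; m <- d$chg_dmv; y <- d$sv
  n <- length(x); n_boot <- 8; seed <- 12
  draws <- spectromed:::boot_mediation_draws(x, m, y, n_boot, seed)
  set.seed(seed)
  idx_all <- sample.int(n, n * n_boot, replace = TRUE)
  for (r in seq_len(n_boot)) {
    idx <- idx_all[((r - 1) * n + 1):(r * n)]
    a_ref <- unname(coef(lm(m[idx] ~ x[idx]))[2])
    cf <- coef(lm(y[idx] ~ x[idx] + m[idx]))
    expect_equal(draws$a[r], a_ref, tolerance = 1e-10)
    expect_equal(draws$b[r], unname(cf[3]), tolerance = 1e-10)
    expect_equal(draws$ie[r], a_ref * unname(cf[3]), tolerance = 1e-10)
  }
})

test_that("bias-corrected intervals differ from percentile but agree on symmetry", {
  d <- regenerant_data()
  pc <- mediate_simple(d, f1010_940, chg_dmv, sv,
                       boot = boot_config(n_boot = 1000, seed = 4,
                                          type = "percentile"))
  bc <- mediate_simple(d, f1010_940, chg_dmv, sv,
                       boot = boot_config(n_boot = 1000, seed = 4, type = "bc"))
  expect_equal(pc$ie, bc$ie)                 # point estimate is boot-free
  expect_false(identical(pc$ie_ci, bc$ie_ci))
  expect_lt(pc$ie_ci[1], pc$ie_ci[2])
})

test_that("degenerate inputs are rejected", {
  d <- regenerant_data()
  expect_error(mediate_simple(d[1:5, ], f1010_940, chg_dmv, sv,
                              boot = fast_boot), "10")
  d_const <- d
  d_const$chg_dmv <- 1
  expect_error(mediate_simple(d_const, f1010_940, chg_dmv, sv,
                              boot = fast_boot),
               class = "spectromed_variance_error")
})
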