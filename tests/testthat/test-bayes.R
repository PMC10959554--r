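test_that("the HDI is the shortest interval and matches the brute-force oracle exactly", {
  expect_equal(unname(hdi(rep(3.2, 50))), c(3.2, 3.2))
  set.seed(10)
  x <- rnorm(50000)
  h <- hdi(x)
  expect_equal(unname(h), c(-1.96, 1.96), tolerance = 0.03)
  for (i in 1:5) {
    y <- rexp(500) * sample(c(-1, 1), 500, replace = TRUE) + rnorm(500)
    expect_identical(unname(hdi(y, 0.9)), hdi_bruteforce(y, 0.9))
    expect_identical(unname(hdi(y, 0.95)), hdi_bruteforce(y, 0.95))
  }
})

test_that("ROPE decisions follow the HDI overlap rule and the Gaussian closed form", {
  d0 <- rope_decision(rep(0, 100), 0.2)
  expect_identical(d0$decision, "practically_equivalent")
  expect_equal(d0$pct_in_rope, 100)
  expect_identical(rope_decision(rep(2, 100), 0.2)$decision, "different")
  set.seed(11)
  x <- rnorm(200000)
  rd <- rope_decision(x, 0.2)
  expect_identical(rd$decision, "undecided")
  expect_equal(rd$pct_in_rope, 100 * (pnorm(0.2) - pnorm(-0.2)),
               tolerance = 0.01)
})

test_that("the ROPE half-width is 0.2 pooled SD and scales with the data", {
  set.seed(12)
  v <- rnorm(500)
  v <- (v - mean(v)) / sd(v)  # exactly unit SD
  expect_equal(rope_halfwidth(v), 0.2)
  expect_equal(rope_halfwidth(5 * v), 5 * rope_halfwidth(v))
  expect_equal(rope_halfwidth(v), 0.2 * sd(v))
})

test_that("Savage-Dickey Bayes factors match the conjugate closed form", {
  set.seed(13)
  prior_sd <- 1.6
  # posterior equals prior -> BF10 = 1
  bf <- bayes_factor_savage_dickey(rnorm(100000, 0, prior_sd), prior_sd)
  expect_equal(bf$bf10, 1, tolerance = 0.05)
  # conjugate normal-normal: y ~ N(d, s0^2/n), prior d ~ N(0, prior_sd^2)
  ybar <- 0.5; s0 <- 1; n <- 16
  post_var <- 1 / (1 / prior_sd^2 + n / s0^2)
  post_mean <- post_var * n * ybar / s0^2
  bf2 <- bayes_factor_savage_dickey(rnorm(200000, post_mean, sqrt(post_var)),
                                    prior_sd)
  analytic_bf01 <- dnorm(0, post_mean, sqrt(post_var)) / dnorm(0, 0, prior_sd)
  expect_equal(bf2$bf01, analytic_bf01, tolerance = 0.1)
  # posterior far from zero -> strong evidence for an effect
  bf3 <- bayes_factor_savage_dickey(rnorm(50000, 8, 0.5), prior_sd)
  expect_gt(bf3$bf10, 100)
})

test_that("the robustness curve is deterministic and widens evidence for the null", {
  set.seed(14)
  x <- rnorm(50000, 0, 0.5)  # posterior concentrated at the null
  single <- bf_robustness(x, prior_sds = 1.6)
  expect_equal(nrow(single), 1)
  expect_equal(single$bf10,
               bayes_factor_savage_dickey(x, 1.6)$bf10)
  curve <- bf_robustness(x, prior_sds = c(0.5, 1, 2, 4, 8))
  expect_true(all(diff(curve$bf01) > 0))
  expect_identical(curve, bf_robustness(x, prior_sds = c(0.5, 1, 2, 4, 8)))
})

test_that("the MAP-based p-value follows its Gaussian closed form", {
  set.seed(15)
  expect_equal(p_map(rnorm(100000, 0, 1)), 1, tolerance = 0.02)
  expect_equal(p_map(rnorm(200000, 2, 1)), exp(-2), tolerance = 0.1)
  expect_lt(p_map(rnorm(50000, 9, 1)), 0.01)
})

test_that("split-Rhat and ESS behave as theory predicts", {
  set.seed(16)
  n <- 20000
  chains <- list(matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x")),
                 matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x")))
  d <- mcmc_diagnostics(chains)
  expect_lt(abs(d$rhat[["x"]] - 1), 0.01)
  expect_equal(d$ess[["x"]], 2 * n, tolerance = 0.1)

  phi <- 0.9
  ar1 <- function() {
    e <- rnorm(n)
    x <- numeric(n)
    for (i in 2:n) x[i] <- phi * x[i - 1] + e[i]
    matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  }
  d2 <- mcmc_diagnostics(list(ar1(), ar1()))
  expect_equal(d2$ess[["x"]], 2 * n * (1 - phi) / (1 + phi), tolerance = 0.2)
})

test_that("diagnostics agree with an independent reference implementation", {
  skip_if_not_installed("coda")
  set.seed(17)
  n <- 10000
  phi <- 0.8
  e <- rnorm(n)
  x <- numeric(n)
  for (i in 2:n) x[i] <- phi * x[i - 1] + e[i]
  ours <- mcmc_diagnostics(list(matrix(x, ncol = 1,
                                       dimnames = list(NULL, "x"))))
  ref <- unname(coda::effectiveSize(coda::mcmc(x)))
  expect_equal(ours$ess[["x"]], ref, tolerance = 0.25)
})

test_that("the mixed model recovers simulated fixed effects", {
  d <- sim_summary_table(21, speed_effect = -20, subject_sd = 3, resid_sd = 3,
                         mu = 113)
  fit <- quiet_fit(d, "value", chains = 2, iter = 1200, warmup = 400, seed = 5)
  expect_lt(max(fit$diagnostics$rhat), 1.05)
  delta <- contrast_samples(fit, "speed_main")
  expect_lt(abs(mean(delta) - (-20)), 3 * sd(delta))
  expect_lt(abs(mean(delta) + 20), 2.5)
  inter <- contrast_samples(fit, "speed_slow_minus_normal@360") -
    contrast_samples(fit, "speed_slow_minus_normal@90")
  expect_lt(abs(mean(inter)), 3 * sd(inter))
})

test_that("a simulated standardized effect of -2.4 is recovered on the d scale", {
  d <- sim_summary_table(22, speed_effect = -2.4 * 3, subject_sd = 2,
                         resid_sd = 3, mu = 100)
  fit <- quiet_fit(d, "value", chains = 2, iter = 1200, warmup = 400, seed = 6)
  dd <- cohens_d(fit, "speed_main")
  expect_lt(abs(mean(dd) - (-2.4)), 3 * sd(dd) + 0.3)
})

test_that("degenerate and rescaled responses behave predictably", {
  d0 <- sim_summary_table(23)
  d0$value <- 0
  fit0 <- quiet_fit(d0, "value", chains = 2, iter = 400, warmup = 200, seed = 2)
  expect_lt(max(abs(coef(fit0))), 1e-3)

  d1 <- sim_summary_table(24, speed_effect = -5, resid_sd = 2)
  f1 <- quiet_fit(d1, "value", chains = 2, iter = 600, warmup = 300, seed = 3)
  d2 <- d1
  d2$value <- 10 * d2$value
  f2 <- quiet_fit(d2, "value", chains = 2, iter = 600, warmup = 300, seed = 3)
  expect_equal(mean(cohens_d(f1, "speed_main")),
               mean(cohens_d(f2, "speed_main")), tolerance = 1e-6)
  # zero contrast -> identically zero d
  zero <- cohens_d(f1, rep(0, length(f1$coef_names)))
  expect_true(all(zero == 0))
})

test_that("chains are reproducible given the seed", {
  d <- sim_summary_table(25, speed_effect = -3)
  f1 <- quiet_fit(d, "value", chains = 2, iter = 300, warmup = 150, seed = 42)
  f2 <- quiet_fit(d, "value", chains = 2, iter = 300, warmup = 150, seed = 42)
  expect_identical(f1$samples, f2$samples)
})

test_that("non-convergence is flagged rather than silent", {
  d <- sim_summary_table(29, speed_effect = -3)
  expect_warning(
    fit <- suppressMessages(fit_turn_effects(d, "value", chains = 2,
                                             iter = 30, warmup = 5, seed = 1)),
    "not converged")
  expect_false(fit$converged)
})

test_that("eta squared is a bounded variance fraction with the right ordering", {
  d <- sim_summary_table(26, speed_effect = 4, subject_sd = 0, resid_sd = 1)
  fit <- quiet_fit(d, "value", chains = 2, iter = 800, warmup = 300, seed = 8)
  es <- eta_squared(fit, "speed")
  ea <- eta_squared(fit, "amplitude")
  expect_true(all(es >= 0 & es <= 1))
  expect_true(all(ea >= 0 & ea <= 1))
  # analytic fraction: SS_speed = 6 (delta/2)^2, total adds 6 sigma^2
  analytic <- (6 * 4) / (6 * 4 + 6 * 1)
  expect_equal(mean(es), analytic, tolerance = 0.12)
  expect_gt(mean(es), 10 * mean(ea))

  dnull <- sim_summary_table(27, speed_effect = 0, subject_sd = 0.5)
  fnull <- quiet_fit(dnull, "value", chains = 2, iter = 800, warmup = 300,
                     seed = 9)
  expect_lt(mean(eta_squared(fnull, "speed")), 0.15)
})

test_that("effect tables carry decisions, glyphs and diagnostics", {
  d <- sim_summary_table(28, speed_effect = -20, subject_sd = 3, resid_sd = 3,
                         mu = 113)
  fit <- quiet_fit(d, "value", chains = 2, iter = 800, warmup = 300, seed = 10)
  eff <- effect_estimates(fit)
  expect_s3_class(eff, "turn_effect_table")
  row <- eff[eff$contrast == "speed_main", ]
  expect_identical(row$decision, "different")
  expect_identical(row$glyph, "<")
  expect_lt(row$hdi_high, -15)
  expect_gt(row$bf10, 30)
  expect_lt(row$p_map, 0.01)
  expect_true(all(eff$pct_in_rope >= 0 & eff$pct_in_rope <= 100))
  expect_true(all(eff$hdi_low <= eff$hdi_high))
  sm <- summary(fit)
  expect_output(print(sm), "speed_main")
})
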