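test_that("bootstrap of a constant estimator collapses to that constant", {
  tab <- make_table(A = rep(c(0, 1), 20), Y = rep(c(0, 1), each = 20))
  b <- bootstrap_estimate(tab, function(t) 0.042, B = 25, seed = 3)
  expect_true(all(b$replicates == 0.042))
  expect_equal(unname(b$quantile_ci), c(0.042, 0.042))
  expect_equal(b$boot_mean, 0.042)
})

test_that("bootstrap replicates are reproducible and seed-stable", {
  tab <- generate_cohort(kisumu_like_params(n = 800, seed = 31,
                                            missingness = FALSE))
  est <- function(t) g_compute(t, fit_outcome(t, main_effects_q))$psi
  b1 <- bootstrap_estimate(tab, est, B = 120, seed = 5)
  b2 <- bootstrap_estimate(tab, est, B = 120, seed = 5)
  expect_identical(b1$replicates, b2$replicates)
  # two different seeds: quantile endpoints agree within 3 bootstrap SEs
  b3 <- bootstrap_estimate(tab, est, B = 120, seed = 6)
  expect_lt(max(abs(b1$quantile_ci - b3$quantile_ci)), 3 * b1$boot_se)
})

test_that("bootstrap mean sits within one bootstrap SE of the estimate", {
  tab <- generate_cohort(kisumu_like_params(n = 2519, seed = 37,
                                            missingness = FALSE))
  qf <- fit_outcome(tab, main_effects_q)
  point <- g_compute(tab, qf)
  b <- bootstrap_estimate(
    tab, function(t) g_compute(t, fit_outcome(t, main_effects_q))$psi,
    B = 200, seed = 7)
  expect_lt(abs(b$boot_mean - point$psi), b$boot_se)
})

test_that("failing replicates are counted and capped at 20%", {
  tab <- make_table(A = rep(c(0, 1), 20), Y = rep(c(0, 1), 20))
  expect_error(
    bootstrap_estimate(tab, function(t) stop("boom"), B = 20, seed = 1),
    "20%")
  flaky <- function(t) if (sum(t$Y) %% 13 == 0) stop("rare") else 0.01
  b <- bootstrap_estimate(tab, flaky, B = 50, seed = 2)
  expect_equal(length(b$replicates) + b$n_failed, 50)
})

test_that("strata with an empty exposure arm are flagged", {
  # construct a cohort in which post-secondary, unmarried, nulliparous
  # women never use contraception
  set.seed(41)
  n <- 3000
  edu <- sample(0:3, n, TRUE)
  mar <- rbinom(n, 1, 0.5)
  grav <- sample(c(0, 1, 3), n, TRUE)
  never <- edu == 3 & mar == 0 & grav == 0
  A <- ifelse(never, 0L, rbinom(n, 1, 0.4))
  tab <- structure(
    data.frame(age = 30L, education = edu, marital = mar, gravidity = grav,
               cd4_nadir = 300, A = A, Y = rbinom(n, 1, 0.1),
               months_observed = 24, frac_visits_coc = ifelse(A == 1, .5, 0)),
    class = c("cohort_table", "data.frame"))
  rep <- positivity_report(tab, strata_cols = c("education", "marital",
                                                "gravidity"))
  expect_true(any(grepl("^3 \\| 0 \\| 0$", rep$flagged_strata$stratum)))
  flagged_row <- rep$flagged_strata[rep$flagged_strata$stratum == "3 | 0 | 0", ]
  expect_equal(flagged_row$n_exposed, 0)
  # fair-coin exposure in a single stratum: nothing to flag
  tab2 <- make_table(A = rep(c(0, 1), 500), Y = rbinom(1000, 1, 0.1))
  rep2 <- positivity_report(tab2)
  expect_equal(nrow(rep2$flagged_strata), 0)
})

test_that("symmetry diagnostics vanish for symmetric replicates", {
  boot <- structure(list(replicates = c(0.01, 0.02, 0.03, 0.04, 0.05),
                         boot_mean = 0.03, boot_se = sd(c(1:5) / 100),
                         quantile_ci = c(0.012, 0.048), n_failed = 0,
                         B = 5, seed = 1), class = "bootstrap_result")
  point <- estimate_result(0.03, method = "gcomp")
  tab <- make_table(A = rep(c(0, 1), 10), Y = rep(c(0, 1), 10))
  rep <- positivity_report(tab, boot = boot, point = point)
  expect_equal(unname(rep$symmetry["mean_minus_estimate"]), 0)
  expect_equal(unname(rep$symmetry["skewness"]), 0)
})

test_that("propensity extremes outside the truncation bounds are counted", {
  tab <- saturated_fixture(n = 800, seed = 43)
  gfit <- fit_propensity(tab, A ~ marital, g_bounds = c(0.45, 0.55))
  rep <- positivity_report(tab, gfit = gfit)
  g_raw <- gfit$g_raw(tab)
  expect_equal(rep$g_extremes, sum(g_raw < 0.45 | g_raw > 0.55))
  expect_gt(rep$g_extremes, 0)
})

test_that("pipeline pooling composes Rubin's rule over estimate results", {
  r1 <- estimate_result(0.02, variance = 1e-4, method = "tmle")
  r2 <- estimate_result(0.04, variance = 1e-4, method = "tmle")
  pooled <- pool_pipeline(list(r1, r2))
  expect_equal(pooled$estimate, 0.03)
  expect_equal(pooled$total_var, 1e-4 + 1.5 * 2e-4)
  # same arithmetic through plain (psi, var) pairs
  pooled2 <- pool_pipeline(list(c(0.02, 1e-4), c(0.04, 1e-4)))
  expect_equal(pooled2$estimate, pooled$estimate)
  expect_equal(pooled2$total_var, pooled$total_var)
  expect_error(pool_pipeline(list(r1)), "m >= 2")
})

test_that("bootstrap SE and influence-curve SE agree for TMLE at scale", {
  tab <- generate_cohort(kisumu_like_params(n = 2519, seed = 47,
                                            missingness = FALSE))
  point <- tmle_estimate(tab, fit_outcome(tab, main_effects_q),
                         fit_propensity(tab, main_effects_g))
  est <- function(t) {
    tmle_estimate(t, fit_outcome(t, main_effects_q),
                  fit_propensity(t, main_effects_g))$psi
  }
  b <- bootstrap_estimate(tab, est, B = 150, seed = 9)
  ic_se <- sqrt(point$variance)
  expect_lt(abs(b$boot_se - ic_se) / ic_se, 0.2)
})
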