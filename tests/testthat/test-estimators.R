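test_that("a single-learner library is returned without CV deciding", {
  tab <- generate_cohort(kisumu_like_params(n = 300, seed = 1,
                                            missingness = FALSE))
  fit <- discrete_super_learner(tab, "outcome",
                                learner_library("main_effects", v_folds = 2),
                                seed = 1)
  expect_s3_class(fit, "outcome_fit")
  expect_equal(fit$learner_id, "main_effects")
})

test_that("CV selects the main-effects learner on main-effects data", {
  sel <- vapply(1:50, function(i) {
    tab <- generate_cohort(kisumu_like_params(n = 5000, seed = 3000 + i,
                                              missingness = FALSE))
    discrete_super_learner(tab, "outcome", learner_library(v_folds = 10),
                           seed = 3000 + i)$learner_id
  }, character(1))
  expect_gte(mean(sel == "main_effects"), 0.8)
})

test_that("CV selects the intercept learner when the outcome is noise", {
  sel <- vapply(1:50, function(i) {
    p <- no_confounder_params(n = 800, seed = 4000 + i, b_A = 0)
    # re-activate confounder variation without outcome dependence
    p$confounder_spec <- kisumu_like_params()$confounder_spec
    tab <- generate_cohort(p)
    discrete_super_learner(tab, "outcome", learner_library(v_folds = 10),
                           seed = 4000 + i)$learner_id
  }, character(1))
  expect_gt(mean(sel == "intercept"), 0.5)
})

test_that("g-computation returns exactly zero when the fit ignores A", {
  tab <- saturated_fixture()
  fit <- fit_outcome(tab, Y ~ marital)
  expect_identical(g_compute(tab, fit)$psi, 0)
})

test_that("saturated estimators equal nonparametric standardization", {
  tab <- saturated_fixture()
  psi_np <- np_standardization(tab, "marital")
  qfit <- fit_outcome(tab, Y ~ A * marital)
  gfit <- fit_propensity(tab, A ~ marital, g_bounds = c(1e-6, 1 - 1e-6))
  expect_lt(abs(g_compute(tab, qfit)$psi - psi_np), 1e-10)
  expect_lt(abs(iptw_estimate(tab, stabilized_weights(tab, gfit))$psi -
                  psi_np), 1e-10)
  expect_lt(abs(tmle_estimate(tab, qfit, gfit)$psi - psi_np), 1e-10)
})

test_that("stabilized weights behave like design weights", {
  tab <- saturated_fixture()
  # randomized-exposure limit: constant g equal to P(A = 1) gives weight 1
  gconst <- fit_propensity(tab, A ~ 1)
  expect_equal(stabilized_weights(tab, gconst), rep(1, nrow(tab)),
               tolerance = 1e-10)
  # direct formula: g = 0.1, A = 1, P(A = 1) = 0.35 => weight 3.5
  fake_g <- structure(list(g = function(nd) rep(0.1, nrow(nd)),
                           truncation_bounds = c(0.01, 0.99)),
                      class = "propensity_fit")
  tab2 <- make_table(A = c(1, rep(c(1, 0), c(34, 65))),
                     Y = rep(0:1, 50))
  w <- stabilized_weights(tab2, fake_g)
  expect_equal(w[1], 0.35 / 0.1)
  # correctly specified g: mean weight near 1 at large n
  big <- generate_cohort(kisumu_like_params(n = 5000, seed = 19,
                                            missingness = FALSE))
  gfit <- fit_propensity(big, main_effects_g)
  expect_lt(abs(mean(stabilized_weights(big, gfit)) - 1), 0.05)
})

test_that("IPTW reduces to hand arithmetic and to the crude difference", {
  # all weights 1: crude prevalence difference
  tab <- saturated_fixture()
  w1 <- rep(1, nrow(tab))
  crude <- mean(tab$Y[tab$A == 1]) - mean(tab$Y[tab$A == 0])
  expect_equal(iptw_estimate(tab, w1)$psi, crude, tolerance = 1e-12)
  # 4-record hand case: psi = 2/3 - 1/4
  tab4 <- make_table(A = c(1, 1, 0, 0), Y = c(1, 0, 1, 0))
  w4 <- c(2, 1, 1, 3)
  expect_equal(iptw_estimate(tab4, w4)$psi, 2 / 3 - 1 / 4,
               tolerance = 1e-12)
  # unnormalized Horvitz-Thompson form
  expect_equal(iptw_estimate(tab4, w4, normalized = FALSE)$psi,
               (2 * 1 - 1 * 1) / 4, tolerance = 1e-12)
  # empty arm
  tab_one <- make_table(A = rep(1, 4), Y = c(1, 0, 1, 0))
  expect_error(iptw_estimate(tab_one, w4), "zero total weight")
})

test_that("TMLE with an NPMLE initial fit has zero fluctuation", {
  tab <- saturated_fixture()
  qfit <- fit_outcome(tab, Y ~ A * marital)
  gfit <- fit_propensity(tab, A ~ marital, g_bounds = c(1e-6, 1 - 1e-6))
  res <- tmle_estimate(tab, qfit, gfit)
  expect_lt(abs(res$diagnostics$epsilon), 1e-6)
  expect_equal(res$psi, g_compute(tab, qfit)$psi, tolerance = 1e-8)
})

test_that("TMLE solves the score equation and centers the influence curve", {
  tab <- generate_cohort(kisumu_like_params(n = 3000, seed = 23,
                                            missingness = FALSE))
  res <- tmle_estimate(tab, fit_outcome(tab, Y ~ A + age + marital),
                       fit_propensity(tab, A ~ age + education))
  expect_lt(abs(res$diagnostics$score), 1e-8)
  expect_lt(abs(mean(res$diagnostics$influence_curve)), 1e-8)
  expect_true(res$ci_low <= res$psi && res$psi <= res$ci_high)
})

test_that("estimates are invariant to record order and column order", {
  tab <- generate_cohort(kisumu_like_params(n = 1500, seed = 29,
                                            missingness = FALSE))
  perm <- withr::with_seed(1, sample.int(nrow(tab)))
  tab_p <- tab[perm, ]
  tab_c <- tab[, rev(names(tab))]
  run_all <- function(t) {
    qf <- fit_outcome(t, main_effects_q)
    gf <- fit_propensity(t, main_effects_g)
    c(g_compute(t, qf)$psi,
      iptw_estimate(t, stabilized_weights(t, gf))$psi,
      tmle_estimate(t, qf, gf)$psi)
  }
  expect_equal(run_all(tab), run_all(tab_p), tolerance = 1e-8)
  expect_equal(run_all(tab), run_all(tab_c), tolerance = 1e-12)
})

test_that("a degenerate outcome returns zero with a warning", {
  tab <- make_table(A = rep(c(0, 1), 10), Y = rep(0L, 20))
  qfit <- suppressWarnings(fit_outcome(tab, Y ~ A))
  expect_warning(res <- g_compute(tab, qfit), "degenerate")
  expect_identical(res$psi, 0)
  gfit <- fit_propensity(tab, A ~ 1)
  expect_warning(res2 <- tmle_estimate(tab, qfit, gfit), "degenerate")
  expect_identical(res2$psi, 0)
  expect_warning(res3 <- iptw_estimate(tab, rep(1, 20)), "degenerate")
  expect_identical(res3$psi, 0)
})

test_that("propensity fits reject outcome leakage and bad bounds", {
  tab <- saturated_fixture()
  expect_error(fit_propensity(tab, A ~ Y + marital), "outcome")
  expect_error(fit_propensity(tab, A ~ marital, g_bounds = c(0.9, 0.1)),
               "g_bounds")
})
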