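test_that("cohort generation is deterministic given the seed", {
  p <- kisumu_like_params(n = 300, seed = 42)
  expect_identical(generate_cohort(p), generate_cohort(p))
  p2 <- kisumu_like_params(n = 300, seed = 43)
  expect_false(identical(generate_cohort(p), generate_cohort(p2)))
})

test_that("generated cohorts satisfy the structural invariants", {
  p <- kisumu_like_params(n = 2000, seed = 7)
  tab <- generate_cohort(p)
  expect_equal(nrow(tab), 2000)
  expect_false(anyNA(tab))
  expect_true(all(tab$frac_visits_coc[tab$A == 0] == 0))
  expect_true(all(tab$frac_visits_coc[tab$A == 1] > 0))
  expect_true(all(tab$frac_visits_coc <= 1))
  expect_true(all(tab$months_observed >= 0))
  expect_identical(tab$true_A, tab$A)
  expect_true(all(tab$gravidity <= 12))
})

test_that("a null exposure coefficient yields equal outcome laws by arm", {
  # unconfounded fixture: with a null effect and no shared causes, the
  # outcome law is identical across exposure arms
  p <- no_confounder_params(n = 40000, seed = 5, b_A = 0)
  tab <- generate_cohort(p)
  # large-n frequency check: P(Y | A = 1) == P(Y | A = 0) up to noise
  p1 <- mean(tab$Y[tab$A == 1])
  p0 <- mean(tab$Y[tab$A == 0])
  se <- sqrt(p1 * (1 - p1) / sum(tab$A) + p0 * (1 - p0) / sum(1 - tab$A))
  expect_lt(abs(p1 - p0), 3 * se)
  # and the counterfactual truth is exactly zero under enumeration
  pnull <- one_binary_confounder_params(b_A = 0)
  expect_identical(true_prevalence_difference(pnull, method = "enumerate"), 0)
})

test_that("default parameters reproduce the target cohort margins", {
  p <- kisumu_like_params(n = 2519, seed = 1, missingness = FALSE)
  tab <- generate_cohort(p)
  expect_lt(abs(mean(tab$A) - 0.35), 0.03)
  expect_lt(abs(mean(tab$Y) - 0.087), 0.02)
})

test_that("true psi matches closed form in the no-covariate limit", {
  p <- no_confounder_params(intercept = -1.5, b_A = 0.8)
  expect_equal(true_prevalence_difference(p, method = "enumerate"),
               plogis(-1.5 + 0.8) - plogis(-1.5), tolerance = 1e-12)
})

test_that("true psi matches the two-stratum hand enumeration", {
  p <- one_binary_confounder_params(b_marital_Y = 0.9, b_A = 0.6)
  # hand sum over marital = 0 (weight .6) and marital = 1 (weight .4)
  hand <- 0.6 * (plogis(-1.2 + 0.6) - plogis(-1.2)) +
    0.4 * (plogis(-1.2 + 0.9 + 0.6) - plogis(-1.2 + 0.9))
  expect_equal(true_prevalence_difference(p, method = "enumerate"), hand,
               tolerance = 1e-12)
})

test_that("Monte Carlo truth converges to the enumerated truth", {
  p <- one_binary_confounder_params(seed = 77)
  exact <- true_prevalence_difference(p, method = "enumerate")
  n_mc <- 2e5
  mc <- true_prevalence_difference(p, n_mc = n_mc, method = "mc")
  # conservative bound on SE: the averaged integrand lies in [-1, 1]
  expect_lt(abs(mc - exact), 3 * 1 / sqrt(n_mc))
})

test_that("MAR missingness hits configured rates and never touches A or Y", {
  p <- kisumu_like_params(n = 2000, seed = 3)
  tab <- generate_cohort(p)
  # logit 0 => a fair coin per cell
  p50 <- p
  p50$miss_spec <- list(cd4_nadir = c(intercept = 0))
  out <- apply_mar_missingness(tab, p50)
  expect_lt(abs(mean(is.na(out$cd4_nadir)) - 0.5), 0.05)
  expect_false(anyNA(out$A) || anyNA(out$Y))
  expect_equal(nrow(out), nrow(tab))
  # all logits -Inf => untouched
  pnone <- p
  pnone$miss_spec <- list(cd4_nadir = c(intercept = -Inf))
  expect_identical(apply_mar_missingness(tab, pnone), tab)
  # outcome-dependent missingness: stratum rates track expit of the logits
  pdep <- p
  pdep$miss_spec <- list(cd4_nadir = c(intercept = -1, Y = 1.5))
  big <- generate_cohort(kisumu_like_params(n = 30000, seed = 4))
  outd <- apply_mar_missingness(big, pdep)
  r0 <- mean(is.na(outd$cd4_nadir[big$Y == 0]))
  r1 <- mean(is.na(outd$cd4_nadir[big$Y == 1]))
  expect_lt(abs(r0 - plogis(-1)), 0.02)
  expect_lt(abs(r1 - plogis(0.5)), 0.04)
})

test_that("missingness logits may only reference always-observed columns", {
  expect_error(
    scm_params(
      n = 10,
      confounder_spec = kisumu_like_params()$confounder_spec,
      beta_A = c(intercept = 0), beta_Y = c(intercept = 0, A = 0),
      miss_spec = list(cd4_nadir = c(intercept = 0, education = 1))),
    "MAR")
})

test_that("exposure misclassification flips at the configured rates", {
  p <- kisumu_like_params(n = 4000, seed = 9, missingness = FALSE)
  tab <- generate_cohort(p)
  # perfect sensitivity/specificity: identity
  expect_identical(misclassify_exposure(tab, 1, 1, seed = 1)$A, tab$A)
  # sensitivity 0.7: ~30% of true exposed become recorded non-users
  mis <- misclassify_exposure(tab, 0.7, 1, seed = 2)
  n_exp <- sum(tab$true_A == 1)
  fn <- sum(tab$true_A == 1 & mis$A == 0)
  expect_lt(abs(fn - 0.3 * n_exp), 3 * sqrt(n_exp * 0.3 * 0.7))
  # recorded-exposure consistency of the visit fraction
  expect_true(all(mis$frac_visits_coc[mis$A == 0] == 0))
  expect_true(all(mis$frac_visits_coc[mis$A == 1] > 0))
  # true_A untouched
  expect_identical(mis$true_A, tab$true_A)
  # missing true_A is a state error
  tab$true_A <- NULL
  tab$true_A <- NA
  expect_error(misclassify_exposure(tab, 0.9, 0.9, seed = 1), "true_A")
})

test_that("invalid parameterisations are rejected by field name", {
  spec <- kisumu_like_params()$confounder_spec
  expect_error(kisumu_like_params(n = 0), "n")
  bad <- spec
  bad$education$prob <- c(0.5, 0.6)
  expect_error(
    scm_params(n = 10, confounder_spec = bad, beta_A = c(intercept = 0),
               beta_Y = c(intercept = 0)),
    "education")
  expect_error(
    scm_params(n = 10, confounder_spec = spec, beta_A = c(intercept = 0),
               beta_Y = c(intercept = 0), misclass = c(sensitivity = 0,
                                                       specificity = 1)),
    "misclass|sensitivity")
  expect_error(
    scm_params(n = 10, confounder_spec = spec,
               beta_A = c(intercept = 0, nonsense = 1),
               beta_Y = c(intercept = 0)),
    "beta_A")
})

test_that("cohort CSV round-trips with empty fields as missing", {
  p <- kisumu_like_params(n = 200, seed = 12)
  tab <- apply_mar_missingness(generate_cohort(p), p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_true(anyNA(back$cd4_nadir))
})

test_that("SCM config files round-trip", {
  p <- kisumu_like_params(n = 123, seed = 99)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_scm_config(p, path)
  p2 <- read_scm_config(path)
  expect_equal(p2, p)
  shipped <- read_scm_config(system.file("extdata", "kisumu_like.cfg",
                                         package = "causalprev"))
  expect_equal(shipped$n, 2519)
})
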