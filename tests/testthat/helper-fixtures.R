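# Parameter fixtures built in code.

point_mass <- function(v) list(dist = "discrete", values = v, prob = 1)

# All confounders collapsed to point masses except a single active binary
# confounder (marital), so counterfactual truth is a 2-stratum hand sum.
one_binary_confounder_params <- function(n = 500, seed = 1,
                                         b_marital_A = 1.2,
                                         b_marital_Y = 0.9,
                                         b_A = 0.6) {
  scm_params(
    n = n,
    confounder_spec = list(
      age = point_mass(30),
      education = point_mass(1),
      marital = list(dist = "bernoulli", prob = 0.4),
      gravidity = point_mass(2),
      cd4_nadir = point_mass(300)
    ),
    beta_A = c(intercept = -0.5, marital = b_marital_A),
    beta_Y = c(intercept = -1.2, marital = b_marital_Y, A = b_A),
    seed = seed
  )
}

# No active confounders at all: outcome logit is intercept + b * A.
no_confounder_params <- function(n = 100, seed = 1, intercept = -1.5,
                                 b_A = 0.8) {
  scm_params(
    n = n,
    confounder_spec = list(
      age = point_mass(30),
      education = point_mass(1),
      marital = point_mass(1),
      gravidity = point_mass(2),
      cd4_nadir = point_mass(300)
    ),
    beta_A = c(intercept = 0),
    beta_Y = c(intercept = intercept, A = b_A),
    seed = seed
  )
}

# A complete cohort_table assembled directly from vectors (bypassing the
# simulator) for hand-arithmetic tests.
make_table <- function(A, Y, marital = NULL, months = 24, frac = NULL) {
  n <- length(A)
  if (is.null(marital)) marital <- rep(1L, n)
  if (is.null(frac)) frac <- ifelse(A == 1, 0.5, 0)
  structure(
    data.frame(age = rep(30L, n), education = rep(1L, n),
               marital = marital, gravidity = rep(2L, n),
               cd4_nadir = rep(300, n), A = A, Y = Y,
               months_observed = rep(months, length.out = n),
               frac_visits_coc = frac),
    class = c("cohort_table", "data.frame"))
}

# Saturated fixture on one binary confounder where every (A, W) cell has
# outcomes of both kinds, so empirical cell means lie strictly in (0, 1).
saturated_fixture <- function(n = 600, seed = 17) {
  p <- one_binary_confounder_params(n = n, seed = seed)
  tab <- generate_cohort(p)
  stopifnot(all(table(tab$A, tab$marital, tab$Y) > 0))
  tab
}

main_effects_q <- Y ~ A + age + education + marital + gravidity + cd4_nadir
main_effects_g <- A ~ age + education + marital + gravidity + cd4_nadir
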