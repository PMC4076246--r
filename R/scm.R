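#' Structural-causal-model parameters for cohort simulation
#'
#' Defines the data-generating process for a simulated cross-sectional
#' cohort of women in HIV care: baseline confounders `W` (age, educational
#' attainment, marital status, gravidity, CD4+ cell count nadir), a binary
#' exposure `A` (combined oral contraceptive ever-use) drawn from a
#' logistic model on `W`, and a binary outcome `Y` (CIN2+, cervical
#' intraepithelial neoplasia grade 2 or higher) drawn from a logistic
#' model on `W` and `A`. Observation metadata (months observed, fraction
#' of clinic visits at which contraceptive use was reported),
#' missing-at-random missingness in confounders, and exposure
#' misclassification are layered on top by [apply_mar_missingness()] and
#' [misclassify_exposure()].
#'
#' @param n Cohort size (number of women).
#' @param confounder_spec Named list of marginal confounder distributions.
#'   Each entry is a list whose `dist` element is one of `"uniform_int"`
#'   (fields `min`, `max`), `"categorical"` (field `prob`, levels coded
#'   `0:(k-1)`), `"bernoulli"` (field `prob`), `"truncated_poisson"`
#'   (fields `lambda`, `max`), `"lognormal"` (fields `meanlog`, `sdlog`),
#'   or `"discrete"` (fields `values`, `prob`). Names must be
#'   `age`, `education`, `marital`, `gravidity`, `cd4_nadir`.
#' @param beta_A Named coefficient vector for the exposure logit:
#'   `logit P(A = 1 | W) = beta_A["intercept"] + sum(beta_A[j] * W[j])`.
#'   Recognised names: `intercept`, the confounder names, and optionally
#'   `age_sq` (coefficient on `age^2`, for building misspecified-model
#'   scenarios).
#' @param beta_Y Named coefficient vector for the outcome logit on the
#'   confounders plus `A`; the `A` entry is the causal knob.
#' @param visit_spec Distributions of observation metadata:
#'   `months = list(shape, scale)` (gamma, rounded to whole months) and
#'   `frac = list(shape1, shape2)` (beta distribution of the fraction of
#'   visits reporting contraceptive use among recorded users; always 0
#'   for recorded non-users).
#' @param miss_spec Named list of missingness logits, one per confounder
#'   that may go missing. Each entry is a named numeric vector of logit
#'   coefficients over always-observed columns only (`intercept`, `A`,
#'   `Y`, `age`), so missingness is at random (MAR) by construction.
#' @param misclass Length-2 numeric `c(sensitivity, specificity)` of the
#'   recorded exposure relative to true exposure; `c(1, 1)` means no
#'   misclassification.
#' @param seed Master integer seed; every stochastic stage derives an
#'   independent substream from it.
#'
#' @return An object of class `scm_params`.
#' @seealso [kisumu_like_params()] for the shipped default
#'   parameterisation, [generate_cohort()], [true_prevalence_difference()].
#' @export
scm_params <- function(n,
                       confounder_spec,
                       beta_A,
                       beta_Y,
                       visit_spec = list(months = list(shape = 2, scale = 12),
                                         frac = list(shape1 = 2, shape2 = 2)),
                       miss_spec = list(),
                       misclass = c(sensitivity = 1, specificity = 1),
                       seed = 1L) {
  params <- structure(
    list(n = n, confounder_spec = confounder_spec, beta_A = beta_A,
         beta_Y = beta_Y, visit_spec = visit_spec, miss_spec = miss_spec,
         misclass = misclass, seed = seed),
    class = "scm_params")
  validate_scm_params(params)
  params
}

confounder_names <- c("age", "education", "marital", "gravidity", "cd4_nadir")

validate_scm_params <- function(p) {
  stopifnot(inherits(p, "scm_params"))
  if (!is.numeric(p$n) || length(p$n) != 1 || p$n < 1 || p$n != round(p$n)) {
    stop("scm_params: `n` must be a single integer >= 1", call. = FALSE)
  }
  if (!setequal(names(p$confounder_spec), confounder_names)) {
    stop("scm_params: `confounder_spec` must have entries exactly for ",
         paste(confounder_names, collapse = ", "), call. = FALSE)
  }
  for (nm in names(p$confounder_spec)) {
    spec <- p$confounder_spec[[nm]]
    if (is.null(spec$dist)) {
      stop("scm_params: confounder_spec$", nm, " lacks a `dist` field",
           call. = FALSE)
    }
    switch(spec$dist,
      uniform_int = {
        if (spec$min > spec$max) {
          stop("scm_params: confounder_spec$", nm, ": min > max",
               call. = FALSE)
        }
      },
      categorical = ,
      discrete = {
        pr <- spec$prob
        if (any(pr < 0) || abs(sum(pr) - 1) > 1e-8) {
          stop("scm_params: confounder_spec$", nm,
               ": probabilities must be non-negative and sum to 1",
               call. = FALSE)
        }
        if (spec$dist == "discrete" &&
            length(spec$values) != length(pr)) {
          stop("scm_params: confounder_spec$", nm,
               ": values and prob lengths differ", call. = FALSE)
        }
      },
      bernoulli = {
        if (spec$prob < 0 || spec$prob > 1) {
          stop("scm_params: confounder_spec$", nm,
               ": prob must be in [0, 1]", call. = FALSE)
        }
      },
      truncated_poisson = {
        if (spec$lambda <= 0 || spec$max < 0) {
          stop("scm_params: confounder_spec$", nm,
               ": lambda must be > 0 and max >= 0", call. = FALSE)
        }
      },
      lognormal = {
        if (spec$sdlog < 0) {
          stop("scm_params: confounder_spec$", nm, ": sdlog must be >= 0",
               call. = FALSE)
        }
      },
      stop("scm_params: confounder_spec$", nm, ": unknown dist `",
           spec$dist, "`", call. = FALSE)
    )
  }
  ok_A <- c("intercept", confounder_names, "age_sq")
  if (!all(names(p$beta_A) %in% ok_A)) {
    stop("scm_params: `beta_A` has unrecognised names: ",
         paste(setdiff(names(p$beta_A), ok_A), collapse = ", "),
         call. = FALSE)
  }
  if (!all(names(p$beta_Y) %in% c(ok_A, "A"))) {
    stop("scm_params: `beta_Y` has unrecognised names: ",
         paste(setdiff(names(p$beta_Y), c(ok_A, "A")), collapse = ", "),
         call. = FALSE)
  }
  sens <- p$misclass[["sensitivity"]]
  spc <- p$misclass[["specificity"]]
  if (sens <= 0 || sens > 1 || spc <= 0 || spc > 1) {
    stop("scm_params: `misclass` sensitivity and specificity must be in ",
         "(0, 1]", call. = FALSE)
  }
  allowed_miss <- c("intercept", "A", "Y", "age")
  for (nm in names(p$miss_spec)) {
    if (!nm %in% setdiff(confounder_names, "age")) {
      stop("scm_params: `miss_spec` targets unknown or ineligible column `",
           nm, "`", call. = FALSE)
    }
    bad <- setdiff(names(p$miss_spec[[nm]]), allowed_miss)
    if (length(bad)) {
      stop("scm_params: miss_spec$", nm, " references column(s) that may ",
           "themselves be missing (", paste(bad, collapse = ", "),
           "); MAR-by-construction requires predictors among ",
           paste(allowed_miss, collapse = ", "), call. = FALSE)
    }
  }
  invisible(p)
}

#' Default cohort-simulator parameterisation
#'
#' A stylised parameterisation emulating the structure of a Kenyan HIV-care
#' cervical-screening cohort: n = 2519 women under 50, roughly 35%
#' exposure (combined oral contraceptive ever-use) and 8.7% outcome
#' (CIN2+) prevalence, and a true marginal prevalence difference near
#' +0.029. Coefficients were fixed once by Monte Carlo calibration of the
#' two logistic intercepts and the exposure coefficient against those
#' three margins; the confounder marginals are stylised choices, not
#' estimates of any real population.
#'
#' @param n Cohort size; default 2519.
#' @param seed Master seed; default 1.
#' @param exposure_effect Coefficient of the exposure in the outcome
#'   logit; default 0.35 (the calibrated value). Set to 0 for a null
#'   data-generating process.
#' @param misclass `c(sensitivity, specificity)` of recorded exposure;
#'   default perfect recording.
#' @param missingness If `TRUE` (default) include MAR missingness logits
#'   for CD4+ nadir (~13% missing, more often when the outcome is
#'   present) and education (~6% missing); if `FALSE`, no missingness.
#' @return An `scm_params` object.
#' @export
kisumu_like_params <- function(n = 2519L, seed = 1L, exposure_effect = 0.35,
                               misclass = c(sensitivity = 1, specificity = 1),
                               missingness = TRUE) {
  miss_spec <- if (missingness) {
    list(
      cd4_nadir = c(intercept = -2.0, Y = 0.5, A = 0.3),
      education = c(intercept = -2.8, Y = 0.4)
    )
  } else {
    list()
  }
  scm_params(
    n = n,
    confounder_spec = list(
      age = list(dist = "uniform_int", min = 18, max = 49),
      education = list(dist = "categorical",
                       prob = c(0.15, 0.45, 0.30, 0.10)),
      marital = list(dist = "bernoulli", prob = 0.6),
      gravidity = list(dist = "truncated_poisson", lambda = 3, max = 12),
      cd4_nadir = list(dist = "lognormal", meanlog = log(250), sdlog = 0.8)
    ),
    beta_A = c(intercept = -0.91, age = -0.02, education = 0.25,
               marital = 0.35, gravidity = 0.04, cd4_nadir = 0.0008),
    beta_Y = c(intercept = -2.54, age = 0.015, education = -0.12,
               marital = -0.08, gravidity = 0.04, cd4_nadir = -0.0012,
               A = exposure_effect),
    miss_spec = miss_spec,
    misclass = misclass,
    seed = seed
  )
}

#' @export
print.scm_params <- function(x, ...) {
  cat("Structural causal model parameters\n")
  cat("  n =", x$n, "  seed =", x$seed, "\n")
  cat("  exposure logit:",
      paste(names(x$beta_A), signif(x$beta_A, 4), sep = "=",
            collapse = ", "), "\n")
  cat("  outcome logit: ",
      paste(names(x$beta_Y), signif(x$beta_Y, 4), sep = "=",
            collapse = ", "), "\n")
  if (length(x$miss_spec)) {
    cat("  MAR missingness on:",
        paste(names(x$miss_spec), collapse = ", "), "\n")
  }
  if (x$misclass[["sensitivity"]] < 1 || x$misclass[["specificity"]] < 1) {
    cat("  exposure misclassification: sensitivity",
        x$misclass[["sensitivity"]], "specificity",
        x$misclass[["specificity"]], "\n")
  }
  invisible(x)
}

draw_confounder <- function(spec, n) {
  switch(spec$dist,
    uniform_int = sample(seq.int(spec$min, spec$max), n, replace = TRUE),
    categorical = sample(seq_along(spec$prob) - 1L, n, replace = TRUE,
                         prob = spec$prob),
    bernoulli = stats::rbinom(n, 1L, spec$prob),
    truncated_poisson = pmin(stats::rpois(n, spec$lambda), spec$max),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    discrete = spec$values[sample.int(length(spec$values), n,
                                      replace = TRUE, prob = spec$prob)]
  )
}

# Finite support (values, prob) of a confounder spec, or NULL when the
# distribution is continuous.
confounder_support <- function(spec) {
  switch(spec$dist,
    uniform_int = {
      v <- seq.int(spec$min, spec$max)
      list(values = v, prob = rep(1 / length(v), length(v)))
    },
    categorical = list(values = seq_along(spec$prob) - 1L, prob = spec$prob),
    bernoulli = list(values = c(0L, 1L),
                     prob = c(1 - spec$prob, spec$prob)),
    truncated_poisson = {
      v <- 0:spec$max
      pr <- stats::dpois(v, spec$lambda)
      pr[length(pr)] <- pr[length(pr)] +
        stats::ppois(spec$max, spec$lambda, lower.tail = FALSE)
      list(values = v, prob = pr / sum(pr))
    },
    discrete = list(values = spec$values, prob = spec$prob),
    lognormal = NULL
  )
}

# Linear predictor beta . x(W [, A]) with coefficients matched by name.
linear_predictor <- function(beta, data, a = NULL) {
  lp <- rep(unname(beta["intercept"]) %||% 0, nrow(data))
  if (is.na(lp[1])) lp <- rep(0, nrow(data))
  for (nm in names(beta)) {
    if (nm == "intercept") next
    if (nm == "A") {
      av <- if (is.null(a)) data$A else a
      lp <- lp + beta[[nm]] * av
    } else if (nm == "age_sq") {
      lp <- lp + beta[[nm]] * data$age^2
    } else {
      lp <- lp + beta[[nm]] * data[[nm]]
    }
  }
  lp
}

cohort_columns <- c("age", "education", "marital", "gravidity", "cd4_nadir",
                    "A", "Y", "months_observed", "frac_visits_coc", "true_A")

#' Simulate a cohort from a structural causal model
#'
#' Draws `n` women: confounders from their marginal distributions,
#' exposure `A ~ Bernoulli(expit(beta_A . x(W)))`, outcome
#' `Y ~ Bernoulli(expit(beta_Y . x(W, A)))`, plus observation metadata.
#' No missingness or misclassification is applied at this stage; see
#' [apply_mar_missingness()] and [misclassify_exposure()]. The result is
#' deterministic given `params$seed`.
#'
#' @param params An [scm_params()] object.
#' @return A `cohort_table`: a data frame with columns `age`, `education`,
#'   `marital`, `gravidity`, `cd4_nadir`, `A`, `Y`, `months_observed`,
#'   `frac_visits_coc`, and `true_A` (the latent exposure, equal to `A`
#'   until misclassification is applied).
#' @export
generate_cohort <- function(params) {
  validate_scm_params(params)
  n <- params$n
  with_seed(substream(params$seed, 1L), {
    W <- as.data.frame(lapply(params$confounder_spec, draw_confounder, n = n))
    names(W) <- names(params$confounder_spec)
    W <- W[confounder_names]
    pA <- stats::plogis(linear_predictor(params$beta_A, W))
    A <- stats::rbinom(n, 1L, pA)
    pY <- stats::plogis(linear_predictor(params$beta_Y, W, a = A))
    Y <- stats::rbinom(n, 1L, pY)
    months <- round(stats::rgamma(n, shape = params$visit_spec$months$shape,
                                  scale = params$visit_spec$months$scale))
    frac <- draw_frac_visits(n, A, params$visit_spec$frac)
    out <- cbind(W, data.frame(A = A, Y = Y, months_observed = months,
                               frac_visits_coc = frac, true_A = A))
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

# Fraction of visits at which contraceptive use was reported: Beta for
# recorded users, rescaled into (0, 1]; exactly 0 for recorded non-users.
draw_frac_visits <- function(n, a, frac_spec) {
  frac <- numeric(n)
  k <- sum(a == 1)
  if (k > 0) {
    u <- stats::rbeta(k, frac_spec$shape1, frac_spec$shape2)
    frac[a == 1] <- pmax(u, .Machine$double.eps)
  }
  frac
}

#' True marginal prevalence difference implied by SCM parameters
#'
#' The counterfactual contrast psi = E\[Y(1)\] - E\[Y(0)\]: the change in
#' outcome prevalence if the whole population were exposed versus
#' unexposed. Computed by exact enumeration over the confounder support
#' when all confounders are discrete, otherwise by Monte Carlo averaging
#' of `expit(beta_Y . x(W, 1)) - expit(beta_Y . x(W, 0))` over `n_mc`
#' confounder draws.
#'
#' @param params An [scm_params()] object.
#' @param n_mc Number of Monte Carlo confounder draws (ignored under
#'   enumeration); default 1e6.
#' @param method `"auto"` (enumerate when possible), `"enumerate"`, or
#'   `"mc"`.
#' @param max_enum Largest confounder-support size enumerated under
#'   `"auto"`; beyond it Monte Carlo is used.
#' @return The prevalence difference (a number in \[-1, 1\]).
#' @export
true_prevalence_difference <- function(params, n_mc = 1e6,
                                       method = c("auto", "enumerate", "mc"),
                                       max_enum = 2e6) {
  validate_scm_params(params)
  method <- match.arg(method)
  if (n_mc < 1) stop("`n_mc` must be >= 1", call. = FALSE)
  supports <- lapply(params$confounder_spec, confounder_support)
  enumerable <- !any(vapply(supports, is.null, logical(1)))
  size <- if (enumerable) prod(vapply(supports, function(s)
    length(s$values), numeric(1))) else Inf
  use_enum <- switch(method,
    enumerate = {
      if (!enumerable) {
        stop("enumeration requires all confounders to have finite support",
             call. = FALSE)
      }
      TRUE
    },
    mc = FALSE,
    auto = enumerable && size <= max_enum
  )
  if (use_enum) {
    grid <- expand.grid(lapply(supports, function(s) s$values),
                        KEEP.OUT.ATTRS = FALSE)
    names(grid) <- names(supports)
    wts <- Reduce(`*`, Map(function(s, nm) s$prob[match(grid[[nm]], s$values)],
                           supports, names(supports)))
    grid <- grid[confounder_names]
    lp <- linear_predictor(params$beta_Y, grid, a = 0)
    bA <- params$beta_Y[["A"]] %||% 0
    if (is.na(bA)) bA <- 0
    sum(wts * (stats::plogis(lp + bA) - stats::plogis(lp)))
  } else {
    with_seed(substream(params$seed, 99L), {
      W <- as.data.frame(lapply(params$confounder_spec, draw_confounder,
                                n = n_mc))
      names(W) <- names(params$confounder_spec)
      lp <- linear_predictor(params$beta_Y, W, a = 0)
      bA <- params$beta_Y[["A"]] %||% 0
      if (is.na(bA)) bA <- 0
      mean(stats::plogis(lp + bA) - stats::plogis(lp))
    })
  }
}

#' Apply missing-at-random missingness to confounders
#'
#' Sets confounder cells to `NA` with probability
#' `expit(miss_spec logit)`, where each missingness logit may depend only
#' on always-observed columns (`A`, `Y`, `age`), so the mechanism is MAR
#' by construction. Exposure and outcome are never made missing.
#'
#' @param table A `cohort_table` from [generate_cohort()] or
#'   [read_cohort()].
#' @param params The [scm_params()] whose `miss_spec` defines the
#'   mechanism (and whose `seed` makes the result deterministic).
#' @return The table with selected confounder cells set to `NA`; row
#'   count and all other cells unchanged.
#' @export
apply_mar_missingness <- function(table, params) {
  validate_scm_params(params)
  validate_cohort(table)
  n <- nrow(table)
  with_seed(substream(params$seed, 2L), {
    for (col in names(params$miss_spec)) {
      beta <- params$miss_spec[[col]]
      p <- stats::plogis(linear_predictor(beta, table))
      miss <- stats::runif(n) < p
      table[[col]][miss] <- NA
    }
  })
  table
}

#' Misclassify the recorded exposure
#'
#' Flips the recorded exposure relative to the latent true exposure with
#' rate `1 - sensitivity` among the truly exposed and `1 - specificity`
#' among the truly unexposed, then regenerates `frac_visits_coc`
#' consistently with the new recorded exposure (0 for recorded non-users;
#' a fresh draw for records that become recorded users).
#'
#' False positives (true non-users recorded as users) draw their visit
#' fraction from a low-mean distribution (`fp_frac_spec`, default
#' Beta(1, 9)): a spurious ever-use record typically stems from isolated
#' visit reports, so misclassified users concentrate below conventional
#' reporting-consistency thresholds. This is what gives a stricter
#' exposure classification (see [apply_sensitivity_filter()]) its power
#' to shed misclassified records.
#'
#' @param table A `cohort_table` containing `true_A`.
#' @param sensitivity,specificity Probabilities in (0, 1\].
#' @param seed Integer seed.
#' @param frac_spec Beta parameters for visit fractions of genuinely
#'   exposed recorded users; default `list(shape1 = 2, shape2 = 2)`.
#' @param fp_frac_spec Beta parameters for visit fractions of falsely
#'   recorded users; default `list(shape1 = 1, shape2 = 9)`.
#' @return The table with `A` (and where needed `frac_visits_coc`)
#'   updated; `true_A` unchanged.
#' @export
misclassify_exposure <- function(table, sensitivity, specificity, seed,
                                 frac_spec = list(shape1 = 2, shape2 = 2),
                                 fp_frac_spec = list(shape1 = 1,
                                                     shape2 = 9)) {
  validate_cohort(table)
  if (is.null(table$true_A) || anyNA(table$true_A)) {
    stop("misclassify_exposure requires a complete `true_A` column ",
         "(simulated data only)", call. = FALSE)
  }
  stopifnot(sensitivity > 0, sensitivity <= 1,
            specificity > 0, specificity <= 1)
  with_seed(substream(seed, 3L), {
    n <- nrow(table)
    u <- stats::runif(n)
    rec <- ifelse(table$true_A == 1,
                  as.integer(u < sensitivity),
                  as.integer(u >= specificity))
    became_user <- rec == 1 & table$A == 0
    false_positive <- became_user & table$true_A == 0
    missed_user <- became_user & table$true_A == 1
    became_nonuser <- rec == 0
    table$A <- rec
    table$frac_visits_coc[became_nonuser] <- 0
    draw_beta <- function(idx, spec) {
      k <- sum(idx)
      if (k > 0) {
        table$frac_visits_coc[idx] <<-
          pmax(stats::rbeta(k, spec$shape1, spec$shape2),
               .Machine$double.eps)
      }
    }
    draw_beta(false_positive, fp_frac_spec)
    draw_beta(missed_user, frac_spec)
  })
  table
}

validate_cohort <- function(table) {
  if (!is.data.frame(table)) stop("cohort must be a data frame",
                                  call. = FALSE)
  need <- setdiff(cohort_columns, "true_A")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("cohort table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyNA(table$A) || anyNA(table$Y)) {
    stop("exposure (A) and outcome (Y) must never be missing",
         call. = FALSE)
  }
  if (any(table$frac_visits_coc < 0 | table$frac_visits_coc > 1,
          na.rm = TRUE)) {
    stop("frac_visits_coc must lie in [0, 1]", call. = FALSE)
  }
  if (any(table$months_observed < 0, na.rm = TRUE)) {
    stop("months_observed must be >= 0", call. = FALSE)
  }
  invisible(table)
}

#' Read or write a cohort as delimited text
#'
#' Cohorts are stored as comma-separated text with a header row; an empty
#' field denotes a missing value. Column names are fixed: `age`,
#' `education`, `marital`, `gravidity`, `cd4_nadir`, `A`, `Y`,
#' `months_observed`, `frac_visits_coc`, and optionally `true_A`
#' (simulated data only).
#'
#' @param table A `cohort_table`.
#' @param path File path.
#' @return `read_cohort` returns a validated `cohort_table`;
#'   `write_cohort` returns `path` invisibly.
#' @export
write_cohort <- function(table, path) {
  validate_cohort(table)
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, na.strings = "")
  validate_cohort(tab)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort of", nrow(x), "records:",
      sum(x$A == 1), "exposed,", sum(x$Y == 1), "with the outcome")
  n_miss <- sum(is.na(x))
  if (n_miss > 0) cat(";", n_miss, "missing confounder cells")
  cat("\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more records\n")
  invisible(x)
}

#' Read or write SCM parameters as a structured config file
#'
#' Serialises [scm_params()] to YAML. The shipped default fixture is
#' `system.file("extdata", "kisumu_like.cfg", package = "causalprev")`.
#'
#' @param params An `scm_params` object.
#' @param path File path.
#' @return `read_scm_config` returns an `scm_params`; `write_scm_config`
#'   returns `path` invisibly.
#' @export
write_scm_config <- function(params, path) {
  validate_scm_params(params)
  x <- unclass(params)
  x$beta_A <- as.list(x$beta_A)
  x$beta_Y <- as.list(x$beta_Y)
  x$misclass <- as.list(x$misclass)
  x$miss_spec <- lapply(x$miss_spec, as.list)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_scm_config
#' @export
read_scm_config <- function(path) {
  x <- yaml::read_yaml(path)
  scm_params(
    n = x$n,
    confounder_spec = x$confounder_spec,
    beta_A = unlist(x$beta_A),
    beta_Y = unlist(x$beta_Y),
    visit_spec = x$visit_spec,
    miss_spec = lapply(x$miss_spec %||% list(), unlist),
    misclass = unlist(x$misclass),
    seed = x$seed
  )
}
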