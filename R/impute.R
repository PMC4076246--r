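#' Configuration for chained multiple imputation
#'
#' @param m Number of imputed datasets; default 10.
#' @param n_cycles Chained-equation sweeps per dataset; default 10.
#' @param seed Integer seed.
#' @param predictors Character vector of columns used as predictors in
#'   every conditional imputation model (the target column is removed
#'   automatically). Defaults to exposure, outcome, and all confounders.
#' @return An `imputation_config` object.
#' @export
imputation_config <- function(m = 10L, n_cycles = 10L, seed = 1L,
                              predictors = c("A", "Y", confounder_names)) {
  if (m < 2) stop("imputation requires m >= 2 datasets", call. = FALSE)
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  structure(list(m = as.integer(m), n_cycles = as.integer(n_cycles),
                 seed = seed, predictors = predictors),
            class = "imputation_config")
}

# Conditional imputation model for one target column, fit on rows where
# the target was observed, given the current completed data. Families:
# binary -> logistic; unordered/ordinal categorical -> multinomial
# logistic; counts -> Poisson (draws truncated to the observed range);
# positive continuous -> linear-normal on the log scale.
impute_column_draw <- function(data, target, predictors, obs_rows) {
  rhs <- paste(setdiff(predictors, target), collapse = " + ")
  miss_rows <- which(!obs_rows)
  newdata <- data[miss_rows, , drop = FALSE]
  obs_vals <- data[[target]][obs_rows]
  if (target == "marital") {
    fit <- stats::glm(stats::reformulate(setdiff(predictors, target),
                                         response = target),
                      data = data[obs_rows, ], family = stats::binomial())
    p <- stats::predict(fit, newdata = newdata, type = "response")
    stats::rbinom(length(p), 1L, p)
  } else if (target == "education") {
    if (length(unique(obs_vals)) < 2) {
      rep(obs_vals[1], length(miss_rows))
    } else {
      yfac <- factor(data[[target]][obs_rows])
      cap <- utils::capture.output(
        fit <- nnet::multinom(
          stats::as.formula(paste("yfac ~", rhs)),
          data = data[obs_rows, ], trace = FALSE)
      )
      p <- stats::predict(fit, newdata = newdata, type = "probs")
      if (is.null(dim(p))) p <- cbind(1 - p, p)  # two observed levels
      lev <- as.numeric(levels(yfac))
      vapply(seq_len(nrow(p)), function(i) {
        sample(lev, 1L, prob = p[i, ])
      }, numeric(1))
    }
  } else if (target == "gravidity") {
    fit <- stats::glm(stats::reformulate(setdiff(predictors, target),
                                         response = target),
                      data = data[obs_rows, ], family = stats::poisson())
    mu <- stats::predict(fit, newdata = newdata, type = "response")
    pmin(stats::rpois(length(mu), mu), max(obs_vals))
  } else if (target == "cd4_nadir") {
    df <- data[obs_rows, , drop = FALSE]
    df$.log_target <- log(df[[target]])
    fit <- stats::lm(stats::as.formula(paste(".log_target ~", rhs)),
                     data = df)
    mu <- stats::predict(fit, newdata = newdata)
    sigma <- sqrt(sum(stats::residuals(fit)^2) /
                    max(stats::df.residual(fit), 1))
    exp(mu + stats::rnorm(length(mu), 0, sigma))
  } else {  # age or other continuous: linear-normal
    fit <- stats::lm(stats::reformulate(setdiff(predictors, target),
                                        response = target),
                     data = data[obs_rows, ])
    mu <- stats::predict(fit, newdata = newdata)
    sigma <- sqrt(sum(stats::residuals(fit)^2) /
                    max(stats::df.residual(fit), 1))
    mu + stats::rnorm(length(mu), 0, sigma)
  }
}

#' Chained multiple imputation of missing confounders
#'
#' Fills missing confounder cells by iterated conditional draws (multiple
#' imputation by chained equations): each dataset starts from random hot
#' -deck initial values, then for `n_cycles` sweeps every incomplete
#' column is re-imputed from a conditional model refit on the current
#' completed data. Coefficients are refit rather than drawn from their
#' posterior, a deliberate simplification of fully proper imputation;
#' residual noise is drawn for continuous targets and category draws for
#' discrete ones, so the `m` datasets differ. Observed cells are never
#' altered.
#'
#' @param table A `cohort_table`; missingness only in confounder columns.
#' @param cfg An [imputation_config()].
#' @return A list of `m` complete `cohort_table`s.
#' @export
chained_impute <- function(table, cfg = imputation_config()) {
  validate_cohort(table)
  stopifnot(inherits(cfg, "imputation_config"))
  non_confounders <- setdiff(names(table), confounder_names)
  if (any(vapply(non_confounders, function(cl) anyNA(table[[cl]]),
                 logical(1)))) {
    stop("missingness is only supported in confounder columns",
         call. = FALSE)
  }
  incomplete <- confounder_names[vapply(confounder_names,
                                        function(cl) anyNA(table[[cl]]),
                                        logical(1))]
  if (!length(incomplete)) {
    return(replicate(cfg$m, table, simplify = FALSE))
  }
  for (cl in incomplete) {
    if (all(is.na(table[[cl]]))) {
      stop("column `", cl, "` has no observed values; unimputable",
           call. = FALSE)
    }
  }
  obs <- lapply(table[incomplete], function(x) !is.na(x))
  lapply(seq_len(cfg$m), function(k) {
    with_seed(substream(cfg$seed, 100L + k), {
      filled <- table
      # hot-deck initialisation from the observed marginal
      for (cl in incomplete) {
        nmiss <- sum(!obs[[cl]])
        filled[[cl]][!obs[[cl]]] <-
          sample(table[[cl]][obs[[cl]]], nmiss, replace = TRUE)
      }
      for (cycle in seq_len(cfg$n_cycles)) {
        for (cl in incomplete) {
          draws <- impute_column_draw(filled, cl, cfg$predictors, obs[[cl]])
          if (is.integer(table[[cl]])) draws <- as.integer(round(draws))
          filled[[cl]][!obs[[cl]]] <- draws
        }
      }
      filled
    })
  })
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' Combines per-dataset point estimates and variances: the pooled
#' estimate is the mean of the estimates; total variance is the mean
#' within-dataset variance plus `(1 + 1/m)` times the between-dataset
#' sample variance; the confidence interval uses a t quantile with
#' Rubin's degrees of freedom
#' `(m - 1) * (1 + within / ((1 + 1/m) * between))^2` (normal quantile
#' when the between-variance is zero).
#'
#' @param estimates Numeric vector of per-dataset estimates (length m >= 2).
#' @param variances Numeric vector of per-dataset variances (same length,
#'   all non-negative).
#' @param conf_level Confidence level; default 0.95.
#' @return A `pooled_result` with elements `estimate`, `within_var`,
#'   `between_var`, `total_var`, `df`, `ci_low`, `ci_high`, `m`.
#' @export
rubins_rule <- function(estimates, variances, conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2) stop("Rubin's rules require m >= 2 estimates", call. = FALSE)
  if (length(variances) != m) {
    stop("`estimates` and `variances` must have equal length", call. = FALSE)
  }
  if (any(variances < 0)) stop("variances must be >= 0", call. = FALSE)
  est <- mean(estimates)
  within <- mean(variances)
  between <- stats::var(estimates)
  total <- within + (1 + 1 / m) * between
  alpha <- 1 - conf_level
  if (between == 0) {
    df <- Inf
    q <- stats::qnorm(1 - alpha / 2)
  } else {
    df <- (m - 1) * (1 + within / ((1 + 1 / m) * between))^2
    q <- stats::qt(1 - alpha / 2, df)
  }
  structure(list(estimate = est, within_var = within, between_var = between,
                 total_var = total, df = df,
                 ci_low = est - q * sqrt(total),
                 ci_high = est + q * sqrt(total), m = m,
                 conf_level = conf_level),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Pooled estimate over %d imputations: %.*f (%.0f%% CI %.*f, %.*f)\n",
    x$m, digits, x$estimate, 100 * x$conf_level, digits, x$ci_low,
    digits, x$ci_high))
  cat(sprintf("  within-var %.3g, between-var %.3g, total %.3g, df %.3g\n",
              x$within_var, x$between_var, x$total_var, x$df))
  invisible(x)
}
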