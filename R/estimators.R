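#' Estimate container for the marginal prevalence difference
#'
#' @param psi Point estimate of psi = E\[Y(1)\] - E\[Y(0)\] on the
#'   probability scale.
#' @param variance Variance of the estimate (`NA` when left to the
#'   bootstrap).
#' @param ci_low,ci_high Confidence bounds (`NA` when not yet available).
#' @param method One of `"gcomp"`, `"iptw"`, `"tmle"`.
#' @param diagnostics Named list of method-specific diagnostics.
#' @return An `estimate_result`.
#' @export
estimate_result <- function(psi, variance = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, method, diagnostics = list()) {
  if (!is.na(psi) && (psi < -1 || psi > 1)) {
    stop("psi must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(psi = psi, variance = variance, ci_low = ci_low,
                 ci_high = ci_high, method = method,
                 diagnostics = diagnostics),
            class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, digits = 3, ...) {
  cat(sprintf("%s estimate of the prevalence difference: %.*f",
              toupper(x$method), digits, x$psi))
  if (!is.na(x$ci_low)) {
    cat(sprintf(" (95%% CI %.*f, %.*f)", digits, x$ci_low, digits,
                x$ci_high))
  }
  cat("\n")
  invisible(x)
}

degenerate_outcome <- function(table) {
  if (length(unique(table$Y)) < 2) {
    warning("degenerate outcome (all Y identical); returning psi = 0",
            call. = FALSE)
    TRUE
  } else {
    FALSE
  }
}

#' G-computation (standardization) estimate
#'
#' Substitution estimator: with a fitted outcome regression, predict every
#' woman's outcome probability with exposure set to 1 and again set to 0,
#' and average the difference over the sample. The variance is left unset
#' here and filled in by the bootstrap ([bootstrap_estimate()]).
#'
#' @param table A complete `cohort_table`.
#' @param fit An `outcome_fit` (see [fit_outcome()] or
#'   [discrete_super_learner()]).
#' @return An `estimate_result` with `method = "gcomp"`.
#' @export
g_compute <- function(table, fit) {
  stopifnot(inherits(fit, "outcome_fit"))
  if (degenerate_outcome(table)) {
    return(estimate_result(0, method = "gcomp",
                           diagnostics = list(degenerate = TRUE)))
  }
  q1 <- fit$predict_fn(table, a = 1)
  q0 <- fit$predict_fn(table, a = 0)
  estimate_result(mean(q1) - mean(q0), method = "gcomp",
                  diagnostics = list(learner_id = fit$learner_id))
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' `w_i = P(A = 1) / g(W_i)` for exposed records and
#' `w_i = P(A = 0) / (1 - g(W_i))` for unexposed, with `P` the empirical
#' exposure prevalence and `g` the truncated propensity. Under a correct
#' propensity model the weights average approximately 1.
#'
#' @param table A complete `cohort_table`.
#' @param fit A `propensity_fit`.
#' @return Numeric weight vector (all positive).
#' @export
stabilized_weights <- function(table, fit) {
  stopifnot(inherits(fit, "propensity_fit"))
  g <- fit$g(table)
  if (any(g <= 0 | g >= 1)) {
    stop("propensity reached 0 or 1; tighten `truncation_bounds` on the ",
         "propensity fit (positivity violation)", call. = FALSE)
  }
  p1 <- mean(table$A)
  ifelse(table$A == 1, p1 / g, (1 - p1) / (1 - g))
}

#' IPTW estimate of the prevalence difference
#'
#' Difference in outcome prevalence between the weighted exposed and
#' weighted unexposed populations. The default is the normalized (Hajek)
#' form, each arm's weighted mean outcome; the unnormalized
#' Horvitz-Thompson form (weighted sums divided by n) is available for
#' testing. Variance is left to the bootstrap.
#'
#' @param table A complete `cohort_table`.
#' @param weights Weight vector from [stabilized_weights()].
#' @param normalized Use the Hajek form (default `TRUE`).
#' @return An `estimate_result` with `method = "iptw"`.
#' @export
iptw_estimate <- function(table, weights, normalized = TRUE) {
  stopifnot(length(weights) == nrow(table), all(weights > 0))
  if (degenerate_outcome(table)) {
    return(estimate_result(0, method = "iptw",
                           diagnostics = list(degenerate = TRUE)))
  }
  a <- table$A
  y <- table$Y
  if (sum(weights[a == 1]) == 0 || sum(weights[a == 0]) == 0) {
    stop("an exposure arm has zero total weight; cannot estimate",
         call. = FALSE)
  }
  psi <- if (normalized) {
    sum(weights * a * y) / sum(weights * a) -
      sum(weights * (1 - a) * y) / sum(weights * (1 - a))
  } else {
    (sum(weights * a * y) - sum(weights * (1 - a) * y)) / length(a)
  }
  estimate_result(psi, method = "iptw",
                  diagnostics = list(mean_weight = mean(weights),
                                     normalized = normalized))
}

#' Targeted maximum likelihood estimate of the prevalence difference
#'
#' Updates an initial outcome regression `Q0` along a one-dimensional
#' logistic fluctuation indexed by the propensity: the clever covariate is
#' `H_i = A_i / g(W_i) - (1 - A_i) / (1 - g(W_i))`, and the fluctuation
#' coefficient epsilon is fit by maximum likelihood in the intercept-free
#' logistic model `logit Q*(A, W) = logit Q0(A, W) + epsilon * H`. The
#' estimate is the standardized difference of the targeted predictions,
#' its variance the sample variance of the efficient influence curve over
#' n, and the confidence interval a Wald interval. The estimator is doubly
#' robust: consistent if either `Q0` or `g` is correctly specified.
#'
#' @param table A complete `cohort_table`.
#' @param q0 Initial `outcome_fit`.
#' @param gfit A `propensity_fit` (truncated).
#' @param conf_level Confidence level; default 0.95.
#' @return An `estimate_result` with `method = "tmle"`; the diagnostics
#'   carry `epsilon`, the mean clever-covariate score after targeting, and
#'   the influence-curve values.
#' @export
tmle_estimate <- function(table, q0, gfit, conf_level = 0.95) {
  stopifnot(inherits(q0, "outcome_fit"), inherits(gfit, "propensity_fit"))
  if (degenerate_outcome(table)) {
    return(estimate_result(0, method = "tmle",
                           diagnostics = list(degenerate = TRUE)))
  }
  n <- nrow(table)
  a <- table$A
  y <- table$Y
  g <- gfit$g(table)
  q_aw <- q0$predict_fn(table)
  q1 <- q0$predict_fn(table, a = 1)
  q0w <- q0$predict_fn(table, a = 0)
  h <- a / g - (1 - a) / (1 - g)
  off <- stats::qlogis(q_aw)
  flu <- tryCatch(
    withCallingHandlers(
      stats::glm(y ~ -1 + h + offset(off), family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-14, maxit = 200)),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) e)
  if (inherits(flu, "error") || !flu$converged) {
    eps_trace <- if (inherits(flu, "error")) NA_real_ else
      unname(stats::coef(flu))
    stop("TMLE fluctuation failed to converge (epsilon trace: ",
         paste(signif(eps_trace, 4), collapse = ", "), ")", call. = FALSE)
  }
  eps <- unname(stats::coef(flu))
  qs_aw <- stats::plogis(stats::qlogis(q_aw) + eps * h)
  qs1 <- stats::plogis(stats::qlogis(q1) + eps / g)
  qs0 <- stats::plogis(stats::qlogis(q0w) - eps / (1 - g))
  psi <- mean(qs1 - qs0)
  ic <- h * (y - qs_aw) + qs1 - qs0 - psi
  variance <- stats::var(ic) / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  estimate_result(psi, variance = variance,
                  ci_low = psi - z * sqrt(variance),
                  ci_high = psi + z * sqrt(variance),
                  method = "tmle",
                  diagnostics = list(
                    epsilon = eps,
                    score = mean(h * (y - qs_aw)),
                    influence_curve = ic,
                    q_learner = q0$learner_id,
                    g_learner = gfit$learner_id))
}
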