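#' Candidate learner library for discrete model selection
#'
#' Four transparent parametric logistic learners, ordered from least to
#' most flexible: intercept-only; main effects; main effects plus all
#' pairwise interactions; main effects plus a quadratic age term. The
#' exposure regression uses the same forms without `A` (and never `Y`).
#' The discrete selector ([discrete_super_learner()]) picks the single
#' learner with the lowest V-fold cross-validated negative Bernoulli
#' log-likelihood.
#'
#' @param learners Character vector naming the candidates to include, in
#'   tie-break order.
#' @param v_folds Number of cross-validation folds (>= 2); default 10.
#' @return A `learner_library` object.
#' @export
learner_library <- function(learners = c("intercept", "main_effects",
                                         "interactions", "quadratic_age"),
                            v_folds = 10L) {
  known <- c("intercept", "main_effects", "interactions", "quadratic_age")
  bad <- setdiff(learners, known)
  if (length(bad)) {
    stop("unknown learner(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(learners) < 1) stop("need at least one learner", call. = FALSE)
  if (v_folds < 2) stop("v_folds must be >= 2", call. = FALSE)
  structure(list(learners = learners, v_folds = as.integer(v_folds)),
            class = "learner_library")
}

learner_formula <- function(learner_id, target) {
  response <- if (target == "outcome") "Y" else "A"
  preds <- confounder_names
  if (target == "outcome") preds <- c("A", preds)
  switch(learner_id,
    intercept = stats::reformulate("1", response = response),
    main_effects = stats::reformulate(preds, response = response),
    interactions = stats::as.formula(paste(
      response, "~ (", paste(preds, collapse = " + "), ")^2")),
    quadratic_age = stats::reformulate(c(preds, "I(age^2)"),
                                       response = response),
    stop("unknown learner `", learner_id, "`", call. = FALSE)
  )
}

# Mean negative Bernoulli log-likelihood of predictions p for outcomes y.
nll_loss <- function(y, p) {
  p <- bound_prob(p, 1e-12, 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

fit_glm_quiet <- function(formula, data) {
  withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

#' Select a learner by V-fold cross-validation
#'
#' Computes the V-fold cross-validated negative log-likelihood of each
#' learner in the library on a seed-fixed fold split, refits the winner
#' (ties broken by library order) on the full data, and returns the
#' corresponding fit object. A learner whose fit fails is assigned
#' infinite loss; if every learner fails, an error is raised.
#'
#' @param table A complete (post-imputation) `cohort_table`.
#' @param target `"outcome"` (regression of `Y` on `A` and confounders)
#'   or `"exposure"` (regression of `A` on confounders).
#' @param lib A [learner_library()].
#' @param seed Integer seed fixing the fold split.
#' @param g_bounds Truncation bounds applied to propensity predictions
#'   when `target = "exposure"`.
#' @return An `outcome_fit` or `propensity_fit` (see [fit_outcome()] and
#'   [fit_propensity()]) with `learner_id` and the per-learner CV losses
#'   attached.
#' @export
discrete_super_learner <- function(table, target = c("outcome", "exposure"),
                                   lib = learner_library(), seed = 1L,
                                   g_bounds = c(0.01, 0.99)) {
  target <- match.arg(target)
  stopifnot(inherits(lib, "learner_library"))
  n <- nrow(table)
  y <- if (target == "outcome") table$Y else table$A
  folds <- with_seed(substream(seed, 7L),
                     sample(rep_len(seq_len(lib$v_folds), n)))
  losses <- vapply(lib$learners, function(id) {
    f <- learner_formula(id, target)
    fold_loss <- try(vapply(seq_len(lib$v_folds), function(v) {
      train <- table[folds != v, , drop = FALSE]
      test <- table[folds == v, , drop = FALSE]
      fit <- fit_glm_quiet(f, train)
      nll_loss(y[folds == v],
               stats::predict(fit, newdata = test, type = "response"))
    }, numeric(1)), silent = TRUE)
    if (inherits(fold_loss, "try-error") || anyNA(fold_loss)) {
      Inf
    } else {
      mean(fold_loss)
    }
  }, numeric(1))
  if (all(!is.finite(losses))) {
    stop("all candidate learners failed to fit", call. = FALSE)
  }
  winner <- lib$learners[which.min(losses)]
  fit <- if (target == "outcome") {
    fit_outcome(table, learner_formula(winner, "outcome"),
                learner_id = winner)
  } else {
    fit_propensity(table, learner_formula(winner, "exposure"),
                   g_bounds = g_bounds, learner_id = winner)
  }
  fit$cv_losses <- losses
  fit
}

#' Fit the outcome regression
#'
#' Fits a logistic regression of the outcome and wraps it as an
#' `outcome_fit`: a predictor of `P(Y = 1 | A = a, W)` evaluable at both
#' exposure levels for every record. Predictions are bounded inside
#' (0, 1) so logits stay finite.
#'
#' @param table A complete `cohort_table`.
#' @param formula Model formula with response `Y` (e.g.
#'   `Y ~ A + age + education + marital + gravidity + cd4_nadir`).
#' @param learner_id Label stored on the fit.
#' @return An `outcome_fit` with elements `model`, `learner_id`, and
#'   `predict_fn(newdata, a)`.
#' @export
fit_outcome <- function(table, formula, learner_id = "custom") {
  model <- fit_glm_quiet(formula, table)
  structure(list(model = model, learner_id = learner_id,
                 predict_fn = function(newdata, a = NULL) {
                   if (!is.null(a)) newdata$A <- a
                   bound_prob(stats::predict(model, newdata = newdata,
                                             type = "response"))
                 }),
            class = "outcome_fit")
}

#' Fit the exposure (propensity) regression
#'
#' Fits a logistic regression of the exposure on confounders and wraps it
#' as a `propensity_fit`. Predicted probabilities are truncated into
#' `g_bounds` (default \[0.01, 0.99\]) as a practical-positivity guard;
#' the untruncated predictions remain available for diagnostics.
#'
#' @param table A complete `cohort_table`.
#' @param formula Model formula with response `A` (no outcome on the
#'   right-hand side).
#' @param g_bounds Length-2 truncation bounds inside (0, 1).
#' @param learner_id Label stored on the fit.
#' @return A `propensity_fit` with elements `model`, `learner_id`,
#'   `truncation_bounds`, `g(newdata)` (truncated) and `g_raw(newdata)`.
#' @export
fit_propensity <- function(table, formula, g_bounds = c(0.01, 0.99),
                           learner_id = "custom") {
  if (length(g_bounds) != 2 || g_bounds[1] < 0 || g_bounds[2] > 1 ||
      g_bounds[1] >= g_bounds[2]) {
    stop("`g_bounds` must be an increasing pair within [0, 1]",
         call. = FALSE)
  }
  if ("Y" %in% all.vars(formula[[3]])) {
    stop("the propensity model must not condition on the outcome",
         call. = FALSE)
  }
  model <- fit_glm_quiet(formula, table)
  g_raw <- function(newdata) {
    stats::predict(model, newdata = newdata, type = "response")
  }
  structure(list(model = model, learner_id = learner_id,
                 truncation_bounds = g_bounds,
                 g_raw = g_raw,
                 g = function(newdata) {
                   pmin(pmax(g_raw(newdata), g_bounds[1]), g_bounds[2])
                 }),
            class = "propensity_fit")
}
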