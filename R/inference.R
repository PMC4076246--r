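#' Nonparametric bootstrap of a prevalence-difference estimator
#'
#' Resamples records with replacement `B` times and reruns the full
#' estimator — including any model refitting inside `estimator` — on each
#' resample. Replicates in which the estimator fails (e.g. an empty
#' exposure arm in a resample) are dropped and counted; more than 20%
#' failures is an error. The quantile interval uses the empirical 2.5th
#' and 97.5th percentiles.
#'
#' @param table A complete `cohort_table`.
#' @param estimator A function `table -> numeric psi` or
#'   `table -> estimate_result`.
#' @param B Number of bootstrap replicates (>= 2); default 200.
#' @param seed Integer seed; the replicate vector is deterministic given
#'   it.
#' @param conf_level Quantile-interval level; default 0.95.
#' @return A `bootstrap_result` with `replicates`, `boot_mean`, `boot_se`,
#'   `quantile_ci`, `n_failed`, `B`, and `seed`.
#' @export
bootstrap_estimate <- function(table, estimator, B = 200L, seed = 1L,
                               conf_level = 0.95) {
  if (B < 2) stop("bootstrap requires B >= 2", call. = FALSE)
  n <- nrow(table)
  reps <- with_seed(substream(seed, 11L), {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      out <- tryCatch({
        r <- estimator(table[idx, , drop = FALSE])
        if (inherits(r, "estimate_result")) r$psi else as.numeric(r)
      }, error = function(e) NA_real_)
      out
    }, numeric(1))
  })
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.2 * B) {
    stop("more than 20% of bootstrap replicates failed (", n_failed,
         " of ", B, ")", call. = FALSE)
  }
  reps <- reps[!is.na(reps)]
  alpha <- 1 - conf_level
  structure(list(replicates = reps,
                 boot_mean = mean(reps),
                 boot_se = stats::sd(reps),
                 quantile_ci = unname(stats::quantile(
                   reps, c(alpha / 2, 1 - alpha / 2))),
                 n_failed = n_failed, B = B, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Bootstrap (%d replicates, %d failed): mean %.*f, 95%% quantile CI (%.*f, %.*f)\n",
    x$B, x$n_failed, digits, x$boot_mean, digits, x$quantile_ci[1],
    digits, x$quantile_ci[2]))
  invisible(x)
}

# Clinically conventional discretisation used for positivity scans:
# age in decades, CD4+ nadir in {<200, 200-500, >500} cells/uL,
# gravidity in {0, 1-2, 3+}.
bin_strata <- function(table, strata_cols) {
  out <- list()
  for (col in strata_cols) {
    x <- table[[col]]
    out[[col]] <- switch(col,
      age = cut(x, breaks = c(-Inf, 19, 29, 39, 49, Inf),
                labels = c("<20", "20-29", "30-39", "40-49", "50+")),
      cd4_nadir = cut(x, breaks = c(-Inf, 200, 500, Inf),
                      labels = c("<200", "200-500", ">500")),
      gravidity = cut(x, breaks = c(-Inf, 0, 2, Inf),
                      labels = c("0", "1-2", "3+")),
      factor(x))
  }
  as.data.frame(out, optional = TRUE)
}

#' Positivity and bootstrap-symmetry diagnostics
#'
#' Scans the observed covariate combinations (continuous columns binned
#' to clinical categories) for strata with zero exposed or zero unexposed
#' records — practical positivity violations — and reports how many
#' untruncated propensity predictions fell outside the truncation bounds,
#' together with the symmetry of the bootstrap replicate distribution
#' around the point estimate (difference of the bootstrap mean from the
#' estimate, and the replicate skewness).
#'
#' @param table A complete `cohort_table`.
#' @param gfit Optional `propensity_fit`; when supplied, pre-truncation
#'   extremes are counted.
#' @param boot Optional `bootstrap_result` for the symmetry statistics.
#' @param point Optional `estimate_result` matching `boot`.
#' @param strata_cols Columns defining the covariate combinations;
#'   default all five confounders.
#' @return A `positivity_report` with `flagged_strata` (data frame of
#'   combinations with an empty exposure arm, with counts), `n_strata`,
#'   `g_extremes`, and `symmetry`.
#' @export
positivity_report <- function(table, gfit = NULL, boot = NULL, point = NULL,
                              strata_cols = confounder_names) {
  binned <- bin_strata(table, strata_cols)
  key <- interaction(binned, drop = TRUE, sep = " | ")
  n_exposed <- tapply(table$A, key, sum)
  n_total <- tapply(table$A, key, length)
  n_unexposed <- n_total - n_exposed
  flagged_idx <- which(n_exposed == 0 | n_unexposed == 0)
  flagged <- data.frame(
    stratum = names(flagged_idx),
    n = as.vector(n_total[flagged_idx]),
    n_exposed = as.vector(n_exposed[flagged_idx]),
    n_unexposed = as.vector(n_unexposed[flagged_idx]),
    row.names = NULL, check.names = FALSE)
  g_extremes <- if (!is.null(gfit)) {
    g_raw <- gfit$g_raw(table)
    sum(g_raw < gfit$truncation_bounds[1] |
          g_raw > gfit$truncation_bounds[2])
  } else {
    NA_integer_
  }
  symmetry <- if (!is.null(boot) && !is.null(point)) {
    c(mean_minus_estimate = boot$boot_mean - point$psi,
      skewness = skewness(boot$replicates))
  } else {
    c(mean_minus_estimate = NA_real_, skewness = NA_real_)
  }
  structure(list(flagged_strata = flagged,
                 n_strata = length(n_total),
                 strata_cols = strata_cols,
                 g_extremes = g_extremes,
                 symmetry = symmetry),
            class = "positivity_report")
}

#' @export
print.positivity_report <- function(x, ...) {
  cat("Positivity diagnostics over", x$n_strata,
      "observed covariate combinations (",
      paste(x$strata_cols, collapse = ", "), ")\n")
  if (nrow(x$flagged_strata) == 0) {
    cat("  no stratum with an empty exposure arm\n")
  } else {
    cat(" ", nrow(x$flagged_strata),
        "strata with zero exposed or zero unexposed records:\n")
    print(x$flagged_strata, row.names = FALSE)
  }
  if (!is.na(x$g_extremes)) {
    cat("  propensity predictions outside truncation bounds:",
        x$g_extremes, "\n")
  }
  if (!is.na(x$symmetry[1])) {
    cat(sprintf(
      "  bootstrap symmetry: mean - estimate = %.4g, skewness = %.3g\n",
      x$symmetry[1], x$symmetry[2]))
  }
  invisible(x)
}

#' Pool per-imputation estimates
#'
#' Composition wrapper around [rubins_rule()]: accepts a list of
#' `estimate_result`s (or of `c(psi, var)` pairs) — one per imputed
#' dataset — and pools them. For bootstrap-variance estimators the
#' per-imputation variance is the bootstrap replicate variance.
#'
#' @param per_imputation_results List of `estimate_result` objects or
#'   length-2 numeric vectors `(psi, variance)`.
#' @param conf_level Confidence level; default 0.95.
#' @return A `pooled_result`.
#' @export
pool_pipeline <- function(per_imputation_results, conf_level = 0.95) {
  ests <- vapply(per_imputation_results, function(r) {
    if (inherits(r, "estimate_result")) r$psi else r[[1]]
  }, numeric(1))
  vars <- vapply(per_imputation_results, function(r) {
    if (inherits(r, "estimate_result")) r$variance else r[[2]]
  }, numeric(1))
  rubins_rule(ests, vars, conf_level = conf_level)
}
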