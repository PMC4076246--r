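#' Analysis configuration
#'
#' Bundles everything needed to run the full pipeline: input (a cohort
#' file or simulator parameters), imputation settings, learner settings,
#' estimators, bootstrap size, seeds, the sensitivity-restriction rule,
#' and the output directory.
#'
#' @param input Path to a cohort CSV, or `NULL` to simulate.
#' @param scm An [scm_params()] object or path to an SCM config file;
#'   used when `input` is `NULL`. Defaults to [kisumu_like_params()] with
#'   the config seed.
#' @param estimators Character subset of `c("gcomp", "iptw", "tmle")`, or
#'   `"all"`.
#' @param m Number of imputed datasets (used when the cohort has missing
#'   cells); default 10.
#' @param n_cycles Chained-equation sweeps; default 10.
#' @param B Bootstrap replicates per imputed dataset; default 200.
#' @param seed Master seed for every stochastic stage.
#' @param learners `"cv"` for discrete cross-validated selection, or one
#'   fixed learner id (e.g. `"main_effects"`).
#' @param v_folds Cross-validation folds when `learners = "cv"`.
#' @param g_bounds Propensity truncation bounds.
#' @param min_months,min_frac Sensitivity-restriction rule: keep records
#'   observed at least `min_months` months and with either no reported
#'   use or use reported at more than `min_frac` of visits. Defaults 6
#'   months and 0.2.
#' @param max_age Eligibility cap applied at load; default 50 (women
#'   under 50).
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param conf_level Confidence level; default 0.95.
#' @return An `analysis_config`.
#' @export
analysis_config <- function(input = NULL, scm = NULL,
                            estimators = c("gcomp", "iptw", "tmle"),
                            m = 10L, n_cycles = 10L, B = 200L, seed = 1L,
                            learners = "cv", v_folds = 10L,
                            g_bounds = c(0.01, 0.99),
                            min_months = 6, min_frac = 0.2,
                            max_age = 50, out_dir = NULL,
                            conf_level = 0.95) {
  if (identical(estimators, "all")) estimators <- c("gcomp", "iptw", "tmle")
  bad <- setdiff(estimators, c("gcomp", "iptw", "tmle"))
  if (length(bad) || !length(estimators)) {
    stop("`estimators` must be a non-empty subset of gcomp, iptw, tmle",
         call. = FALSE)
  }
  if (min_months < 0) stop("min_months must be >= 0", call. = FALSE)
  if (min_frac < 0 || min_frac > 1) {
    stop("min_frac must be in [0, 1]", call. = FALSE)
  }
  structure(list(input = input, scm = scm, estimators = estimators,
                 m = as.integer(m), n_cycles = as.integer(n_cycles),
                 B = as.integer(B), seed = seed, learners = learners,
                 v_folds = as.integer(v_folds), g_bounds = g_bounds,
                 min_months = min_months, min_frac = min_frac,
                 max_age = max_age, out_dir = out_dir,
                 conf_level = conf_level),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()]; `scm` may be a path
#' to an SCM config file (resolved relative to the config file's
#' directory).
#'
#' @param path Path to the YAML config.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  x <- yaml::read_yaml(path)
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(dirname(path), p)
  }
  analysis_config(
    input = resolve(x$input),
    scm = if (is.character(x$scm)) resolve(x$scm) else x$scm,
    estimators = x$estimators %||% c("gcomp", "iptw", "tmle"),
    m = x$m %||% 10L, n_cycles = x$n_cycles %||% 10L,
    B = x$B %||% 200L, seed = x$seed %||% 1L,
    learners = x$learners %||% "cv", v_folds = x$v_folds %||% 10L,
    g_bounds = unlist(x$g_bounds %||% c(0.01, 0.99)),
    min_months = x$min_months %||% 6, min_frac = x$min_frac %||% 0.2,
    max_age = x$max_age %||% 50, out_dir = x$out_dir,
    conf_level = x$conf_level %||% 0.95
  )
}

#' Crude descriptive summary of a cohort
#'
#' Exact counts and prevalences of the outcome overall and by exposure
#' group, the descriptive layer reported alongside the adjusted
#' estimates.
#'
#' @param table A `cohort_table` with complete `A` and `Y`.
#' @return A `crude_summary` with counts (`n_total`, `n_cases`,
#'   `n_exposed`, `cases_exposed`, `cases_unexposed`) and exact-ratio
#'   prevalences on the 0-1 scale (`NA` when a denominator is zero).
#' @export
crude_summary <- function(table) {
  n_total <- nrow(table)
  n_cases <- sum(table$Y == 1)
  n_exposed <- sum(table$A == 1)
  cases_exposed <- sum(table$Y == 1 & table$A == 1)
  cases_unexposed <- n_cases - cases_exposed
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    n_total = n_total, n_cases = n_cases, n_exposed = n_exposed,
    cases_exposed = cases_exposed, cases_unexposed = cases_unexposed,
    prevalence_exposed = ratio(cases_exposed, n_exposed),
    prevalence_unexposed = ratio(cases_unexposed, n_total - n_exposed),
    prevalence_overall = ratio(n_cases, n_total)),
    class = "crude_summary")
}

#' @export
print.crude_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d records, %d cases, %d exposed\n",
              x$n_total, x$n_cases, x$n_exposed))
  fmt <- function(p) if (is.na(p)) "NA" else sprintf("%.4f", p)
  cat(sprintf("  prevalence: exposed %s, unexposed %s, overall %s\n",
              fmt(x$prevalence_exposed), fmt(x$prevalence_unexposed),
              fmt(x$prevalence_overall)))
  invisible(x)
}

#' Sensitivity restriction on observation quality
#'
#' Restricts to records with at least `min_months` of observed data and a
#' stricter exposure classification: records reporting use at a fraction
#' of visits in `(0, min_frac]` are excluded, so retained exposed records
#' are exactly those with `frac_visits_coc > min_frac` and retained
#' never-reporters are kept unconditionally (subject to the months rule).
#'
#' @param table A `cohort_table` with `months_observed` and
#'   `frac_visits_coc`.
#' @param min_months Minimum months observed; default 6.
#' @param min_frac Visit-fraction threshold; default 0.2.
#' @return The filtered `cohort_table`.
#' @export
apply_sensitivity_filter <- function(table, min_months = 6, min_frac = 0.2) {
  if (is.null(table$months_observed) || is.null(table$frac_visits_coc)) {
    stop("sensitivity filter requires `months_observed` and ",
         "`frac_visits_coc` columns", call. = FALSE)
  }
  keep <- table$months_observed >= min_months &
    (table$frac_visits_coc == 0 | table$frac_visits_coc > min_frac)
  table[keep, , drop = FALSE]
}

# One estimator as a self-contained function table -> psi, refitting the
# given model formulas; used as the unit the bootstrap reruns.
make_estimator <- function(method, q_formula, g_formula, g_bounds) {
  force(q_formula); force(g_formula); force(g_bounds)
  function(tab) {
    switch(method,
      gcomp = g_compute(tab, fit_outcome(tab, q_formula))$psi,
      iptw = {
        gf <- fit_propensity(tab, g_formula, g_bounds)
        iptw_estimate(tab, stabilized_weights(tab, gf))$psi
      },
      tmle = {
        qf <- fit_outcome(tab, q_formula)
        gf <- fit_propensity(tab, g_formula, g_bounds)
        tmle_estimate(tab, qf, gf)$psi
      })
  }
}

# Run imputation, learner selection, estimation, bootstrap and pooling on
# one analysis population. Returns per-estimator rows plus diagnostics.
analyze_population <- function(table, cfg, label, seed_base, log) {
  imputed <- if (anyNA(table[confounder_names])) {
    chained_impute(table, imputation_config(m = cfg$m,
                                            n_cycles = cfg$n_cycles,
                                            seed = substream(cfg$seed,
                                                             seed_base)))
  } else {
    list(table)
  }
  m <- length(imputed)
  log(sprintf("[%s] n = %d, imputed datasets = %d", label, nrow(table), m))
  lib <- learner_library(v_folds = cfg$v_folds)
  per_est <- stats::setNames(
    lapply(cfg$estimators, function(e) list(psi = numeric(m),
                                            var = numeric(m),
                                            boot_mean = numeric(m),
                                            reps = list())),
    cfg$estimators)
  or_log <- numeric(m)
  or_var <- numeric(m)
  pos_report <- NULL
  for (k in seq_len(m)) {
    tab_k <- imputed[[k]]
    if (cfg$learners == "cv") {
      qfit <- discrete_super_learner(tab_k, "outcome", lib,
                                     seed = substream(cfg$seed,
                                                      seed_base + 2 * k),
                                     g_bounds = cfg$g_bounds)
      gfit <- discrete_super_learner(tab_k, "exposure", lib,
                                     seed = substream(cfg$seed,
                                                      seed_base + 2 * k + 1),
                                     g_bounds = cfg$g_bounds)
    } else {
      qfit <- fit_outcome(tab_k, learner_formula(cfg$learners, "outcome"),
                          learner_id = cfg$learners)
      gfit <- fit_propensity(tab_k, learner_formula(cfg$learners, "exposure"),
                             g_bounds = cfg$g_bounds,
                             learner_id = cfg$learners)
    }
    log(sprintf("[%s] dataset %d: outcome learner = %s, exposure learner = %s",
                label, k, qfit$learner_id, gfit$learner_id))
    q_formula <- stats::formula(qfit$model)
    g_formula <- stats::formula(gfit$model)
    for (e in cfg$estimators) {
      point <- switch(e,
        gcomp = g_compute(tab_k, qfit),
        iptw = iptw_estimate(tab_k, stabilized_weights(tab_k, gfit)),
        tmle = tmle_estimate(tab_k, qfit, gfit, cfg$conf_level))
      boot <- bootstrap_estimate(
        tab_k, make_estimator(e, q_formula, g_formula, cfg$g_bounds),
        B = cfg$B,
        seed = substream(cfg$seed, seed_base + 100 * k + match(
          e, c("gcomp", "iptw", "tmle"))),
        conf_level = cfg$conf_level)
      if (boot$n_failed > 0) {
        log(sprintf("[%s] dataset %d: %s bootstrap dropped %d replicates",
                    label, k, e, boot$n_failed))
      }
      per_est[[e]]$psi[k] <- point$psi
      per_est[[e]]$var[k] <- if (e == "tmle") point$variance else
        stats::var(boot$replicates)
      per_est[[e]]$boot_mean[k] <- boot$boot_mean
      per_est[[e]]$reps[[k]] <- boot$replicates
      if (is.null(pos_report) && e == cfg$estimators[[1]] && k == 1) {
        pos_report <- positivity_report(tab_k, gfit, boot, point)
      }
    }
    # supplementary conditional logistic odds ratio (traditional analysis)
    orfit <- fit_glm_quiet(learner_formula("main_effects", "outcome"), tab_k)
    or_log[k] <- stats::coef(orfit)[["A"]]
    or_var[k] <- stats::vcov(orfit)["A", "A"]
  }
  alpha <- 1 - cfg$conf_level
  z <- stats::qnorm(1 - alpha / 2)
  rows <- lapply(cfg$estimators, function(e) {
    x <- per_est[[e]]
    all_reps <- unlist(x$reps)
    boot_ci <- unname(stats::quantile(all_reps, c(alpha / 2, 1 - alpha / 2)))
    if (m >= 2) {
      pooled <- rubins_rule(x$psi, x$var, cfg$conf_level)
      est <- pooled$estimate; lo <- pooled$ci_low; hi <- pooled$ci_high
    } else {
      est <- x$psi[1]
      se <- sqrt(x$var[1])
      lo <- est - z * se; hi <- est + z * se
    }
    data.frame(analysis = label, method = e, estimate = est,
               ci_low = lo, ci_high = hi,
               boot_mean = mean(x$boot_mean),
               boot_ci_low = boot_ci[1], boot_ci_high = boot_ci[2])
  })
  or_pooled <- if (m >= 2) {
    p <- rubins_rule(or_log, or_var, cfg$conf_level)
    c(or = exp(p$estimate), ci_low = exp(p$ci_low), ci_high = exp(p$ci_high))
  } else {
    se <- sqrt(or_var[1])
    c(or = exp(or_log[1]), ci_low = exp(or_log[1] - z * se),
      ci_high = exp(or_log[1] + z * se))
  }
  list(rows = do.call(rbind, rows), positivity = pos_report,
       logistic_or = or_pooled, m = m)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis: load or simulate the cohort
#' (applying the under-`max_age` eligibility rule), summarise crude
#' prevalences, impute missing confounders into `m` datasets, select
#' learners and compute every requested estimator with a bootstrap in
#' each dataset, pool across datasets by Rubin's rules, produce
#' positivity diagnostics, and repeat on the sensitivity-restricted
#' population. When `cfg$out_dir` is set, writes `results.csv` (one row
#' per estimator and analysis), `crude.csv`, `positivity.txt`,
#' `supplementary.csv` (the traditional logistic odds ratio) and
#' `run_log.txt`; partial outputs are removed if any stage fails. The
#' whole run is deterministic given the config.
#'
#' @param cfg An [analysis_config()] or path to a YAML config file.
#' @return An `analysis_result` (invisibly when writing files): config,
#'   crude summaries, the results table, positivity reports, the pooled
#'   logistic odds ratio per analysis, and the run log.
#' @export
run_analysis <- function(cfg) {
  if (is.character(cfg)) cfg <- read_analysis_config(cfg)
  stopifnot(inherits(cfg, "analysis_config"))
  log_lines <- character(0)
  log <- function(msg) log_lines[[length(log_lines) + 1]] <<- msg
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  written <- character(0)
  done <- FALSE
  on.exit(if (!done && length(written)) unlink(written), add = TRUE)

  cohort <- stage("load", {
    if (!is.null(cfg$input)) {
      read_cohort(cfg$input)
    } else {
      params <- cfg$scm
      if (is.null(params)) params <- kisumu_like_params(seed = cfg$seed)
      if (is.character(params)) params <- read_scm_config(params)
      tab <- generate_cohort(params)
      tab <- apply_mar_missingness(tab, params)
      if (params$misclass[["sensitivity"]] < 1 ||
          params$misclass[["specificity"]] < 1) {
        tab <- misclassify_exposure(tab,
                                    params$misclass[["sensitivity"]],
                                    params$misclass[["specificity"]],
                                    seed = params$seed)
      }
      tab
    }
  })
  log(sprintf("master seed = %s", format(cfg$seed)))
  n_raw <- nrow(cohort)
  cohort <- cohort[cohort$age < cfg$max_age, , drop = FALSE]
  if (nrow(cohort) < n_raw) {
    log(sprintf("eligibility: dropped %d records aged >= %g",
                n_raw - nrow(cohort), cfg$max_age))
  }
  crude_main <- stage("crude", crude_summary(cohort))
  main <- stage("main analysis",
                analyze_population(cohort, cfg, "main", 200L, log))
  sens_tab <- stage("sensitivity filter",
                    apply_sensitivity_filter(cohort, cfg$min_months,
                                             cfg$min_frac))
  log(sprintf("sensitivity restriction retained %d of %d records",
              nrow(sens_tab), nrow(cohort)))
  crude_sens <- crude_summary(sens_tab)
  sens <- stage("sensitivity analysis",
                analyze_population(sens_tab, cfg, "sensitivity", 500L, log))
  results <- rbind(main$rows, sens$rows)
  rownames(results) <- NULL
  out <- structure(list(
    config = cfg,
    crude = list(main = crude_main, sensitivity = crude_sens),
    results = results,
    positivity = list(main = main$positivity,
                      sensitivity = sens$positivity),
    logistic_or = list(main = main$logistic_or,
                       sensitivity = sens$logistic_or),
    log = log_lines), class = "analysis_result")
  if (!is.null(cfg$out_dir)) {
    stage("write outputs", {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      p <- function(f) file.path(cfg$out_dir, f)
      written <<- c(p("results.csv"), p("crude.csv"), p("positivity.txt"),
                    p("supplementary.csv"), p("run_log.txt"))
      utils::write.csv(results, p("results.csv"), row.names = FALSE,
                       quote = FALSE)
      crude_df <- rbind(
        data.frame(analysis = "main",
                   as.data.frame(unclass(crude_main))),
        data.frame(analysis = "sensitivity",
                   as.data.frame(unclass(crude_sens))))
      utils::write.csv(crude_df, p("crude.csv"), row.names = FALSE,
                       quote = FALSE)
      or_df <- data.frame(
        analysis = c("main", "sensitivity"),
        measure = "odds_ratio_COC",
        rbind(main$logistic_or, sens$logistic_or), row.names = NULL)
      utils::write.csv(or_df, p("supplementary.csv"), row.names = FALSE,
                       quote = FALSE)
      con <- file(p("positivity.txt"), "w")
      sink(con)
      cat("== main analysis ==\n"); print(main$positivity)
      cat("\n== sensitivity analysis ==\n"); print(sens$positivity)
      sink(); close(con)
      writeLines(log_lines, p("run_log.txt"))
    })
    done <- TRUE
    return(invisible(out))
  }
  done <- TRUE
  out
}

#' @export
print.analysis_result <- function(x, ...) {
  cat("Marginal prevalence difference analysis\n\n")
  print(x$crude$main)
  cat("\n")
  res <- x$results
  num <- vapply(res, is.numeric, logical(1))
  res[num] <- lapply(res[num], function(v) sprintf("%.3f", v))
  print(res, row.names = FALSE)
  cat(sprintf("\nTraditional logistic odds ratio (main): %.2f (%.2f, %.2f)\n",
              x$logistic_or$main[["or"]], x$logistic_or$main[["ci_low"]],
              x$logistic_or$main[["ci_high"]]))
  invisible(x)
}
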