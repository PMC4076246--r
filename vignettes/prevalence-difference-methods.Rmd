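---
title: "Estimating a marginal prevalence difference: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating a marginal prevalence difference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalprev)
```

## The scientific problem

Whether combined oral contraceptives (COC) increase the risk of cervical
precancer is an open question with particular weight for women living
with HIV, who face elevated baseline risk of cervical intraepithelial
neoplasia grade 2 or higher (CIN2+). The best available data are
observational: cross-sectional screening cohorts in which COC ever-use,
the outcome, and a handful of confounders (age, educational attainment,
marital status, gravidity, CD4+ cell count nadir) are recorded, with
missing values in some confounders and imperfect exposure recording.

The target parameter throughout this package is the **marginal
prevalence difference**

$$\psi = E[Y(1)] - E[Y(0)],$$

the counterfactual change in outcome prevalence if the whole population
were exposed versus unexposed. This is a population-level quantity on
the additive scale, distinct from the conditional odds ratio a logistic
regression reports (the pipeline still emits that odds ratio as a
supplementary output for comparison with traditional analysis).

## The cohort simulator and what it emulates

Because screening-cohort data of this kind are not public, the package
ships a structural-causal-model simulator (`scm_params()`,
`generate_cohort()`) whose defaults (`kisumu_like_params()`) emulate the
*structure* of a Kenyan HIV-care screening cohort: n = 2519 women under
50, roughly 35% COC ever-use, roughly 8.7% CIN2+ prevalence, and a true
marginal prevalence difference near +0.029, with missing-at-random
missingness in CD4+ nadir (~13%) and education (~6%).

Generation follows the reduced graph W → A → Y: confounders W from
stylised marginals (age uniform on 18–49; education ordinal 0–3;
marital status Bernoulli(0.6); gravidity Poisson(3) truncated at 12;
CD4+ nadir log-normal with median 250 cells/µL), then
A ~ Bernoulli(expit(β_A·x(W))) and Y ~ Bernoulli(expit(β_Y·x(W, A))).
Both links are logistic with main-effects linear predictors — the
simplest forms under which "correct model" and "wrong model" scenarios
are cleanly constructible (an optional quadratic age coefficient exists
for building misspecification scenarios). The two logistic intercepts
and the exposure coefficient were fixed once by Monte Carlo calibration
against the three target margins (35%, 8.7%, ψ ≈ 0.029) and are not
revisited; the confounder marginals are realism-motivated choices, not
estimates of any real population.

What the simulator deliberately does **not** emulate: the
HPV-acquisition pathway, antiretroviral-therapy dynamics, longitudinal
visit-level records, or time-varying exposure. Passing tests on this
generator therefore demonstrate correctness of the estimation machinery
under a known truth — not that any particular real-world estimate is
unconfounded.

```{r simulator}
params <- kisumu_like_params()
cohort <- generate_cohort(params)
crude_summary(cohort)
true_prevalence_difference(params, n_mc = 2e5)
```

### Observation metadata and exposure misclassification

Ever-use is recorded from visit reports, so the simulator carries
`months_observed` (gamma, mean 24 months) and `frac_visits_coc`, the
fraction of visits at which use was reported: Beta(2, 2) rescaled into
(0, 1] for recorded users — placing mass on both sides of the 0.2
reporting-consistency threshold — and exactly 0 for recorded non-users.

`misclassify_exposure()` flips the recorded exposure at rate
1 − sensitivity among true users and 1 − specificity among true
non-users. Falsely recorded users draw their visit fraction from a
low-mean Beta(1, 9) rather than the genuine-user Beta(2, 2): a spurious
ever-use record typically stems from isolated visit reports. This
mechanistic link is what gives the stricter exposure classification in
the sensitivity analysis its repair power; if the visit fraction were
independent of misclassification status, restricting on it could not
preferentially shed misclassified records (and no filter can reach
false negatives, which carry a fraction of exactly 0). For the same
reason the misclassification test fixtures combine imperfect
sensitivity (0.7) with mildly imperfect specificity (0.9): the
false-positive channel is the one the filter can repair.

## Identification: DAG utilities

`causal_dag()` represents a causal graph as named nodes and directed
edges. `d_separated()` implements standard d-separation by reachability
over (node, travel-direction) states; `backdoor_admissible()` checks
the backdoor criterion (no descendant of the exposure in the set, and
the set blocks every path into the exposure) by removing the exposure's
outgoing edges and testing d-separation; `minimal_adjustment_sets()`
enumerates all inclusion-minimal admissible sets by exhaustive search
over subsets of non-descendants, smallest first and lexicographic
within size. Exogenous "U" nodes are ordinary nodes with no special
semantics.

The test suite cross-checks d-separation against an independent
brute-force oracle that enumerates every undirected path and applies
the blocking rules edge by edge, exhaustively over all DAG structures
with up to five nodes (upper-triangular adjacency covers every
structure up to relabelling, and d-separation is invariant to
relabelling).

Three worked panels ship as fixtures (`dag_panel()`, and text files
under `inst/extdata/`): confounding (adjust for {W}), a collider
(adjust for nothing; conditioning on the collider *opens* the path),
and a three-confounder graph in which adjusting for W3 alone opens a
new biasing path through W1 and W2, so the minimal sufficient sets are
{W1, W3} and {W2, W3}. The exact wiring of the three-confounder panel
is a reconstruction — the unique canonical structure consistent with
all of the facts just listed — and is flagged as such in the fixture
comments, as is the stylised two-time-point full model
(`full_model_two_timepoints.txt`), which exists only as a graph fixture
and is never simulated.

```{r dag}
minimal_adjustment_sets(dag_panel("C"), "X", "Y")
backdoor_admissible(dag_panel("C"), "X", "Y", "W3")
```

## Missing confounders: chained multiple imputation

`chained_impute()` fills missing confounder cells by chained equations:
hot-deck initialisation, then (by default) 10 sweeps in which each
incomplete column is redrawn from a conditional model refit on the
current completed data, producing (by default) m = 10 completed
datasets. Conditional families follow the measurement level of each
column: logistic for binary, multinomial logistic for education,
Poisson (draws truncated to the observed range) for gravidity, and
linear-normal on the log scale for CD4+ nadir. Predictors are the
exposure, the outcome, and all other confounders — the standard
MAR-compatible default; the site/time data-quality drivers that a real
cohort's imputation would include have no counterpart in this schema.

One deliberate simplification: coefficients are refit rather than drawn
from their posterior, with stochastic draws entering only through the
imputation noise. This understates between-imputation variability
slightly relative to fully proper imputation but keeps the procedure
deterministic given the seed and adequate for the property suite (the
pooled-variance invariants do not depend on properness).

`rubins_rule()` pools estimates across completed datasets: pooled
estimate = mean; total variance = within + (1 + 1/m) × between; CI from
a t quantile with Rubin's degrees of freedom
(m − 1)(1 + within/((1 + 1/m) between))², falling back to a normal
quantile when the between-variance is exactly zero.

## The three estimators

All three target the same ψ on a completed dataset.

**G-computation** (`g_compute()`): fit an outcome regression
Q(A, W) = P(Y = 1 | A, W), predict for every record with A set to 1 and
to 0, and average the difference. Consistent when Q is correct;
variance comes from the bootstrap.

**Stabilized IPTW** (`stabilized_weights()`, `iptw_estimate()`): fit a
propensity g(W) = P(A = 1 | W), weight exposed records by P̂(A=1)/g and
unexposed by P̂(A=0)/(1−g), and contrast the weighted outcome means.
The normalized (Hájek) form is the default — the weighted-population
reading of the estimand — with the unnormalized Horvitz–Thompson form
behind a flag for testing. Consistent when g is correct; variance from
the bootstrap.

**TMLE** (`tmle_estimate()`): update the initial Q along a
one-dimensional logistic fluctuation with clever covariate
H = A/g − (1−A)/(1−g), the coefficient ε fit by maximum likelihood with
logit Q as offset (a single shared ε for both exposure levels — the
standard one-dimensional fluctuation for this parameter); then
standardize the targeted predictions. The variance is the sample
variance of the efficient influence curve over n, giving a Wald CI.
Doubly robust: consistent if either Q or g is correct, which the test
suite demonstrates directly at n = 50&nbsp;000 with intercept-only
misspecifications on either side.

Numerical choices: predictions are bounded inside (0, 1) at 10⁻⁹ so
logits stay finite (loose enough that saturated-model tests still agree
with nonparametric standardization to 10⁻¹⁰); the fluctuation glm runs
with tolerance 10⁻¹⁴ so the score identity
mean(H (Y − Q*)) = 0 holds to ~10⁻⁸ in tests; propensity truncation
defaults to [0.01, 0.99] — a standard practical-positivity guard, since
inspecting positivity does not by itself prescribe a truncation rule —
and is configurable, with pre-truncation extremes counted in the
positivity report. A degenerate outcome (all Y identical) makes every
estimator return ψ = 0 with a warning rather than fail, so pathological
resamples and fixtures have defined behaviour.

### Learner selection

`discrete_super_learner()` performs discrete selection over a fixed,
transparent library of four parametric logistic learners
(intercept-only; main effects; all pairwise interactions; main effects
plus quadratic age), choosing by V-fold cross-validated negative
log-likelihood on a seed-fixed split, ties broken by library order, and
refitting the winner on the full data. A deliberately small discrete
library — rather than a full stacked ensemble — keeps model selection
reproducible and desk-scale while still exercising the selection logic
(the simulation tests confirm the main-effects learner wins on
main-effects data and the intercept learner wins on noise). Failed
learners receive infinite loss; selection happens once per imputed
dataset, and bootstrap resamples refit the *selected* learner rather
than re-running selection, the usual practice that keeps the bootstrap
measuring sampling variability of the chosen estimator.

## Inference and diagnostics

`bootstrap_estimate()` resamples individual records with replacement
(the cohort is cross-sectional; there is no clustering to respect) and
reruns the full estimator per resample — 200 replicates per imputed
dataset by default. Replicates where a model fails or an arm empties
are dropped and counted, with a hard error beyond 20%. It reports the
replicate mean, SE, and the 2.5th/97.5th percentile interval.

`positivity_report()` scans the observed covariate combinations — age
binned to decades, CD4+ nadir to the clinical {<200, 200–500, >500}
cut-points, gravidity to {0, 1–2, 3+} — for strata with zero exposed or
zero unexposed records, counts pre-truncation propensity extremes, and
reports the symmetry of the bootstrap distribution around the point
estimate (mean difference and skewness), the same informal check that
near-positivity violations have not distorted the estimate.

Across imputed datasets, point estimates are pooled by Rubin's rules
with per-dataset variance taken from the bootstrap (g-computation,
IPTW) or the influence curve (TMLE), mirroring how the two kinds of
variance estimate are naturally produced. How bootstrap *quantile*
intervals should be pooled across imputations has no canonical answer;
this package pools the replicate sets themselves — the reported
bootstrap interval is the percentile interval of all m × B replicates —
which propagates between-imputation spread into the interval without
further distributional assumptions. This is an interpretation, and is
labelled as such.

## The pipeline

`run_analysis()` chains the stages: load or simulate → under-50
eligibility filter → crude summary → imputation (skipped, with m
collapsing to one dataset, when the cohort is complete — guaranteeing
that a missingness-free analysis is identical with and without the
imputation stage) → per-dataset learner selection, estimation,
bootstrap → Rubin pooling → positivity diagnostics → the same sequence
on the sensitivity-restricted population → delimited-text outputs and a
run log recording seeds, learner selections, and dropped replicates.
Every stochastic stage derives an independent substream from the single
config seed, so a rerun with the same config is byte-identical.

The sensitivity restriction keeps records with at least `min_months`
(default 6) months of observation and excludes records reporting use at
a fraction of visits in (0, `min_frac`] (default 0.2): retained exposed
records are exactly those reporting use at more than 20% of visits, and
never-reporters are retained unconditionally subject to the months
rule. The restriction's wording is ambiguous between a sample
restriction and an exposure redefinition; this rule implements the
intersection of the two readings, and both thresholds are configurable
so either pure reading is reachable.

```{r pipeline, eval = FALSE}
cfg <- analysis_config(scm = kisumu_like_params(), m = 10, B = 200,
                       seed = 1, learners = "cv", out_dir = "out")
res <- run_analysis(cfg)
print(res)
```

A thin command-line wrapper is installed under `exec/causalprev`
(subcommands `simulate`, `run`, and `dag check` / `dag minimal-sets`).

## Problem sizes used in the test suite

The shipped tests scale the simulations to desk size as the package's
own choice of study design: parameter-recovery and CI-coverage runs use
200 replicates at the cohort size n = 2519 with correctly specified
parametric learners; double-robustness contrasts use 12 replicates at
n = 50 000 (where Monte-Carlo error is small enough that a 3-SE
separation is decisive); learner-selection studies use 50 replicates;
pipeline determinism and shape checks use small cohorts (600–1500) with
m = 2 imputations and 20–40 bootstrap replicates. All seeds are fixed
in the tests, so every reported property is reproducible exactly.

## Known limitations

* The simulator's truth is a main-effects logistic world; it cannot
  probe robustness to interactions or non-logistic links beyond the
  optional quadratic-age device.
* Imputation is not fully proper (coefficients refit, not drawn), so
  Rubin intervals may be mildly anti-conservative under heavy
  missingness.
* The discrete learner library is parametric by design; no claim is
  made about performance with flexible machine-learning nuisance
  estimators.
* Exposure is binary ever-use at a single time point: no duration,
  recency, time-varying exposure, or stochastic-intervention parameters.
* The positivity scan flags *observed* empty strata only; it cannot
  detect theoretical positivity violations in unobserved combinations.
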