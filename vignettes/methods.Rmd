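---
title: "Models and methods in eftrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in eftrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eftrial)
```

This vignette documents the statistical machinery the package
implements, the assumptions behind each piece, the defaults and why they
were chosen, and what the synthetic-cohort generator can and cannot tell
you about real data.

## The adjusting-amount task and hyperbolic discounting

The titration engine presents binary choices between a smaller-sooner
(SS) amount available now and a fixed larger-later (LL) amount $A$
(default \$1000) at delay $D$. Trial 1 offers $A/2$; after each choice
the SS amount moves down (if SS was chosen) or up (if LL was chosen) by
$A/2^{t+1}$ on trial $t$. After $T$ trials (default 6) the indifference
point is defined as the amount that *would have been offered on trial
$T+1$* — the midpoint of the final bracketing interval. Two properties
follow exactly and are enforced by tests over all $2^6$ choice paths:

* the procedure is a binary search with resolution $A/2^{T+1}$
  (\$7.8125 at the defaults), and any monotone (threshold) responder is
  located to within one resolution step;
* the always-SS and always-LL paths land symmetrically at
  $A/2^{T+1}$ and $A - A/2^{T+1}$.

Indifference points $V$ are then fit to the hyperbolic model
$V = A/(1 + kD)$ by least squares on the dollar scale. The estimation
questions left open by convention were resolved as follows:

* **Estimation scale.** Least squares on $V$ itself (not $\log V$, not
  pooled trial-level choice modelling). Fitting on indifference points
  is the dominant convention for this task; the choice is recorded in
  the fit object's `method` field.
* **Search.** $\ln k$ is scanned on a 600-point grid over
  $k \in [10^{-10}, 10^{3}]$ and refined by golden-section search in the
  bracketing interval. The scan guarantees the estimate can never be
  worse than the best grid point (verified against an independent dense
  grid in the tests); the refinement brings noiseless recovery below
  $10^{-6}$ relative error. Degenerate curves (all $0$ or all $A$)
  return a fit pinned at the corresponding bound with `boundary_flag`
  set rather than an error, since zero-discounting responders are a
  real, expected pattern.
* **Delay units.** Calendar delays convert to days as 2 weeks = 14,
  1 month = 30, 3 months = 90, 1 year = 365, 5 years = 1825,
  25 years = 9125. The convention is configurable via
  `titration_schedule()`.
* **Systematicity screening.** The Johnson–Bickel thresholds are 20% of
  $A$ for a rise between adjacent delays (criterion 1) and 10% of $A$
  for the required first-to-last decrease (criterion 2). Both are
  exposed as arguments; violations *flag* a curve and never remove it.

## Exponentiated demand

Purchase-task responses are capped at 50 drinks per price (flagged, and
idempotent) and fit to

$$Q(C) = Q_0 \cdot 10^{\,k\,(e^{-\alpha Q_0 C} - 1)}$$

by least squares on the raw consumption scale with zeros retained — the
exponentiated form exists precisely so zeros need no offset. The span
$k$ is *not* free per fit: it is fixed across a dataset at
$\log_{10}(\max Q) - \log_{10}(\min Q_{>0}) + 0.5$ from the pooled
capped quantities, the convention of the standard demand-analysis
toolchain, exposed as the `k_span` argument.

Numerical choices: the optimizer is L-BFGS-B on
$(\log Q_0, \log \alpha)$ with bounds $Q_0 \in (0, 2\cdot\text{cap}]$
and $\alpha \in [10^{-8}, 10]$, started from five deterministic
initializations ($Q_0$ at the observed intensity, $\alpha$ on a log
ladder from $10^{-4}$ to $10^{-1}$), followed by a Nelder–Mead polish.
A fit is `converged = FALSE` — and excluded from downstream summaries —
when quantities are all zero, every start fails, or the optimum sits on
the $\alpha$ bounds. Tests verify noiseless recovery to $10^{-4}$
relative error and dominance over an independent dense 2-D grid.

Observed metrics are intensity ($Q$ at $C = 0$), $O_{max}$ (maximum of
$C \cdot Q$) and $P_{max}$ (the *smallest* price attaining $O_{max}$ —
the tie rule matters for flat expenditure series). The observed
$P_{max}$ is the primary quantity; a fitted unit-elasticity price is
also provided. One subtlety: the exponentiated curve has a nonzero floor
$Q_0 10^{-k}$, so fitted expenditure eventually *rises* again at extreme
prices. `fitted_pmax()` therefore solves for the interior unit-elasticity
point $k \ln 10 \cdot \alpha Q_0 C e^{-\alpha Q_0 C} = 1$ (the peak
before the floor branch), falling back to an expenditure-grid argmax on
$[0,\; 10\,P_{max}^{obs} + 1]$ when no interior point exists in range.
Because the equation depends on price only through $\alpha Q_0 C$,
doubling $\alpha$ halves the fitted $P_{max}$; the tests check this
scale property numerically.

## Consumption aggregation and eligibility

Phase summaries report **both** drinks/day denominators, because the two
conventions answer different questions and diverge under missingness:

* `drinks_per_day` divides total drinks by *total calendar days* in the
  phase — the trial's stated figure convention. Missing reports
  contribute days but no drinks, so this measure falls mechanically as
  missingness rises.
* `drinks_per_reported_day` divides by days with a report and is robust
  to missingness; the qualitative phase-pattern checks in the test suite
  use it (and drinks/drinking-day) for exactly this reason.

`drinks_per_drinking_day` divides by days with at least one reported
drink and is `NA` — never zero-filled — when there are no drinking days.
Phase lengths are taken from the data calendar, not fixed, since session
scheduling makes phase duration vary across participants.

Baseline eligibility over the 7-day window requires at least 5 reported
days, at least 4 drinking days, and the harmful-drinking clause (≥ 4
days of 4+ drinks, and/or more than 4 drinks per drinking day); the
returned reasons name every failed clause, and the rule is monotone in
added drinks (property-tested).

## Concordance

A day is breath-positive when its *peak* breath alcohol concentration
reaches 0.02% (strictly below is negative; no samples is missing).
Days cross-tabulate into a 3×3 matrix whose non-missing 2×2 feeds
`fisher_exact_or()` — the conditional maximum-likelihood odds ratio
under the noncentral hypergeometric model with the two-sided exact
p-value, via `stats::fisher.test`, which the test suite checks against
an exhaustive enumeration oracle (all tables with total ≤ 16, plus a
seeded sample up to 40; agreement to the exact-test solver's own ~0.1%
root-finding precision for the odds ratio and to $10^{-9}$ for the
p-value). The conditional MLE, not the sample cross-product, is
reported. A zero margin raises a classed degenerate-table error rather
than returning a misleading number. The ROC AUC of peak BrAC for
predicting a drinking day is the Mann–Whitney rank statistic —
$P(\text{drinking-day peak} > \text{sober-day peak}) + \tfrac12 P(\text{tie})$
— pooled over participant-days (the within-participant average is a
plausible alternative; pooling was chosen as the simpler estimand
matching a single reported AUC). Days lacking either measurement are
excluded pairwise.

## Minimization randomization

Candidates are assigned by covariate-adaptive minimization balancing
√(drinks/day) and baseline ln($k$). For each hypothetical assignment the
imbalance score is the sum over covariates of the absolute between-arm
mean difference standardized by the pooled SD of allocated participants
(a covariate is skipped while its SD is undefined or zero), plus
$\lambda\,|n_{EFT} - n_{CET}|$ with $\lambda = 0.5$; the candidate goes
to the score-minimizing arm with probability 0.8 (a biased coin), ties
by a fair coin. The published description of such algorithms states the
goals (probability adjustment, balance on the two covariates, 1:1
allocation) without the metric, so these defaults are declared rather
than inferred, and bias, $\lambda$ and the covariate list are all
configurable. Tests verify the fair first draw, deterministic correction
at bias 1, alternation under identical covariates, and strictly better
covariate balance than simple randomization over repeated simulated
trials.

## Adherence model selection

Missing daily submissions are modeled by maximum-likelihood logistic
regression, with an exhaustive search over all subsets of the main
effects crossed with hierarchy-respecting subsets of the interactions
(an interaction requires both mains; the intercept-only model is
included). Ranking is by $BIC = -2\ell + p\ln n$ with $p$ counting the
intercept and dummy-coded levels against first-level reference.
Candidates are dropped with a warning when IRLS fails, when R reports
numerically 0/1 fitted probabilities, or when any coefficient exceeds 20
in absolute value — the latter catches quasi-complete separation that
IRLS "converges" through. Logistic fits are cross-checked against a
coarse grid-search likelihood maximization, and BIC consistency is
property-tested: phase-driven missingness selects the phase model, and
pure-noise outcomes select the intercept-only model in the large
majority of seeded replicates.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` generates the full trial: profiles with latent
truths, five sessions of titration choices and purchase responses, and
35 daily records (7 + 14 + 14) per participant. Defaults were fixed once
to describe a realistic cohort of the kind the pipeline targets:

* ln($k$) ~ Normal(−5, 2.5²) and baseline drinking ~5.5 drinks/day with
  Gamma between-person rates (shape 6.25, giving an SD near 2.2) — the
  scale of published baseline tables for harmful-drinking samples;
* latent intensity lognormal around 10 drinks and elasticity lognormal
  around 0.003 (log-SD 0.5), generated through the same exponentiated
  equation with span 2 and multiplicative log₁₀-normal response noise of
  0.12, then integer-rounded and capped — 0.1–0.15 log₁₀ units is a
  typical residual spread for purchase-task data;
* phase rate factors 1 / 0.8 / 0.6 in the active arm and 1 / 1 / 1 in
  the control arm, encoding an active-arm-only consumption reduction;
* per-phase missingness log-odds −2 / −2 / −0.5, i.e. ~12% missing
  submissions early rising to ~38% in the final phase, reproducing the
  compliance decline such monitoring designs show;
* breath readings 0.02% per drink with a 1 / 0.75 / 0.5 decay over the
  day's three samples and additive noise (SD 0.005%) truncated at zero;
* choice noise is a logistic (softmax) rule on the two options' present
  values with temperature in dollars (default \$20; 0 recovers the
  deterministic value maximizer used by the oracle tests).

Days are conditionally independent given the participant's rate — the
generator does not model day-to-day autocorrelation in drinking, since
no usable estimate of it was available to calibrate against. One master
seed fans out to fixed per-participant substreams, so enlarging a cohort
extends it without reshuffling existing participants, and identical
configurations are byte-identical.

What passing tests on this cohort shows: the estimators recover their
generating parameters through the full task → file → estimate path, the
aggregation rules and missingness mechanics behave as specified, and the
pipeline's qualitative group-by-phase structure is faithfully extracted.
What it does not show: performance under real behavioral features the
generator omits — drinking autocorrelation and weekend cycles, reactive
or non-ignorable missingness (here missingness is independent of
consumption), pharmacokinetically realistic BrAC trajectories (the
generator ties breath directly to the day's count, so breath/self-report
concordance is near-perfect by construction — AUC close to 1, against
the more modest discrimination real monitoring yields), heaping of
self-reported counts, or participant dropout (analysis-population
filtering is exercised on datasets with dropout constructed in the
tests).

## Problem sizes and runtime posture

The shipped tests and the acceptance script use cohorts of 64–100
participants, 50-responder recovery sweeps, exhaustive enumeration of
small exact-test tables with seeded sampling of larger ones, and
12–40-replicate selection simulations. These sizes were chosen so the
full suite documents every property at interactive timescales; all
generators and estimators scale to larger cohorts unchanged, and the
sizes are arguments, not constants.

## Known limitations

* The hyperbolic form is the only discounting model; exponential and
  hyperboloid alternatives, effective-delay-50 summaries, and Bayesian
  estimation are out of scope.
* Demand is the exponentiated form only; zero-inflated and
  linear-elasticity models are not provided, and the analyzed
  $P_{max}$ convention (observed) is a declared choice.
* The pipeline emits analysis-ready model frames for the trial's mixed
  models rather than fitting them; random-effect selection, small-sample
  degrees-of-freedom corrections and multiplicity-adjusted contrasts
  belong to the downstream modelling environment.
* `fisher_exact_or()` inherits the precision of the standard exact-test
  solver's conditional-MLE root finding (~3 significant digits for
  extreme tables); the p-value is exact.
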