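# eftrial

Analysis machinery for randomized trials of episodic future thinking
(EFT) in alcohol use disorder, where participants complete laboratory
delay-discounting and alcohol purchase tasks across sessions while their
drinking is monitored remotely (daily self-reported drink counts plus
breathalyzer samples). The package is aimed at behavioral-economic and
addiction researchers who need the quantitative pipeline of such a trial
as tested, reusable code: task engines, estimators, aggregation rules,
concordance statistics, covariate-adaptive randomization, and adherence
model selection — together with a seeded synthetic-cohort generator so
every stage can be exercised and validated without participant data.

## What it computes

**Delay discounting.** The adjusting-amount task titrates a
smaller-sooner amount against a fixed larger-later amount *A* = $1000 at
seven delays (1 day to 25 years), six trials per delay: the step halves
after every choice, so the procedure is a binary search with resolution
*A*/2⁷ = $7.8125. Indifference points *V* are fit by least squares to the
hyperbolic model

> *V* = *A* / (1 + *k·D*)

with the discount rate *k* searched in log space; ln(*k*) is the analysis
scale. Curves are screened with the Johnson–Bickel criteria (flagged,
never dropped).

**Behavioral-economic demand.** Alcohol purchase task responses (13
ascending prices, $0–$80/drink, capped at 50 drinks/price) are fit to the
exponentiated demand equation

> *Q* = *Q*₀ · 10^{*k*(e^{−α*Q*₀*C*} − 1)}

on the raw consumption scale (zeros retained), with the span *k* shared
across a dataset (log₁₀ range of pooled consumption + 0.5). Observed
intensity, O<sub>max</sub> and P<sub>max</sub> are reported alongside the
fitted *Q*₀, α and the fitted unit-elasticity price.

**Consumption, concordance, adherence.** Daily records aggregate to
phase-level drinks/day and drinks/drinking-day (both denominator
conventions are produced and labeled); baseline eligibility applies the
harmful-drinking rules. Days are classified by peak breath alcohol
concentration (≥ 0.02% = positive) against the self-report, giving a 3×3
concordance matrix, a conditional-MLE Fisher exact odds ratio on the
non-missing 2×2, and a rank-based ROC AUC. Missing-submission adherence
is modeled by an exhaustive BIC search over hierarchy-respecting logistic
models. Covariate-adaptive minimization randomization balances arms on
√(drinks/day) and baseline ln(*k*) with a biased coin.

## Worked example

```r
library(eftrial)

# a deterministic hyperbolic responder with k = 0.01/day, run through the task
sch   <- titration_schedule()
curve <- run_titration(simulated_chooser(log(0.01), temperature = 0), sch)
fit_hyperbolic(curve, sch)
#> Hyperbolic discounting fit: V = A / (1 + k D)
#>   k = 0.0099954  ln(k) = -4.6056  SSE = 95.508
```

The engine recovers the generating rate to within titration resolution
(ln *k* error ≈ 0.001 here; the SSE reflects the $7.8125 quantization of
the indifference points, not model misfit).

```r
# breath/self-report association on a reference non-missing 2x2
fisher_exact_or(matrix(c(184, 519, 18, 844), 2, 2, byrow = TRUE))
#> $odds_ratio
#> [1] 16.59857
#> $p_value
#> [1] 1.595744e-49
```

The odds of a positive breath sample are about 16.6 times higher on days
with at least one reported drink.

```r
# a full synthetic trial: 32 participants, active-arm-only reduction
rep <- run_pipeline(cohort_config(n_per_group = 16, seed = 1),
                    out_dir = "trial_out")
rep
#> Trial analysis report (intention_to_treat, seed 1, n = 32)
#>
#> Drinks/day by group x phase:
#>   group       phase drinks_per_day drinks_per_reported_day
#> 1   CET    baseline          5.134                   5.580
#> 2   CET monitoring1          5.098                   5.847
#> 3   CET monitoring2          3.469                   6.017
#> 4   EFT    baseline          5.750                   6.035
#> 5   EFT monitoring1          4.094                   4.770
#> 6   EFT monitoring2          2.168                   3.493
#> ...
#> Concordance: OR = Inf, p = 1.49e-32, AUC = 0.999
#> Adherence best model: ~ phase
#> Discounting sessions fit: 160 (0 flagged nonsystematic)
#> Demand fits: 160 (0 nonconverged, excluded)
```

The report shows the generated structure being recovered: the EFT arm's
drinks per reported day fall across phases (6.04 → 4.77 → 3.49, tracking
the built-in 1/0.8/0.6 rate factors) while the control arm stays level
(the calendar-day column falls in *both* arms because monitoring-phase-2
missingness inflates its denominator — which is why both conventions are
reported), and the BIC search identifies phase as the predictor of
missing submissions. Every interface file (`choices.csv`,
`purchase.csv`, `daily.csv`, `discounting.csv`, `demand.csv`,
`phase_summaries.csv`, `concordance_matrix.csv`, `report.json`, …) is
written to `out_dir`.

A thin command-line wrapper for `simulate`, `run-all` and `randomize`
ships in `inst/scripts/eftrial-cli.R`.

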