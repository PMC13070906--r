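# tnsalvage

Chrono-stratified survival analysis, latent patient subtyping and two-arm
cost–utility modelling for salvage therapy in recurrent trigeminal
neuralgia (TN).

## The problem

When trigeminal neuralgia recurs after microvascular decompression (MVD),
percutaneous balloon compression (PBC) is a minimally invasive salvage
option, with Gamma Knife radiosurgery (GKRS) as the main comparator.
Published cohorts of this population are small and their raw data are
rarely deposited, yet they report a rich set of summary quantities: marginal
recurrence-free survival at fixed horizons, epoch-specific hazard ratios
(predictors of *early* relapse ≤ 24 months differ from predictors of *late*
relapse), latent patient subtypes with distinct biomarker profiles, and
Markov-model cost-utility comparisons.

`tnsalvage` is a reusable, tested implementation of that whole analysis
chain, exercised on a **calibrated synthetic cohort generator** that stands
in for the unavailable patient-level data. It is aimed at biostatisticians
and health-economics analysts who want to reproduce, stress-test or extend
this class of single-centre salvage-therapy analyses.

## What is inside

| Layer | Contents |
|---|---|
| Cohort generator | Seeded synthetic patients; recurrence times from a piecewise-exponential hazard `λ(t) = λ_piece(t)·exp(Σ β_epoch,j x_j)` with covariate effects switching at 24 months; baseline rates calibrated so the population-marginal survival passes through printed targets (closed-form mixture, monotone root search); class-conditional lognormal IL-6 coupled to the latent recurrence-time quantile; administrative censoring |
| Survival | From-scratch product-limit estimator with Greenwood variance and log-log bands; Brookmeyer–Crowley median CI; two-sample log-rank; Cox partial likelihood with Efron ties by Newton–Raphson on counting-process episodes; `epoch_cox()` for the 24-month epoch-split (time-varying effect) analysis |
| Latent classes | EM for a K-class mixture of independent Bernoulli indicators (multi-restart, monotone log-likelihood asserted each iteration), BIC model selection, modal assignment, class-vs-outcome hazard ratio |
| Cost–utility | Four-state Markov cohort engine (PainFree, Recurred, PostReintervention, Dead) with half-cycle correction and discounting; transition calibration to printed 5-year reintervention rates (closed form) and recurrence-free shapes (bisection); value calibration to printed per-arm cost/QALY totals; ICER with dominance logic; tornado and probabilistic sensitivity analysis with CEAC |
| Pipeline | `run_pipeline()` orchestration, MCAR masking + simplified multiple imputation with Rubin pooling, report bundle with checksummed artifacts, thin CLI (`inst/scripts/pipeline.R`) |

## Worked example

```r
library(tnsalvage)

# Calibrate the generator to the study conditions: marginal recurrence-free
# survival 82.1 / 68.4 / 45.2 % at 1 / 2 / 5 years, median 3.21 y, and an
# IL-6 / pain-free-time correlation of about -0.65.
cfg <- calibrated_cohort_config(n = 5000, seed = 42)
cohort <- generate_cohort(cfg, seed = 42)

km <- km_estimate(cohort$time_to_recurrence, cohort$event)
survival_at(km, 5)$estimate        # 0.4625  (five-year recurrence-free survival)
km_median(km)$median               # 3.299   (median pain-free interval, years)

cohort$latent_resistant <- as.integer(cohort$latent_class == "resistant")
epoch_cox(cohort, cutpoint = 2,
          covariate_epoch_map = list(hypertension = "early",
                                     v1_involved = "late",
                                     latent_resistant = "both"))
#>                term epoch   coef      se                  hr    p_value
#>  hypertension:early early 0.7818 0.05303 2.185 (1.970-2.425)  3.514e-49
#>    v1_involved:late  late 0.9525 0.08376 2.592 (2.200-3.055)  5.786e-30
#>    latent_resistant  both 1.4724 0.04866 4.360 (3.963-4.796) 4.203e-201
```

Hypertension roughly doubles the early-relapse hazard, ophthalmic-division
(V1) involvement roughly triples the late-relapse hazard, and the
treatment-resistant latent class carries a four-fold hazard — each estimate
recovering the effect the generator was calibrated to.

The cost–utility engine reproduces the printed two-arm comparison:

```r
arms <- default_cua_arms()
compare_arms(run_cohort_trace(arms$new), run_cohort_trace(arms$comp))
#> PBC vs GKRS: delta cost -1845.00, delta QALY 0.8000 -> dominant
```

PBC is *dominant* (cheaper and more effective), so no ICER is reported —
dominance is the engine's verdict whenever both differences favour the same
arm.

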