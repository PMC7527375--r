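# retscreen

Cost-effectiveness simulation of diabetic retinopathy screening strategies
for type 2 diabetes cohorts.

People with type 2 diabetes are screened for diabetic retinopathy so that
sight-threatening retinopathy (STR, EURODIAB grade 3–5) is referred in
time. `retscreen` replays a longitudinal cohort under three policies —
fixed **annual** screening, the stratified **Dutch guideline** (1–3 years
by previous grade), and a **personalised** schedule derived from a
Weibull proportional-hazards risk model — and compares them on delayed
STR diagnoses and discounted screening costs.

The personalised engine models the cumulative incidence of STR as

    F(t | x) = 1 − exp{ −exp(βᵀx) · t^p },   t in months,

with x = (sex, log diabetes duration, log HbA1c, log systolic BP,
retinopathy presence), and assigns the screening interval that solves
`F(t* | x) = ε` for a preset risk margin ε, clamped to 6–60 months. The
package covers the full analysis chain:

* `generate_cohort()` — synthetic longitudinal cohorts with realistic
  grade progression, covariate drift and routine-care missingness, plus a
  complete-data truth channel (`truth_channel()`, `fit_str_hazard()`);
* `read_cohort()` / `write_cohort()` / `select_analysis_cohort()` — the
  long-format CSV and the study's selection filters;
* `impute_cohort()` — grade interpolation, grade-conditional covariate
  means, and the fast/slow STR-onset scenarios;
* `simulate_cohort()` — event-driven screening replay with
  delayed-diagnosis accounting (screens embedded in annual-care visits by
  default);
* `margin_grid_analysis()`, `best_risk_margin()`,
  `bootstrap_two_stage()`, `ceac()` — costs from healthcare and societal
  perspectives, risk-margin optimisation, two-stage bootstrap with
  probabilistic sensitivity analysis, CEAC curves;
* `run_pipeline()` and a thin CLI (`inst/cli/retscreen`) to orchestrate
  generate → select → impute → simulate → cea with a run manifest.

## Worked example

```r
library(retscreen)

coh <- generate_cohort(cohort_config(n_patients = 7000, seed = 2026))
sel <- select_analysis_cohort(coh)
print(sel)
#> Cohort selection: 5040 of 7000 patients retained
#>   excluded: 60 without any retinopathy grade, 0 with STR at baseline, 1900 with short follow-up

imp <- impute_cohort(sel$cohort, scenario = "fast", seed = 1)
print(imp)
#> Imputed cohort (fast STR progression): 5040 patients, 136 STR cases

params <- default_risk_model()
res <- simulate_cohort(imp$cohort, imp$onsets, "personalised",
                       risk_margin = 0.02, params = params)
print(res)
#> Screening simulation (personalised policy): 5040 patients, 45374 screens
#>   STR cases: 136; delayed diagnoses: 7 (5.1%); median delay 12.0 months (max 36)

grid <- margin_grid_analysis(imp$cohort, imp$onsets,
                             econ = econ_params(), params = params)
best_risk_margin(grid)
#> Best risk margin: 1.2% (peak incremental saving 24.92 EUR per delayed STR diagnosis)

cea <- bootstrap_two_stage(imp$cohort, imp$onsets, B = 200, seed = 1)
print(cea)
#> Cost-effectiveness analysis (5040 patients, B = 200, seed 1)
#> Stage 1 best risk margin: mean 1.4% (95% CI 1.2%, 2.1%); stage 2 run at 1.4%
#> ... Total costs - annual        healthcare 1279293.5 ...
#> ... Total costs - personalised  healthcare 1067404.1 ...
#> ... Saving per patient-year - personalised vs annual healthcare 3.7 (2.3, 5.4) ...
#> ... Delayed STR diagnoses - personalised 1.9 (0.0, 5.0)
#> ... Delayed STR diagnoses - guideline   14.8 (7.0, 22.0)
```

Reading the output: of 136 simulated STR cases, the personalised policy at
a 2% risk margin delays 7 diagnoses (5.1%), with delays capped at 48
months by construction (screens are carried out at annual-care visits).
The stepwise optimisation finds the risk margin at which the incremental
saving per additional delayed diagnosis peaks; the bootstrap then
quantifies sampling and cost uncertainty around totals, savings per
patient-year, ICERs and delayed counts, under both perspectives. CEAC
curves come from the stored draws:

```r
ceac(cea$draws$personalised_vs_annual, thresholds = seq(0, 5e4, 500))
plot(cea, type = "plane")
```

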