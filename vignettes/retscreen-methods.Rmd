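---
title: "Methods: simulating personalised diabetic retinopathy screening and its cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating personalised diabetic retinopathy screening and its cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

People with type 2 diabetes are screened at regular intervals for diabetic
retinopathy so that sight-threatening retinopathy (STR, EURODIAB grade 3-5)
is referred to an ophthalmologist before irreversible damage occurs. Annual
screening is the common default; stratified guidelines (such as the Dutch
1-3 year scheme) and personalised risk-model-based intervals screen less
often in low-risk patients. `retscreen` replays a longitudinal cohort under
all three policies and compares them on two axes: **delayed STR diagnoses**
(an onset falling before the next scheduled screen) and **discounted
screening costs** from a healthcare or societal perspective. The package
also generates synthetic cohorts with the statistical structure this
analysis assumes, so that every stage is testable without access to any
patient-level data.

## The risk model and its inversion

The personalised engine models the cumulative incidence of STR as a Weibull
proportional-hazards function of the patient's current profile $x$ (sex,
log diabetes duration, log HbA1c, log systolic blood pressure, presence of
mild retinopathy):

$$F(t \mid x) \;=\; 1 - \exp\{-e^{\beta^\top x}\, t^{p}\},\qquad t \text{ in months}.$$

Given a preset *risk margin* $\varepsilon$ — the accepted probability of
developing STR before the next screen — the interval solves
$F(t^\ast \mid x) = \varepsilon$ analytically,

$$t^\ast = \left(\frac{-\log(1-\varepsilon)}{e^{\beta^\top x}}\right)^{1/p},$$

is clamped to the model's admissible range (6 to 60 months) and rounded
down to whole months. The analytic inversion is cross-checked against
bisection root-finding in the test suite (1,000 random profiles, agreement
to $10^{-8}$ months). Margins are fractions internally; per cent appears
only at interfaces.

The shipped coefficient file, `inst/extdata/risk_model_synthetic.yaml`, is
a **synthetic calibration**, not a transcription of a published coefficient
table: shape $p = 1.3$ and coefficients chosen so that a Dutch
primary-care type 2 diabetes population gets a cohort-mean interval of
about 32 months at a 4.0% margin, the 6-month floor at a 0.0% margin, and
the 60-month cap for minimal-risk profiles at 4.0%. All package behaviour
except those two clamp values is coefficient-agnostic (monotonicity,
inversion consistency, oracle equivalence), so replacing the config with a
transcribed set changes numbers, not correctness. Analyses of real data
should do exactly that via `read_risk_model()`.

## Screening policies

* **Annual**: screen every 12 months; refer at grade >= 3.
* **Dutch guideline**: 24 months after a retinopathy-free screen, 36
  months after two *consecutive* retinopathy-free screens, 12 months for
  grades 1-2, referral at grade >= 3. A grade-0 screen after a grade-1/2
  screen restarts at 24 months: the 3-year interval is read as requiring
  two consecutive retinopathy-free observations.
* **Personalised**: referral at grade >= 3, otherwise the inverted-model
  interval at the chosen margin, using covariates carried forward from the
  latest visit (LOCF).

## Event simulation and visit alignment

Screens start at the baseline visit and are scheduled iteratively; the
grade observed at a screen is the imputed grade trajectory at the latest
visit at or before it. Detection of an STR case is the first screen at or
after onset; ties count as detected on time; the delay is detection minus
onset. An onset with no later in-window screen is counted as delayed with
the delay censored at the end of follow-up (switch `censor_undetected`).

By default the scheduled date is **carried out at the next attended
visit** (`align_to_visits = TRUE`). In the kind of cohort this package
emulates, retinopathy screening is embedded in routine annual
diabetes-care visits, so a model interval of, say, 17 months is realised
at the 24-month visit and sub-annual intervals are realised annually. Two
structural facts follow that free-running schedules do not provide: annual
screening detects every on-grid onset on time (zero delays), and with a
60-month maximum interval no delay can exceed 60 - 12 = 48 months (the
screen preceding onset sits at least one visit-spacing before it). With
`align_to_visits = FALSE` screens fall exactly where scheduled, between
visits if need be; small misalignment delays then become common and the
48-month cap no longer binds.

A month-by-month brute-force event loop, written independently of the
package internals, reproduces all screen times and delays exactly on
random synthetic patients in the test suite.

## Imputation of routine-care data

Missing data are handled the way registry-based retinopathy analyses do:

* **Covariates** (HbA1c, SBP, diabetes duration): replaced by the
  cohort-wide mean conditional on the retinopathy grade at that visit;
  visits with missing grades, and grade strata without any observed value,
  fall back to the overall mean (with a warning).
* **Grades**: internal gaps flanked by equal sub-STR grades are filled
  with that grade; gaps flanked by differing sub-STR grades are filled by
  a continuous uniform draw between the two grades, rounded half away from
  zero. Gaps ending in an STR grade are the *onset gap* and are left to
  the scenarios below; leading/trailing gaps and post-STR gaps stay
  missing (baseline is the earliest observed grade; post-onset grades do
  not affect outcomes).
* **STR onset scenarios**: when grades are missing between the last
  sub-STR observation (time $S$) and the first STR observation (time $T$),
  the *fast* progression assumption places onset at the first
  missing-grade visit after $S$, the *slow* assumption at $T$. With no gap
  both give $T$. Fast onset <= slow onset always, and on synthetic data
  the true onset lies in $[\text{fast}, \text{slow}]$ for every case.

Grades are interpolated before covariates are imputed (the conditional
means then condition on filled grades); the order is a package choice.
One global seed drives all stochastic fills, split into per-patient
substreams keyed by a hash of the patient id, so a patient's fills do not
depend on which other patients are present.

## The synthetic cohort generator

`generate_cohort()` emulates a dynamic primary-care type 2 diabetes
cohort: per-patient follow-up uniform over 0-18 years with visits every 12
months; baseline grades 0/1/2 with probabilities 93.8/5.1/1.1%; per-grade
baseline HbA1c, SBP, age (normal) and diabetes duration (log-normal
matched to per-grade median/IQR); covariates evolving as small annual
random walks (SD 4 mmol/mol HbA1c, 6 mmHg SBP). The STR onset time is
drawn from the configured Weibull hazard at baseline covariates; its
default intercept (-26.0, against the interval engine's -23.2) makes
roughly 3% of an analysis cohort develop STR over follow-up, the order of
magnitude seen in well-controlled screened populations, and encodes the
empirical fact that screening models calibrated on higher-incidence
populations over-predict risk in such cohorts. The *recorded* onset is the
first visit at or after the latent time (STR is a visit-level observation);
the latent time is kept in the truth channel, and `fit_str_hazard()`
(maximum likelihood via `survival::survreg`, mapped to the
proportional-hazards parameterisation) recovers the generating parameters
from it — the test suite checks shape and the log-hazard scale at a
cohort-typical profile to within 10% on a 20,000-patient cohort. The raw
intercept is deliberately not the recovery target: it is an extrapolation
to log-covariate zero whose standard error at a few hundred events far
exceeds 10%.

Sub-STR grade dynamics are *not* constrained by the data the package
emulates beyond baseline cross-sections, so they are a documented
modelling choice: a monotone discrete-time Markov chain on grades 0-2 with
HbA1c-dependent upward drift, plus a **pre-onset ramp** — visits within 36
months before STR onset show at least grade 1 (at least grade 2 in the
final year), because severe retinopathy develops out of milder grades.
The ramp is what gives stratified and personalised policies their
fair warning; without it STR strikes grade-0 patients with long assigned
intervals and delayed fractions become implausibly large. Baseline visits
are exempt so the entry cross-section matches the configured mix.

Masking reproduces reported routine-care missingness: 12.2% of grade
records in never-STR patients (missing completely at random), a masked
pre-onset run of grades in 22% of STR cases (never the first visit, so
baseline stays observable), and 1.0/1.7/2.0% of
duration/HbA1c/SBP values. Complete data are generated first and retained
as a truth channel for testing; masking only hides values.

What the generator does **not** emulate: calendar structure and secular
trends, visit-time jitter and missed visits, per-eye grades, treatment
after referral, screening non-attendance, and any correlation structure of
real registry data beyond the documented marginals. Passing tests on
synthetic cohorts therefore validate the machinery and its structural
properties, not the headline numbers of any particular real cohort.

## Health economics

Per-screen unit costs (2015 euros) are screening 15.25-41.07,
travel 1.58-14.19, productivity 2.63-16.62; the healthcare perspective
counts screening only, the societal perspective all three. "Fitting a
gamma distribution to the minimum and maximum" is interpreted as matching
the 2.5% and 97.5% quantiles: the quantile ratio depends on the shape
alone, so the shape is found by monotone root-finding on its logarithm and
the rate follows; a moment-matching alternative (mean = midpoint,
SD = range/4) sits behind `gamma_fit = "moment"`. Costs are discounted at
4.0%/year from patient entry; the 1.5%/year effect discount is kept for
completeness but headline delayed-diagnosis counts are undiscounted
integers, as count outcomes usually are.

The **margin grid** (0.0-4.0% in 0.1% steps) reports mean discounted cost
per patient and delayed-diagnosis counts per margin, using the gamma means
as point unit costs. The **best margin** maximises the incremental cost
saving per additional delayed diagnosis between consecutive margins;
plateaus with no delayed increment carry their savings forward, ties
resolve to the fewer delayed diagnoses and then the lower margin.

The **two-stage bootstrap** follows the published design: stage 1
resamples patients (with replacement, original size, B iterations) and
summarises the per-iteration best margin by its mean and percentile 95%
CI; stage 2 fixes the margin at the grid point nearest that mean and
resamples patients *and* unit costs from the gamma distributions,
recording totals, savings per patient-year (undiscounted follow-up years
as denominator), delayed counts and ICERs per draw, under both
perspectives. Because every screen carries the same unit cost, the
stage-1 ratio scales by the unit cost, so the per-iteration best margin
needs no cost draws and is identical under both perspectives — stage 1 is
therefore cost-free by construction rather than by assumption. ICER
summaries are means over informative draws (non-zero delayed increment),
with the ratio-of-means reported alongside. One master seed spawns three
substreams (stage-1 resampling, stage-2 resampling, cost draws); results
are bit-reproducible. If no iteration yields an informative margin step
(tiny cohorts without STR cases), the analysis falls back to the mid-grid
margin with a classed warning. CEAC curves report, per willingness-to-pay
threshold $\lambda$ (euros per delayed diagnosis avoided), the fraction of
draws with positive net benefit $\lambda(-\Delta d) - \Delta c$.

## Numerical and design choices, in brief

* Intervals: analytic inversion, clamp to [6, 60] months, floor to whole
  months; optional snapping to a 6/12/24/36/48/60 menu (off by default).
* Ties: onset exactly at a screen counts as detected on time.
* Rounding of uniform grade fills: half away from zero.
* Baseline: earliest visit with an observed grade; "at least 5 years
  follow-up" means >= 60 months, the model's maximum interval.
* Exclusions are attributed to the first failing criterion, in the order
  grade availability, baseline STR, follow-up length.
* Gamma fits: `uniroot` on log-shape, tolerance near machine precision;
  fitted quantiles reproduce the range to 1e-6 relative.
* Problem sizes in the test suite are package choices balancing Monte
  Carlo resolution against runtime: 50,000 patients for baseline-mix
  checks, 20,000 for hazard recovery, ~5,000 (7,000 generated) for margin
  curves, 100 patients for oracle equivalence, 1,000 profiles for
  inversion checks.

## Known limitations

* The delayed-diagnosis count per patient is **not monotone in the risk
  margin**: detection requires a screen to coincide with the onset visit,
  and coincidence probability changes non-monotonically as intervals
  lengthen (a 36-month interval can detect an onset at 48 months on time
  where a 24-month interval is late). Aggregate delayed-count curves over
  the margin grid are therefore monotone only up to occasional one-case
  dips, and the fast-progression scenario can occasionally fall one case
  below the slow one for the personalised strategy. Cost curves are
  monotone. The same mechanism makes "pointwise shorter intervals imply
  shorter delays" false in general.
* Delayed *fractions* depend strongly on visit alignment: free-running
  schedules (`align_to_visits = FALSE`) count many small misalignment
  delays that embedded-in-annual-care screening does not.
* The shipped risk-model coefficients are synthetic (see above); clamp
  behaviour and structure are meaningful, absolute intervals for a given
  profile are not.
* Onsets are visit-level by construction; nothing is said about timing
  within a visit interval.
* No QALYs, no treatment costs, no attendance behaviour, no per-eye
  grades: deliberately out of scope.
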