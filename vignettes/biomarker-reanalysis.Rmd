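---
title: "Biomarker-based re-analysis of nutrition trials: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomarker-based re-analysis of nutrition trials: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavatrial)
```

This vignette documents the statistical models behind `flavatrial`, the
assumptions they make, the tunable parameters that matter, and the design
choices taken where more than one reasonable construction existed. It states
no empirical result that the package's tests and acceptance script do not
themselves compute.

## 1. The exposure-misclassification problem

In a randomized nutrition trial, randomized assignment and actual exposure
can disagree in both arms. Placebo-arm participants whose habitual diet
already supplies the intervention dose are effectively exposed;
intervention-arm participants who do not take their pills (and whose diet is
low) are effectively unexposed. Under such two-sided misclassification the
intention-to-treat hazard ratio is a person-time-weighted mixture of exposed
and unexposed hazards in each arm and is therefore attenuated toward 1
relative to the causal effect of actual exposure. Per-protocol censoring at
the first self-reported non-adherence removes part of the intervention-arm
misclassification but inherits the inaccuracy of self-report and does
nothing about the background diet. Classifying participants by a measured
exposure biomarker addresses both sources at the price of (a) losing
participants whose exposure cannot be determined and (b) breaking the
randomization, so that the biomarker contrast is an observational comparison
requiring covariate adjustment.

## 2. Threshold calibration

`fit_dose_response()` fits ordinary least squares of log2 urine concentration
(µM) on daily dose (mg):

$$\log_2 C_i = a + b \cdot d_i + \varepsilon_i,\qquad
  \varepsilon_i \sim N(0, \sigma^2).$$

Only the concentration is log-transformed by default; the predictor is the
untransformed dose. Because dose-escalation designs are sometimes analysed on
a log-dose axis and the original calibration analysis does not pin this down,
both predictor modes are implemented (`dose_transform = "identity"` or
`"log2"`); the identity default follows the stated form of the calibration
model (log-transformed concentration data). Records with non-positive
concentration cannot enter a log-scale fit; they are excluded with a warning
listing their rows and counted in the result, rather than silently dropped.

`derive_threshold()` returns the lower bound of a two-sided interval at the
target dose $d_0$ (500 mg by default), back-transformed:

$$T = 2^{\,\hat a + \hat b d_0 - t_{n-2,\,0.975}\, \mathrm{se}},$$

with `se` either the mean-response standard error (`mean_ci`) or
$\sqrt{\mathrm{se}_{\text{mean}}^2 + \hat\sigma^2}$ (`prediction`). Two
readings of "the bottom 95% CI limit of the expected concentration after the
reference intake" are defensible: the confidence limit of the *mean*
response, or the limit of the *individual* predictive distribution. The
stated rationale for a conservative threshold — inter-individual variability
and the wish to avoid false negatives — concerns individuals, not means, so
the package defaults to the prediction interval; the choice is exposed as a
parameter and both are tested. A Student-t quantile with $n-2$ degrees of
freedom is used rather than a normal quantile because calibration studies
are small. With $\hat\sigma = 0$ both intervals collapse exactly to the
point prediction, which the tests assert.

The standard profile `cosmos_thresholds()` (18.2 µM gVLM, 7.8 µM SREM) is a
documented default, not a recomputation: the original dose-escalation raw
data are not distributed with this package.

## 3. Classification rules

* **Sample rule**: above ⇔ gVLM ≥ T_gVLM **or** SREM ≥ T_SREM. The two
  biomarkers have different half-lives, so the OR captures both recent and
  less recent intake. A value exactly at the threshold counts as above,
  matching the "at least 500 mg/d" reading of the target; the boundary
  convention is asserted in tests.
* **Participant rule**: *biomarker active* if above at baseline or at any
  follow-up visit (the any-visit OR is the natural extension of "either at
  baseline or follow-up" when one to three follow-up samples exist);
  *biomarker control* otherwise; *excluded* if intervention-arm, baseline
  below, and no follow-up sample — for these participants adherence is
  undeterminable. The exclusion is deliberately asymmetric: a placebo-arm
  participant with the same data pattern is a valid control, because
  placebo-arm exposure is determined by the baseline (background-diet)
  sample alone.
* **Edge cases**: a participant with follow-up samples but no baseline
  sample is flagged `unclassifiable` and excluded from all biomarker
  analyses with a diagnostic count (how such patterns should be treated is
  not settled by the source analyses; flagging is the conservative option).
  Below-LOQ concentrations participate in classification as their stored
  numeric values — they are below any realistic threshold by construction —
  while the below-LOQ *statistic* is computed from the flags, requiring both
  biomarkers below their LOQs.
* **Display**: percentages are rounded half-up to integer percent, the
  display convention of the benchmark table; empty denominators give `NA`,
  never 0%.

## 4. Survival models

`fit_cox()` wraps the Cox proportional-hazards partial likelihood with
**Efron tie handling** (the default of the standard survival software this
field uses). Continuous covariates enter as **restricted cubic splines with
3 knots**: outer knots at the 0.1 and 0.9 sample quantiles; the middle knot
is not fixed by the stated design, so the package places it at the median
and makes it configurable. The basis is the truncated-power form

$$s(x) = \frac{(x-t_1)_+^3 - (x-t_2)_+^3 \frac{t_3-t_1}{t_3-t_2}
       + (x-t_3)_+^3 \frac{t_2-t_1}{t_3-t_2}}{(t_3-t_1)^2},$$

linear beyond the outer knots; tests verify it against exact rational-
arithmetic values and against the span of a natural cubic spline basis
(`splines::ns`), an independent construction of the same function space.
Fitting fewer than three distinct values falls back to a linear term with a
warning. Knots are recorded at fitting time so that reference-profile
evaluation (below) uses the identical basis.

The five-model adjustment ladder is: model 1 — sex, age (spline), recruitment
cohort; model 2 — plus BMI (spline), smoking status, aspirin use; model 3 —
plus aHEI (spline), family history, hypertension history; model 4 — model 2
plus randomized assignment; model 5 — model 2 plus aHEI. aHEI is consumed as
a supplied numeric column; constructing it from diet questionnaires is out of
scope. Model 4 deliberately adjusts the biomarker contrast for randomization;
because biomarker group and randomized arm are strongly associated, this
inflates the exposure standard error, which the tests assert as a
collinearity property.

The proportional-hazards assumption is checked per term by the scaled
Schoenfeld-residual test (the `cox.zph` construction) with an identity time
transform by default (the transform is not fixed by the stated design and is
configurable).

**Per-protocol censoring** uses the earliest self-report of missing more
than 8 pills per month, being unsure of the number missed, or outside
supplement use; events after that date become censorings at it. It applies
to all randomized participants, both arms. A flagged report dated after a
recorded event cannot rewind the event; such reports are counted in a
diagnostic attribute.

**Multiple imputation** (`impute_missing()`) is chained-equations with the
event indicator and the Nelson–Aalen cumulative-hazard estimate (computed
once on the full data before imputation) among the predictors — the standard
recipe for Cox-model covariates under a missing-at-random assumption.
Numeric columns use Bayesian linear-regression draws, logical columns
logistic draws, and 3+-level factors multinomial draws. Defaults: m = 10
imputations, 5 chained iterations, seed-controlled. Pooling follows Rubin's
rules (`fit_cox_pooled()`): pooled variance $W + (1+1/m)B$, Barnard–Rubin
style degrees of freedom, and an exact reduction to the single fit when the
between-imputation variance is zero — asserted in tests.

**Adjusted cumulative incidence** (`cumulative_incidence()`) evaluates
$1 - S(t \mid x_{\mathrm{ref}}, \text{group})$ from the fitted model's
baseline hazard. The default reference profile is age 75, male, BMI 25
kg/m², never-smoker, no aspirin, WHI recruitment cohort — the convention of
the source analyses' incidence displays. A reference value outside the
fitted knot range triggers a warning; beyond the outer knots the spline is
linear, so extrapolation is linear on the spline scale.

## 5. Threshold sensitivity

`sweep_thresholds()` re-runs classification *and* the exclusion rule at
every point of a (gVLM, SREM) threshold grid — the excluded set depends on
baseline status and must move with the thresholds — then refits the chosen
model (model 2 by default, matching the published sweep convention). The
default grids are 1–50 µM and 1–30 µM in 1 µM steps. Confidence intervals
are not adjusted for multiple comparisons across cells, matching the
convention of the analysis this mirrors. Cells with fewer than 5 events in
either group are flagged not-estimable rather than reported as numbers. A
single-cell sweep is bit-identical to the standalone biomarker analysis
because both run through the same classification and fitting path.

"No material change" is not defined numerically in the source analyses;
`stability_report()` operationalizes it as: the HR upper 95% confidence
limit stays within ±10% (configurable) of the reference cell's value and on
the same side of 1. The maximal contiguous rectangle around the reference
cell is grown greedily one grid line at a time in a fixed direction cycle,
which is deterministic; it may under-cover non-convex stable regions, a
known and accepted simplification.

## 6. The synthetic cohort generator

`generate_cohort()` draws, per participant: arm; covariates (age ≥ 60 with
sex-specific minima, sex, BMI, smoking, aspirin, recruitment cohort, aHEI,
histories); a latent background-intake class — **zero** (below LOQ, default
5%), **moderate** (lognormal mg/d, median 60, log-sd 0.6, capped below the
reference dose), or **high** (uniform 500–900 mg/d, default 20%) — and a
latent pill-adherence indicator (default 67%). Actual exposure is
"background + supplement if adherent", thresholded at 500 mg/d.

Urine concentrations are drawn from the log2-linear dose–response at the
participant's actual current dose, with the generator's default coefficients
chosen so that the lower 95% normal bound at 500 mg/d equals the standard
thresholds — making generator truth and classification thresholds mutually
consistent. Spot-urine time-of-collection variability is folded into the
lognormal sd rather than modelled separately. Baseline samples exist for
everyone; any follow-up exists with probability 0.315 (matching the ~68%
follow-up missingness of the emulated cohort structure), with 1–3 visits.

Self-reports are six-monthly. The misreporting defaults are chosen so that
true biomarker adherence (67%) and observed self-reported adherence (85%)
coexist, as both figures are reported for the emulated cohort: with
P(adherent ever false-flags) = 0.02 and P(non-adherent never flags) = 0.59,
expected self-reported adherence is 0.67·0.98 + 0.33·0.59 ≈ 0.85.

Event times are exponential per endpoint with the hazard multiplied by
exp(true log-HR) iff actually exposed; all-cause death censors the other
endpoints. Default unexposed rates (events per person-year: total CVD
0.0105, CVD death 0.0018, all-cause death 0.008, major CVD 0.0068) were
chosen to give event counts typical of a trial of this size, age range and
3.6-year follow-up. The per-endpoint draws are otherwise independent: a
cardiovascular death drawn for the CVD-mortality endpoint is not forced to
coincide with the all-cause draw. This keeps every endpoint's cause-specific
hazard exactly proportional (which the parameter-recovery validation needs)
at the cost of cross-endpoint incoherence that a joint competing-risks
construction would avoid; the package's analyses never compare endpoints
jointly, so nothing downstream consumes the incoherent margin.

Randomness: base R has no counter-based RNG stream, so each sub-table
(participants, urine, self-reports, events) is drawn under its own seed
derived deterministically from the master seed; regenerating any one table
is reproducible independently of the others.

The deterministic benchmark cohort (`table1_fixture()`) places biomarker
values above/below the standard thresholds so that every margin of the
published classification table holds exactly. The joint baseline-by-follow-up
overlap within each arm is not published; `solve_table1_overlaps()` searches
all feasible integer unions (placebo ∈ [186, 361], intervention ∈
[706, 934]) for pairs whose implied group-composition percentages round
(half-up) to the published 62%/10%, and selects the pair whose exact
percentages are closest to 62/10 — a deterministic, constraint-solved
choice, not a published figure.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no covariate–outcome confounding (covariates are
outcome-neutral, so the biomarker contrast is unconfounded by construction,
unlike reality); no within-person correlation of repeated urine samples
beyond the shared dose; no measurement-error structure beyond lognormal
noise; no time-varying adherence (adherence is a fixed latent state); no
seasonal or batch effects; no multivitamin co-randomization; no
informative missingness of follow-up samples.

## 7. Validation problem sizes

The package's own validation (tests and acceptance script) uses: 50,000
participants for mixture-tail checks against numerical-integration oracles
(3 standard errors); 100 replicates of 20,000 participants for the
attenuation ordering (|log HR_biomarker| ≥ |log HR_ITT| in ≥ 90/100, PP
between them on average); 100 seeds of 20,000 participants with perfect
classification for parameter recovery, run at an elevated 0.03/person-year
event rate so that the Monte-Carlo standard error of the mean log-HR
(≈ 0.005) sits well inside the ±0.02 recovery band; a 10,000-replicate
parametric bootstrap as the independent oracle for threshold derivation; and
a brute-force grid maximization of the explicit partial likelihood as the
oracle for the Cox fit on a 6-subject dataset.

## 8. Known limitations

* Concentration biomarkers support threshold classification only; no
  absolute-intake estimation is attempted.
* The biomarker contrast is observational; the package adjusts but cannot
  randomize. Model 4 quantifies the cost of forcing randomization back into
  the model.
* No competing-risks (Fine–Gray) modelling; endpoints are analysed with
  cause-specific Cox models.
* The calibration module fits a single-level regression; a repeated-measures
  dose-escalation design would support a mixed model, but the source design
  is not described in enough detail to justify one.
* The stability rectangle is greedy-maximal, not globally maximal, for
  non-convex stable regions.
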