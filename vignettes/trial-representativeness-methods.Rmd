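---
title: "Assessing trial representativeness: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing trial representativeness: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

trialrep quantifies how well randomised-trial populations represent the
patients who actually receive a treatment in routine care. It combines four
complementary lenses — eligibility emulation, comorbidity-burden comparison,
indirectly standardised event ratios, and kidney-function trajectories — and
ships a synthetic-data generator so that every method can be exercised, and
its operating characteristics measured, against known ground truth. This
vignette explains the models behind each stage, the tunable parameters and
their defaults, and the design decisions taken where the methodology was
genuinely open.

```{r setup, message=FALSE}
library(trialrep)
library(dplyr)
```

## The comparison design

Three populations are contrasted for each trial:

1. **trial participants** (individual-level baseline and outcome data);
2. **treated-eligible**: community patients on the index drug who would have
   met the trial's eligibility criteria at their first prescription;
3. **treated-ineligible**: community patients on the drug who would not.

All community measurements are anchored at the *index date* — the first
recorded prescription of the drug class — and use only records strictly
before it (day-granular; "prior to" is strict everywhere). Persons who
joined the database less than a year before their first prescription are
never generated, mirroring the incident-user design and protecting
condition ascertainment.

## Multimorbidity phenotyping

Long-term conditions come from a 57-condition registry, each condition
classed as cardiometabolic (exactly ten circulatory/kidney conditions:
stroke, coronary artery disease, heart failure, peripheral artery disease,
heart valve disorders, arrhythmia, venous thromboembolic disease, aneurysm,
hypertension, chronic kidney disease) or non-cardiometabolic. A condition
is present when any mapped code appears before the index date; counting is
idempotent in duplicate codes and invariant to the coding dialect
(community records and trial medical-history terms use different code
strings for the same condition, exercising the dual-vocabulary mapping that
real linked analyses require). Type 2 diabetes is the index condition and
is never counted.

Two special rules:

* **CKD by eGFR, not codes.** Chronic kidney disease is present iff eGFR
  < 60 mL/min/1.73m² (strict) at index, computed by the 2009 CKD-EPI
  creatinine equation (no race term) from the single most recent creatinine
  before index within a 2-year lookback. The lookback mirrors the
  laboratory-criteria convention; with no usable creatinine the CKD status
  is *unknown*, counted as absent with a logged note (whether absent or
  unknown is the better accounting is not decidable from first principles;
  the choice is logged and visible in the `ckd` column).
* The registry ships as an editable JSON fixture with synthetic code lists;
  real Read/ICD-10/MedDRA lists are deliberately out of scope.

## Eligibility emulation

Criteria are declarative (`age_range`, `sex`, `lab_range`, `egfr_range`,
`diagnosis_required`, `diagnosis_excluded`, `procedure_excluded`) and
conjunctive; OR-logic is expressed by expanding into multiple criteria
sets, keeping every file auditable. Labs use the most recent value before
index within a 2-year lookback, same-day ties broken by record sequence
number (logged). A criterion can be *unevaluable* when its data do not
exist; the missing-data policy is explicit because the right answer is not
obvious: the default `strict` policy treats unevaluable as ineligible
(making "eligible" conservative), while `lenient` ignores unevaluable
criteria. Classification is order-independent and monotone: adding a
criterion can never increase the eligible proportion.

## Comorbidity-count distributions

Counts per population are summarised by maximum-likelihood Poisson or
negative-binomial fits (mean/dispersion parameterisation,
`Var = mean(1 + dispersion * mean)`), so that only *parameters* need cross
a secure-enclave boundary for joint plotting — never row-level counts.

Fit is assessed with a Kolmogorov–Smirnov-type statistic (the maximum
absolute ECDF–CDF gap over the observed support). Because the data are
discrete and the parameters estimated from the same sample, the classical
KS reference distribution is badly calibrated; p-values therefore come from
a parametric bootstrap (default 999 replicates, seeded) that re-simulates
from the fitted law and refits. Family selection first asks whether the
families are distinguishable at all, via a boundary-corrected
likelihood-ratio test on the dispersion (the null sits on the edge of the
parameter space, so the statistic is referred to a 50:50 mixture of a point
mass at zero and χ²₁). Without evidence of overdispersion the parsimonious
Poisson is reported — this operationalises "ties go to fewer parameters",
since on equidispersed data the two fitted laws coincide and their
goodness-of-fit p-values differ only by Monte-Carlo noise. When
overdispersion is real, the family with the larger bootstrap p wins.

## Observed/expected event ratios

The core transportability machinery. In the treated-eligible community,
first-event rates (serious adverse events — any hospitalisation or death —
plus MACE and cause-specific death) are modelled by Poisson or
negative-binomial regression with a log link and an offset of log
person-time at risk, where time at risk runs from index to the first of
event, practice deregistration, death, or the end of the trial-matched
window. Model 1 standardises by age and sex; model 2 adds the comorbidity
count.

Flexibility comes from fractional polynomials: up to two terms per
continuous covariate with powers from {−2, −1, −0.5, 0, 0.5, 1, 2, 3},
power 0 meaning log and a repeated power p contributing (x^p, x^p·log x).
Age is pre-scaled by 1/10 and count shifted by +1 before transforming —
FP bases require strictly positive inputs and the scaling keeps high powers
numerically tame. Structure search is fully logged: family by the
boundary-corrected LRT; powers by the closed-test procedure on deviance
(best FP2 vs null on 4 df, vs linear on 3 df, vs best FP1 on 2 df, α=0.05),
with the variable kept linear rather than dropped when no effect is found,
because the analysis models standardise by age and sex by design;
interactions (age×sex, sex×count, age×count) kept only when the LRT is
significant *and* AIC improves. During the search the negative-binomial
dispersion is held at its linear-structure estimate for speed and freed in
the final refit.

Only the coefficient vector β and covariance Σ leave the "enclave"
(`write_rate_model()`); the expected count on the trial side is
E = Σᵢ exp(xᵢβ)·tᵢ over participants' covariates and person-time. Three
choices the methodology leaves open are made explicit and configurable:

* **Per-participant follow-up**, not nominal trial duration, is used for tᵢ
  when available — the more faithful refinement, and for exponential first
  events it makes the offset algebra exactly calibrated (E[observed] =
  Σ λᵢ E[min(Tᵢ, τ)]).
* **Jeffreys beta prior** (observed + ½, n − observed + ½) for the observed
  first-event proportion: the conjugate family is dictated by the binomial
  likelihood, the noninformative prior is a choice.
* **Negative-binomial expected counts use the mean function only** — the
  dispersion affects Σ, not E[count].

Uncertainty in the ratio O/E combines 10,000 draws β_s ~ MVN(β̂, Σ) (giving
E_s) with 10,000 draws from the beta posterior (O_s = p_s·n), via
independent substreams of one seed; the 95% interval is the 2.5th/97.5th
centiles of O_s/E_s. Draws with nonpositive expected counts are rejected
and logged; more than 1% rejections aborts rather than silently distorting
the interval. The point estimate always uses β̂ and the observed count
directly, so `ratio = observed/expected` exactly.

## eGFR total slope

Kidney-function decline is summarised by the annualised *total* slope from
baseline: trajectories are piecewise linear with an acute segment over days
0–21 (the first post-treatment sample point in trial schedules) and a
chronic annual slope thereafter,

  eGFR(t) = b + a·min(t,21)/21 + s·max(t−21,0)/365.25 + ε.

The total slope over a window of W years is (a + s·(W − 21/365.25))/W; the
chronic slope is reported alongside for diagnostics. Total rather than
chronic is the headline because routine care rarely measures eGFR in the
weeks right after initiation, so the acute segment cannot be estimated
precisely there — the total slope remains well identified.

Mixed-model structure: reference analyses of trial data use an unstructured
residual covariance over a fixed visit grid, but routine-care visits are
irregular, so the default engine here is a random intercept + random
chronic slope per person with independent residuals, which handles any
visit pattern; an `mmrm` engine (generalised least squares with
unstructured residual correlation and per-visit variances) is available
when the data lie on a declared common grid. This deviation from the
fixed-grid convention is deliberate and documented. Persons need a baseline
(most recent value on/before day 0), at least one post-baseline value, and
at least two years of follow-up — shorter windows have not been validated
for predicting kidney outcomes, and the per-person spans below that
threshold are dropped with a logged count. Fewer than ten retained persons
refuses to fit. On degenerate (e.g. noise-free) data where the mixed model
cannot be estimated, an exact fixed-effects spline fit with per-person
intercepts takes over.

## The synthetic-data generator

The generator defines the study conditions for every recovery test; its
defaults are fixed once, not tuned:

| parameter | default | rationale |
|---|---|---|
| `n_community`, `n_trial` | 20,000 / 2,000 | community scale of a national prescribing cohort, trial scale of a large outcome trial |
| age mean (SD), % female | 62 (10), 39% | demographics of incident users of this drug class |
| condition prevalences | sum ≈ 2.7 | mean comorbidity count of treated patients; hypertension (0.30), depression, osteoarthritis, coronary artery disease lead |
| `comorbidity_dispersion` | 0.4 | variance/mean ≈ 2 at the default mean — clearly overdispersed counts |
| `base_event_rate` | 0.12/person-year | serious-adverse-event (hospitalisation/death) scale for treated type 2 diabetes |
| `rate_log_hr_per_comorbidity` | 0.25 | ≈ 28% higher hazard per condition |
| `rate_log_hr_age_per_year`, `sex_log_hr` | 0.03, −0.1 | modest age gradient, slightly lower female rates |
| `selection_log_odds_per_comorbidity` | −0.5 | marked under-representation of multimorbidity beyond explicit criteria |
| `cv_death_fraction` | 0.4 | cardiovascular share of deaths in this population |
| baseline eGFR mean (SD) | 80 (18) | ≈ 13% below 60, i.e. a realistic CKD prevalence |
| `acute_change`, `chronic_slope`, `residual_sd` | −3, −2, 3 | acute dip and chronic decline on the scale reported for these drugs; routine-lab noise |
| `followup_years`, `dereg_rate` | 3, 0.02/yr | outcome-trial horizon; practice-switching rate |

Comorbidities are per-condition Bernoulli draws with probabilities scaled
by a per-person gamma frailty (mean 1, variance d), so condition
*identities* exist for phenotyping and eligibility while total counts are
overdispersed with variance/mean ≈ 1 + d·mean (a small Bernoulli-thinning
correction, (1+d)·Σp²/m, is the price of having identities; it is < 4% at
the defaults). CKD arises from the baseline eGFR distribution rather than
a prevalence parameter, and creatinine values are obtained by inverting
the CKD-EPI equation, so the laboratory stream and the CKD state are
mutually consistent. First events follow an exponential law, log-linear in
age (centred at 60), sex and the true comorbidity count; an event is a
death with probability 0.2, and deaths take an underlying-cause code
beginning "I" with probability `cv_death_fraction` (independent of
comorbidity by default; a log-odds coupling is available). Deregistration
is independent exponential censoring — the dependence between comorbidity
and deregistration is not described in the sources this design follows, so
independence is the declared default. Trial sampling applies the
eligibility engine first, then samples without replacement with weights
exp(selection_log_odds × count).

Time is internal in days, with 365.25 days/year for every annualised
quantity; rates configured per person-year are converted once, avoiding
calendar ambiguity.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: disease natural history and condition clustering
beyond a single frailty; recurrent hospitalisations beyond the first few
events; calendar-time prescribing drift; measurement error in diagnosis
codes; informative deregistration; treatment effects (both trial arms share
one outcome law, which is the correct null for machinery tests but says
nothing about efficacy transport).

## Numerical choices and degenerate inputs

* Dispersion estimates truncated at (or below) zero, and negative-binomial
  profile likelihoods that dip below the Poisson boundary, collapse to the
  Poisson limit rather than erroring.
* Constant covariate columns are collinear with the intercept and are
  dropped with a warning naming them.
* All-zero count vectors cannot identify a dispersion: degenerate fit,
  Poisson(0) fallback with a warning.
* Day-0 events are prevalent, not incident, and never count; admission
  streams end at deregistration.
* Every random stage derives an independent substream from one user seed
  (`derive_seed()`), so identical configurations reproduce outputs
  bitwise while stages stay independently re-runnable.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the calibration study at
20,000 community persons and 2,000 trial participants with 200 replicates
(1,000 Monte-Carlo samples per interval), the attenuation and
family-selection studies at 100 replicates, slope recovery at 500 persons
× 100 replicates, and the fractional-polynomial selection study at 40
replicates of n = 20,000 — sizes at which each property's Monte-Carlo error
is comfortably below its acceptance margin.

## Known limitations

* The synthetic vocabulary is flat; real code hierarchies (and their
  mapping ambiguities) are out of scope, so phenotyping performance on real
  Read/ICD-10/MedDRA data is not evidenced here.
* Eligibility emulation cannot represent investigator discretion or
  criteria requiring data absent from routine records (e.g. ethnicity); the
  strict/lenient policy bounds, but does not resolve, the resulting
  uncertainty.
* The O/E framework standardises by measured covariates only; it is not a
  causal transport estimator and does not reweight for unmeasured
  differences between trial volunteers and routine patients.
* The slope engine's default covariance structure trades the unstructured
  residual model for robustness to irregular visits; on a common grid the
  `mmrm` engine recovers the conventional analysis.
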