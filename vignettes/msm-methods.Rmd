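---
title: "Marginal structural modelling of antidepressant exposure and cardiovascular events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal structural modelling of antidepressant exposure and cardiovascular events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmcvd)
```

## The estimation problem

Observational claims cohorts of people with post-traumatic stress disorder
(PTSD) are a natural place to study whether antidepressant medication
changes the risk of major adverse cardiovascular events (MACE), but the
treatment process is entangled with the disease process: psychiatric
symptom severity and comorbidity raise both the probability of being
prescribed an antidepressant and the risk of a cardiovascular event, and
are themselves altered by prior treatment. Covariates of this kind —
*time-varying confounders affected by prior treatment* — break ordinary
regression adjustment: conditioning on them blocks part of the confounding
but simultaneously opens collider paths through the shared latent severity
process, so both the "adjust at baseline" and "adjust at every interval"
Cox analyses are biased for the causal effect.

The standard remedy is a marginal structural model (MSM) estimated by
inverse-probability-of-treatment (IPT) weighting. Follow-up is discretised
into 91-day intervals indexed by $k$; for person $i$, $A_{ik}$ is the
antidepressant exposure indicator in interval $k$, $L_{ik}$ the
time-varying covariate block (psychiatric comorbidity code-group
indicators, psychiatric hospitalization, check-up values), $V_i$ the
baseline block, and $Y_{ik}$ the event indicator. The stabilized weight is

$$
sw_{ik} \;=\; \prod_{j \le k}
\frac{P(A_{ij} = a_{ij} \mid \bar A_{i,j-1}, V_i)}
     {P(A_{ij} = a_{ij} \mid \bar A_{i,j-1}, \bar L_{ij}, V_i)},
$$

with both probabilities estimated by pooled logistic regression over
person-periods. The outcome model is a weighted pooled logistic
(discrete-time survival) regression of $Y_{ik}$ on current exposure, a
flexible interval term, the treatment-history encoding and $V_i$; because
events are rare in every interval, the exponentiated exposure coefficient
approximates a hazard ratio. Inference uses a person-clustered sandwich
covariance, which is conservative for estimated weights.

Two deliberate modelling choices deserve emphasis:

* **History in the numerator requires history in the outcome model.** The
  weight numerator conditions on prior-interval treatment and an
  ever-treated flag (the parsimonious standard encoding). Stabilizing on
  history leaves the pseudo-population's current exposure dependent on past
  exposure, so the outcome model includes the same history terms; the
  reported hazard ratio is the current-interval treatment effect. Dropping
  the history terms while keeping a history-stabilized numerator produces a
  measurably biased estimate — we verified this directly in simulation.
* **Both e-value conventions are computed.** For a hazard ratio $RR \ge 1$
  (inverted first if below 1) the e-value is
  $E = RR + \sqrt{RR(RR - 1)}$: the minimum strength of association an
  unmeasured confounder would need with both exposure and outcome to
  explain the estimate away. Published analyses in this area mix two
  conventions — the formula applied to the point estimate and applied to
  the confidence limit closer to the null — so `evalue_ci()` returns both,
  labelled, rather than guessing one.

## What the synthetic generator emulates

The real data for studies of this design are restricted national insurance
databases, so the package ships a claims-style generator
(`simulate_cohort()`) whose causal structure reproduces the
treatment-confounder feedback loop, plus a counterfactual oracle
(`counterfactual_truth()`) that computes the true marginal "always treated
vs never treated" hazard ratio by simulating both regimes directly.

The generator draws, per person and 91-day interval:

* a latent treatment-free severity core $\tilde S_k$, a stationary AR(1)
  process (autocorrelation 0.7);
* a recorded severity $S_k = \tilde S_k + \gamma B_k$, where $B_k$ is an
  exponentially discounted burden of past treatment. The default feedback
  coefficient $\gamma$ is **positive**: treated patients stay engaged with
  psychiatric services and accrue *more* recorded comorbidity codes, a
  surveillance effect that reproduces the qualitative finding that
  conventional time-varying adjustment is biased **toward the null**
  relative to the MSM;
* comorbidity code-group flags (psychotic, bipolar, depressive, anxiety,
  somatoform) emitted with log-odds increasing in recorded severity, and a
  psychiatric-hospitalization flag;
* treatment $A_k$ with log-odds increasing in the number of active
  comorbidity flags, in prior treatment (episode persistence) and slightly
  in female sex. Assignment depends on latent severity only *through the
  emitted flags*, so an analysis-side logistic model on the flags is
  exactly correctly specified — without this the weight-calibration
  checks would be testing an unattainable target;
* the event, with log-odds depending on current treatment and on the
  treatment-free core $\tilde S_k$. Past treatment therefore influences
  future *recorded* covariates (feedback) but not the counterfactual
  hazard, keeping the current-exposure MSM correctly specified while the
  conventional time-varying model remains biased through collider
  stratification on the flags;
* administrative censoring at a constant per-interval rate, and a hard
  horizon at `n_intervals`.

The panel is rendered into claims tables: a PTSD index claim (ICD-10
F43.1) at day 0, a routine follow-up claim each interval (so the last
claim defines the end of follow-up), outpatient F-code claims for the
comorbidity flags, inpatient admissions for hospitalizations, WHO-DDD
priced antidepressant prescriptions, periodic health check-ups, and
inpatient/emergency MACE claims with revascularization or brain-imaging
markers (or a cardiovascular death record). Identical parameters and seed
give byte-identical tables; each table has its own derived random stream.

Defaults are calibrated to qualitative features of the cohorts this design
emulates: mean index age near 40 with a female majority, roughly half the
cohort ever treated, SSRIs the commonest class, and a per-interval event
fraction well inside the rare-outcome regime (the parameter validator
rejects configurations whose worst-case per-interval hazard reaches 0.1,
since the hazard-ratio reading of the discrete-time odds ratio depends on
rarity). The confounding strength (0.3 log-odds per active comorbidity
flag) and feedback strength ($\gamma = 1.2$) were fixed once, after pilot
runs, at values where the conventional comparator's bias is material while
the IPTW estimator's finite-sample bias at cohort sizes of a few thousand
is negligible; weight products over many intervals are heavy-tailed, and
pushing confounding much harder makes *any* weighting estimator unusable
at desk scale — a well-known practical limit of IPTW, not a defect of the
implementation.

What the generator does **not** emulate: medication adherence gaps (claims
overstate compliance), national billing-code dialects, calendar seasonality
(the calendar is abstracted to integer days with exactly 91-day
intervals), informative censoring, competing risks of non-cardiovascular
death, and dose titration within a prescription. Tests passing on this
generator therefore demonstrate correctness of the estimation machinery
under the stated causal structure, not robustness to these additional
features of real claims data.

## Cohort construction conventions

* Day 0 is the index date (first PTSD claim); intervals are half-open
  $[91k, 91(k+1))$ and 0-based, so an event on day 91 falls in interval 1.
* Eligibility filters run in a fixed order for the attrition tally —
  (i) aged 18 or younger at index, (ii) missing sex/birth year/premium
  band, (iii) never checked up, (iv) MACE before index, (v) antidepressant
  before index — though the retained set is order-invariant.
* Follow-up ends at the first MACE or the last claim; non-MACE
  cardiovascular diagnoses do not terminate follow-up. Administrative
  censoring is treated as noninformative (no censoring weights).
* Check-up covariates use last observation carried forward: the value for
  interval $k$ is the most recent measurement before the interval's end.
  Comorbidity flags are per-interval presence indicators, not carried
  forward — a code's absence is informative in claims data.
* Outcome adjudication requires inpatient or emergency setting; "same
  treatment session" is operationalized as same-day claims at the same
  setting, with procedure flags carried on the claim rows. Same-day
  qualifying events of different types resolve by the fixed precedence
  CAD-with-revascularization > ischaemic stroke > haemorrhagic stroke >
  cardiovascular death, with a warning.
* Prescriptions crossing interval boundaries allocate their defined daily
  doses pro-rata by day overlap, conserving total dose mass. The dose
  transform is $\log(1 + \text{cumulative DDD})$ so untreated
  person-periods are representable at dose 0.
* The comorbidity-exclusion reanalysis restricts the anxiety group to
  F40–F42: the F43 block contains the cohort-defining PTSD code, so
  excluding it verbatim would empty any PTSD cohort.

## Numerical choices

* Fitted treatment probabilities are clipped to $[10^{-8}, 1-10^{-8}]$
  before weight products; the number of clipped rows is reported. Fitted
  probabilities within $10^{-10}$ of 0 or 1 are treated as separation and
  raise a positivity error naming the covariate pattern.
* Weight-truncation percentiles use linear-interpolation quantiles
  (type 7), computed over all person-period weights; the (0, 100) pair is
  the exact identity and is always included as the sweep's reference.
* The baseline hazard uses a categorical interval term for the first 12
  intervals with a linear tail beyond (all-categorical when follow-up is
  shorter).
* The dose–response spline is a degree-5 basis of log cumulative DDD with
  interior knots at the 5/25/50/75/95 percentiles of positive cumulative
  dose (duplicate knots merged with a warning), anchored so the curve is
  exactly 1 at dose 0; pointwise bands use the delta method on the
  clustered covariance.
* Dose–response weights discretize interval dose into zero plus tertiles
  of the positive doses and use multinomial numerator/denominator models;
  with two levels the code reuses the binary logistic pathway, so the
  binary collapse reproduces `compute_weights()` exactly rather than
  approximately.
* The clustered sandwich is computed in-package from the glm's QR
  decomposition (it is called thousands of times in replicate studies) and
  is tested for agreement with `sandwich::vcovCL`.
* The counterfactual oracle reports the unpaired binomial standard error
  for its log hazard ratio. Regimes share random draws, so this is an
  upper bound on the Monte-Carlo uncertainty.

## Problem sizes used by the test suite

The validation studies are sized to run comfortably on a single CPU:
weight calibration uses one cohort of 20 000 persons over 8 intervals;
parameter-recovery and null-calibration studies use 200 replicates of
5 000 persons over 12 intervals with the oracle evaluated once at 200 000
persons per regime; model cross-checks use cohorts of 8 000–50 000 where a
single fit suffices. These sizes give Monte-Carlo standard errors around
0.01 on mean log-hazard-ratio bias, adequate for the documented tolerance
of 0.02.

## Known limitations

* The hazard-ratio reading of weighted logistic coefficients requires rare
  per-interval events; the generator enforces this, but the fitting
  functions will happily run on non-rare data where the odds-ratio/
  hazard-ratio gap matters.
* IPT weighting assumes positivity; the package probes it (truncation
  sweep, log-weight diagnostics, separation errors) but cannot repair
  genuine violations.
* The dose–response weight model conditions on the same covariate sets as
  the binary model; continuous-dose density-ratio weights are out of
  scope.
* Cause-of-death linkage is simplified to a death register with an ICD-10
  "I" cause; real vital-statistics linkage is messier.
* E-values address unmeasured confounding only under the rare-outcome
  risk-ratio approximation; they are reported to two decimals half-up,
  matching conventional presentation.
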