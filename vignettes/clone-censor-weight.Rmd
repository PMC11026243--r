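---
title: "Emulating anticoagulant initiation-threshold trials with clone-censor-weight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating anticoagulant initiation-threshold trials with clone-censor-weight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the estimand

Elderly patients newly diagnosed with non-valvular atrial fibrillation
(AFib) on top of an existing cancer face a genuine timing decision: start an
oral anticoagulant (OAC) now, at a low stroke risk, or wait until the
CHA2DS2-VASc score — the standard 0-9 stroke-risk score in AFib — climbs
higher. Because no randomized trial compares these *dynamic* strategies,
`ccwemu` emulates one on longitudinal person-month data. The strategies are
"initiate OAC in the first month the CHA2DS2-VASc score reaches k" for k in
{1, 2, 4, 6}, plus "never initiate" as the reference; the estimand is the
observational analog of the per-protocol effect on 12-month ischemic stroke
and major bleeding hazards.

The difficulty is twofold. Assigning patients by what they eventually did
misaligns time zero with assignment (immortal time bias), and initiation is
confounded by indication: clinicians treat high-score patients, who are
also at the highest stroke risk. The clone-censor-weight (CCW) design
addresses both:

1. **Clone.** Every eligible patient enters *every* strategy at the common
   time zero (AFib diagnosis month). Clones whose month-0 data already
   contradict their strategy (e.g. a baseline initiator cloned into the
   never arm) are deleted.
2. **Censor.** A clone is artificially censored in the first month its
   patient's observed behavior deviates from the assigned strategy:
   initiating before the score has ever reached k, failing to initiate by
   the end of the grace window after first crossing k, or initiating at all
   in the never arm.
3. **Weight.** Artificial censoring is informative (high-score patients are
   censored from the never arm precisely when their risk is highest), so
   remaining clone-months are weighted by cumulative unstabilized inverse
   probabilities of their observed, strategy-consistent behavior — an IPTW
   factor for treatment decisions times an IPCW factor for loss to
   follow-up — estimated from pooled logistic models on the uncloned panel.

Effects are summarized by a weighted pooled logistic (discrete-time hazard)
model of the monthly event on regimen indicators and time terms. With rare
monthly events the hazard odds ratio is read as a hazard ratio. Because a
patient's clones are correlated, the variance is a sandwich clustered on
the original patient — equivalently a GEE with independence working
correlation — which is conservative for this design. Unstabilized weights
are used deliberately; a stabilizing numerator model is not offered because
stabilization is not generally valid for this kind of artificial-censoring
design.

## Parameters that matter

* `grace_months` (default 1). How quickly a threshold-arm patient must
  initiate after first crossing k: in the crossing month or the next.
  Monthly covariate resolution makes a sub-month requirement unobservable;
  grace 0 is available. Inside the grace window either behavior is
  protocol-consistent, so the per-month weight factor there is exactly 1;
  at the deadline the factor is 1/p-hat (initiation required), and in
  must-wait months it is 1/(1-p-hat).
* `follow_up_months` (default 12, sensitivity 36). Administrative
  censoring horizon. Months are 0-indexed from the AFib index month, so no
  output row has month >= `follow_up_months`.
* `truncation_percentile` (default 99, sensitivity 95). Cumulative weights
  are capped at the linear-interpolation sample percentile of the *pooled*
  clone-month weight distribution across arms. Truncation trades a small
  bias for variance; percentile 100 is the identity.
* Weight/outcome model time terms: linear + quadratic month by default,
  month indicators (`"indicator"`) for a saturated-in-time fit. With a
  single arm, unit weights and indicator time, the standardized survival
  curve reproduces the discrete product-limit (Kaplan-Meier) estimator
  exactly, which is how the curve code is tested.

## Conventions that fix ambiguity

* **Within-month ordering** (generator and compliance alike): covariate and
  score update -> initiation decision -> outcome, death and dropout draws.
  Hence initiating in the month the score first crosses k is compliant.
* **Censoring precedes same-month outcomes.** An event in a clone's
  deviation month is not counted for that clone and the deviation month
  contributes no person-time; per-protocol person-time never includes
  non-compliant exposure.
* **Baseline violations are deletions, follow-up violations are
  censorings** — two distinct mechanisms, applied by
  `apply_baseline_exclusion()` and `apply_artificial_censoring()`.
* **Death and loss to follow-up end follow-up** (censoring), they are not
  modelled as competing risks.
* **Treatment is absorbing.** The strategies concern initiation timing
  only; discontinuation and agent switching are out of scope.
* Weight models are fitted on the **uncloned** panel and predicted onto
  clones, so a patient's identical history is not counted five times.
* Arms with zero events are excluded from the outcome fit and reported as
  undefined HRs rather than divergent ones; if the *reference* arm has no
  events the fit errors.

## What the synthetic generator emulates

`simulate_cohort()` produces the statistical structure the estimator
assumes, not a literal claims feed: an elderly (>= 66, truncated-normal
ages around 77) AFib + cancer cohort with monthly rows; absorbing
CHA2DS2-VASc component flags that switch on at a constant monthly rate
(the annual age increment is the only deterministic score transition);
score-confounded initiation `logit p = intercept + per_point * score`;
stroke/bleed hazards `baseline * score_HR^score * OAC_HR^[on OAC]`; and
independent death and dropout hazards. A single seeded RNG stream with a
documented draw order makes runs bit-reproducible.

Default calibration, chosen once: baseline monthly hazards (stroke 0.001,
bleed 0.0006) put the uninitiated arm near the published incidence for
this population (~35 strokes and ~17 major bleeds per 1000 person-years);
the initiation intercept/slope (-4.6, 0.25) give roughly one in four
patients initiating within 12 months; prevalences put the mean baseline
score near 4. Score-transition rates over follow-up are not reported
anywhere for this population, so the monthly component progression rate
(0.01) is a free parameter, not a calibrated one.

What the generator deliberately does **not** reproduce: raw ICD/NDC claim
streams (covariates are boolean flags), missing data (panels are complete;
the pipeline fails fast on missing required fields instead of imputing),
OAC agent/dose detail, and outcome recurrence (only the first stroke and
first bleed are modelled). A green parameter-recovery test therefore
establishes that the estimator recovers effects *under the assumed data
law* — correctly specified weight models, monotone scores, independent
dropout — not that it is robust to claims-data pathologies.

`counterfactual_truth()` is the validation oracle: it replays the same
patients with treatment *forced* to follow a regimen (and, sharing random
draws, the never regimen) and summarizes the truly randomized contrast
with the same pooled-logistic functional the weighted analysis reports.
Forced runs consume random draws in the same order as observational runs,
so with a null treatment effect both arms produce identical histories and
the true log-HR is exactly zero.

## Design choices where the design was open

* **Sequential first-hit attrition.** Eligibility criteria are applied in
  a fixed, documented order and each excluded patient is attributed to the
  first criterion failed, as flowchart reporting requires; the order
  affects per-criterion counts, never the final cohort.
* **Pooled truncation.** "Total weights" are treated as one pooled
  distribution across arms when computing the truncation cap, rather than
  per-arm caps.
* **HAS-BLED without labile INR.** Claims data carry no INR laboratory
  values, so the claims-adapted 7-component sum is used (maximum 7).
* **No bootstrap by default.** Cluster-robust CIs are reported; a seeded
  non-parametric bootstrap over whole patients (`bootstrap_hr()`) is
  provided as an opt-in alternative but is expensive and intentionally not
  the default.
* **No-event guard asymmetry.** A panel with no initiation events cannot
  support the design at all, so `fit_initiation_model()` errors; a panel
  with no dropout is perfectly analyzable, so `fit_dropout_model()` warns
  and sets all censoring factors to 1.

## Worked example

```{r, eval = FALSE}
library(ccwemu)

cfg <- run_config(sim = sim_config(n_patients = 5000), seed = 2024,
                  out_dir = "ccw_out")
res <- run_emulation(cfg)
res                      # per-arm events, person-years, rates, HRs
results_table(res)       # tidy regimen x outcome table
res$attrition            # eligibility flowchart counts
weight_diagnostics(res$clones)

# validate against the forced-regimen oracle
truth <- counterfactual_truth(cfg$sim, regimen("threshold", 4),
                              n_mc = 50000)
truth$hr
```

## Known limitations

* The hazard-ratio summary assumes a time-averaged (proportional) regimen
  effect; true contrasts of threshold regimens are time-varying because
  exposure begins only after crossing.
* Unstabilized cumulative weights are heavy-tailed; with strong
  confounding the deadline factor 1/p-hat can be large, and results at
  small n are sensitive to the truncation percentile.
* Cluster-robust CIs are conservative (clones are near-duplicates), so
  nominal 95% intervals over-cover under the null.
* Positivity is assumed: predicted initiation and dropout probabilities
  must stay strictly inside (0, 1); the weight code errors (or warns near
  the boundary) rather than silently extrapolating.
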