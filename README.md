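# ccwemu

Clone–censor–weight emulation of a target trial comparing **dynamic oral
anticoagulant (OAC) initiation strategies** in elderly patients with atrial
fibrillation (AFib) and cancer.

## The problem

When should a cancer patient newly diagnosed with AFib start
anticoagulation? The strategies of interest are *dynamic*: "initiate OAC in
the first month the CHA₂DS₂-VASc score reaches *k*" for k ∈ {1, 2, 4, 6},
versus "never initiate" as reference. Comparing them in observational
claims data faces immortal time bias (time zero vs. assignment
misalignment) and confounding by indication (high-score patients are both
more likely to be treated and more likely to stroke). The
clone–censor–weight (CCW) estimator handles both:

* **clone** — every eligible patient enters every strategy at the common
  time zero (AFib diagnosis month); month-0 violators are deleted;
* **censor** — a clone is artificially censored in the first month its
  patient's behavior deviates from the assigned strategy (premature
  initiation, missing the grace deadline after first crossing *k*, or any
  initiation in the never arm);
* **weight** — remaining clone-months get cumulative unstabilized inverse
  probability weights, `w(t) = Π_{s≤t} 1/P(consistent treatment at s | history)
  × 1/P(remaining under observation at s | history)`, from pooled logistic
  models for initiation and dropout, truncated at the pooled 99th
  percentile.

Per-regimen monthly hazards are then modelled by a weighted pooled logistic
regression (discrete-time hazard model) with regimen indicators and time
terms; hazard ratios vs. the never arm come with sandwich 95% CIs clustered
on the original patient (a GEE with independence working correlation);
standardized survival curves are `S(t) = Π_{s<t} (1 − ĥ(s))` with weighted
hazard averaging. Incidence rates are reported per 1000 person-years.

Because the real linked registry/claims cohort is restricted-access, the
package ships a **synthetic cohort generator** (`simulate_cohort()`) with
score-confounded initiation and score/treatment-dependent hazards, plus a
**forced-regimen Monte Carlo oracle** (`counterfactual_truth()`) so the
whole pipeline is validated by parameter recovery.

## Worked example

```r
library(ccwemu)
cfg <- run_config(sim = sim_config(n_patients = 5000), seed = 2024)
res <- run_emulation(cfg)
res
```

```
Clone-censor-weight emulation
  patients: 5000 (eligible: 3430); clones: 17150 (post-exclusion: 16962, deviation-censored: 11048)
  follow-up: 12 months; grace: 1; truncation: p99 (cap 39.623)
  outcome: stroke
   regimen events person_years rate_per_1000py    hr lower upper
1:     ge1     16        449.0           35.63  0.55  0.17  1.81
2:     ge2     16        463.0           34.56  0.56  0.17  1.82
3:     ge4     41       1125.3           36.43  0.48  0.21  1.11
4:     ge6     85       2225.7           38.19  0.68  0.59  0.79
5:   never    121       2601.8           46.51    NA    NA    NA
  outcome: bleed
   regimen events person_years rate_per_1000py    hr lower upper
1:     ge1     14        450.2           31.10  1.09  0.33  3.59
2:     ge2     14        464.2           30.16  1.09  0.33  3.61
3:     ge4     21       1131.2           18.56  1.19  0.41  3.46
4:     ge6     43       2241.9           19.18  1.18  0.57  2.44
5:   never     55       2622.4           20.97  NA    NA    NA
```

Reading this: each row is one strategy's clone arm after deviation
censoring and weighting. `events`/`person_years` are per-protocol counts
(a clone's follow-up ends at its deviation month, censoring preceding
same-month outcomes), `rate_per_1000py = events/person_years × 1000`, and
`hr` is the weighted discrete-time hazard ratio vs. the never arm with its
cluster-robust 95% CI. In this simulated world the generator's true OAC
stroke hazard ratio is 0.6; the ge6 arm — where nearly everyone eventually
crosses the threshold and exposure time is longest — shows it most
clearly (HR 0.68, CI 0.59–0.79). The forced-regimen oracle for the ge4
strategy on the same configuration gives a true marginal HR of 0.68
(`counterfactual_truth(cfg$sim, regimen("threshold", 4), n_mc = 20000)`),
which the weighted estimate (0.48, CI 0.21–1.11) covers.

`res$attrition` is the eligibility flowchart (age, enrollment, prior OAC,
valvular disease/VTE, recent stroke, recent surgery/bleed, ESRD — applied
in that order, first hit counted), `weight_diagnostics(res$clones)` the
per-arm weight distribution table, and `run_sensitivity_suite(cfg)` the
36-month / no-metastatic / no-thrombocytopenia / 95th-percentile variants.

A command-line interface wraps the same pipeline:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/ccwemu.R", package = "ccwemu"))')
Rscript "$CLI" simulate --config cfg.json --out panel.csv --seed 7
Rscript "$CLI" emulate  --config cfg.json --out-dir ccw_out --seed 7
Rscript "$CLI" report   --dir ccw_out
```

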