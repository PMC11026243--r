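library(data.table)

# small default cohort for structural tests
small_config <- function(n = 300, seed = 101, months = 12, ...) {
  sim_config(n_patients = n, seed = seed, max_months = months, ...)
}

# 20-patient, 3-month fixture with busy initiation/dropout so every
# compliance and weighting rule is exercised (oracle-equivalence tests)
fixture_config <- function(seed = 42) {
  sim_config(
    n_patients = 20, seed = seed, max_months = 3,
    score_progression_rate = 0.10,
    initiation = list(intercept = -2, per_point = 0.3),
    hazards = list(stroke = 0.02, bleed = 0.01, death = 0.05, dropout = 0.10),
    effects = list(oac_stroke_hr = 0.6, oac_bleed_hr = 1.4,
                   score_stroke_hr = 1.3, score_bleed_hr = 1.2))
}

# event-rich strongly confounded world: score drives both initiation
# (per-point log-odds 0.5) and stroke (HR 1.5/point); true OAC stroke HR 0.6
confounded_config <- function(n, seed, oac_hr = 0.6) {
  sim_config(
    n_patients = n, seed = seed,
    initiation = list(intercept = -5, per_point = 0.5),
    hazards = list(stroke = 0.002, bleed = 0.0006, death = 0.010,
                   dropout = 0.005),
    effects = list(oac_stroke_hr = oac_hr, oac_bleed_hr = 1.4,
                   score_stroke_hr = 1.5, score_bleed_hr = 1.2))
}

# full clone/censor/weight prep on a simulated cohort
prep_clones <- function(cfg, grace = 1L, regimens = default_regimens(),
                        percentile = 99, spec = weight_spec()) {
  pan <- score_panel(simulate_cohort(cfg))
  el <- apply_eligibility(pan)$panel
  cl <- expand_clones(el, regimens)
  cl <- apply_baseline_exclusion(cl, grace)
  cl <- apply_artificial_censoring(cl, grace)
  wm <- suppressWarnings(weight_model(fit_initiation_model(el, spec),
                                      fit_dropout_model(el, spec)))
  cl <- compute_cumulative_weights(cl, wm, grace)
  cl <- truncate_weights(cl, percentile)
  list(panel = pan, eligible = el, clones = cl, wm = wm)
}

quiet_run <- function(config) suppressWarnings(run_emulation(config))

# hand-built single-clone panel for exact-weight examples
manual_clone <- function(months, regimen_kind = "never", regimen_k = NA_integer_,
                         score = 0L, initiated_month = NA_integer_,
                         dropout_month = NA_integer_, patient = 1L,
                         label = if (regimen_kind == "never") "never"
                                 else paste0("ge", regimen_k)) {
  m <- seq_len(months) - 1L
  init <- !is.na(initiated_month) & m == initiated_month
  data.table(
    patient_id = patient, month = m,
    chads_vasc = rep_len(score, months),
    on_oac = !is.na(initiated_month) & m >= initiated_month,
    initiated_this_month = init,
    event_stroke = FALSE, event_bleed = FALSE, death = FALSE,
    dropout = !is.na(dropout_month) & m == dropout_month,
    regimen = label, regimen_kind = regimen_kind, regimen_k = regimen_k,
    compliant = TRUE, artificially_censored = FALSE,
    censor_month = NA_integer_, truncated_weight = 1)
}
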