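#' Simulation configuration for a synthetic AFib + cancer claims cohort
#'
#' Builds a validated configuration for [simulate_cohort()]. The defaults
#' describe an elderly (>= 66) cohort newly diagnosed with non-valvular
#' atrial fibrillation and a history of breast, lung or prostate cancer,
#' with monthly covariate updates over 12 months of potential follow-up,
#' score-confounded oral-anticoagulant (OAC) initiation, and
#' score/treatment-dependent stroke and bleeding hazards.
#'
#' Monthly event ordering within a patient is fixed: covariate/score update
#' (including the annual age increment), then the initiation decision, then
#' the stroke, bleeding, death and dropout draws. Treatment is absorbing:
#' once initiated, a patient stays on OAC.
#'
#' @param n_patients number of patients (>= 0).
#' @param seed integer RNG seed; the generator uses one RNG stream with a
#'   documented draw order, so identical seed + config gives a bit-identical
#'   panel.
#' @param max_months months of potential follow-up (administrative
#'   censoring horizon); months are 0-indexed, so rows run 0..max_months-1.
#' @param age_mean,age_sd,age_min baseline age distribution: normal with
#'   this mean/SD, truncated at `age_min` (Medicare entry at 66) and
#'   floored to integer years.
#' @param female_fraction probability of female sex.
#' @param baseline_prevalences named list of baseline flag prevalences; see
#'   `default_prevalences()` in the source for the full set (CHA2DS2-VASc
#'   and HAS-BLED components, cancer status, and the eligibility exclusion
#'   flags).
#' @param cancer_type_probs,cancer_stage_probs named probability vectors
#'   over cancer type (breast/lung/prostate) and summary stage
#'   (in_situ/local/regional/distant); each must sum to 1.
#' @param score_progression_rate monthly probability that each absent
#'   CHA2DS2-VASc component flag turns on (absorbing).
#' @param initiation list with `intercept` and `per_point`: monthly
#'   initiation probability among the still-untreated is
#'   `plogis(intercept + per_point * chads_vasc)`; `per_point > 0` creates
#'   confounding by indication.
#' @param hazards list of monthly baseline hazards in `[0, 1]` for
#'   `stroke`, `bleed`, `death`, `dropout`.
#' @param effects list of multiplicative hazard ratios (> 0):
#'   `oac_stroke_hr`, `oac_bleed_hr` (effect of being on OAC) and
#'   `score_stroke_hr`, `score_bleed_hr` (per CHA2DS2-VASc point).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 1000L,
                       seed = 1L,
                       max_months = 12L,
                       age_mean = 77,
                       age_sd = 7.3,
                       age_min = 66,
                       female_fraction = 0.4633,
                       baseline_prevalences = list(),
                       cancer_type_probs = c(breast = 0.30, lung = 0.43, prostate = 0.27),
                       cancer_stage_probs = c(in_situ = 0.05, local = 0.48,
                                              regional = 0.27, distant = 0.20),
                       score_progression_rate = 0.01,
                       initiation = list(intercept = -4.6, per_point = 0.25),
                       hazards = list(stroke = 0.001, bleed = 0.0006,
                                      death = 0.010, dropout = 0.005),
                       effects = list(oac_stroke_hr = 0.6, oac_bleed_hr = 1.4,
                                      score_stroke_hr = 1.3, score_bleed_hr = 1.2)) {
  prev <- utils::modifyList(default_prevalences(), baseline_prevalences)
  unknown <- setdiff(names(baseline_prevalences), names(default_prevalences()))
  if (length(unknown))
    stop_config(paste0("baseline_prevalences$", unknown[1]), "unknown flag")
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 0)
    stop_config("n_patients", "must be a non-negative integer")
  if (!is.numeric(max_months) || max_months < 1)
    stop_config("max_months", "must be >= 1")
  check_prob(female_fraction, "female_fraction")
  check_prob(score_progression_rate, "score_progression_rate")
  for (nm in names(prev)) check_prob(prev[[nm]], paste0("baseline_prevalences$", nm))
  for (nm in names(hazards)) check_prob(hazards[[nm]], paste0("hazards$", nm))
  for (nm in names(effects)) check_pos(effects[[nm]], paste0("effects$", nm))
  if (abs(sum(cancer_type_probs) - 1) > 1e-8)
    stop_config("cancer_type_probs", "must sum to 1")
  if (abs(sum(cancer_stage_probs) - 1) > 1e-8)
    stop_config("cancer_stage_probs", "must sum to 1")
  if (!is.list(initiation) || is.null(initiation$intercept) || is.null(initiation$per_point))
    stop_config("initiation", "must be list(intercept=, per_point=)")
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    max_months = as.integer(max_months),
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    female_fraction = female_fraction,
    baseline_prevalences = prev,
    cancer_type_probs = cancer_type_probs,
    cancer_stage_probs = cancer_stage_probs,
    score_progression_rate = score_progression_rate,
    initiation = initiation, hazards = hazards, effects = effects
  ), class = "sim_config")
}

default_prevalences <- function() {
  list(
    # CHA2DS2-VASc components
    chf = 0.25, hypertension = 0.85, diabetes = 0.30,
    prior_stroke_tia = 0.15, vascular_disease = 0.30,
    # extra HAS-BLED components
    renal_abnormal = 0.10, liver_abnormal = 0.05,
    bleeding_history = 0.10, drugs_alcohol = 0.05,
    # cancer status
    active_cancer = 0.29, thrombocytopenia = 0.08,
    # eligibility exclusion flags (baseline only)
    prior_oac = 0.10, valvular_disease = 0.15, recent_stroke_14d = 0.02,
    recent_surgery_bleed_30d = 0.03, esrd = 0.02,
    continuous_enrollment = 0.95
  )
}

# absorbing CHA2DS2-VASc component flags eligible for monthly progression
.progress_cols <- c("chf", "hypertension", "diabetes", "prior_stroke_tia",
                    "vascular_disease")

#' Fixed column order of a person-month panel
#'
#' The documented CSV schema: identifiers, baseline and time-varying
#' covariate flags, scores, treatment and outcome indicators.
#'
#' @return character vector of column names.
#' @export
panel_columns <- function() {
  c("patient_id", "month", "age", "female",
    .progress_cols,
    "renal_abnormal", "liver_abnormal", "bleeding_history", "drugs_alcohol",
    "cancer_type", "cancer_stage", "active_cancer", "thrombocytopenia",
    "prior_oac", "valvular_disease", "recent_stroke_14d",
    "recent_surgery_bleed_30d", "esrd", "continuous_enrollment",
    "chads_vasc", "has_bled", "on_oac", "initiated_this_month",
    "event_stroke", "event_bleed", "death", "dropout", "eligible")
}

empty_panel <- function() {
  cols <- panel_columns()
  out <- data.table::as.data.table(
    stats::setNames(rep(list(logical(0)), length(cols)), cols))
  out[, patient_id := integer(0)][, month := integer(0)]
  out[, age := integer(0)][, chads_vasc := integer(0)][, has_bled := integer(0)]
  out[, cancer_type := character(0)][, cancer_stage := character(0)]
  data.table::setcolorder(out, cols)
  out[]
}

# categorical draw from one uniform per row (fixed draw count, reproducible)
.draw_cat <- function(u, probs) {
  names(probs)[findInterval(u, cumsum(probs), left.open = TRUE) + 1L]
}

# Core engine. `forced` is NULL for observational initiation, or a regimen
# (see regimen()): treatment is then forced to follow the strategy exactly
# (initiate in the first month the score reaches the threshold; never under
# the never-regimen). The forced mode consumes the SAME random draws in the
# SAME order as the observational mode (initiation uniforms are drawn and
# discarded), so forced and observational runs share patient histories up
# to the point treatment alters hazards.
simulate_engine <- function(config, forced = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  if (n == 0L) return(empty_panel())
  set.seed(config$seed)
  prev <- config$baseline_prevalences

  # --- baseline draws, fixed order ---
  u <- runif(n)
  p0 <- stats::pnorm((config$age_min - config$age_mean) / config$age_sd)
  age <- as.integer(floor(config$age_mean +
                            config$age_sd * stats::qnorm(p0 + u * (1 - p0))))
  female <- runif(n) < config$female_fraction
  flags <- list()
  for (nm in names(default_prevalences())) flags[[nm]] <- runif(n) < prev[[nm]]
  cancer_type <- .draw_cat(runif(n), config$cancer_type_probs)
  cancer_stage <- .draw_cat(runif(n), config$cancer_stage_probs)

  comp <- do.call(cbind, flags[.progress_cols]) # progressable score components

  on_oac <- rep(FALSE, n)
  had_stroke <- rep(FALSE, n)
  had_bleed <- rep(FALSE, n)
  alive <- rep(TRUE, n)

  hz <- config$hazards; ef <- config$effects
  ini <- config$initiation
  rate <- config$score_progression_rate
  rows <- vector("list", config$max_months)

  for (m in seq_len(config$max_months) - 1L) {
    idx <- which(alive)
    if (!length(idx)) break
    na <- length(idx)

    # 1. covariate update: each absent component turns on with fixed prob
    for (j in seq_along(.progress_cols)) {
      uj <- runif(na)
      turn <- !comp[idx, j] & uj < rate
      comp[idx[turn], j] <- TRUE
    }
    # annual age increment (deterministic)
    if (m > 0L && m %% 12L == 0L) age[idx] <- age[idx] + 1L

    score <- chads_vasc(age[idx], female[idx], comp[idx, 1], comp[idx, 2],
                        comp[idx, 3], comp[idx, 4], comp[idx, 5])

    # 2. initiation decision (uniform always drawn to keep streams aligned)
    u_init <- runif(na)
    if (is.null(forced)) {
      p_init <- stats::plogis(ini$intercept + ini$per_point * score)
      init_now <- !on_oac[idx] & u_init < p_init
    } else if (forced$kind == "never") {
      init_now <- rep(FALSE, na)
    } else {
      init_now <- !on_oac[idx] & score >= forced$k
    }
    on_oac[idx[init_now]] <- TRUE
    oac <- on_oac[idx]

    # 3-6. outcome, death and dropout draws
    h_str <- pmin(hz$stroke * ef$score_stroke_hr^score *
                    ifelse(oac, ef$oac_stroke_hr, 1), 0.99)
    ev_str <- !had_stroke[idx] & runif(na) < h_str
    h_bld <- pmin(hz$bleed * ef$score_bleed_hr^score *
                    ifelse(oac, ef$oac_bleed_hr, 1), 0.99)
    ev_bld <- !had_bleed[idx] & runif(na) < h_bld
    ev_death <- runif(na) < hz$death
    ev_drop <- !ev_death & runif(na) < hz$dropout

    had_stroke[idx[ev_str]] <- TRUE
    had_bleed[idx[ev_bld]] <- TRUE

    rows[[m + 1L]] <- data.table::data.table(
      patient_id = idx, month = m, age = age[idx], female = female[idx],
      chf = comp[idx, 1], hypertension = comp[idx, 2], diabetes = comp[idx, 3],
      prior_stroke_tia = comp[idx, 4], vascular_disease = comp[idx, 5],
      renal_abnormal = flags$renal_abnormal[idx],
      liver_abnormal = flags$liver_abnormal[idx],
      bleeding_history = flags$bleeding_history[idx],
      drugs_alcohol = flags$drugs_alcohol[idx],
      cancer_type = cancer_type[idx], cancer_stage = cancer_stage[idx],
      active_cancer = flags$active_cancer[idx],
      thrombocytopenia = flags$thrombocytopenia[idx],
      prior_oac = flags$prior_oac[idx],
      valvular_disease = flags$valvular_disease[idx],
      recent_stroke_14d = flags$recent_stroke_14d[idx],
      recent_surgery_bleed_30d = flags$recent_surgery_bleed_30d[idx],
      esrd = flags$esrd[idx],
      continuous_enrollment = flags$continuous_enrollment[idx],
      chads_vasc = score,
      has_bled = has_bled(age[idx], comp[idx, 2], flags$renal_abnormal[idx],
                          flags$liver_abnormal[idx], comp[idx, 4],
                          flags$bleeding_history[idx], flags$drugs_alcohol[idx]),
      on_oac = oac, initiated_this_month = init_now,
      event_stroke = ev_str, event_bleed = ev_bld,
      death = ev_death, dropout = ev_drop, eligible = TRUE
    )
    alive[idx[ev_death | ev_drop]] <- FALSE
  }
  out <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
  data.table::setkey(out, patient_id, month)
  out[]
}

#' Simulate a confounded person-month cohort
#'
#' Generates a long-format panel (one row per patient-month) from a
#' [sim_config()]. Month 0 is the AFib diagnosis (index) month. OAC
#' initiation each month follows a logistic model in the current
#' CHA2DS2-VASc score, so initiators are systematically higher-risk
#' (confounding by indication); monthly stroke and bleeding hazards are
#' `baseline * score_HR^score * OAC_HR^[on OAC]`. Rows end at the first of
#' death, loss to follow-up, or the administrative horizon; a first stroke
#' and a first bleed are each recorded once and follow-up continues (the
#' analysis stage truncates at the outcome under study).
#'
#' @param config a [sim_config()].
#' @return a `data.table` person-month panel with the fixed column order of
#'   `panel_columns()`.
#' @export
simulate_cohort <- function(config) {
  simulate_engine(config, forced = NULL)
}

#' Counterfactual truth under an enforced regimen
#'
#' Monte Carlo oracle for the per-protocol estimand: re-simulates patient
#' histories with treatment forced to follow the regimen exactly (initiate
#' in the first month the score reaches the threshold; never initiate under
#' the never-regimen) and, sharing random draws, the never-initiate
#' reference. Returns the true marginal cumulative-incidence curve under
#' the regimen and the true marginal summary hazard ratio versus never,
#' obtained from an (unconfounded, unweighted) pooled logistic fit of the
#' monthly event indicator on a regimen indicator plus linear + quadratic
#' month on the stacked forced cohorts — the same summary functional the
#' weighted analysis reports.
#'
#' @param config a [sim_config()]; `n_patients` is overridden by `n_mc`.
#' @param regimen a [regimen()].
#' @param n_mc Monte Carlo cohort size (>= 1000).
#' @param outcome `"stroke"` or `"bleed"`.
#' @return list with `risk` (data.table month / cumulative incidence under
#'   the regimen), `risk_never`, `hr`, `log_hr`.
#' @export
counterfactual_truth <- function(config, regimen, n_mc = 10000L,
                                 outcome = c("stroke", "bleed")) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(config, "sim_config"))
  if (n_mc < 1000) stop_config("n_mc", "must be >= 1000")
  cfg <- config
  cfg$n_patients <- as.integer(n_mc)
  pan_r <- simulate_engine(cfg, forced = regimen)
  pan_0 <- simulate_engine(cfg, forced = regimen("never"))
  ev <- paste0("event_", outcome)
  risk_curve <- function(p) {
    p <- truncate_at_event(p, outcome)
    agg <- p[, .(events = sum(.SD[[1]]), at_risk = .N), by = month,
             .SDcols = ev][order(month)]
    agg[, hazard := events / at_risk]
    agg[, risk := 1 - cumprod(1 - hazard)]
    agg[, .(month, risk)]
  }
  arm_r <- truncate_at_event(pan_r, outcome)
  arm_0 <- truncate_at_event(pan_0, outcome)
  y <- c(arm_r[[ev]], arm_0[[ev]])
  mo <- c(arm_r$month, arm_0$month)
  X <- cbind(1, c(rep(1, nrow(arm_r)), rep(0, nrow(arm_0))), mo, mo^2)
  colnames(X) <- c("(Intercept)", "arm", "month", "month2")
  fit <- fit_pooled_logit(X, as.numeric(y))
  list(risk = risk_curve(pan_r), risk_never = risk_curve(pan_0),
       hr = unname(exp(fit$coef["arm"])), log_hr = unname(fit$coef["arm"]))
}

#' Drop rows after the first event of an outcome
#'
#' Truncates each unit's follow-up at (and including) the month of its
#' first `event_<outcome>`; the generator keeps simulating after a first
#' stroke or bleed so the same panel serves both outcome analyses, and
#' this restores outcome-specific at-risk time.
#'
#' @param panel person-month (or clone) panel.
#' @param outcome `"stroke"` or `"bleed"`.
#' @param by grouping column(s) identifying a unit (patient or clone).
#' @return the truncated panel.
#' @export
truncate_at_event <- function(panel, outcome, by = "patient_id") {
  ev <- paste0("event_", outcome)
  p <- data.table::as.data.table(panel)
  pos <- p[, {
    w <- which(.SD[[1]])
    keep <- if (length(w)) seq_len(w[1]) else seq_len(.N)
    .(row = .I[keep])
  }, by = by, .SDcols = ev]
  p[pos$row]
}

#' Write / read a person-month panel as CSV
#'
#' The CSV uses the fixed column order of `panel_columns()` with a header
#' row; logical columns are stored as TRUE/FALSE.
#'
#' @param panel a person-month panel.
#' @param path file path.
#' @return `read_panel` returns a `data.table`; `write_panel` returns the
#'   path invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- data.table::as.data.table(panel)
  data.table::setcolorder(panel, intersect(panel_columns(), names(panel)))
  data.table::fwrite(panel, path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  p <- data.table::fread(path)
  check_columns(p, c("patient_id", "month"), "read_panel")
  data.table::setkey(p, patient_id, month)
  p[]
}
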