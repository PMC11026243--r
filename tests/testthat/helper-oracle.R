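# Independent brute-force oracles: naive month-by-month replays of the
# compliance, censoring and weighting rules, written directly from the
# protocol definitions and kept free of any package internals.

# first deviation month of one clone (NA if compliant throughout)
oracle_deviation <- function(hist, kind, k, grace) {
  reached <- FALSE
  deadline <- NA_integer_
  treated <- FALSE
  for (i in seq_len(nrow(hist))) {
    m <- hist$month[i]
    if (kind == "threshold" && !reached && hist$chads_vasc[i] >= k) {
      reached <- TRUE
      deadline <- m + grace
    }
    init <- hist$initiated_this_month[i]
    if (kind == "never") {
      if (init) return(m)
    } else {
      if (init && !treated) {
        if (!reached) return(m) # initiated before ever reaching threshold
        treated <- TRUE
      } else if (!treated && reached && m == deadline) {
        return(m) # untreated at the end of the grace window
      }
    }
  }
  NA_integer_
}

# per-clone deviation months for a whole cohort x regimen set
oracle_censor_table <- function(panel, regimens, grace) {
  panel <- data.table::as.data.table(panel)
  rows <- list()
  for (pid in unique(panel$patient_id)) {
    hist <- panel[patient_id == pid][order(month)]
    for (r in regimens) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        patient_id = pid, regimen = r$label,
        deviation_month = oracle_deviation(hist, r$kind, r$k, grace))
    }
  }
  data.table::rbindlist(rows)
}

# cumulative weights of one clone's retained rows, replayed month by month
# from predicted initiation (p_init) and dropout (d_hat) probabilities
oracle_clone_weights <- function(hist, kind, k, grace, p_init, d_hat) {
  reached <- FALSE
  deadline <- NA_integer_
  treated <- FALSE
  cum <- 1
  out <- numeric(nrow(hist))
  for (i in seq_len(nrow(hist))) {
    m <- hist$month[i]
    if (kind == "threshold" && !reached && hist$chads_vasc[i] >= k) {
      reached <- TRUE
      deadline <- m + grace
    }
    ft <- 1
    fc <- 1
    if (!hist$artificially_censored[i]) {
      if (!treated) {
        if (kind == "never" || !reached) {
          ft <- 1 / (1 - p_init[i]) # must remain untreated
        } else if (m == deadline) {
          ft <- 1 / p_init[i] # must initiate now
        } # inside the grace window: either behavior consistent -> 1
      }
      if (!hist$dropout[i]) fc <- 1 / (1 - d_hat[i])
    }
    if (hist$initiated_this_month[i]) treated <- TRUE
    cum <- cum * ft * fc
    out[i] <- cum
  }
  out
}

# independent CHA2DS2-VASc arithmetic (per-row loop over printed points)
oracle_chads_row <- function(row) {
  pts <- 0L
  if (row$chf) pts <- pts + 1L
  if (row$hypertension) pts <- pts + 1L
  if (row$age >= 75) pts <- pts + 2L else if (row$age >= 65) pts <- pts + 1L
  if (row$diabetes) pts <- pts + 1L
  if (row$prior_stroke_tia) pts <- pts + 2L
  if (row$vascular_disease) pts <- pts + 1L
  if (row$female) pts <- pts + 1L
  pts
}

# discrete product-limit (KM) risk on a person-month panel, one arm
oracle_km_survival <- function(rows, event_col) {
  agg <- data.table::as.data.table(rows)[
    , .(ev = sum(.SD[[1]]), n = .N), by = month, .SDcols = event_col][order(month)]
  cumprod(1 - agg$ev / agg$n)
}
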