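#' Treatment strategy (regimen) constructors
#'
#' A regimen is either a threshold strategy "initiate OAC in the first
#' month the CHA2DS2-VASc score reaches `k` (within the grace period)" or
#' the "never initiate" reference strategy.
#'
#' @param kind `"threshold"` or `"never"`.
#' @param k integer threshold in 1..9 (required iff `kind = "threshold"`).
#' @param label optional label; defaults to `"ge<k>"` / `"never"`.
#' @return an object of class `regimen`.
#' @export
regimen <- function(kind = c("threshold", "never"), k = NULL, label = NULL) {
  kind <- match.arg(kind)
  if (kind == "threshold") {
    if (is.null(k) || !k %in% 1:9)
      stop_config("k", "threshold must be an integer in 1..9")
    k <- as.integer(k)
    label <- label %||% paste0("ge", k)
  } else {
    k <- NA_integer_
    label <- label %||% "never"
  }
  structure(list(kind = kind, k = k, label = label), class = "regimen")
}

#' @param thresholds increasing integer thresholds for the active arms.
#' @rdname regimen
#' @export
default_regimens <- function(thresholds = c(1L, 2L, 4L, 6L)) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop_config("thresholds", "must be strictly increasing")
  c(lapply(thresholds, function(k) regimen("threshold", k)),
    list(regimen("never")))
}

#' @export
print.regimen <- function(x, ...) {
  cat(if (x$kind == "never") "Regimen: never initiate OAC\n"
      else sprintf("Regimen: initiate OAC when CHA2DS2-VASc >= %d\n", x$k))
  invisible(x)
}

#' Expand an eligible panel into per-regimen clones
#'
#' Creates one exact copy (clone) of every patient's person-month data per
#' regimen: the pre-exclusion clone count is
#' `length(regimens) * n_patients`. Adds the bookkeeping columns
#' `regimen` (label), `regimen_kind`, `regimen_k`, `compliant`,
#' `artificially_censored` and `censor_month`. Rows are ordered
#' (patient, regimen, month).
#'
#' @param panel eligible person-month panel.
#' @param regimens list of [regimen()] objects with distinct labels.
#' @return a clone panel `data.table`.
#' @export
expand_clones <- function(panel, regimens = default_regimens()) {
  if (length(regimens) < 1) stop_config("regimens", "need at least one regimen")
  labels <- vapply(regimens, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop_config("regimens", "duplicate regimen labels")
  panel <- data.table::as.data.table(panel)
  copies <- lapply(regimens, function(r) {
    cl <- data.table::copy(panel)
    cl[, `:=`(regimen = r$label, regimen_kind = r$kind, regimen_k = r$k)]
    cl
  })
  clones <- data.table::rbindlist(copies)
  clones[, `:=`(compliant = TRUE, artificially_censored = FALSE,
                censor_month = NA_integer_)]
  data.table::setkey(clones, patient_id, regimen, month)
  clones[]
}

# first month (if any) at which a clone's observed history deviates from
# its regimen. score/init/on_oac are a single clone's columns ordered by
# month (contiguous from 0). Returns NA_integer_ if compliant throughout.
.deviation_month <- function(month, score, initiated, on_oac, kind, k, grace) {
  if (any(diff(on_oac) < 0))
    stop("data error: on_oac is not absorbing", call. = FALSE)
  init_m <- if (any(initiated)) month[which(initiated)[1]] else NA_integer_
  if (kind == "never") return(init_m)
  cs <- cummax(score)
  reach <- which(cs >= k)
  t0 <- if (length(reach)) month[reach[1]] else NA_integer_
  dev <- NA_integer_
  # (a) premature initiation: before the score has ever reached k
  if (!is.na(init_m) && (is.na(t0) || init_m < t0)) dev <- init_m
  # (b) missed deadline: untreated at the end of the grace window
  if (!is.na(t0)) {
    dl <- t0 + grace
    late <- (is.na(init_m) || init_m > dl) && max(month) >= dl
    if (late) dev <- min(dev, dl, na.rm = TRUE)
  }
  as.integer(dev)
}

#' Assess a single clone's compliance with its regimen
#'
#' Pure rule evaluation on one clone's ordered month history. A
#' threshold-`k` clone deviates if (a) initiation occurs in a month where
#' the running maximum score has never yet reached `k` (the within-month
#' ordering puts the score update before the initiation decision, so
#' initiating in the crossing month itself is compliant), or (b) the score
#' first reaches `k` at month `t0` and no initiation has occurred by month
#' `t0 + grace_months` while still under follow-up. A never-regimen clone
#' deviates at the month of initiation. The deviation month is the first
#' month either rule is violated.
#'
#' @param history data.frame with columns `month`, `chads_vasc`,
#'   `initiated_this_month`, `on_oac`, ordered by month.
#' @param regimen a [regimen()].
#' @param grace_months non-negative integer grace period.
#' @return list with `compliant` (logical) and `deviation_month` (integer,
#'   `NA` if compliant).
#' @export
assess_compliance <- function(history, regimen, grace_months = 1L) {
  check_columns(history, c("month", "chads_vasc", "initiated_this_month",
                           "on_oac"), "assess_compliance")
  if (grace_months < 0) stop_config("grace_months", "must be >= 0")
  dev <- .deviation_month(history$month, history$chads_vasc,
                          history$initiated_this_month, history$on_oac,
                          regimen$kind, regimen$k, as.integer(grace_months))
  list(compliant = is.na(dev), deviation_month = dev)
}

# vectorized deviation months for every clone in a clone panel
.clone_deviations <- function(clones, grace_months) {
  clones[, .(deviation_month = .deviation_month(
    month, chads_vasc, initiated_this_month, on_oac,
    regimen_kind[1], regimen_k[1], as.integer(grace_months))),
    by = .(patient_id, regimen)]
}

#' Remove baseline-noncompliant clones
#'
#' Clones whose month-0 state already violates their regimen (deviation
#' month 0 under [assess_compliance()]) are deleted outright — e.g. a
#' never-clone of a patient who initiates at baseline, or a threshold-`k`
#' clone of a patient initiating at baseline with score below `k`.
#' Follow-up violations are *not* handled here; they are censorings
#' ([apply_artificial_censoring()]).
#'
#' @param clones an expanded clone panel.
#' @param grace_months grace period in months.
#' @return the clone panel without baseline-noncompliant clones.
#' @export
apply_baseline_exclusion <- function(clones, grace_months = 1L) {
  clones <- data.table::as.data.table(clones)
  dev <- .clone_deviations(clones, grace_months)
  drop <- dev[!is.na(deviation_month) & deviation_month == 0L,
              .(patient_id, regimen)]
  out <- clones[!drop, on = c("patient_id", "regimen")]
  data.table::setkey(out, patient_id, regimen, month)
  out[]
}

#' Censor clones at protocol deviation
#'
#' Computes each clone's deviation month, drops all rows after it, flags
#' the deviation-month row `artificially_censored = TRUE` and clears its
#' event indicators: censoring takes precedence over a same-month outcome,
#' so per-protocol person-time never includes non-compliant exposure.
#' Downstream estimation excludes flagged rows from the at-risk set.
#'
#' @inheritParams apply_baseline_exclusion
#' @return the censored clone panel with `compliant`, `censor_month` and
#'   `artificially_censored` filled in.
#' @export
apply_artificial_censoring <- function(clones, grace_months = 1L) {
  clones <- data.table::as.data.table(clones)
  dev <- .clone_deviations(clones, grace_months)
  out <- dev[clones, on = c("patient_id", "regimen")]
  out <- out[is.na(deviation_month) | month <= deviation_month]
  out[, compliant := is.na(deviation_month)]
  out[, censor_month := deviation_month]
  out[, artificially_censored := !is.na(deviation_month) & month == deviation_month]
  out[artificially_censored == TRUE,
      `:=`(event_stroke = FALSE, event_bleed = FALSE)]
  out[, deviation_month := NULL]
  data.table::setkey(out, patient_id, regimen, month)
  out[]
}
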