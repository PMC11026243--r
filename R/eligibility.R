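#' Target-trial eligibility criteria
#'
#' Criteria are evaluated on each patient's baseline (month 0) row and are
#' applied sequentially in the fixed order below, so the attrition log
#' attributes each excluded patient to the *first* criterion they fail
#' (flowchart-style reporting):
#'
#' 1. age >= `min_age` at baseline;
#' 2. continuous Medicare enrollment over the pre-index year
#'    (`continuous_enrollment` flag);
#' 3. no history of OAC use (`prior_oac`);
#' 4. no valvular disease / VTE / joint replacement (`valvular_disease`);
#' 5. no stroke within the previous 14 days (`recent_stroke_14d`);
#' 6. no major surgery or critical bleed within the previous 30 days
#'    (`recent_surgery_bleed_30d`);
#' 7. no stage-5 renal impairment / ESRD (`esrd`).
#'
#' @param min_age minimum baseline age (default 66).
#' @param require_continuous_enrollment_months enrollment look-back, months
#'   (informational; in synthetic data enrollment is a baseline flag).
#' @return an object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(min_age = 66L,
                                 require_continuous_enrollment_months = 12L) {
  if (require_continuous_enrollment_months < 1)
    stop_config("require_continuous_enrollment_months", "must be >= 1")
  structure(list(min_age = min_age,
                 require_continuous_enrollment_months =
                   require_continuous_enrollment_months),
            class = "eligibility_criteria")
}

# (criterion label, baseline predicate returning TRUE = excluded)
.eligibility_rules <- function(criteria) {
  list(
    list(name = sprintf("age < %d", criteria$min_age),
         fails = function(b) b$age < criteria$min_age),
    list(name = "not continuously enrolled",
         fails = function(b) !b$continuous_enrollment),
    list(name = "prior OAC use",
         fails = function(b) b$prior_oac),
    list(name = "valvular disease, VTE or joint replacement",
         fails = function(b) b$valvular_disease),
    list(name = "stroke within 14 days",
         fails = function(b) b$recent_stroke_14d),
    list(name = "major surgery or critical bleed within 30 days",
         fails = function(b) b$recent_surgery_bleed_30d),
    list(name = "ESRD / renal impairment stage 5",
         fails = function(b) b$esrd)
  )
}

#' Apply eligibility criteria and log attrition
#'
#' Removes entire patients whose baseline (month 0) row fails any
#' criterion, in the fixed order documented in [eligibility_criteria()],
#' and returns a sequential attrition log. Applying the function twice is a
#' no-op (idempotence), and removed + retained always equals the input
#' count.
#'
#' @param panel person-month panel containing baseline criterion columns.
#' @param criteria an [eligibility_criteria()].
#' @return list with `panel` (eligible rows, `eligible = TRUE`) and
#'   `attrition` (data.table: criterion, n_removed, n_remaining).
#' @export
apply_eligibility <- function(panel, criteria = eligibility_criteria()) {
  panel <- data.table::as.data.table(panel)
  needed <- c("age", "continuous_enrollment", "prior_oac", "valvular_disease",
              "recent_stroke_14d", "recent_surgery_bleed_30d", "esrd")
  check_columns(panel, c("patient_id", "month", needed), "apply_eligibility")
  base <- panel[month == 0L]
  rules <- .eligibility_rules(criteria)
  remaining <- base$patient_id
  log_rows <- vector("list", length(rules))
  for (i in seq_along(rules)) {
    b <- base[patient_id %in% remaining]
    out <- b$patient_id[rules[[i]]$fails(b)]
    remaining <- setdiff(remaining, out)
    log_rows[[i]] <- data.table::data.table(
      criterion = rules[[i]]$name,
      n_removed = length(out),
      n_remaining = length(remaining))
  }
  eligible <- panel[patient_id %in% remaining]
  eligible[, eligible := TRUE]
  list(panel = eligible[], attrition = data.table::rbindlist(log_rows))
}

#' @export
print.eligibility_criteria <- function(x, ...) {
  cat("Eligibility criteria: age >=", x$min_age, "; continuous enrollment",
      x$require_continuous_enrollment_months, "months; no prior OAC,",
      "valvular disease/VTE, recent stroke (14d), recent surgery/bleed",
      "(30d), or ESRD at baseline\n")
  invisible(x)
}
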