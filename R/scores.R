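#' CHA2DS2-VASc stroke-risk score
#'
#' Computes the integer CHA2DS2-VASc score from its components: congestive
#' heart failure (1 point), hypertension (1), age 65-74 (1) or age >= 75 (2,
#' the bands are mutually exclusive), diabetes mellitus (1), prior stroke /
#' TIA / thromboembolism (2), vascular disease (1), and female sex (1).
#' The score ranges from 0 to 9.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param age integer age in years, must be >= 0.
#' @param female,chf,hypertension,diabetes,prior_stroke_tia,vascular_disease
#'   logical component flags.
#' @return integer vector of scores in `[0, 9]`.
#' @examples
#' chads_vasc(66, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE) # 1 (age band)
#' chads_vasc(77, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)     # 7
#' @export
chads_vasc <- function(age, female, chf, hypertension, diabetes,
                       prior_stroke_tia, vascular_disease) {
  if (any(age < 0, na.rm = TRUE)) stop("input error: negative age", call. = FALSE)
  age_pts <- ifelse(age >= 75L, 2L, ifelse(age >= 65L, 1L, 0L))
  as.integer(age_pts + chf + hypertension + diabetes +
               2L * prior_stroke_tia + vascular_disease + female)
}

#' HAS-BLED bleeding-risk score (claims-adapted)
#'
#' Seven-component HAS-BLED sum: hypertension (1), abnormal renal function
#' (1), abnormal liver function (1), prior stroke (1), bleeding history (1),
#' elderly, age > 65 (1), and drugs/alcohol use (1). The labile-INR
#' component is omitted because INR laboratory values are not observable in
#' claims data; the maximum attainable score is therefore 7 rather than 9.
#'
#' @param age integer age in years, must be >= 0.
#' @param hypertension,renal_abnormal,liver_abnormal,prior_stroke_tia,bleeding_history,drugs_alcohol
#'   logical component flags.
#' @return integer vector of scores in `[0, 7]`.
#' @examples
#' has_bled(60, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE) # 0
#' has_bled(70, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)   # 3
#' @export
has_bled <- function(age, hypertension, renal_abnormal, liver_abnormal,
                     prior_stroke_tia, bleeding_history, drugs_alcohol) {
  if (any(age < 0, na.rm = TRUE)) stop("input error: negative age", call. = FALSE)
  as.integer((age > 65L) + hypertension + renal_abnormal + liver_abnormal +
               prior_stroke_tia + bleeding_history + drugs_alcohol)
}

# columns score_panel() needs beyond patient_id/month
.score_cols <- c("age", "female", "chf", "hypertension", "diabetes",
                 "prior_stroke_tia", "vascular_disease", "renal_abnormal",
                 "liver_abnormal", "bleeding_history", "drugs_alcohol")

#' Recompute risk scores on a person-month panel
#'
#' Applies [chads_vasc()] and [has_bled()] row-wise so that the `chads_vasc`
#' and `has_bled` columns reflect the covariate flags of each month. When
#' the flags are absorbing (they only ever turn on) and age only increases,
#' the recomputed CHA2DS2-VASc score is non-decreasing within patient.
#'
#' @param panel a person-month panel (`data.frame`/`data.table`) with the
#'   covariate columns listed in the details.
#' @return the panel with `chads_vasc` and `has_bled` columns (re)computed.
#' @export
score_panel <- function(panel) {
  check_columns(panel, .score_cols, "score_panel")
  panel <- data.table::as.data.table(panel)
  panel[, chads_vasc := chads_vasc(age, female, chf, hypertension, diabetes,
                                   prior_stroke_tia, vascular_disease)]
  panel[, has_bled := has_bled(age, hypertension, renal_abnormal,
                               liver_abnormal, prior_stroke_tia,
                               bleeding_history, drugs_alcohol)]
  panel[]
}
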