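#' Covariate specification for the weight models
#'
#' Controls which columns enter the discrete-time (pooled logistic) models
#' for OAC initiation and for loss to follow-up, and how calendar time
#' (month since index) enters.
#'
#' @param baseline character vector of baseline covariate column names.
#' @param timevarying character vector of time-varying covariate column
#'   names (the current CHA2DS2-VASc score by default).
#' @param time `"quadratic"` (linear + quadratic month, the default) or
#'   `"indicator"` (one indicator per month, saturated in time).
#' @return an object of class `weight_spec`.
#' @export
weight_spec <- function(baseline = c("female", "active_cancer"),
                        timevarying = c("chads_vasc"),
                        time = c("quadratic", "indicator")) {
  time <- match.arg(time)
  structure(list(baseline = baseline, timevarying = timevarying, time = time),
            class = "weight_spec")
}

.weight_formula <- function(event, spec) {
  time_term <- if (spec$time == "quadratic") "month + I(month^2)"
               else "factor(month)"
  rhs <- paste(c(spec$baseline, spec$timevarying, time_term), collapse = " + ")
  stats::as.formula(paste(event, "~", rhs))
}

.check_positivity <- function(p, what) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop(sprintf("positivity error: %s model predicts probabilities at 0 or 1",
                 what), call. = FALSE)
  eps <- 1e-8
  if (any(p < eps) || any(p > 1 - eps))
    warning(sprintf("positivity warning: %s model has fitted probabilities within %g of 0/1 (%d rows)",
                    what, eps, sum(p < eps | p > 1 - eps)), call. = FALSE)
  invisible(p)
}

#' Fit the discrete-time OAC-initiation model
#'
#' Pooled logistic regression of the monthly initiation indicator on
#' baseline covariates, time-varying covariates and time terms, fitted on
#' the *uncloned* panel restricted to the initiation risk set (person-months
#' entered untreated). Predictions from this model feed the inverse
#' probability of treatment weights.
#'
#' @param panel person-month panel (scored, typically the eligible cohort).
#' @param spec a [weight_spec()].
#' @return list of class `ccw_model` with elements `fit` (a `glm`),
#'   `spec`, `event`, `no_events` (FALSE here).
#' @export
fit_initiation_model <- function(panel, spec = weight_spec()) {
  panel <- data.table::as.data.table(panel)
  check_columns(panel, c("on_oac", "initiated_this_month", "month",
                         spec$baseline, spec$timevarying),
                "fit_initiation_model")
  risk <- panel[!on_oac | initiated_this_month] # untreated at month start
  if (nrow(risk) == 0L || sum(risk$initiated_this_month) == 0L)
    stop("fitting error: no initiation events in the risk set", call. = FALSE)
  fit <- stats::glm(.weight_formula("initiated_this_month", spec),
                    family = stats::binomial(), data = risk)
  if (!fit$converged)
    stop("fitting error: initiation model did not converge", call. = FALSE)
  .check_positivity(stats::fitted(fit), "initiation")
  structure(list(fit = fit, spec = spec, event = "initiated_this_month",
                 no_events = FALSE), class = "ccw_model")
}

#' Fit the discrete-time dropout (loss to follow-up) model
#'
#' As [fit_initiation_model()] but with the monthly dropout indicator as
#' the event and current treatment status (`on_oac`, treatment history) in
#' the conditioning set. If dropout never occurs in the panel, fitting is
#' skipped with a warning and all censoring factors downstream are 1 (the
#' no-event guard).
#'
#' @inheritParams fit_initiation_model
#' @return a `ccw_model`; `no_events = TRUE` marks the guard case.
#' @export
fit_dropout_model <- function(panel, spec = weight_spec()) {
  panel <- data.table::as.data.table(panel)
  check_columns(panel, c("dropout", "on_oac", "month",
                         spec$baseline, spec$timevarying),
                "fit_dropout_model")
  if (sum(panel$dropout) == 0L) {
    warning("no dropout events; censoring factors set to 1", call. = FALSE)
    return(constant_model(0, event = "dropout"))
  }
  spec2 <- spec
  spec2$timevarying <- union(spec$timevarying, "on_oac")
  fit <- stats::glm(.weight_formula("dropout", spec2),
                    family = stats::binomial(), data = panel)
  if (!fit$converged)
    stop("fitting error: dropout model did not converge", call. = FALSE)
  .check_positivity(stats::fitted(fit), "dropout")
  structure(list(fit = fit, spec = spec2, event = "dropout",
                 no_events = FALSE), class = "ccw_model")
}

#' Constant-probability weight-model component
#'
#' A degenerate `ccw_model` that predicts the same probability for every
#' row. Used internally for the no-dropout guard (probability 0) and
#' useful for constructing exact weight examples and diagnostics.
#'
#' @param p probability in `[0, 1)`.
#' @param event event name label.
#' @return a `ccw_model`.
#' @export
constant_model <- function(p, event = "constant") {
  if (!is.numeric(p) || p < 0 || p >= 1) stop_config("p", "must be in [0, 1)")
  structure(list(fit = NULL, const = p, spec = NULL, event = event,
                 no_events = p == 0), class = "ccw_model")
}

# predicted event probability of a ccw_model on new rows
.predict_ccw <- function(m, newdata) {
  if (!is.null(m$const)) return(rep(m$const, nrow(newdata)))
  stats::predict(m$fit, newdata = newdata, type = "response")
}

#' Bundle fitted weight models
#'
#' @param initiation a `ccw_model` from [fit_initiation_model()].
#' @param dropout a `ccw_model` from [fit_dropout_model()].
#' @return list of class `weight_model`.
#' @export
weight_model <- function(initiation, dropout) {
  structure(list(initiation = initiation, dropout = dropout),
            class = "weight_model")
}

#' Cumulative unstabilized inverse-probability weights for clones
#'
#' For each clone-month the treatment factor is the reciprocal of the
#' predicted probability of behaving consistently with the assigned regimen
#' given history: `1 / (1 - p_t)` in months the regimen requires remaining
#' untreated (score still below the threshold, or the never-regimen);
#' `1 / p_t` at the grace deadline, when the regimen requires initiation;
#' 1 inside the grace window (either behavior is consistent, so deviation
#' has probability zero there) and after initiation (treatment is
#' absorbing). The censoring factor is `1 / (1 - d_t)` for every month the
#' clone remains under observation. The cumulative weight is the running
#' product of both factors within clone; unstabilized factors are always
#' >= 1.
#'
#' @param clones a censored clone panel ([apply_artificial_censoring()]).
#' @param model a [weight_model()] fitted on the uncloned panel.
#' @param grace_months grace period used for compliance (must match the
#'   censoring step).
#' @return the clone panel with columns `factor_treatment`,
#'   `factor_censoring`, `cumulative_weight` added (rows flagged
#'   `artificially_censored` get factors of 1 and carry the last cumulative
#'   weight; they are excluded from estimation anyway).
#' @export
compute_cumulative_weights <- function(clones, model, grace_months = 1L) {
  stopifnot(inherits(model, "weight_model"))
  clones <- data.table::as.data.table(clones)
  check_columns(clones, c("patient_id", "regimen", "regimen_kind", "regimen_k",
                          "month", "chads_vasc", "on_oac",
                          "initiated_this_month", "dropout",
                          "artificially_censored"),
                "compute_cumulative_weights")
  p_init <- .predict_ccw(model$initiation, clones)
  if (is.null(model$initiation$const)) .check_positivity(p_init, "initiation")
  d_hat <- .predict_ccw(model$dropout, clones)
  if (any(d_hat >= 1)) stop("positivity error: dropout probability >= 1",
                            call. = FALSE)
  out <- data.table::copy(clones)
  out[, `:=`(p_init_ = p_init, d_hat_ = d_hat)]
  out[, untreated_start_ := !on_oac | initiated_this_month]
  out[, `:=`(factor_treatment = 1, factor_censoring = 1)]
  out[, c("factor_treatment", "factor_censoring") := {
    cs <- cummax(chads_vasc)
    ft <- rep(1, .N)
    if (regimen_kind[1] == "never") {
      must_wait <- untreated_start_
      deadline <- rep(FALSE, .N)
    } else {
      k <- regimen_k[1]
      reach <- which(cs >= k)
      t0 <- if (length(reach)) month[reach[1]] else NA_integer_
      must_wait <- untreated_start_ & cs < k
      deadline <- untreated_start_ & !is.na(t0) & month == t0 + grace_months
    }
    ft[must_wait] <- 1 / (1 - p_init_[must_wait])
    ft[deadline] <- 1 / p_init_[deadline]
    fc <- ifelse(dropout, 1, 1 / (1 - d_hat_))
    # the artificially-censored row leaves the analysis; neutral factors
    ft[artificially_censored] <- 1
    fc[artificially_censored] <- 1
    list(ft, fc)
  }, by = .(patient_id, regimen)]
  out[, cumulative_weight := cumprod(factor_treatment * factor_censoring),
      by = .(patient_id, regimen)]
  out[, c("p_init_", "d_hat_", "untreated_start_") := NULL]
  data.table::setkey(out, patient_id, regimen, month)
  out[]
}

#' Truncate cumulative weights at a pooled percentile
#'
#' The cap is the linear-interpolation sample percentile (`quantile`
#' type 7) of all clone-month cumulative weights pooled across regimens;
#' weights above the cap are set to the cap. Percentile 100 is the
#' identity.
#'
#' @param clones clone panel with a `cumulative_weight` column.
#' @param percentile number in (0, 100].
#' @return clone panel with a `truncated_weight` column; the cap is
#'   attached as attribute `"weight_cap"`.
#' @export
truncate_weights <- function(clones, percentile = 99) {
  if (!is.numeric(percentile) || percentile <= 0 || percentile > 100)
    stop_config("percentile", "must be in (0, 100]")
  clones <- data.table::as.data.table(clones)
  check_columns(clones, "cumulative_weight", "truncate_weights")
  cap <- stats::quantile(clones$cumulative_weight, percentile / 100,
                         type = 7, names = FALSE)
  clones[, truncated_weight := pmin(cumulative_weight, cap)]
  data.table::setattr(clones, "weight_cap", cap)
  clones[]
}

#' Per-regimen weight diagnostics
#'
#' @param clones clone panel with weight columns.
#' @return data.table of mean / SD / selected percentiles of the cumulative
#'   and truncated weights by regimen.
#' @export
weight_diagnostics <- function(clones) {
  clones <- data.table::as.data.table(clones)
  check_columns(clones, c("regimen", "cumulative_weight"), "weight_diagnostics")
  has_trunc <- "truncated_weight" %in% names(clones)
  clones[artificially_censored == FALSE, {
    q <- stats::quantile(cumulative_weight, c(.5, .95, .99), names = FALSE)
    .(n_clone_months = .N,
      mean = mean(cumulative_weight), sd = stats::sd(cumulative_weight),
      p50 = q[1], p95 = q[2], p99 = q[3], max = max(cumulative_weight),
      mean_truncated = if (has_trunc) mean(truncated_weight) else NA_real_,
      max_truncated = if (has_trunc) max(truncated_weight) else NA_real_)
  }, by = regimen][order(regimen)]
}
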