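#' Incidence rate per 1000 person-years
#'
#' `events / person_years * 1000`, rounded half-up to 2 decimals for parity
#' with printed epidemiological tables.
#'
#' @param events non-negative event count (vectorized).
#' @param person_years positive person-years (vectorized).
#' @return numeric rate(s) per 1000 person-years, 2 decimals.
#' @examples
#' incidence_rate(188, 4980) # 37.75
#' @export
incidence_rate <- function(events, person_years) {
  if (any(events < 0)) stop("input error: negative event count", call. = FALSE)
  if (any(person_years <= 0))
    stop("input error: person_years must be > 0", call. = FALSE)
  round_half_up(events / person_years * 1000, 2)
}

# weighted logistic fit on an explicit model matrix, with optional
# cluster-robust (sandwich) variance. Quasibinomial likelihood so
# non-integer weighted responses do not warn; coefficients equal the
# binomial fit. GEE with independence working correlation + robust
# variance reduces to exactly this estimator.
fit_pooled_logit <- function(X, y, w = NULL, cluster = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  fit <- stats::glm.fit(X, y, weights = w, family = stats::quasibinomial(),
                        control = list(epsilon = 1e-10, maxit = 50))
  if (!fit$converged)
    stop("fitting error: pooled logistic model did not converge", call. = FALSE)
  beta <- fit$coefficients
  mu <- fit$fitted.values
  # Fisher information at the converged estimate (glm.fit$weights lags one
  # IRLS iteration behind, so rebuild the working weights from mu)
  XW <- X * sqrt(w * mu * (1 - mu))
  bread <- chol2inv(chol(crossprod(XW)))
  if (is.null(cluster)) {
    V <- bread
  } else {
    U <- X * (w * (y - mu)) # per-row score contributions
    Us <- rowsum(U, cluster)
    V <- bread %*% crossprod(Us) %*% bread
  }
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coef = beta, vcov = V, fitted = mu, n = length(y),
       n_clusters = if (is.null(cluster)) NA_integer_
                    else length(unique(cluster)))
}

# design matrix: intercept + regimen dummies (reference arm omitted) +
# time terms
.outcome_design <- function(dt, arms, ref, time) {
  active <- setdiff(arms, ref)
  if (length(active)) {
    Xr <- vapply(active, function(a) as.numeric(dt$regimen == a),
                 numeric(nrow(dt)))
    if (length(active) == 1L) Xr <- matrix(Xr, ncol = 1L)
  } else {
    Xr <- matrix(numeric(0), nrow(dt), 0L)
  }
  if (time == "quadratic") {
    Xt <- cbind(month = dt$month, month2 = dt$month^2)
  } else {
    mos <- sort(unique(dt$month))[-1]
    Xt <- vapply(mos, function(m) as.numeric(dt$month == m),
                 numeric(nrow(dt)))
    if (length(mos) == 1L) Xt <- matrix(Xt, ncol = 1L)
    colnames(Xt) <- paste0("month", mos)
  }
  X <- cbind(`(Intercept)` = 1, Xr, Xt)
  colnames(X)[1 + seq_along(active)] <- paste0("regimen", active)
  X
}

# at-risk clone-months for one outcome: drop artificially-censored rows,
# then truncate each clone at its first event of that outcome
at_risk_clone_months <- function(clones, outcome = c("stroke", "bleed")) {
  outcome <- match.arg(outcome)
  clones <- data.table::as.data.table(clones)
  keep <- clones[artificially_censored == FALSE]
  keep[, clone_id_ := paste(patient_id, regimen, sep = "\r")]
  out <- truncate_at_event(keep, outcome, by = "clone_id_")
  out[, clone_id_ := NULL]
  out[]
}

#' Per-regimen events and person-years
#'
#' Events are counted once per clone at the event month; person-years are
#' at-risk clone-months divided by 12. Artificially-censored rows
#' contribute neither events nor person-time (censoring precedes the
#' outcome within a month).
#'
#' @param clones censored (and possibly weighted) clone panel.
#' @param outcome `"stroke"` or `"bleed"`.
#' @return data.table: regimen, events, person_years, rate_per_1000py.
#' @export
person_time_summary <- function(clones, outcome = c("stroke", "bleed")) {
  outcome <- match.arg(outcome)
  ar <- at_risk_clone_months(clones, outcome)
  ev <- paste0("event_", outcome)
  out <- ar[, .(events = sum(.SD[[1]]), person_years = .N / 12),
            by = regimen, .SDcols = ev][order(regimen)]
  out[, rate_per_1000py := incidence_rate(events, person_years)]
  out[]
}

#' Weighted discrete-time outcome (hazard) model
#'
#' Fits a weighted pooled logistic regression of the monthly event
#' indicator on regimen indicators (reference: the never-initiate arm) plus
#' time terms, on the at-risk clone-months, weighted by the truncated
#' cumulative weights. The variance is a robust sandwich clustered on the
#' original patient (all clones of one patient share a cluster), i.e. a GEE
#' with independence working correlation. Arms with zero events are
#' excluded from the fit and flagged; their HR is undefined.
#'
#' @param clones weighted clone panel (after [truncate_weights()]).
#' @param outcome `"stroke"` or `"bleed"`.
#' @param weight_col weight column name (`"truncated_weight"`; use
#'   `"cumulative_weight"` for untruncated).
#' @param time `"quadratic"` or `"indicator"` time terms.
#' @param ref reference regimen label.
#' @return list of class `ccw_outcome_model`: `fit` (coef/vcov), `arms`,
#'   `ref`, `zero_event_arms`, `time`, `outcome`.
#' @export
fit_outcome_model <- function(clones, outcome = c("stroke", "bleed"),
                              weight_col = "truncated_weight",
                              time = c("quadratic", "indicator"),
                              ref = "never") {
  outcome <- match.arg(outcome)
  time <- match.arg(time)
  ar <- at_risk_clone_months(clones, outcome)
  check_columns(ar, c(weight_col, "regimen", "month"), "fit_outcome_model")
  ev <- paste0("event_", outcome)
  arm_events <- ar[, .(events = sum(.SD[[1]])), by = regimen, .SDcols = ev]
  zero <- arm_events[events == 0L, regimen]
  if (ref %in% zero)
    stop("fitting error: reference arm has zero events", call. = FALSE)
  if (length(zero)) {
    warning(sprintf("arm(s) with zero events excluded from fit: %s",
                    paste(zero, collapse = ", ")), call. = FALSE)
    ar <- ar[!regimen %in% zero]
  }
  arms <- sort(unique(ar$regimen))
  X <- .outcome_design(ar, arms, ref, time)
  fit <- fit_pooled_logit(X, as.numeric(ar[[ev]]), w = ar[[weight_col]],
                          cluster = ar$patient_id)
  structure(list(fit = fit, arms = arms, ref = ref,
                 zero_event_arms = zero, time = time, outcome = outcome),
            class = "ccw_outcome_model")
}

#' Summary hazard ratios with 95% confidence intervals
#'
#' The discrete-time hazard odds ratio per regimen (interpreted as an HR
#' for rare monthly events): `exp(coef)`, with Wald CI
#' `exp(coef +/- 1.96 * robust SE)`. Arms excluded for zero events are
#' returned with `NA` estimates.
#'
#' @param model a `ccw_outcome_model`.
#' @return data.table: regimen, log_hr, se, hr, lower, upper.
#' @export
summary_hr <- function(model) {
  stopifnot(inherits(model, "ccw_outcome_model"))
  active <- setdiff(model$arms, model$ref)
  nm <- paste0("regimen", active)
  est <- model$fit$coef[nm]
  se <- sqrt(diag(model$fit$vcov)[nm])
  out <- data.table::data.table(
    regimen = c(active, model$zero_event_arms),
    log_hr = c(est, rep(NA_real_, length(model$zero_event_arms))),
    se = c(se, rep(NA_real_, length(model$zero_event_arms))))
  out[, hr := exp(log_hr)]
  out[, lower := exp(log_hr - 1.96 * se)]
  out[, upper := exp(log_hr + 1.96 * se)]
  out[order(regimen)]
}

#' Standardized weighted survival curves
#'
#' For each regimen, the fitted monthly hazard is predicted for every
#' at-risk clone-month, averaged with the clone weights, and converted to a
#' survival curve `S(m) = prod_{s < m} (1 - hbar(s))` with `S(0) = 1`. With
#' `time = "indicator"`, unit weights and a single arm this reproduces the
#' discrete product-limit (Kaplan-Meier) estimator.
#'
#' @param model a `ccw_outcome_model`.
#' @param clones the same weighted clone panel the model was fitted on.
#' @param weight_col weight column used for averaging.
#' @return data.table: regimen, month (0..T), survival.
#' @export
survival_curves <- function(model, clones, weight_col = "truncated_weight") {
  stopifnot(inherits(model, "ccw_outcome_model"))
  ar <- at_risk_clone_months(clones, model$outcome)
  ar <- ar[!regimen %in% model$zero_event_arms]
  X <- .outcome_design(ar, model$arms, model$ref, model$time)
  ar[, hazard_ := stats::plogis(drop(X %*% model$fit$coef))]
  ar[, w_ := ar[[weight_col]]]
  hbar <- ar[, .(hbar = stats::weighted.mean(hazard_, w_)),
             by = .(regimen, month)]
  curves <- hbar[order(regimen, month)][, {
    .(month = c(0L, month + 1L), survival = c(1, cumprod(1 - hbar)))
  }, by = regimen]
  curves[]
}

#' Seeded patient-level bootstrap for regimen hazard ratios
#'
#' Optional alternative to the default cluster-robust (conservative)
#' intervals: resamples whole patients with replacement from the eligible
#' panel and re-runs cloning, censoring, weighting and the outcome fit on
#' each replicate. Duplicated patients enter as distinct clusters.
#' Replicates where the fit fails (e.g. a zero-event reference arm) are
#' dropped and counted in `n_failed`.
#'
#' @param panel scored, eligible person-month panel.
#' @param outcome `"stroke"` or `"bleed"`.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed for the resampling stream.
#' @param regimens list of [regimen()] objects.
#' @param grace_months grace period in months.
#' @param truncation_percentile pooled weight-truncation percentile.
#' @param weights a [weight_spec()].
#' @param time time terms of the outcome model.
#' @return list with `hr` (data.table: regimen, hr, lower, upper from the
#'   2.5/97.5 percentiles of the bootstrap log-HRs, n_boot), `log_hr_draws`
#'   (matrix, replicates x arms) and `n_failed`.
#' @export
bootstrap_hr <- function(panel, outcome = c("stroke", "bleed"), n_boot = 200L,
                         seed = 1L, regimens = default_regimens(),
                         grace_months = 1L, truncation_percentile = 99,
                         weights = weight_spec(),
                         time = c("quadratic", "indicator")) {
  outcome <- match.arg(outcome)
  time <- match.arg(time)
  panel <- data.table::as.data.table(panel)
  ids <- unique(panel$patient_id)
  arms <- setdiff(vapply(regimens, `[[`, character(1), "label"), "never")
  one_fit <- function(p) {
    cl <- apply_artificial_censoring(
      apply_baseline_exclusion(expand_clones(p, regimens), grace_months),
      grace_months)
    wm <- suppressWarnings(weight_model(fit_initiation_model(p, weights),
                                        fit_dropout_model(p, weights)))
    cl <- truncate_weights(compute_cumulative_weights(cl, wm, grace_months),
                           truncation_percentile)
    hr <- summary_hr(suppressWarnings(fit_outcome_model(cl, outcome, time = time)))
    hr$log_hr[match(arms, hr$regimen)]
  }
  point <- one_fit(panel)
  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, length(arms),
                  dimnames = list(NULL, arms))
  for (b in seq_len(n_boot)) {
    sel <- data.table::data.table(patient_id = sample(ids, replace = TRUE))
    sel[, boot_id_ := .I]
    rep_panel <- panel[sel, on = "patient_id", allow.cartesian = TRUE]
    rep_panel[, patient_id := boot_id_][, boot_id_ := NULL]
    draws[b, ] <- tryCatch(one_fit(rep_panel),
                           error = function(e) rep(NA_real_, length(arms)))
  }
  ok <- stats::complete.cases(draws)
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  out <- data.table::data.table(regimen = arms, log_hr = point,
                                hr = exp(point), lower = exp(qs[1, ]),
                                upper = exp(qs[2, ]), n_boot = sum(ok))
  list(hr = out[], log_hr_draws = draws, n_failed = sum(!ok))
}

#' Naive (unweighted, non-cloned) treatment association
#'
#' Pooled logistic regression of the monthly outcome on current OAC status
#' plus time terms, fitted directly on the person-month panel with no
#' cloning, censoring or weighting — the confounded association the
#' clone-censor-weight design is meant to correct. Used as a bias
#' benchmark.
#'
#' @param panel person-month panel.
#' @param outcome `"stroke"` or `"bleed"`.
#' @return list with `log_or`, `or`, `se`.
#' @export
naive_association <- function(panel, outcome = c("stroke", "bleed")) {
  outcome <- match.arg(outcome)
  p <- truncate_at_event(data.table::as.data.table(panel), outcome)
  ev <- paste0("event_", outcome)
  X <- cbind(`(Intercept)` = 1, on_oac = as.numeric(p$on_oac),
             month = p$month, month2 = p$month^2)
  fit <- fit_pooled_logit(X, as.numeric(p[[ev]]), cluster = p$patient_id)
  list(log_or = unname(fit$coef["on_oac"]),
       or = unname(exp(fit$coef["on_oac"])),
       se = sqrt(diag(fit$vcov)["on_oac"]))
}
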