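test_that("initiation model recovers the generating coefficients (n = 20,000)", {
  cfg <- small_config(20000, seed = 55)
  pan <- score_panel(simulate_cohort(cfg))
  wmod <- fit_initiation_model(pan, weight_spec(baseline = character(0),
                                                timevarying = "chads_vasc"))
  est <- summary(wmod$fit)$coefficients
  # truth: logit p = -4.6 + 0.25 * score, no time trend
  for (term in c("(Intercept)", "chads_vasc", "month", "I(month^2)")) {
    truth <- c(`(Intercept)` = -4.6, chads_vasc = 0.25, month = 0,
               `I(month^2)` = 0)[[term]]
    expect_lt(abs(est[term, "Estimate"] - truth), 3 * est[term, "Std. Error"])
  }
})

test_that("dropout model recovers a covariate-free hazard; guards and errors", {
  cfg <- small_config(20000, seed = 56)
  pan <- score_panel(simulate_cohort(cfg))
  dmod <- fit_dropout_model(pan, weight_spec(baseline = character(0),
                                             timevarying = "chads_vasc"))
  est <- summary(dmod$fit)$coefficients
  expect_lt(abs(est["(Intercept)", "Estimate"] - stats::qlogis(0.005)),
            3 * est["(Intercept)", "Std. Error"])
  for (term in c("chads_vasc", "on_oacTRUE"))
    expect_lt(abs(est[term, "Estimate"]), 3 * est[term, "Std. Error"])

  # no-event guard for dropout, hard error for initiation
  nodrop <- copy(pan)[, dropout := FALSE]
  expect_warning(g <- fit_dropout_model(nodrop), "no dropout")
  expect_true(g$no_events)
  noinit <- copy(pan)[, `:=`(initiated_this_month = FALSE, on_oac = FALSE)]
  expect_error(fit_initiation_model(noinit), "no initiation events")
})

test_that("covariate-free saturated-in-time fit equals empirical proportions", {
  pan <- score_panel(simulate_cohort(small_config(3000, seed = 57)))
  spec <- weight_spec(baseline = character(0), timevarying = character(0),
                      time = "indicator")
  wmod <- fit_initiation_model(pan, spec)
  risk <- pan[!on_oac | initiated_this_month]
  emp <- risk[, .(p = mean(initiated_this_month)), by = month][order(month)]
  fit_p <- unique(data.table(month = risk$month,
                             p = fitted(wmod$fit)))[order(month)]
  expect_equal(fit_p$p, emp$p, tolerance = 1e-8)
})

test_that("cumulative weights follow the exact product rule", {
  # regimen-consistent probability 0.8 in each of 3 months, no dropout
  clone <- manual_clone(3, "never")
  wm <- weight_model(constant_model(0.2), constant_model(0))
  w <- compute_cumulative_weights(clone, wm)
  expect_identical(w$cumulative_weight, c(1.25, 1.5625, 1.953125))
  # consistent behavior certain -> every weight exactly 1
  w1 <- compute_cumulative_weights(clone, weight_model(constant_model(0),
                                                       constant_model(0)))
  expect_true(all(w1$cumulative_weight == 1))
  # threshold arm: wait (score < k), grace window, deadline, post-initiation
  cl <- manual_clone(6, "threshold", 4L, score = c(2L, 2L, 4L, 4L, 4L, 4L),
                     initiated_month = 3L)
  w2 <- compute_cumulative_weights(cl, wm, grace_months = 1)
  # months 0-1: 1/0.8; month 2 (crossing, inside grace): 1;
  # month 3 (deadline, initiates): 1/0.2; months 4-5 treated: 1
  expect_equal(w2$factor_treatment, c(1.25, 1.25, 1, 5, 1, 1))
  expect_equal(w2$cumulative_weight, cumprod(c(1.25, 1.25, 1, 5, 1, 1)))
  # dropout factors multiply in: d = 0.1 every observed month
  w3 <- compute_cumulative_weights(clone, weight_model(constant_model(0.2),
                                                       constant_model(0.1)))
  expect_equal(w3$cumulative_weight, cumprod(rep(1 / (0.8 * 0.9), 3)))
})

test_that("clone weights match the brute-force replay on a small cohort", {
  prep <- prep_clones(small_config(200, seed = 61,
                                   initiation = list(intercept = -2.5,
                                                     per_point = 0.3)))
  cl <- prep$clones
  p_init <- ccwemu:::.predict_ccw(prep$wm$initiation, cl)
  d_hat <- ccwemu:::.predict_ccw(prep$wm$dropout, cl)
  cl[, `:=`(p_ = p_init, d_ = d_hat)]
  oracle <- cl[, .(month = month, want = oracle_clone_weights(
    .SD, regimen_kind[1], regimen_k[1], 1, p_, d_)),
    by = .(patient_id, regimen)]
  expect_equal(cl$cumulative_weight, oracle$want, tolerance = 1e-12)
})

test_that("weight invariants: factors >= 1, cumulative non-decreasing", {
  prep <- prep_clones(small_config(200, seed = 71))
  cl <- prep$clones
  expect_true(all(cl$factor_treatment >= 1))
  expect_true(all(cl$factor_censoring >= 1))
  expect_true(all(cl[, all(diff(cumulative_weight) >= 0),
                     by = .(patient_id, regimen)]$V1))
})

test_that("truncation uses the pooled linear-interpolation percentile", {
  cl <- manual_clone(3, "never")[, cumulative_weight := c(1, 2, 3)]
  expect_identical(truncate_weights(copy(cl), 100)$truncated_weight,
                   cl$cumulative_weight) # identity at percentile 100
  w <- manual_clone(100, "never")[, cumulative_weight := as.numeric(1:100)]
  t95 <- truncate_weights(copy(w), 95)
  cap <- stats::quantile(1:100, 0.95, type = 7, names = FALSE)
  expect_identical(attr(t95, "weight_cap"), cap)
  expect_identical(sum(t95$truncated_weight == cap) - sum(w$cumulative_weight == cap),
                   sum(w$cumulative_weight > cap))
  expect_true(all(t95$truncated_weight <= cap))
  # degenerate distribution unchanged at any percentile
  eq <- manual_clone(10, "never")[, cumulative_weight := 2]
  expect_identical(truncate_weights(copy(eq), 50)$truncated_weight, rep(2, 10))
  # monotone: a lower percentile never leaves a larger weight
  t99 <- truncate_weights(copy(w), 99)
  expect_true(all(t95$truncated_weight <= t99$truncated_weight))
  expect_error(truncate_weights(w, 0), "percentile")
  expect_error(truncate_weights(w, 101), "percentile")
})

test_that("pseudo-population: weighted clone-months rebuild the cohort risk set", {
  cfg <- sim_config(n_patients = 10000, seed = 5,
                    hazards = list(stroke = 0.001, bleed = 0.0006,
                                   death = 0.010, dropout = 0))
  prep <- suppressWarnings(prep_clones(cfg))
  atrisk <- prep$eligible[, .N, by = month]
  mass <- prep$clones[artificially_censored == FALSE,
                      .(mass = sum(cumulative_weight)), by = .(regimen, month)]
  chk <- merge(mass, atrisk, by = "month")
  expect_lt(max(abs(chk$mass / chk$N - 1)), 0.10)
})

test_that("ignorable dropout: IPCW-weighted and unweighted risks agree", {
  cfg <- sim_config(n_patients = 8000, seed = 19,
                    initiation = list(intercept = -50, per_point = 0),
                    hazards = list(stroke = 0.004, bleed = 0.0006,
                                   death = 0.010, dropout = 0.02))
  pan <- score_panel(simulate_cohort(cfg))
  # nobody ever initiates, so the on_oac term is inestimable (rank warning)
  dmod <- suppressWarnings(fit_dropout_model(pan))
  d_hat <- suppressWarnings(ccwemu:::.predict_ccw(dmod, pan))
  pan[, w_ipcw := cumprod(ifelse(dropout, 1, 1 / (1 - d_hat[.I]))),
      by = patient_id]
  ar <- truncate_at_event(pan, "stroke")
  unw <- ar[, .(h = mean(event_stroke)), by = month][order(month)]
  wgt <- ar[, .(h = weighted.mean(event_stroke, w_ipcw)), by = month][order(month)]
  risk_u <- 1 - prod(1 - unw$h)
  risk_w <- 1 - prod(1 - wgt$h)
  expect_lt(abs(risk_u - risk_w), 0.01)
})
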