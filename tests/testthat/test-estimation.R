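# crafted outcome-model object with known coefficients
crafted_model <- function(coef, vcov, arms, ref = "never",
                          time = "quadratic", outcome = "stroke") {
  structure(list(fit = list(coef = coef, vcov = vcov), arms = arms, ref = ref,
                 zero_event_arms = character(0), time = time,
                 outcome = outcome), class = "ccw_outcome_model")
}

test_that("incidence_rate reproduces printed-table arithmetic exactly", {
  expect_identical(incidence_rate(188, 4980), 37.75)
  expect_identical(incidence_rate(358, 20898), 17.13)
  expect_identical(incidence_rate(0, 100), 0)
  expect_error(incidence_rate(10, 0), "person_years")
  expect_error(incidence_rate(-1, 10), "negative")
})

test_that("summary_hr is the exponentiated coefficient with Wald CI", {
  m <- crafted_model(
    coef = c(`(Intercept)` = -5, regimenge4 = 0, regimenge6 = -0.446,
             month = 0, month2 = 0),
    vcov = diag(c(1, 0.1^2, 0.05^2, 1, 1)) |>
      (\(v) { dimnames(v) <- rep(list(c("(Intercept)", "regimenge4",
                                        "regimenge6", "month", "month2")), 2); v })(),
    arms = c("ge4", "ge6", "never"))
  hr <- summary_hr(m)
  expect_equal(hr[regimen == "ge4"]$hr, 1)
  expect_equal(round(hr[regimen == "ge4"]$lower, 2), 0.82)
  expect_equal(round(hr[regimen == "ge4"]$upper, 2), 1.22)
  expect_equal(round(hr[regimen == "ge6"]$hr, 2), 0.64)
  expect_equal(round(hr[regimen == "ge6"]$lower, 2), 0.58)
  expect_equal(round(hr[regimen == "ge6"]$upper, 2), 0.71)
  expect_true(all(hr[, lower <= hr & hr <= upper]))
})

test_that("survival closed forms: constant hazard and degenerate no-event fit", {
  clones <- manual_clone(12, "never")
  m <- crafted_model(
    coef = c(`(Intercept)` = stats::qlogis(0.01), month = 0, month2 = 0),
    vcov = diag(3), arms = "never")
  sc <- survival_curves(m, clones, weight_col = "truncated_weight")
  expect_equal(sc[month == 12]$survival, 0.99^12, tolerance = 1e-12)
  expect_equal(sc[month == 0]$survival, 1)
  expect_true(all(diff(sc$survival) <= 0))
  m0 <- crafted_model(coef = c(`(Intercept)` = -50, month = 0, month2 = 0),
                      vcov = diag(3), arms = "never")
  expect_equal(survival_curves(m0, clones)$survival, rep(1, 13),
               tolerance = 1e-12)
})

test_that("indicator-time single-arm curve equals the product-limit estimator", {
  cfg <- sim_config(n_patients = 1000, seed = 33,
                    initiation = list(intercept = -50, per_point = 0),
                    hazards = list(stroke = 0.02, bleed = 0.0006,
                                   death = 0.01, dropout = 0.005))
  pan <- score_panel(simulate_cohort(cfg))
  clones <- expand_clones(pan, list(regimen("never")))
  clones <- apply_artificial_censoring(clones, 1)
  clones[, truncated_weight := 1]
  m <- fit_outcome_model(clones, "stroke", time = "indicator")
  sc <- survival_curves(m, clones)
  km <- oracle_km_survival(truncate_at_event(pan, "stroke"), "event_stroke")
  expect_equal(sc[month > 0]$survival, km, tolerance = 1e-8)
})

test_that("weighted HRs are invariant to rescaling all weights", {
  prep <- prep_clones(small_config(400, seed = 44))
  m1 <- fit_outcome_model(prep$clones, "stroke")
  scaled <- copy(prep$clones)[, truncated_weight := truncated_weight * 3]
  m2 <- fit_outcome_model(scaled, "stroke")
  expect_equal(m1$fit$coef, m2$fit$coef, tolerance = 1e-6)
  # bread scales as 1/c^2 and meat as c^2, so robust SEs match too
  expect_equal(summary_hr(m1)$se, summary_hr(m2)$se, tolerance = 1e-6)
})

test_that("person-time bookkeeping: unit conversion and row-count oracle", {
  # one clone followed 12 months, no event
  full <- manual_clone(12, "never")
  pt <- person_time_summary(full, "stroke")
  expect_equal(pt$person_years, 1.0)
  expect_identical(pt$events, 0L)
  # clone artificially censored at month 6: months 0..5 at risk
  cen <- manual_clone(7, "never")
  cen[month == 6, artificially_censored := TRUE][, censor_month := 6L]
  expect_equal(person_time_summary(cen, "stroke")$person_years, 0.5)
  # event in the censoring month of another clone is not counted
  # (cleared by apply_artificial_censoring; person_time ignores flagged rows)
  # seeded run equals direct row counting
  prep <- prep_clones(small_config(150, seed = 47))
  pt2 <- person_time_summary(prep$clones, "bleed")
  ar <- prep$clones[artificially_censored == FALSE]
  ar[, cid := paste(patient_id, regimen)]
  manual <- ar[, {
    w <- which(event_bleed)
    keep <- if (length(w)) seq_len(w[1]) else seq_len(.N)
    .(months = length(keep), ev = length(w) > 0)
  }, by = .(cid, regimen)][, .(events = sum(ev), person_years = sum(months) / 12),
                           by = regimen][order(regimen)]
  expect_equal(pt2$events, as.integer(manual$events))
  expect_equal(pt2$person_years, manual$person_years)
})

test_that("zero-event arms are flagged and excluded, reference must have events", {
  prep <- prep_clones(small_config(
    800, seed = 48,
    hazards = list(stroke = 0.01, bleed = 0.0006, death = 0.01,
                   dropout = 0.005)))
  cl <- copy(prep$clones)
  cl[regimen == "ge1", `:=`(event_stroke = FALSE)]
  expect_warning(m <- fit_outcome_model(cl, "stroke"), "zero events")
  hr <- summary_hr(m)
  expect_true(is.na(hr[regimen == "ge1"]$hr))
  expect_false(anyNA(hr[regimen != "ge1"]$hr))
  cl2 <- copy(prep$clones)[, event_stroke := FALSE]
  expect_error(fit_outcome_model(cl2, "stroke"), "reference arm")
})

test_that("patient-level bootstrap is seeded, shaped and centered on the fit", {
  cfg <- small_config(500, seed = 64,
                      hazards = list(stroke = 0.01, bleed = 0.0006,
                                     death = 0.01, dropout = 0.005))
  pan <- apply_eligibility(score_panel(simulate_cohort(cfg)))$panel
  b1 <- suppressWarnings(bootstrap_hr(pan, "stroke", n_boot = 6, seed = 3))
  b2 <- suppressWarnings(bootstrap_hr(pan, "stroke", n_boot = 6, seed = 3))
  expect_identical(b1$log_hr_draws, b2$log_hr_draws)
  expect_identical(dim(b1$log_hr_draws), c(6L, 4L))
  expect_identical(b1$hr$n_boot + b1$n_failed, rep(6L, 4))
  # point estimate equals the non-resampled pipeline fit
  prep <- prep_clones(cfg)
  hr <- summary_hr(suppressWarnings(fit_outcome_model(prep$clones, "stroke")))
  expect_equal(b1$hr$log_hr, hr[match(b1$hr$regimen, regimen)]$log_hr,
               tolerance = 1e-10)
  expect_true(all(b1$hr[!is.na(lower), lower <= upper]))
})

test_that("cluster-robust sandwich matches a direct computation", {
  set.seed(99)
  n <- 400
  x <- rnorm(n)
  cl <- rep(1:100, each = 4)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * x))
  w <- runif(n, 0.5, 2)
  X <- cbind(1, x)
  fit <- ccwemu:::fit_pooled_logit(X, y, w, cluster = cl)
  # independent reference: glm coefficients + textbook sandwich
  ref <- suppressWarnings(glm(y ~ x, family = binomial(), weights = w,
                              control = glm.control(epsilon = 1e-12)))
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  mu <- fitted(ref)
  bread <- solve(t(X) %*% (X * (w * mu * (1 - mu))))
  U <- rowsum(X * (w * (y - mu)), cl)
  V <- bread %*% (t(U) %*% U) %*% bread
  expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-6)
})
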