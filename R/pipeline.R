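#' Configuration for a full emulation run
#'
#' Bundles every knob of the simulate -> score -> eligibility ->
#' clone/censor -> weight -> estimate pipeline. Defaults reproduce the
#' primary analysis: strategies "initiate when CHA2DS2-VASc first >= k"
#' for k in {1, 2, 4, 6} plus never-initiate (reference), 12 months of
#' follow-up with administrative censoring, a 1-month grace period, and
#' weight truncation at the pooled 99th percentile.
#'
#' @param sim a [sim_config()] used when no input panel is given; its seed
#'   is overridden by `seed`.
#' @param input_panel optional path to a person-month CSV ([read_panel()]);
#'   takes precedence over simulation.
#' @param out_dir optional output directory; when set, [run_emulation()]
#'   writes the result bundle there.
#' @param thresholds strictly increasing CHA2DS2-VASc thresholds for the
#'   active arms.
#' @param grace_months grace period for threshold compliance.
#' @param follow_up_months administrative censoring horizon (12 primary;
#'   36 in sensitivity analysis). Months are 0-indexed: the maximum month
#'   in any output is `follow_up_months - 1`.
#' @param truncation_percentile pooled weight-truncation percentile (99
#'   primary; 95 in sensitivity analysis).
#' @param weights a [weight_spec()] for both weight models.
#' @param outcome_time time terms of the outcome model (`"quadratic"` or
#'   `"indicator"`).
#' @param outcomes outcomes to analyse.
#' @param subgroup optional `list(column =, value =)` restricting the
#'   cohort to patients with that baseline value (e.g.
#'   `list(column = "cancer_type", value = "lung")`).
#' @param drop_metastatic,drop_thrombocytopenia sensitivity toggles that
#'   exclude patients with distant-stage cancer / baseline
#'   thrombocytopenia before eligibility.
#' @param criteria an [eligibility_criteria()].
#' @param seed integer seed driving simulation.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       input_panel = NULL,
                       out_dir = NULL,
                       thresholds = c(1L, 2L, 4L, 6L),
                       grace_months = 1L,
                       follow_up_months = 12L,
                       truncation_percentile = 99,
                       weights = weight_spec(),
                       outcome_time = "quadratic",
                       outcomes = c("stroke", "bleed"),
                       subgroup = NULL,
                       drop_metastatic = FALSE,
                       drop_thrombocytopenia = FALSE,
                       criteria = eligibility_criteria(),
                       seed = 1L) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop_config("thresholds", "must be strictly increasing")
  if (follow_up_months < 1) stop_config("follow_up_months", "must be >= 1")
  if (grace_months < 0) stop_config("grace_months", "must be >= 0")
  structure(list(sim = sim, input_panel = input_panel, out_dir = out_dir,
                 thresholds = as.integer(thresholds),
                 grace_months = as.integer(grace_months),
                 follow_up_months = as.integer(follow_up_months),
                 truncation_percentile = truncation_percentile,
                 weights = weights, outcome_time = outcome_time,
                 outcomes = outcomes, subgroup = subgroup,
                 drop_metastatic = drop_metastatic,
                 drop_thrombocytopenia = drop_thrombocytopenia,
                 criteria = criteria, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full target-trial emulation
#'
#' Executes every stage in order for each configured outcome and returns an
#' `EmulationResult` bundle: per-regimen events, person-years and incidence
#' rates, summary hazard ratios with cluster-robust 95% CIs versus the
#' never-initiate arm, standardized survival curves, weight diagnostics,
#' the attrition log, per-stage row counts and a machine-readable manifest.
#' Re-running with the same config and seed reproduces the outputs
#' bit-identically.
#'
#' @param config a [run_config()].
#' @param write write the bundle to `config$out_dir` (default: only when an
#'   output directory is configured).
#' @return an object of class `ccw_result`.
#' @export
run_emulation <- function(config, write = !is.null(config$out_dir)) {
  stopifnot(inherits(config, "run_config"))
  stages <- list()
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  panel <- wrap("input", {
    if (!is.null(config$input_panel)) {
      read_panel(config$input_panel)
    } else {
      cfg <- config$sim
      cfg$seed <- config$seed
      cfg$max_months <- config$follow_up_months
      simulate_cohort(cfg)
    }
  })
  panel <- panel[month < config$follow_up_months]
  required <- setdiff(panel_columns(), c("chads_vasc", "has_bled", "eligible"))
  missing <- setdiff(required, names(panel))
  if (length(missing))
    stop(sprintf("input panel is missing required field(s): %s (multiple imputation is not supported; supply complete data)",
                 paste(missing, collapse = ", ")), call. = FALSE)
  panel <- wrap("scores", score_panel(panel))
  stages$panel_rows <- nrow(panel)
  stages$patients <- data.table::uniqueN(panel$patient_id)

  # cohort restrictions before eligibility (subgroups / sensitivity)
  base <- panel[month == 0L]
  keep <- base$patient_id
  if (!is.null(config$subgroup))
    keep <- intersect(keep,
      base$patient_id[base[[config$subgroup$column]] == config$subgroup$value])
  if (isTRUE(config$drop_metastatic))
    keep <- setdiff(keep, base$patient_id[base$cancer_stage == "distant"])
  if (isTRUE(config$drop_thrombocytopenia))
    keep <- setdiff(keep, base$patient_id[base$thrombocytopenia])
  panel <- panel[patient_id %in% keep]

  elig <- wrap("eligibility", apply_eligibility(panel, config$criteria))
  stages$eligible_patients <- data.table::uniqueN(elig$panel$patient_id)

  regimens <- default_regimens(config$thresholds)
  clones <- wrap("cloning", expand_clones(elig$panel, regimens))
  stages$clones <- nrow(unique(clones[, .(patient_id, regimen)]))
  clones <- wrap("baseline_exclusion",
                 apply_baseline_exclusion(clones, config$grace_months))
  stages$clones_after_baseline_exclusion <-
    nrow(unique(clones[, .(patient_id, regimen)]))
  clones <- wrap("artificial_censoring",
                 apply_artificial_censoring(clones, config$grace_months))
  stages$censored_clones <- nrow(unique(
    clones[artificially_censored == TRUE, .(patient_id, regimen)]))

  wm <- wrap("weight_models", weight_model(
    fit_initiation_model(elig$panel, config$weights),
    fit_dropout_model(elig$panel, config$weights)))
  clones <- wrap("weights",
                 compute_cumulative_weights(clones, wm, config$grace_months))
  clones <- wrap("truncation",
                 truncate_weights(clones, config$truncation_percentile))
  stages$weighted_clone_months <- nrow(clones[artificially_censored == FALSE])

  outcomes <- lapply(config$outcomes, function(oc) {
    pt <- person_time_summary(clones, oc)
    om <- wrap(paste0("outcome_model_", oc),
               fit_outcome_model(clones, oc, time = config$outcome_time))
    hr <- summary_hr(om)
    sc <- survival_curves(om, clones)
    naive <- naive_association(elig$panel, oc)
    list(person_time = pt, model = om, hr = hr, curves = sc, naive = naive)
  })
  names(outcomes) <- config$outcomes

  manifest <- list(
    package = "ccwemu",
    version = as.character(utils::packageVersion("ccwemu")),
    seed = config$seed,
    config = serialize_config(config))
  res <- structure(list(config = config, attrition = elig$attrition,
                        stages = stages, outcomes = outcomes,
                        weight_diagnostics = weight_diagnostics(clones),
                        weight_cap = attr(clones, "weight_cap"),
                        clones = clones, manifest = manifest),
                   class = "ccw_result")
  if (write) write_result(res, config$out_dir)
  res
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  cfg$weights <- unclass(cfg$weights)
  cfg$criteria <- unclass(cfg$criteria)
  cfg$out_dir <- NULL
  cfg
}

#' Tidy results table of an emulation run
#'
#' @param res a `ccw_result`.
#' @return data.table, one row per regimen x outcome with events,
#'   person-years, incidence rate and adjusted HR columns.
#' @export
results_table <- function(res) {
  stopifnot(inherits(res, "ccw_result"))
  rows <- lapply(names(res$outcomes), function(oc) {
    o <- res$outcomes[[oc]]
    tab <- merge(o$person_time, o$hr, by = "regimen", all.x = TRUE)
    tab[, outcome := oc]
    tab
  })
  out <- data.table::rbindlist(rows, fill = TRUE)
  data.table::setcolorder(out, c("outcome", "regimen"))
  out[]
}

write_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(results_table(res), file.path(dir, "results.csv"))
  data.table::fwrite(res$attrition, file.path(dir, "attrition.csv"))
  data.table::fwrite(res$weight_diagnostics,
                     file.path(dir, "weight_diagnostics.csv"))
  curves <- data.table::rbindlist(lapply(names(res$outcomes), function(oc) {
    cv <- data.table::copy(res$outcomes[[oc]]$curves)
    cv[, outcome := oc]
  }))
  data.table::fwrite(curves, file.path(dir, "survival_curves.csv"))
  jsonlite::write_json(c(res$manifest, list(stages = res$stages)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.ccw_result <- function(x, ...) {
  cat("Clone-censor-weight emulation\n")
  cat(sprintf("  patients: %d (eligible: %d); clones: %d (post-exclusion: %d, deviation-censored: %d)\n",
              x$stages$patients, x$stages$eligible_patients, x$stages$clones,
              x$stages$clones_after_baseline_exclusion, x$stages$censored_clones))
  cat(sprintf("  follow-up: %d months; grace: %d; truncation: p%s (cap %.3f)\n",
              x$config$follow_up_months, x$config$grace_months,
              format(x$config$truncation_percentile), x$weight_cap))
  for (oc in names(x$outcomes)) {
    cat(sprintf("  outcome: %s\n", oc))
    tab <- merge(x$outcomes[[oc]]$person_time, x$outcomes[[oc]]$hr,
                 by = "regimen", all.x = TRUE)
    print(tab[, .(regimen, events, person_years = round(person_years, 1),
                  rate_per_1000py, hr = round(hr, 2),
                  lower = round(lower, 2), upper = round(upper, 2))])
  }
  invisible(x)
}

#' Run the sensitivity-analysis suite
#'
#' Re-runs the emulation with one field toggled per variant: 36-month
#' follow-up, exclusion of metastatic (distant-stage) patients, exclusion
#' of baseline thrombocytopenia, and weight truncation at the 95th
#' percentile. Returns the base run, all variant runs and a side-by-side
#' comparison table.
#'
#' @param config a [run_config()] for the base analysis.
#' @return list with `base`, `variants` (named list of `ccw_result`) and
#'   `comparison` (data.table with a `variant` column).
#' @export
run_sensitivity_suite <- function(config) {
  stopifnot(inherits(config, "run_config"))
  variants <- list(
    follow_up_36 = function(cfg) { cfg$follow_up_months <- 36L; cfg },
    no_metastatic = function(cfg) { cfg$drop_metastatic <- TRUE; cfg },
    no_thrombocytopenia = function(cfg) { cfg$drop_thrombocytopenia <- TRUE; cfg },
    truncation_95 = function(cfg) { cfg$truncation_percentile <- 95; cfg })
  base_dir <- config$out_dir
  config$out_dir <- if (!is.null(base_dir)) file.path(base_dir, "base")
  base <- run_emulation(config)
  runs <- lapply(names(variants), function(v) {
    cfg <- variants[[v]](config)
    cfg$out_dir <- if (!is.null(base_dir)) file.path(base_dir, v)
    res <- run_emulation(cfg)
    res$manifest$variant <- v
    res
  })
  names(runs) <- names(variants)
  comparison <- data.table::rbindlist(c(
    list(data.table::copy(results_table(base))[, variant := "base"]),
    lapply(names(runs), function(v)
      data.table::copy(results_table(runs[[v]]))[, variant := v])),
    fill = TRUE)
  data.table::setcolorder(comparison, "variant")
  if (!is.null(base_dir))
    data.table::fwrite(comparison, file.path(base_dir, "sensitivity.csv"))
  list(base = base, variants = runs, comparison = comparison[])
}
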