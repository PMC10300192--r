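#' Configuration of a full synthetic study
#'
#' Bundles every setting of the end-to-end protocol: the two experimental
#' designs, the generating truth, the split fraction, the number of
#' train/validation rounds, the baselines to run, and the calibration
#' control. Per-round seeds are derived from `seed` as `seed + round`, so
#' any round can be reproduced independently.
#'
#' @param rounds Number of train/validation rounds.
#' @param design_a,design_b [design_spec()]s for the untreated and treated
#'   experiments.
#' @param truth A [truth_params()] used to generate the synthetic data.
#' @param train_frac Training fraction of the well-level split.
#' @param models Baseline regressors to evaluate.
#' @param include_mechanism Whether to calibrate and score the mechanistic
#'   model in every round.
#' @param control A [calibration_control()] for the mechanistic stages.
#' @param seed Base seed (data generation uses `seed`; round `r` uses
#'   `seed + r`).
#' @return A list of class `study_config`.
#' @export
study_config <- function(rounds = 50L, design_a = design_spec("A"),
                         design_b = design_spec("B"),
                         truth = truth_params(), train_frac = 0.75,
                         models = c("linear", "knn", "tree", "forest"),
                         include_mechanism = TRUE,
                         control = calibration_control(), seed = 1L) {
  structure(list(rounds = as.integer(rounds), design_a = design_a,
                 design_b = design_b, truth = truth,
                 train_frac = train_frac, models = models,
                 include_mechanism = include_mechanism, control = control,
                 seed = as.integer(seed)),
            class = "study_config")
}

# subset a dataset to a set of well ids, preserving order of appearance
.dataset_subset_ids <- function(ds, ids) {
  keep <- ds$wells$well_id %in% ids
  structure(list(wells = ds$wells[keep, , drop = FALSE],
                 courses = ds$courses[ds$courses$well_id %in% ids, ,
                                      drop = FALSE],
                 seed = ds$seed),
            class = "confluence_dataset")
}

# Step-7 predictor closure for the repeated-evaluation harness: calibrates
# on the round's training wells and predicts the validation rows from their
# measured t = 0 confluences.
.mechanism_predictor <- function(dsA, dsB, fixed, control) {
  function(train_ft, valid_ft, round_seed) {
    ids_tr <- unique(train_ft$well_id)
    a_tr <- .dataset_subset_ids(dsA, ids_tr)
    b_tr <- .dataset_subset_ids(dsB, ids_tr)
    if (nrow(b_tr$wells) == 0L) b_tr <- NULL
    cal <- calibrate_growth(a_tr, b_tr, fixed, control)
    .predict_ft(cal, valid_ft)
  }
}

# predict the rows of a feature table with a calibrated model; returns a
# matrix with live/dead confluence fractions aligned to the rows
.predict_ft <- function(cal, ft) {
  out <- matrix(NA_real_, nrow(ft), 2L,
                dimnames = list(NULL, c("live", "dead")))
  for (id in unique(ft$well_id)) {
    sel <- ft$well_id == id
    w0 <- ft[sel, ][1L, ]
    gin <- gin_for_dose(cal$inhibition, w0$dose)
    kb <- bystander_rate(
      accessible_glucose(w0$G0, w0$N0 * cal$globals$theta, gin),
      cal$relation)
    tt <- ft$time[sel]
    o <- order(tt)
    grid <- sort(unique(c(0, tt)))
    sim <- .sim_conf(w0$N0 * cal$globals$theta, w0$D0 * cal$globals$theta,
                     w0$G0, kb, gin, grid, cal$globals)
    ix <- match(tt, grid)
    out[which(sel), ] <- cbind(sim[ix, "live"], sim[ix, "dead"]) / 100
  }
  out
}

# per-well error metrics of a prediction table against a dataset, averaged
# over wells: rows live/dead, columns the four error summaries
.error_report <- function(pred_df, ds) {
  per <- lapply(unique(pred_df$well_id), function(id) {
    obs <- well_course(ds, id)
    pr <- pred_df[pred_df$well_id == id, ]
    pr <- pr[order(pr$time_days), ]
    em <- error_metrics(pr[, c("time_days", "live_pct", "dead_pct")],
                        obs[, c("time_days", "live_pct", "dead_pct")])
    em
  })
  all <- do.call(rbind, per)
  stats::aggregate(
    all[, c("mean_percent_error", "percent_error_end", "mean_error",
            "error_end")],
    by = list(channel = all$channel), FUN = mean, na.rm = TRUE)
}

#' Run the full synthetic study
#'
#' Generates the untreated and treated datasets from the configured truth,
#' then performs the repeated train/validation protocol: in each round the
#' wells are split (separately within each dataset), the mechanistic model
#' is calibrated on the training wells and predicts the validation wells
#' from initial conditions only, the baseline regressors are trained on the
#' combined training set, and every model is scored with the same
#' R-squared on the same splits. Scores are summarized as mean with 95%
#' confidence intervals, and the models are compared by one-way ANOVA with
#' Bonferroni-corrected pairwise tests.
#'
#' @param config A [study_config()].
#' @return An object of class `study_report` with `scores` (summary table),
#'   `per_round`, `anova`, `pairwise`, `mech_errors` (training- and
#'   validation-stage error metrics, when the mechanistic model is
#'   included), `datasets`, and the `config`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  dsA <- generate_dataset(config$design_a, config$truth, seed = config$seed)
  dsB <- generate_dataset(config$design_b, config$truth,
                          seed = config$seed + 1000L)
  combined <- combine_datasets(dsA, dsB)

  predictors <- NULL
  if (config$include_mechanism)
    predictors <- list(
      mechanism = .mechanism_predictor(dsA, dsB, config$truth$globals,
                                       config$control))
  ev <- repeated_evaluation(combined, models = config$models,
                            rounds = config$rounds, seed0 = config$seed,
                            train_frac = config$train_frac,
                            predictors = predictors)

  mech_errors <- NULL
  if (config$include_mechanism) {
    # error tables for the final round's calibration and prediction
    sp <- split_by_well(combined, config$train_frac,
                        seed = config$seed + config$rounds)
    a_tr <- .dataset_subset_ids(dsA, sp$train)
    b_tr <- .dataset_subset_ids(dsB, sp$train)
    cal <- calibrate_growth(a_tr, b_tr, config$truth$globals,
                            config$control)
    fit_res <- rbind(
      .fitted_courses(cal, "a"),
      .fitted_courses(cal, "b"))
    valid_wells <- combined$wells[combined$wells$well_id %in% sp$valid, ]
    pred <- .predict_from_measured(cal, combined, sp$valid)
    mech_errors <- list(
      training = .error_report(fit_res, combined),
      validation = .error_report(pred, combined))
  }

  tot <- ev$per_round[ev$per_round$set == "valid" &
                        ev$per_round$channel == "total", ]
  groups <- split(tot$r2, tot$model)
  an <- if (length(groups) >= 2L) stats_anova_oneway(groups) else NULL
  pw <- if (length(groups) >= 2L) stats_pairwise_bonferroni(groups)
        else NULL

  structure(list(scores = ev$summary, per_round = ev$per_round,
                 anova = an, pairwise = pw, mech_errors = mech_errors,
                 datasets = list(a = dsA, b = dsB), config = config),
            class = "study_report")
}

# tidy fitted (calibrated, local-parameter) curves for a stage
.fitted_courses <- function(cal, stage) {
  res <- residuals.growth_calibration(cal, stage)
  ds <- if (stage == "a") cal$data$a else cal$data$b
  out <- lapply(unique(res$well_id), function(id) {
    obs <- well_course(ds, id)
    r <- res[res$well_id == id, ]
    data.frame(well_id = id, time_days = obs$time_days,
               live_pct = obs$live_pct +
                 r$residual[r$channel == "live"],
               dead_pct = obs$dead_pct +
                 r$residual[r$channel == "dead"])
  })
  do.call(rbind, out)
}

# step-7 predictions for a set of validation wells, initial conditions
# taken from the measured t = 0 confluences
.predict_from_measured <- function(cal, ds, ids) {
  wd <- .well_data(.dataset_subset_ids(ds, ids))
  out <- lapply(wd, function(w) {
    gin <- gin_for_dose(cal$inhibition, w$dose)
    kb <- bystander_rate(
      accessible_glucose(w$G0, w$N0 * cal$globals$theta, gin),
      cal$relation)
    sim <- .sim_conf(w$N0 * cal$globals$theta, w$D0 * cal$globals$theta,
                     w$G0, kb, gin, w$times, cal$globals)
    data.frame(well_id = w$well_id, time_days = w$times,
               live_pct = sim[, "live"], dead_pct = sim[, "dead"])
  })
  do.call(rbind, out)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Synthetic study: %d rounds, %d + %d wells\n\n",
              x$config$rounds, nrow(x$datasets$a$wells),
              nrow(x$datasets$b$wells)))
  tot <- x$scores[x$scores$channel == "total", ]
  tot <- tot[order(tot$set, -tot$mean), ]
  cat("Total R^2 (mean +/- 95% CI):\n")
  for (i in seq_len(nrow(tot)))
    cat(sprintf("  %-12s %-6s %.4f +/- %.4f\n", tot$model[i], tot$set[i],
                tot$mean[i], tot$ci95[i]))
  if (!is.null(x$anova))
    cat(sprintf("\nOne-way ANOVA on validation R^2: F = %.2f, p = %.3g\n",
                x$anova$F, x$anova$p))
  invisible(x)
}
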