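#' Calibrate the full growth model on untreated and treated datasets
#'
#' The main fitting entry point. Runs the staged calibration workflow:
#' (1) global rates and per-well bystander rates on the untreated dataset;
#' (2) the exponential-decay bystander relation against initial glucose;
#' on the treated dataset, (4) per-dose inhibition constants with the
#' bystander rate pinned through the relation, (5) a joint refit with the
#' inhibition constants confined to their stage-4 confidence intervals and
#' free per-well bystander rates, and (6) a refit of the relation against
#' initial accessible glucose when the decay pattern is confirmed. (Stage 3
#' is the composition used inside stage 4; stage 7 is [predict_course()],
#' exposed through the `predict` method.)
#'
#' @param dataset_a Untreated `confluence_dataset` (dose 0 everywhere).
#' @param dataset_b Treated `confluence_dataset` (may include untreated
#'   wells); `NULL` to calibrate the baseline model only.
#' @param fixed A [global_params()] supplying `theta`, `G_star`, `G_min`.
#' @param control A [calibration_control()].
#' @return An object of class `growth_calibration` with components
#'   `globals`, `relation`, `inhibition`, and the per-stage fits
#'   (`stage_a`, `relation_a`, `stage4`, `stage5`, `stage6`).
#' @seealso [predict.growth_calibration()], [simulate.growth_calibration()]
#' @export
calibrate_growth <- function(dataset_a, dataset_b = NULL,
                             fixed = global_params(),
                             control = calibration_control()) {
  s1 <- fit_dataset_a(dataset_a, fixed, control)
  s2 <- fit_kbys_relation(s1$k_bys, dataset_a$wells$G0, control$level)
  s4 <- s5 <- s6 <- NULL
  relation <- s2$relation
  inhibition <- inhibition_params(0, 0)
  if (!is.null(dataset_b)) {
    s4 <- fit_gin_constrained(dataset_b, s1$globals, s2$relation, control)
    s5 <- fit_gin_and_local_kbys(dataset_b, s1$globals, s4$intervals,
                                 control)
    s6 <- refit_relation_accessible(s5, dataset_b, s1$globals, s2$relation)
    relation <- s6$relation
    inhibition <- inhibition_params(c(0, s5$doses), c(0, unname(s5$G_in)))
  }
  structure(list(globals = s1$globals, relation = relation,
                 inhibition = inhibition,
                 stage_a = s1, relation_a = s2,
                 stage4 = s4, stage5 = s5, stage6 = s6,
                 control = control,
                 data = list(a = dataset_a, b = dataset_b)),
            class = "growth_calibration")
}

#' @export
print.growth_calibration <- function(x, ...) {
  cat("Calibrated glucose-accessibility growth model\n\n")
  print(x$globals)
  cat("\n")
  print(x$relation)
  if (length(x$inhibition$doses) > 1L) {
    cat("\n")
    print(x$inhibition)
  }
  cat(sprintf("\nStage-A objective (SSR): %.4g over %d wells\n",
              x$stage_a$objective, nrow(x$data$a$wells)))
  if (!is.null(x$stage5))
    cat(sprintf("Stage-5 objective (SSR): %.4g over %d wells\n",
                x$stage5$objective, nrow(x$data$b$wells)))
  invisible(x)
}

#' @export
coef.growth_calibration <- function(object, ...) {
  out <- c(k_p = object$globals$k_p, k_d = object$globals$k_d,
           v = object$globals$v,
           k_bys_0 = object$relation$k_bys_0, alpha = object$relation$alpha,
           beta = object$relation$beta)
  if (length(object$inhibition$doses) > 1L) {
    gin <- object$inhibition$G_in[object$inhibition$doses > 0]
    names(gin) <- paste0("G_in.",
                         object$inhibition$doses[object$inhibition$doses > 0])
    out <- c(out, gin)
  }
  out
}

#' @export
summary.growth_calibration <- function(object, ...) {
  s <- list(coef = coef(object),
            globals_ci = object$stage_a$intervals$globals,
            relation_ci = object$relation_a$intervals,
            gin_ci = if (!is.null(object$stage4)) object$stage4$intervals,
            cor_total = if (!is.null(object$stage6))
              object$stage6$cor_total,
            cor_accessible = if (!is.null(object$stage6))
              object$stage6$cor_accessible,
            pattern_ok = if (!is.null(object$stage6))
              object$stage6$pattern_ok,
            objective = c(stage_a = object$stage_a$objective,
                          stage5 = if (!is.null(object$stage5))
                            object$stage5$objective))
  class(s) <- "summary.growth_calibration"
  s
}

#' @export
print.summary.growth_calibration <- function(x, ...) {
  cat("Global rates (95% CI):\n")
  print(signif(x$globals_ci, 4))
  cat("\nBystander relation (95% CI):\n")
  print(signif(x$relation_ci, 4))
  if (!is.null(x$gin_ci)) {
    cat("\nInhibition constants (95% CI):\n")
    print(signif(x$gin_ci, 4))
  }
  if (!is.null(x$cor_total))
    cat(sprintf("\nLocal bystander rate vs glucose: r = %.3f (total), %.3f (accessible); decay pattern %s\n",
                x$cor_total, x$cor_accessible,
                if (isTRUE(x$pattern_ok)) "confirmed" else "not confirmed"))
  invisible(x)
}

#' Predict time courses from initial conditions
#'
#' @param object A `growth_calibration`.
#' @param newdata A well table (as from [make_design()]) or a list of
#'   [well()] objects; each well needs `initial_confluence`, `initial_dead`,
#'   `G0` and a `dose` present in the calibrated inhibition map.
#' @param times Prediction grid, days.
#' @param ... Unused.
#' @return A tidy data frame: `well_id`, `time_days`, `live_pct`,
#'   `dead_pct`.
#' @export
predict.growth_calibration <- function(object, newdata,
                                       times = default_time_grid(), ...) {
  wl <- if (is.data.frame(newdata)) as_well_list(newdata)
        else if (inherits(newdata, "well")) list(newdata) else newdata
  out <- lapply(wl, function(w) {
    tc <- predict_course(w, object$globals, object$relation,
                         object$inhibition, times)
    data.frame(well_id = w$well_id, time_days = tc$time_days,
               live_pct = tc$live_pct, dead_pct = tc$dead_pct)
  })
  do.call(rbind, out)
}

#' Residuals of the calibrated model against its training data
#'
#' @param object A `growth_calibration`.
#' @param stage `"a"` (untreated fit, per-well bystander rates) or `"b"`
#'   (stage-5 joint fit).
#' @param ... Unused.
#' @return Tidy data frame: `well_id`, `time_days`, `channel`, `residual`
#'   (fitted minus measured, confluence points).
#' @export
residuals.growth_calibration <- function(object, stage = c("a", "b"), ...) {
  stage <- match.arg(stage)
  if (stage == "b" && is.null(object$stage5))
    stop("residuals: no treated-dataset fit in this object")
  ds <- if (stage == "a") object$data$a else object$data$b
  kb <- if (stage == "a") object$stage_a$k_bys else object$stage5$k_bys
  gin_map <- if (stage == "a") NULL else object$stage5
  wd <- .well_data(ds)
  out <- lapply(seq_along(wd), function(i) {
    w <- wd[[i]]
    gin <- if (is.null(gin_map) || w$dose == 0) 0
           else gin_map$G_in[match(w$dose, gin_map$doses)]
    sim <- .sim_conf(w$N0 * object$globals$theta,
                     w$D0 * object$globals$theta, w$G0,
                     k_bys = unname(kb[paste0("k_bys.", w$well_id)]),
                     G_in = gin, times = w$times, params = object$globals)
    data.frame(well_id = w$well_id,
               time_days = rep(w$times, 2L),
               channel = rep(c("live", "dead"), each = length(w$times)),
               residual = c(sim[, "live"] - w$live, sim[, "dead"] - w$dead))
  })
  do.call(rbind, out)
}

#' Simulate synthetic datasets from the calibrated model
#'
#' @param object A `growth_calibration`.
#' @param nsim Number of datasets.
#' @param seed Base seed (dataset `i` uses `seed + i - 1`).
#' @param design A [design_spec()] or well table to simulate.
#' @param noise_sd Measurement noise SD, confluence points.
#' @param ... Unused.
#' @return A `confluence_dataset` (or a list of them when `nsim > 1`).
#' @export
simulate.growth_calibration <- function(object, nsim = 1L, seed = 1L,
                                        design = design_spec("B"),
                                        noise_sd = 0.5, ...) {
  truth <- truth_params(globals = object$globals,
                        relation = object$relation,
                        inhibition = object$inhibition,
                        noise_sd = noise_sd)
  out <- lapply(seq_len(nsim), function(i)
    generate_dataset(design, truth, seed = seed + i - 1L))
  if (nsim == 1L) out[[1L]] else out
}

#' Plot fitted or predicted time courses against measurements
#'
#' @param x A `growth_calibration`.
#' @param well_ids Wells to display (default: up to 4 from the untreated
#'   dataset).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.growth_calibration <- function(x, well_ids = NULL, ...) {
  ds <- x$data$a
  if (is.null(well_ids))
    well_ids <- utils::head(ds$wells$well_id, 4L)
  old <- graphics::par(mfrow = c(ceiling(length(well_ids) / 2), 2),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (id in well_ids) {
    obs <- well_course(ds, id)
    i <- match(id, ds$wells$well_id)
    kb <- unname(x$stage_a$k_bys[paste0("k_bys.", id)])
    sim <- .sim_conf(obs$live_pct[1L] / 100 * x$globals$theta,
                     obs$dead_pct[1L] / 100 * x$globals$theta,
                     ds$wells$G0[i], kb, 0, obs$time_days, x$globals)
    graphics::matplot(obs$time_days, cbind(obs$live_pct, obs$dead_pct),
                      pch = 1, col = c("steelblue", "tomato"),
                      xlab = "time (days)", ylab = "confluence (%)",
                      main = id, ...)
    graphics::matlines(obs$time_days, sim, lty = 1,
                       col = c("steelblue", "tomato"))
  }
  invisible(x)
}
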