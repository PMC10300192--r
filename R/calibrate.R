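#' Calibrate global rates and per-well bystander rates on an untreated dataset
#'
#' Stage 1 of the calibration workflow. Fits the proliferation rate `k_p`,
#' the starvation death rate `k_d` and the consumption rate `v` jointly
#' across all wells (global parameters), together with one bystander death
#' rate `k_bys` per well (local parameter), by minimizing the pooled sum of
#' squared residuals between simulated and measured live and dead confluence
#' over every well and time point. The first measured live/dead confluences
#' of each well serve as its initial conditions.
#'
#' @param dataset A `confluence_dataset` of untreated wells (dose 0).
#' @param fixed A [global_params()] supplying the non-fitted constants
#'   (`theta`, `G_star`, `G_min`); its rate entries are ignored.
#' @param control A [calibration_control()].
#' @return A list of class `stage_a_fit` with elements `globals`
#'   (a [global_params()] with fitted rates), `k_bys` (named vector),
#'   `intervals` (list with `globals` and `k_bys` matrices), `objective`,
#'   `per_well` (per-well RSS), and `diagnostics`.
#' @export
fit_dataset_a <- function(dataset, fixed = global_params(),
                          control = calibration_control()) {
  stopifnot(inherits(fixed, "global_params"),
            inherits(control, "calibration_control"))
  wd <- .well_data(dataset)
  if (any(vapply(wd, function(w) w$dose, 0) != 0))
    stop("fit_dataset_a: expects an untreated dataset (all doses 0)")
  if (length(wd) == 1L)
    warning("fit_dataset_a: a single well cannot identify three global ",
            "rates and a local rate reliably")
  n_w <- length(wd)

  lower <- c(0, 0, 0, rep(0, n_w))
  upper <- c(5, 5, 1e-3, rep(5, n_w))
  rows <- .row_index(wd)

  resid_fn <- function(par) .stage_a_resid(par, wd, fixed, control)
  jac_fn <- function(par) {
    .block_jacobian(par, wd, fixed, control, rows,
                    n_glob = 3L, glob_upper = upper[1:3],
                    resid_fn = resid_fn)
  }

  start <- c(0.3, 0.1, 1e-4, rep(0.05, n_w))
  gstarts <- .multi_starts(start[1:3], lower[1:3], upper[1:3],
                           control$n_starts, control$start_seed)
  starts <- lapply(gstarts, function(g) c(g, rep(0.05, n_w)))

  fit <- .bounded_lsq(resid_fn, start, lower, upper, jac_fn = jac_fn,
                      control = control, starts = starts)

  nm <- c("k_p", "k_d", "v", paste0("k_bys.", vapply(wd, `[[`, "", "well_id")))
  names(fit$par) <- nm
  globals <- global_params(k_p = max(fit$par[1L], 1e-12),
                           k_d = max(fit$par[2L], 1e-12),
                           v = max(fit$par[3L], 1e-12),
                           theta = fixed$theta, G_star = fixed$G_star,
                           G_min = fixed$G_min)
  ints <- .stage_intervals(fit, nm, dataset, control, refit = function(idx) {
    sub <- .subset_dataset(dataset, idx)
    f <- fit_dataset_a(sub, fixed,
                       utils::modifyList(control,
                                         list(n_starts = 1L,
                                              ci_method = "jacobian")))
    c(k_p = f$globals$k_p, k_d = f$globals$k_d, v = f$globals$v)
  })

  per_well <- vapply(seq_len(n_w), function(i) {
    sum(fit$fvec[rows[[i]]]^2)
  }, 0)
  names(per_well) <- vapply(wd, `[[`, "", "well_id")

  structure(list(
    stage = "A: global rates + local bystander rates",
    globals = globals,
    k_bys = fit$par[-(1:3)],
    intervals = list(globals = ints[1:3, , drop = FALSE],
                     k_bys = ints[-(1:3), , drop = FALSE]),
    objective = fit$deviance, per_well = per_well,
    wells = dataset$wells,
    diagnostics = list(niter = fit$niter, info = fit$info,
                       message = fit$message, df = fit$df,
                       start_deviances = fit$start_deviances)),
    class = "stage_a_fit")
}

.row_index <- function(wd) {
  lens <- vapply(wd, function(w) 2L * length(w$times), 0L)
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(wd), function(i) seq.int(starts[i], ends[i]))
}

.stage_a_resid <- function(par, wd, fixed, control) {
  gp <- fixed
  gp$k_p <- max(par[1L], 0); gp$k_d <- max(par[2L], 0)
  gp$v <- max(par[3L], 0)
  unlist(lapply(seq_along(wd), function(i) {
    w <- wd[[i]]
    sim <- .sim_conf(w$N0 * fixed$theta, w$D0 * fixed$theta, w$G0,
                     k_bys = max(par[3L + i], 0), G_in = 0, times = w$times,
                     params = gp, rtol = control$rtol, atol = control$atol)
    c(sim[, "live"] - w$live, sim[, "dead"] - w$dead)
  }))
}

# Finite-difference Jacobian exploiting the block structure: the three
# global rates touch every well (one full pass each), while each well's
# local rate touches only its own residual block (a single joint pass).
.block_jacobian <- function(par, wd, fixed, control, rows, n_glob,
                            glob_upper, resid_fn) {
  r0 <- resid_fn(par)
  n_res <- length(r0)
  J <- matrix(0, n_res, length(par))
  for (j in seq_len(n_glob)) {
    h <- 1e-5 * glob_upper[j]
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (resid_fn(pj) - r0) / h
  }
  h_loc <- 1e-5 * 5
  p_loc <- par
  p_loc[-seq_len(n_glob)] <- p_loc[-seq_len(n_glob)] + h_loc
  r_loc <- resid_fn(p_loc)
  for (i in seq_along(wd))
    J[rows[[i]], n_glob + i] <- (r_loc[rows[[i]]] - r0[rows[[i]]]) / h_loc
  J
}

.stage_intervals <- function(fit, nm, dataset, control, refit) {
  ints <- .wald_intervals(fit, control$level, nm)
  if (control$ci_method == "bootstrap" || is.null(ints)) {
    if (is.null(ints))
      warning("singular Jacobian: falling back to bootstrap intervals")
    full <- matrix(NA_real_, length(nm), 4L,
                   dimnames = list(nm, c("estimate", "lower", "upper", "se")))
    full[, "estimate"] <- fit$par
    bi <- tryCatch(
      .bootstrap_intervals(refit, nrow(dataset$wells), control$boot_n,
                           control$start_seed, control$level),
      error = function(e) {
        warning("bootstrap intervals unavailable: ", conditionMessage(e))
        NULL
      })
    if (!is.null(bi)) {
      full[rownames(bi), "lower"] <- bi[, 1L]
      full[rownames(bi), "upper"] <- bi[, 2L]
    }
    return(full)
  }
  ints
}

.subset_dataset <- function(dataset, idx) {
  wells <- dataset$wells[idx, , drop = FALSE]
  # resampled wells may repeat: give them unique ids
  old_ids <- wells$well_id
  wells$well_id <- make.unique(old_ids)
  courses <- do.call(rbind, lapply(seq_along(old_ids), function(k) {
    tc <- dataset$courses[dataset$courses$well_id == old_ids[k], ,
                          drop = FALSE]
    tc$well_id <- wells$well_id[k]
    tc
  }))
  structure(list(wells = wells, courses = courses, seed = dataset$seed),
            class = "confluence_dataset")
}

#' Fit the bystander-rate relation to per-well estimates
#'
#' Stage 2 (reused in stage 6). Nonlinear least-squares fit of the
#' exponential-decay law `k_bys = k_bys_0 * exp(-alpha * G0) + beta` to
#' per-well bystander-rate estimates against their initial glucose levels.
#'
#' @param k_bys Numeric vector of per-well bystander-rate estimates, day^-1.
#' @param G0 Matching initial (accessible) glucose levels, mM.
#' @param level Confidence level for the Wald intervals.
#' @return A list of class `relation_fit` with `relation`
#'   (a [bystander_relation()]), `intervals` (3 x 4 matrix), `rss`, and the
#'   underlying `nls` fit in `fit`.
#' @export
fit_kbys_relation <- function(k_bys, G0, level = 0.95) {
  if (length(k_bys) != length(G0))
    stop("fit_kbys_relation: k_bys and G0 must have equal length")
  if (length(k_bys) < 4L)
    stop("fit_kbys_relation: need at least 4 (G0, k_bys) pairs")
  if (length(unique(G0)) < 2L)
    stop("fit_kbys_relation: degenerate spread in G0 ",
         "(at least 2 distinct glucose levels required)")
  d <- data.frame(k = k_bys, g = G0)
  b0 <- max(min(k_bys), 0)
  k0 <- max(max(k_bys) - b0, 1e-6)
  rng <- diff(range(G0))
  a0 <- if (rng > 0) 1 / max(rng / 3, 1e-6) else 1
  fit <- NULL
  for (st in list(c(k0 = k0, a = a0, b = b0),
                  c(k0 = k0, a = a0 / 10, b = b0),
                  c(k0 = max(k_bys), a = 1, b = 0))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(k ~ k0 * exp(-a * g) + b, data = d,
                        start = as.list(st),
                        lower = c(0, 0, 0), upper = c(20, 100, 5),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    # degenerate (flat) data: only the constant level is identifiable
    lvl <- mean(k_bys)
    se <- stats::sd(k_bys) / sqrt(length(k_bys))
    tq <- stats::qt(1 - (1 - level) / 2, length(k_bys) - 1L)
    ints <- cbind(estimate = c(0, 0, lvl),
                  lower = c(0, 0, lvl - tq * se),
                  upper = c(0, 0, lvl + tq * se),
                  se = c(NA, NA, se))
    rownames(ints) <- c("k_bys_0", "alpha", "beta")
    warning("fit_kbys_relation: no decay structure detected; ",
            "returning a constant relation")
    return(structure(list(relation = bystander_relation(0, 0, max(lvl, 0)),
                          intervals = ints,
                          rss = sum((k_bys - lvl)^2), fit = NULL),
                     class = "relation_fit"))
  }
  cf <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  tq <- stats::qt(1 - (1 - level) / 2, stats::df.residual(fit))
  ints <- cbind(estimate = cf, lower = cf - tq * sm[, "Std. Error"],
                upper = cf + tq * sm[, "Std. Error"],
                se = sm[, "Std. Error"])
  rownames(ints) <- c("k_bys_0", "alpha", "beta")
  structure(list(
    relation = bystander_relation(cf[["k0"]], cf[["a"]], cf[["b"]]),
    intervals = ints, rss = sum(stats::residuals(fit)^2), fit = fit),
    class = "relation_fit")
}

#' Bystander rate as a function of the inhibition constant
#'
#' Stage 3. For a well with initial glucose `G0` and initial live-cell count
#' `N0`, composes the accessible-glucose map with the bystander relation:
#' `k_bys(G_in) = k_bys_0 * exp(-alpha * G0 / (1 + G_in * N0)) + beta`.
#' The result is non-decreasing in `G_in` (more inhibition, less accessible
#' glucose, more bystander death).
#'
#' @param G0 Initial glucose, mM.
#' @param N0 Initial live-cell count, cells.
#' @param rel A [bystander_relation()].
#' @return A function of `G_in` returning the bystander rate, day^-1.
#' @export
kbys_as_function_of_gin <- function(G0, N0, rel) {
  stopifnot(inherits(rel, "bystander_relation"))
  if (!is.finite(G0) || G0 < 0 || !is.finite(N0) || N0 < 0)
    stop("kbys_as_function_of_gin: G0 and N0 must be >= 0")
  function(G_in) bystander_rate(accessible_glucose(G0, N0, G_in), rel)
}

#' Estimate per-dose inhibition constants with the bystander rate pinned
#'
#' Stage 4. For each nonzero dose, fits a single inhibition constant `G_in`
#' over that dose's wells, with every well's bystander rate assigned through
#' the stage-3 composition (not free). Untreated wells are pinned at
#' `G_in = 0`.
#'
#' @param dataset A `confluence_dataset` containing treated wells.
#' @param globals Fitted [global_params()] from stage 1.
#' @param rel Fitted [bystander_relation()] from stage 2.
#' @param control A [calibration_control()].
#' @return A list of class `gin_fit` with `doses`, `G_in` (named vector),
#'   `intervals` (one row per dose), and `diagnostics`.
#' @export
fit_gin_constrained <- function(dataset, globals, rel,
                                control = calibration_control()) {
  # validate (and force) every input before optimization starts: a lazily
  # evaluated argument that itself runs a fit must not fire inside the
  # optimizer's objective callback
  stopifnot(inherits(globals, "global_params"),
            inherits(rel, "bystander_relation"),
            inherits(control, "calibration_control"))
  wd <- .well_data(dataset)
  doses <- sort(unique(vapply(wd, `[[`, 0, "dose")))
  doses <- doses[doses > 0]
  if (length(doses) == 0L)
    stop("fit_gin_constrained: no treated wells in dataset")
  est <- se <- lowr <- uppr <- numeric(length(doses))
  diag <- vector("list", length(doses))
  for (k in seq_along(doses)) {
    sub <- wd[vapply(wd, `[[`, 0, "dose") == doses[k]]
    if (all(vapply(sub, `[[`, 0, "G0") == 0))
      stop("fit_gin_constrained: all wells at glucose 0 for dose ",
           doses[k], " uM; G_in is not identifiable")
    resid_fn <- function(par) {
      gin <- max(par[1L], 0)
      unlist(lapply(sub, function(w) {
        kb <- bystander_rate(
          accessible_glucose(w$G0, w$N0 * globals$theta, gin), rel)
        sim <- .sim_conf(w$N0 * globals$theta, w$D0 * globals$theta, w$G0,
                         k_bys = kb, G_in = gin, times = w$times,
                         params = globals, rtol = control$rtol,
                         atol = control$atol)
        c(sim[, "live"] - w$live, sim[, "dead"] - w$dead)
      }))
    }
    starts <- .multi_starts(1e-4, 0, 1e-2, control$n_starts,
                            control$start_seed + k)
    fit <- .bounded_lsq(resid_fn, 1e-4, 0, 1e-2, control = control,
                        starts = starts)
    wi <- .wald_intervals(fit, control$level)
    est[k] <- fit$par
    se[k] <- if (!is.null(wi)) wi[1L, "se"] else NA_real_
    lowr[k] <- if (!is.null(wi)) max(wi[1L, "lower"], 0) else 0
    uppr[k] <- if (!is.null(wi)) wi[1L, "upper"] else 1e-2
    diag[[k]] <- list(niter = fit$niter, deviance = fit$deviance,
                      info = fit$info)
  }
  names(est) <- paste0("G_in.", doses)
  ints <- cbind(estimate = est, lower = lowr, upper = uppr, se = se)
  rownames(ints) <- names(est)
  structure(list(stage = "B step 4: per-dose G_in, bystander rate pinned",
                 doses = doses, G_in = est, intervals = ints,
                 diagnostics = diag),
            class = "gin_fit")
}

#' Joint estimation of per-dose inhibition constants and free local
#' bystander rates
#'
#' Stage 5. Fits the per-dose global inhibition constants, constrained to
#' the confidence intervals obtained in stage 4, jointly with one free
#' bystander rate per well (including untreated wells, whose residuals do
#' not depend on `G_in`).
#'
#' @param dataset A `confluence_dataset` (treated and/or untreated wells).
#' @param globals Fitted [global_params()] from stage 1.
#' @param gin_bounds Matrix with rownames `G_in.<dose>` and columns `lower`,
#'   `upper` (e.g. the `intervals` of a [fit_gin_constrained()] result).
#' @param control A [calibration_control()].
#' @return A list of class `stage_b_fit` with `G_in`, `k_bys`, `intervals`,
#'   `objective`, `at_bounds` flags and `diagnostics`.
#' @export
fit_gin_and_local_kbys <- function(dataset, globals, gin_bounds,
                                   control = calibration_control()) {
  stopifnot(inherits(globals, "global_params"),
            inherits(control, "calibration_control"))
  gin_bounds <- gin_bounds[, , drop = FALSE]
  wd <- .well_data(dataset)
  n_w <- length(wd)
  well_dose <- vapply(wd, `[[`, 0, "dose")
  doses <- sort(unique(well_dose[well_dose > 0]))
  need <- paste0("G_in.", doses)
  if (!all(need %in% rownames(gin_bounds)))
    stop("fit_gin_and_local_kbys: gin_bounds must cover dose(s) ",
         paste(doses, collapse = ", "))
  gb <- gin_bounds[need, , drop = FALSE]
  n_g <- length(doses)
  lower <- c(pmax(gb[, "lower"], 0), rep(0, n_w))
  upper <- c(pmin(pmax(gb[, "upper"], gb[, "lower"] + 1e-12), 1e-2),
             rep(5, n_w))
  dose_col <- match(well_dose, doses)          # NA for untreated
  rows <- .row_index(wd)

  resid_fn <- function(par) {
    unlist(lapply(seq_len(n_w), function(i) {
      w <- wd[[i]]
      gin <- if (is.na(dose_col[i])) 0 else max(par[dose_col[i]], 0)
      sim <- .sim_conf(w$N0 * globals$theta, w$D0 * globals$theta, w$G0,
                       k_bys = max(par[n_g + i], 0), G_in = gin,
                       times = w$times, params = globals,
                       rtol = control$rtol, atol = control$atol)
      c(sim[, "live"] - w$live, sim[, "dead"] - w$dead)
    }))
  }
  jac_fn <- function(par) {
    .block_jacobian(par, wd, globals, control, rows, n_glob = n_g,
                    glob_upper = rep(1e-2, n_g), resid_fn = resid_fn)
  }
  start <- c(pmin(pmax((gb[, "lower"] + gb[, "upper"]) / 2, lower[1:n_g]),
                  upper[1:n_g]),
             rep(0.05, n_w))
  fit <- .bounded_lsq(resid_fn, start, lower, upper, jac_fn = jac_fn,
                      control = control)
  nm <- c(need, paste0("k_bys.", vapply(wd, `[[`, "", "well_id")))
  names(fit$par) <- nm
  ints <- .wald_intervals(fit, control$level, nm)
  at_bounds <- fit$par[1:n_g] <= lower[1:n_g] + 1e-12 |
    fit$par[1:n_g] >= upper[1:n_g] - 1e-12
  structure(list(
    stage = "B step 5: per-dose G_in within stage-4 bounds + free local rates",
    G_in = fit$par[seq_len(n_g)], doses = doses,
    k_bys = fit$par[-seq_len(n_g)],
    intervals = ints, objective = fit$deviance,
    at_bounds = at_bounds, wells = dataset$wells,
    diagnostics = list(niter = fit$niter, info = fit$info,
                       message = fit$message)),
    class = "stage_b_fit")
}

#' Compare local bystander rates with total and accessible glucose and
#' refit the relation
#'
#' Stage 6. Computes each well's initial accessible glucose with the fitted
#' inhibition constants, reports the correlation of the free local bystander
#' rates with both the initial total and the initial accessible glucose, and
#' -- if a monotone decreasing trend against accessible glucose is detected
#' (one-sided Spearman test) -- refits the exponential-decay relation
#' against accessible glucose. Otherwise the prior relation is returned with
#' `pattern_ok = FALSE`.
#'
#' @param step5 A `stage_b_fit` from [fit_gin_and_local_kbys()].
#' @param dataset The `confluence_dataset` used in stage 5.
#' @param globals Fitted [global_params()].
#' @param prior_rel The [bystander_relation()] from stage 2.
#' @param alpha_trend Significance level of the trend test.
#' @return A list of class `relation_refit` with `relation`, `pattern_ok`,
#'   `cor_total`, `cor_accessible`, `G_acs0`, and (when refitted)
#'   `relation_fit`.
#' @export
refit_relation_accessible <- function(step5, dataset, globals, prior_rel,
                                      alpha_trend = 0.05) {
  stopifnot(inherits(step5, "stage_b_fit"))
  wd <- .well_data(dataset)
  G0 <- vapply(wd, `[[`, 0, "G0")
  N0 <- vapply(wd, `[[`, 0, "N0") * globals$theta
  dose <- vapply(wd, `[[`, 0, "dose")
  gin <- rep(0, length(wd))
  for (k in seq_along(step5$doses))
    gin[dose == step5$doses[k]] <- step5$G_in[k]
  G_acs0 <- accessible_glucose(G0, N0, gin)
  kb <- unname(step5$k_bys)

  cor_total <- suppressWarnings(stats::cor(kb, G0))
  cor_acs <- suppressWarnings(stats::cor(kb, G_acs0))
  trend <- suppressWarnings(
    stats::cor.test(kb, G_acs0, method = "spearman",
                    alternative = "less", exact = FALSE))
  pattern_ok <- is.finite(trend$p.value) && trend$p.value < alpha_trend

  if (pattern_ok) {
    rf <- fit_kbys_relation(kb, G_acs0)
    rel <- rf$relation
  } else {
    rf <- NULL
    rel <- prior_rel
  }
  structure(list(relation = rel, pattern_ok = pattern_ok,
                 cor_total = cor_total, cor_accessible = cor_acs,
                 trend_p = trend$p.value, G_acs0 = G_acs0,
                 relation_fit = rf),
            class = "relation_refit")
}

#' Predict a well's time course from initial conditions only
#'
#' Stage 7. Computes the initial accessible glucose with the calibrated
#' inhibition constant for the well's dose, evaluates the bystander rate
#' from the calibrated relation at that accessible level, and simulates the
#' model forward. No per-well fitting is involved.
#'
#' @param w A [well()] or one-row well data frame.
#' @param globals Fitted [global_params()].
#' @param rel Calibrated [bystander_relation()].
#' @param inhibition An [inhibition_params()] covering the well's dose.
#' @param times Prediction grid, days.
#' @return A `time_course` data frame (see [simulate_well()]).
#' @export
predict_course <- function(w, globals, rel, inhibition,
                           times = default_time_grid()) {
  if (is.data.frame(w)) w <- as_well_list(w)[[1L]]
  gin <- gin_for_dose(inhibition, w$dose)
  N0 <- w$initial_confluence * globals$theta
  kb <- bystander_rate(accessible_glucose(w$G0, N0, gin), rel)
  simulate_well(w, globals, k_bys = kb, G_in = gin, times = times)
}
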