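#' Calibration control settings
#'
#' @param n_starts Number of multi-start initializations (log-uniform over the
#'   parameter bounds, fixed seed) for the global stages.
#' @param start_seed Seed for the multi-start draws.
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @param ftol,ptol LM convergence tolerances.
#' @param rtol,atol ODE solver tolerances used inside the objective.
#' @param ci_method `"jacobian"` (linearized covariance, default) or
#'   `"bootstrap"` (non-parametric over wells).
#' @param boot_n Bootstrap resample count.
#' @param level Confidence level for intervals.
#' @return A list of class `calibration_control`.
#' @export
calibration_control <- function(n_starts = 10L, start_seed = 99L,
                                maxiter = 100L, ftol = 1e-10, ptol = 1e-8,
                                rtol = 1e-8, atol = c(1e-6, 1e-6, 1e-9),
                                ci_method = c("jacobian", "bootstrap"),
                                boot_n = 200L, level = 0.95) {
  structure(list(n_starts = as.integer(n_starts),
                 start_seed = as.integer(start_seed),
                 maxiter = as.integer(maxiter), ftol = ftol, ptol = ptol,
                 rtol = rtol, atol = atol,
                 ci_method = match.arg(ci_method),
                 boot_n = as.integer(boot_n), level = level),
            class = "calibration_control")
}

# minimal forward solve used inside objectives: confluence matrices only
.sim_conf <- function(N0, D0, G0, k_bys, G_in, times, params,
                      rtol = 1e-8, atol = c(1e-6, 1e-6, 1e-9)) {
  p <- c(params$k_p, params$k_d, k_bys, params$v, params$theta,
         params$G_star, params$G_min, G_in, 1)
  out <- deSolve::ode(y = c(N = N0, D = D0, G = G0), times = times,
                      func = "glucodyn_derivs", parms = p,
                      dllname = "glucodyn", initfunc = "glucodyn_initmod",
                      method = "lsoda", rtol = rtol, atol = atol)
  if (nrow(out) < length(times))
    stop("ODE integration failed (k_bys = ", k_bys, ", G_in = ", G_in, ")")
  cbind(live = pmax(out[, 2L], 0) / params$theta * 100,
        dead = pmax(out[, 3L], 0) / params$theta * 100)
}

# Per-well calibration view of a dataset: measured first points become the
# initial conditions, channels are stacked live-then-dead per well.
.well_data <- function(dataset) {
  stopifnot(inherits(dataset, "confluence_dataset"))
  ids <- dataset$wells$well_id
  crs <- split(dataset$courses, dataset$courses$well_id)
  lapply(seq_along(ids), function(i) {
    tc <- crs[[ids[i]]]
    if (is.null(tc) || nrow(tc) < 2L)
      stop("dataset: well '", ids[i], "' has fewer than 2 time points")
    tc <- tc[order(tc$time_days), ]
    list(well_id = ids[i],
         times = tc$time_days - tc$time_days[1L],
         live = tc$live_pct, dead = tc$dead_pct,
         N0 = tc$live_pct[1L] / 100, D0 = tc$dead_pct[1L] / 100,
         G0 = dataset$wells$G0[i], dose = dataset$wells$dose[i])
  })
}

# Bounded Levenberg-Marquardt least squares in a scaled parameter space,
# with an optional analytic-structure Jacobian and multi-start.
# resid_fn(par) returns the residual vector; jac_fn(par) the Jacobian
# (n_res x n_par), or NULL for nls.lm's internal differencing.
.bounded_lsq <- function(resid_fn, start, lower, upper, jac_fn = NULL,
                         control = calibration_control(), scale = NULL,
                         starts = NULL) {
  p <- length(start)
  if (is.null(scale)) scale <- pmax(abs(upper), 1e-12)
  sfn <- function(xs) resid_fn(xs * scale)
  sjac <- if (!is.null(jac_fn))
    function(xs) sweep(jac_fn(xs * scale), 2L, scale, "*")
  ctl <- minpack.lm::nls.lm.control(maxiter = control$maxiter,
                                    ftol = control$ftol, ptol = control$ptol)
  run1 <- function(st) {
    minpack.lm::nls.lm(par = st / scale, lower = lower / scale,
                       upper = upper / scale, fn = sfn, jac = sjac,
                       control = ctl)
  }
  if (is.null(starts)) starts <- list(start)
  best <- NULL
  trace <- numeric(0)
  for (st in starts) {
    fit <- tryCatch(run1(st), error = function(e) NULL)
    if (is.null(fit)) next
    trace <- c(trace, fit$deviance)
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("least-squares fit failed from every start")
  n_res <- length(best$fvec)
  list(par = best$par * scale, deviance = best$deviance,
       hessian = best$hessian / tcrossprod(scale)[seq_len(p), seq_len(p)],
       fvec = best$fvec, niter = best$niter, info = best$info,
       message = best$message, n_res = n_res,
       df = n_res - p, start_deviances = trace, scale = scale)
}

# Multi-start initial points: user start first, then log-uniform draws
# between upper/1e4 and upper (componentwise), fixed seed.
.multi_starts <- function(start, lower, upper, n_starts, seed) {
  starts <- list(start)
  if (n_starts > 1L) {
    set.seed(seed)
    lo <- pmax(lower, upper / 1e4)
    for (k in seq_len(n_starts - 1L))
      starts[[k + 1L]] <- exp(stats::runif(length(start), log(lo), log(upper)))
  }
  starts
}

# Wald intervals from the J^T J of a converged least-squares fit.
# Returns a matrix with columns estimate / lower / upper / se.
.wald_intervals <- function(fit, level = 0.95, names = NULL) {
  p <- length(fit$par)
  sigma2 <- if (fit$df > 0) fit$deviance / fit$df else 0
  cv <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (is.null(cv)) return(NULL)
  se <- sqrt(pmax(diag(cv), 0) * sigma2)
  tq <- stats::qt(1 - (1 - level) / 2, max(fit$df, 1))
  out <- cbind(estimate = fit$par, lower = fit$par - tq * se,
               upper = fit$par + tq * se, se = se)
  rownames(out) <- names
  out
}

# Percentile bootstrap over resampling units (wells). refit_fn(unit_idx)
# must return a named numeric vector of estimates.
.bootstrap_intervals <- function(refit_fn, n_units, n_boot, seed,
                                 level = 0.95) {
  if (n_units < 2L)
    stop("bootstrap intervals need at least 2 resampling units")
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = n_boot, ncol = 0L)
  res <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n_units, n_units, replace = TRUE)
    res[[b]] <- tryCatch(refit_fn(idx), error = function(e) NULL)
  }
  res <- res[!vapply(res, is.null, logical(1L))]
  if (length(res) < 2L) stop("bootstrap failed in nearly all resamples")
  m <- do.call(rbind, res)
  a <- (1 - level) / 2
  t(apply(m, 2L, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE))
}
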