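#' State functions scaling proliferation and starvation death
#'
#' The death state function ramps up as accessible glucose falls below the
#' minimum uptake level and as time passes since the medium change:
#' `S_d = (1 - G_acs / (G_acs + G_min)) * tanh(t)`, with `S_p = 1 - S_d`.
#' Time is in days by default; `tanh_scale` rescales the argument of `tanh`
#' (24 would correspond to hours).
#'
#' @param G_acs Accessible glucose concentration, mM (>= 0).
#' @param t Time since medium change, days (>= 0).
#' @param G_min Minimum glucose level for uptake, mM (> 0).
#' @param tanh_scale Multiplier applied to `t` inside `tanh`; default 1 (days).
#' @return A list with components `S_p` and `S_d`, each in \[0, 1\].
#' @examples
#' state_functions(0.01, 1, 0.01)  # S_d = 0.5 * tanh(1)
#' @export
state_functions <- function(G_acs, t, G_min = 0.01, tanh_scale = 1) {
  if (any(!is.finite(G_acs)) || any(G_acs < 0))
    stop("state_functions: G_acs must be finite and >= 0")
  if (any(!is.finite(t)) || any(t < 0))
    stop("state_functions: t must be finite and >= 0")
  if (!is.finite(G_min) || G_min <= 0)
    stop("state_functions: G_min must be > 0")
  S_d <- (1 - G_acs / (G_acs + G_min)) * tanh(t * tanh_scale)
  list(S_p = 1 - S_d, S_d = S_d)
}

#' Glucose concentration accessible to the cells
#'
#' Under glucose-uptake inhibition only part of the extracellular glucose is
#' accessible: `G_acs = G_total / (1 + G_in * N)`. With no treatment
#' (`G_in = 0`) the accessible level equals the total level.
#'
#' @param G_total Total extracellular glucose, mM (>= 0).
#' @param N Number of live cells (>= 0).
#' @param G_in Inhibition constant, cell^-1 (>= 0).
#' @return Accessible glucose, mM; never exceeds `G_total`.
#' @examples
#' accessible_glucose(10, 5e4, 4.55e-4)
#' @export
accessible_glucose <- function(G_total, N, G_in) {
  if (any(!is.finite(G_total)) || any(G_total < 0) ||
      any(!is.finite(N)) || any(N < 0) ||
      any(!is.finite(G_in)) || any(G_in < 0))
    stop("accessible_glucose: all inputs must be finite and >= 0")
  G_total / (1 + G_in * N)
}

#' Bystander death rate for an initial glucose level
#'
#' Evaluates the exponential-decay law
#' `k_bys = k_bys_0 * exp(-alpha * G0) + beta`.
#'
#' @param G0 Initial (accessible) glucose concentration, mM (>= 0).
#' @param rel A [bystander_relation()].
#' @return Bystander death rate, day^-1; non-increasing in `G0`.
#' @export
bystander_rate <- function(G0, rel) {
  stopifnot(inherits(rel, "bystander_relation"))
  if (any(!is.finite(G0)) || any(G0 < 0))
    stop("bystander_rate: G0 must be finite and >= 0")
  rel$k_bys_0 * exp(-rel$alpha * G0) + rel$beta
}

#' Right-hand side of the growth model
#'
#' The three coupled rates of change: live cells follow logistic growth scaled
#' by `S_p`, minus starvation death scaled by `S_d`, minus bystander death
#' proportional to the dead-cell fraction `D / (D + N)`; dead cells accumulate
#' both death fluxes; glucose is consumed with Michaelis-Menten kinetics in
#' the accessible concentration. The bystander fraction is defined as 0 when
#' `D + N = 0`.
#'
#' This R implementation is the reference form of the dynamics; forward
#' simulation uses an equivalent compiled version for speed.
#'
#' @param state Named numeric vector or list with `N`, `D`, `G_total`.
#' @param t Time since medium change, days.
#' @param params A [global_params()].
#' @param k_bys Bystander death rate, day^-1.
#' @param G_in Inhibition constant, cell^-1.
#' @param tanh_scale Time scaling inside `tanh` (1 = days).
#' @return Named numeric vector `c(dN, dD, dG_total)`.
#' @export
growth_rhs <- function(state, t, params, k_bys, G_in = 0, tanh_scale = 1) {
  stopifnot(inherits(params, "global_params"))
  s <- unlist(state)[c("N", "D", "G_total")]
  if (any(!is.finite(s)))
    stop("growth_rhs: non-finite state")
  if (any(s < 0))
    stop("growth_rhs: negative state")
  N <- s[["N"]]; D <- s[["D"]]; G <- s[["G_total"]]
  G_acs <- accessible_glucose(G, N, G_in)
  sf <- state_functions(G_acs, t, params$G_min, tanh_scale)
  bys <- if (N + D > 0) k_bys * N * D / (D + N) else 0
  dN <- params$k_p * N * (1 - N / params$theta) * sf$S_p -
    params$k_d * N * sf$S_d - bys
  dD <- params$k_d * N * sf$S_d + bys
  dG <- -params$v * N * G_acs / (G_acs + params$G_star)
  c(dN = dN, dD = dD, dG_total = unname(dG))
}

#' Convert between confluence and cell number
#'
#' Confluence (percent of well area covered) maps linearly to cell number via
#' the carrying capacity: `cells = confluence / 100 * theta`.
#'
#' @param value Confluence in percent (\[0, 100\]) or cells (\[0, theta\]).
#' @param theta Carrying capacity, cells.
#' @param direction `"to_cells"` or `"to_confluence"`.
#' @return Converted value.
#' @examples
#' confluence_cells_convert(50, 8e4, "to_cells")
#' @export
confluence_cells_convert <- function(value, theta = 8e4,
                                     direction = c("to_cells", "to_confluence")) {
  direction <- match.arg(direction)
  if (any(!is.finite(value)))
    stop("confluence_cells_convert: non-finite input")
  if (direction == "to_cells") {
    if (any(value < 0) || any(value > 100))
      stop("confluence_cells_convert: confluence must lie in [0, 100]")
    value / 100 * theta
  } else {
    if (any(value < 0) || any(value > theta))
      stop("confluence_cells_convert: cells must lie in [0, theta]")
    value / theta * 100
  }
}

#' Default sampling grid of the confluence experiments
#'
#' @param days Total duration, days.
#' @param step Sampling interval, days (3 h = 0.125 day).
#' @return Numeric vector of times starting at 0.
#' @export
default_time_grid <- function(days = 4, step = 0.125) {
  seq(0, days, by = step)
}

#' A culture well's design point
#'
#' @param well_id Identifier string.
#' @param initial_confluence Initial live-cell confluence as a fraction in
#'   \[0, 1\].
#' @param G0 Initial glucose, mM.
#' @param dose Inhibitor dose, uM.
#' @param replicate Replicate index.
#' @param dataset_tag `"A"` or `"B"`.
#' @param initial_dead Initial dead-cell confluence fraction (default 0.01).
#' @return An object of class `well` (named list).
#' @export
well <- function(well_id, initial_confluence, G0, dose = 0, replicate = 1L,
                 dataset_tag = "A", initial_dead = 0.01) {
  if (!is.finite(initial_confluence) || initial_confluence < 0 ||
      initial_confluence > 1)
    stop("well: initial_confluence must lie in [0, 1]")
  if (!is.finite(G0) || G0 < 0) stop("well: G0 must be >= 0")
  if (!is.finite(dose) || dose < 0) stop("well: dose must be >= 0")
  if (!is.finite(initial_dead) || initial_dead < 0 || initial_dead > 1)
    stop("well: initial_dead must lie in [0, 1]")
  structure(list(well_id = as.character(well_id),
                 initial_confluence = initial_confluence,
                 G0 = G0, dose = dose, replicate = as.integer(replicate),
                 dataset_tag = dataset_tag, initial_dead = initial_dead),
            class = "well")
}

#' Simulate a well forward in time
#'
#' Integrates the three-state model from the well's initial conditions and
#' returns live/dead confluence trajectories together with the glucose
#' trajectories. The default integrator is adaptive (`lsoda`) on the compiled
#' right-hand side; `engine = "r"` uses the reference R implementation
#' ([growth_rhs()]) and supports fixed-step methods for cross-checking.
#'
#' @param w A [well()] (or a one-row data frame with the same fields).
#' @param params A [global_params()].
#' @param k_bys Bystander death rate for this well, day^-1.
#' @param G_in Inhibition constant for this well's dose, cell^-1.
#' @param times Time grid in days; default [default_time_grid()].
#' @param engine `"c"` (compiled, default) or `"r"`.
#' @param method Integration method passed to [deSolve::ode()]; default
#'   `"lsoda"`.
#' @param rtol,atol Solver tolerances. `atol` is in cells for `N`, `D` and in
#'   mM for glucose.
#' @param tanh_scale Time scaling inside `tanh` (1 = days).
#' @param hini Initial/fixed step size for fixed-step methods.
#' @return A data frame of class `time_course` with columns `time_days`,
#'   `live_pct`, `dead_pct`, `G_total`, `G_acs`.
#' @examples
#' w <- well("a", 0.4, 5)
#' tc <- simulate_well(w, global_params(), k_bys = 0.05)
#' head(tc)
#' @export
simulate_well <- function(w, params = global_params(), k_bys = 0, G_in = 0,
                          times = default_time_grid(), engine = c("c", "r"),
                          method = "lsoda", rtol = 1e-8,
                          atol = c(1e-6, 1e-6, 1e-9), tanh_scale = 1,
                          hini = 0) {
  engine <- match.arg(engine)
  if (is.data.frame(w)) w <- as_well_list(w)[[1L]]
  stopifnot(inherits(w, "well"), inherits(params, "global_params"))
  if (!is.finite(k_bys) || k_bys < 0) stop("simulate_well: k_bys must be >= 0")
  if (!is.finite(G_in) || G_in < 0) stop("simulate_well: G_in must be >= 0")
  if (length(times) < 2L || any(diff(times) <= 0) || times[1L] != 0)
    stop("simulate_well: times must start at 0 and be strictly increasing")

  y0 <- c(N = w$initial_confluence * params$theta,
          D = w$initial_dead * params$theta,
          G_total = w$G0)
  p <- c(params$k_p, params$k_d, k_bys, params$v, params$theta,
         params$G_star, params$G_min, G_in, tanh_scale)

  if (engine == "c") {
    out <- deSolve::ode(y = y0, times = times, func = "glucodyn_derivs",
                        parms = p, dllname = "glucodyn",
                        initfunc = "glucodyn_initmod", nout = 0,
                        method = method, rtol = rtol, atol = atol,
                        hini = hini)
  } else {
    gp <- params
    rhs_r <- function(t, y, parms) {
      yc <- pmax(y, 0)
      list(growth_rhs(c(N = yc[[1L]], D = yc[[2L]], G_total = yc[[3L]]),
                      t, gp, k_bys = k_bys, G_in = G_in,
                      tanh_scale = tanh_scale))
    }
    out <- deSolve::ode(y = y0, times = times, func = rhs_r, parms = NULL,
                        method = method, rtol = rtol, atol = atol,
                        hini = hini)
  }

  istate <- attr(out, "istate")
  if ((!is.null(istate) && istate[1L] < 0) || nrow(out) < length(times))
    stop("simulate_well: integration failed for well '", w$well_id, "'")
  out <- as.data.frame(out)
  names(out) <- c("time", "N", "D", "G_total")

  # clip tiny negative excursions; anything larger is a solver failure
  neg_tol <- 1e-3
  for (cl in c("N", "D", "G_total")) {
    bad <- out[[cl]] < -neg_tol
    if (any(bad))
      stop("simulate_well: state '", cl, "' went negative beyond tolerance ",
           "for well '", w$well_id, "'")
    out[[cl]] <- pmax(out[[cl]], 0)
  }

  tc <- data.frame(
    time_days = out$time,
    live_pct = confluence_cells_convert(out$N, params$theta, "to_confluence"),
    dead_pct = confluence_cells_convert(out$D, params$theta, "to_confluence"),
    G_total = out$G_total,
    G_acs = accessible_glucose(out$G_total, out$N, G_in)
  )
  class(tc) <- c("time_course", "data.frame")
  tc
}

#' Closed-form logistic growth (no death, saturating glucose)
#'
#' In the limit of abundant glucose and no death terms the live-cell equation
#' reduces to the logistic law; used as an analytic cross-check for the
#' integrator.
#'
#' @param t Times, days.
#' @param N0 Initial cell number.
#' @param k_p Proliferation rate, day^-1.
#' @param theta Carrying capacity, cells.
#' @return Cell numbers at `t`.
#' @keywords internal
logistic_growth <- function(t, N0, k_p, theta) {
  theta * N0 * exp(k_p * t) / (theta + N0 * (exp(k_p * t) - 1))
}
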