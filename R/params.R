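#' Global cell-line parameters
#'
#' Container for the cell-line-level rates and constants of the growth model:
#' the proliferation rate, the starvation (glucose-depletion) death rate, the
#' glucose consumption rate, the carrying capacity of a well, the
#' Michaelis-Menten constant of glucose consumption, and the minimum glucose
#' level required for uptake. Defaults are the values used for the
#' MDA-MB-231 line.
#'
#' @param k_p Proliferation rate, day^-1.
#' @param k_d Death rate due to glucose depletion, day^-1.
#' @param v General glucose consumption rate, mM cell^-1 day^-1.
#' @param theta Carrying capacity of a well, cells.
#' @param G_star Michaelis-Menten constant of consumption, mM.
#' @param G_min Minimum glucose level for uptake, mM.
#'
#' @return An object of class `global_params` (a named list).
#' @examples
#' gp <- global_params()
#' gp$k_p
#' @export
global_params <- function(k_p = 0.14, k_d = 0.041, v = 4.48e-5,
                          theta = 8e4, G_star = 0.5, G_min = 0.01) {
  p <- list(k_p = k_p, k_d = k_d, v = v, theta = theta,
            G_star = G_star, G_min = G_min)
  for (nm in names(p)) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("global_params: '", nm, "' must be a single positive number")
  }
  structure(p, class = "global_params")
}

#' Bystander death-rate relation
#'
#' Parameters of the exponential-decay law linking the bystander-effect death
#' rate to the initial (accessible) glucose concentration:
#' `k_bys(G0) = k_bys_0 * exp(-alpha * G0) + beta`.
#'
#' @param k_bys_0 Maximum bystander death rate at zero glucose, day^-1.
#' @param alpha Glucose dependence of the decay, mM^-1.
#' @param beta Baseline offset, day^-1.
#'
#' @return An object of class `bystander_relation`.
#' @examples
#' rel <- bystander_relation(0.1, 0.5, 0.01)
#' bystander_rate(2, rel)
#' @export
bystander_relation <- function(k_bys_0 = 1.6, alpha = 0.9, beta = 0.02) {
  p <- list(k_bys_0 = k_bys_0, alpha = alpha, beta = beta)
  for (nm in names(p)) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
      stop("bystander_relation: '", nm, "' must be a single non-negative number")
  }
  structure(p, class = "bystander_relation")
}

#' Dose-dependent inhibition constants
#'
#' Map from inhibitor dose (Cytochalasin B, uM) to the inhibition constant
#' `G_in` (cell^-1) that links total and accessible glucose,
#' `G_acs = G_total / (1 + G_in * N)`. Dose 0 always maps to `G_in = 0`
#' (no treatment leaves all glucose accessible).
#'
#' @param doses Numeric vector of doses in uM.
#' @param G_in Numeric vector of inhibition constants in cell^-1, same length.
#'
#' @return An object of class `inhibition_params`.
#' @examples
#' inhibition_params()
#' @export
inhibition_params <- function(doses = c(0, 2, 10),
                              G_in = c(0, 3.02e-4, 4.55e-4)) {
  if (length(doses) != length(G_in))
    stop("inhibition_params: 'doses' and 'G_in' must have equal length")
  if (anyDuplicated(doses))
    stop("inhibition_params: duplicated doses")
  if (any(!is.finite(doses)) || any(doses < 0) ||
      any(!is.finite(G_in)) || any(G_in < 0))
    stop("inhibition_params: doses and G_in must be finite and non-negative")
  if (any(doses == 0) && any(G_in[doses == 0] != 0))
    stop("inhibition_params: dose 0 must map to G_in = 0")
  o <- order(doses)
  structure(list(doses = doses[o], G_in = G_in[o]),
            class = "inhibition_params")
}

#' Look up the inhibition constant for a dose
#'
#' @param inhibition An [inhibition_params()] object.
#' @param dose Dose in uM; must be present in the map.
#' @return `G_in` in cell^-1.
#' @export
gin_for_dose <- function(inhibition, dose) {
  stopifnot(inherits(inhibition, "inhibition_params"))
  i <- match(dose, inhibition$doses)
  if (anyNA(i))
    stop("gin_for_dose: no inhibition constant recorded for dose ",
         paste(dose[is.na(i)], collapse = ", "), " uM")
  inhibition$G_in[i]
}

#' @export
print.global_params <- function(x, ...) {
  cat("Global growth-model parameters:\n")
  cat(sprintf("  k_p    = %.4g day^-1   (proliferation)\n", x$k_p))
  cat(sprintf("  k_d    = %.4g day^-1   (starvation death)\n", x$k_d))
  cat(sprintf("  v      = %.4g mM cell^-1 day^-1 (consumption)\n", x$v))
  cat(sprintf("  theta  = %.4g cells    (carrying capacity)\n", x$theta))
  cat(sprintf("  G*     = %.4g mM       (Michaelis-Menten constant)\n", x$G_star))
  cat(sprintf("  G_min  = %.4g mM       (minimum uptake level)\n", x$G_min))
  invisible(x)
}

#' @export
print.bystander_relation <- function(x, ...) {
  cat(sprintf(
    "Bystander-rate relation: k_bys(G0) = %.4g * exp(-%.4g * G0) + %.4g  [day^-1]\n",
    x$k_bys_0, x$alpha, x$beta))
  invisible(x)
}

#' @export
print.inhibition_params <- function(x, ...) {
  cat("Inhibition constants (G_in, cell^-1) by dose (uM):\n")
  for (i in seq_along(x$doses))
    cat(sprintf("  %5.3g uM -> %.4g\n", x$doses[i], x$G_in[i]))
  invisible(x)
}
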