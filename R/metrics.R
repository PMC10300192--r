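#' Error metrics between a predicted and a measured time course
#'
#' Signed errors in confluence percentage points, per time point:
#' `error = predicted - measured` and `percent error = 100 * error /
#' measured`. Four summaries are reported per channel: the mean over the
#' time course and the value at the final time point, for both the plain and
#' the percent error. Time points with a measured value of 0 are excluded
#' from the percent metrics, with the exclusion count reported.
#'
#' @param predicted,measured Data frames with columns `time_days` and one or
#'   both of `live_pct`, `dead_pct` on identical time grids (numeric vectors
#'   are also accepted and treated as a single channel).
#' @return A data frame with one row per channel and columns
#'   `mean_percent_error`, `percent_error_end`, `mean_error`, `error_end`,
#'   `n_skipped_percent`.
#' @examples
#' error_metrics(data.frame(time_days = 0:2, dead_pct = c(5, 5, 6)),
#'               data.frame(time_days = 0:2, dead_pct = c(5, 5, 5)))
#' @export
error_metrics <- function(predicted, measured) {
  if (is.numeric(predicted)) predicted <- data.frame(value = predicted)
  if (is.numeric(measured)) measured <- data.frame(value = measured)
  if ("time_days" %in% names(predicted) && "time_days" %in% names(measured)) {
    if (nrow(predicted) != nrow(measured) ||
        any(abs(predicted$time_days - measured$time_days) > 1e-9))
      stop("error_metrics: time grids do not match")
  } else if (nrow(predicted) != nrow(measured)) {
    stop("error_metrics: lengths do not match")
  }
  channels <- intersect(c("live_pct", "dead_pct", "value"),
                        intersect(names(predicted), names(measured)))
  if (length(channels) == 0L)
    stop("error_metrics: no common confluence channel")
  out <- lapply(channels, function(ch) {
    err <- predicted[[ch]] - measured[[ch]]
    nz <- measured[[ch]] != 0
    pct <- 100 * err[nz] / measured[[ch]][nz]
    n <- length(err)
    data.frame(
      channel = sub("_pct$", "", ch),
      mean_percent_error = if (any(nz)) mean(pct) else NA_real_,
      percent_error_end = if (nz[n]) 100 * err[n] / measured[[ch]][n]
                          else NA_real_,
      mean_error = mean(err),
      error_end = err[n],
      n_skipped_percent = sum(!nz))
  })
  do.call(rbind, out)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` about the observation mean; can be negative
#' for predictors worse than the mean.
#'
#' @param predicted,observed Numeric vectors of equal length (>= 2).
#' @return R-squared, or `NA` with a warning if the observations have zero
#'   variance.
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("r_squared: lengths differ")
  if (length(observed) < 2L)
    stop("r_squared: need at least 2 observations")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warning("r_squared: observations have zero variance")
    return(NA_real_)
  }
  1 - sum((predicted - observed)^2) / ss_tot
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two equal-length curves, penalizing both dispersion and
#' location differences:
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`,
#' with population (1/n) moments. Lies in \[-1, 1\] and never exceeds the
#' absolute Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return The concordance correlation coefficient, or `NA` with a warning
#'   when both curves are constant.
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) stop("ccc: lengths differ")
  n <- length(x)
  if (n < 2L) stop("ccc: need at least 2 points")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) {
    warning("ccc: both curves are constant and identical; CCC undefined")
    return(NA_real_)
  }
  2 * cxy / denom
}

#' Match treated wells to an untreated-equivalent glucose level
#'
#' For each treated curve, computes the concordance correlation coefficient
#' against the (replicate-averaged) untreated curve of every candidate
#' glucose level and reports the level with the highest CCC -- the best
#' estimate of the glucose level effectively accessible to the treated
#' cells.
#'
#' @param treated Numeric vector (a confluence curve) or a matrix with one
#'   curve per column.
#' @param untreated_by_level Named list of numeric curves, one per candidate
#'   untreated glucose level; names are the glucose levels (mM).
#' @return A list with `best_level` (numeric, per treated curve) and
#'   `ccc_table` (matrix: treated curves x candidate levels).
#' @export
match_accessible_level <- function(treated, untreated_by_level) {
  if (length(untreated_by_level) == 0L)
    stop("match_accessible_level: empty untreated set")
  if (is.null(names(untreated_by_level)))
    stop("match_accessible_level: untreated curves must be named by level")
  if (!is.matrix(treated)) treated <- matrix(treated, ncol = 1L)
  tab <- sapply(untreated_by_level, function(u)
    apply(treated, 2L, function(tr) ccc(tr, u)))
  if (!is.matrix(tab)) tab <- matrix(tab, nrow = ncol(treated))
  colnames(tab) <- names(untreated_by_level)
  lv <- as.numeric(names(untreated_by_level))
  best <- lv[apply(tab, 1L, which.max)]
  list(best_level = best, ccc_table = tab)
}

#' Partial correlation controlling for one variable
#'
#' Pearson correlation of the residuals of `x` and `y` after linear
#' regression of each on the control variable.
#'
#' @param x,y,control Numeric vectors of equal length (>= 4).
#' @return The partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, control) {
  n <- length(x)
  if (length(y) != n || length(control) != n)
    stop("partial_correlation: lengths differ")
  if (n < 4L) stop("partial_correlation: need at least 4 triples")
  if (stats::var(control) == 0)
    stop("partial_correlation: control variable is constant")
  rx <- stats::residuals(stats::lm(x ~ control))
  ry <- stats::residuals(stats::lm(y ~ control))
  # a variable fully explained by the control leaves only rounding noise:
  # nothing remains to correlate
  if (stats::var(rx) < 1e-20 * max(stats::var(x), 1e-300) ||
      stats::var(ry) < 1e-20 * max(stats::var(y), 1e-300))
    return(0)
  stats::cor(rx, ry)
}

#' Relative improvement between two scores
#'
#' `100 * (end - start) / start`, as used for learning-curve endpoints.
#'
#' @param start_score,end_score Numeric scalars; `start_score` must be
#'   nonzero.
#' @return Percent change (one value per element).
#' @examples
#' relative_improvement(0.4863, 0.6903)  # +41.9
#' @export
relative_improvement <- function(start_score, end_score) {
  if (any(start_score == 0))
    stop("relative_improvement: start score of 0")
  100 * (end_score - start_score) / start_score
}

#' Statistical comparison suite
#'
#' Convenience wrappers for the hypothesis tests used when comparing model
#' performance and parameter estimates: one-way ANOVA across groups,
#' Bonferroni-corrected pairwise Welch t-tests, a plain two-sample t-test,
#' a one-sample Kolmogorov-Smirnov test against a fitted normal, and
#' two-way ANOVA.
#'
#' @param groups Named list of numeric vectors (one per group), each of
#'   length >= 2.
#' @return `stats_anova_oneway`: list with `F`, `p`, and the `aov` fit.
#' @export
stats_anova_oneway <- function(groups) {
  if (length(groups) < 2L)
    stop("stats_anova_oneway: need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2L))
    stop("stats_anova_oneway: each group needs >= 2 values")
  d <- data.frame(value = unlist(groups),
                  group = factor(rep(names(groups),
                                     vapply(groups, length, 0L))))
  fit <- stats::aov(value ~ group, data = d)
  s <- summary(fit)[[1L]]
  list(F = s[["F value"]][1L], p = s[["Pr(>F)"]][1L], fit = fit)
}

#' @rdname stats_anova_oneway
#' @param alpha Family-wise significance level.
#' @return `stats_pairwise_bonferroni`: data frame of pairwise comparisons
#'   with raw and Bonferroni-adjusted p-values and the per-test alpha.
#' @export
stats_pairwise_bonferroni <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L)
    stop("stats_pairwise_bonferroni: need at least 2 groups")
  nm <- names(groups)
  cmb <- utils::combn(length(groups), 2L)
  m <- ncol(cmb)
  out <- data.frame(group1 = nm[cmb[1L, ]], group2 = nm[cmb[2L, ]],
                    t = NA_real_, p_raw = NA_real_)
  for (j in seq_len(m)) {
    tt <- stats::t.test(groups[[cmb[1L, j]]], groups[[cmb[2L, j]]])
    out$t[j] <- unname(tt$statistic)
    out$p_raw[j] <- tt$p.value
  }
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "bonferroni")
  out$alpha_per_test <- alpha / m
  out
}

#' @rdname stats_anova_oneway
#' @param x,y Numeric vectors for the two-sample comparison.
#' @return `stats_t_test`: list with `t`, `p`.
#' @export
stats_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("stats_t_test: each sample needs >= 2 values")
  tt <- stats::t.test(x, y)
  list(t = unname(tt$statistic), p = tt$p.value, fit = tt)
}

#' @rdname stats_anova_oneway
#' @return `stats_ks_normality`: list with `D`, `p` from a one-sample
#'   Kolmogorov-Smirnov test of `x` against a normal with the sample mean
#'   and SD.
#' @export
stats_ks_normality <- function(x) {
  if (length(x) < 2L) stop("stats_ks_normality: need >= 2 values")
  ks <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(D = unname(ks$statistic), p = ks$p.value)
}

#' @rdname stats_anova_oneway
#' @param value Numeric response vector.
#' @param f1,f2 Factors (or vectors coercible to factors) of the same
#'   length as `value`.
#' @return `stats_anova_twoway`: the ANOVA table of `value ~ f1 + f2`.
#' @export
stats_anova_twoway <- function(value, f1, f2) {
  d <- data.frame(value = value, f1 = factor(f1), f2 = factor(f2))
  if (nlevels(d$f1) < 2L || nlevels(d$f2) < 2L)
    stop("stats_anova_twoway: both factors need >= 2 levels")
  fit <- stats::aov(value ~ f1 + f2, data = d)
  summary(fit)[[1L]]
}

# mean and 95% CI half-width (t-based) of a vector; used for report tables
.mean_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(c(mean = NA_real_, ci = NA_real_))
  hw <- if (n > 1L)
    stats::qt(1 - (1 - level) / 2, n - 1L) * stats::sd(x) / sqrt(n) else 0
  c(mean = mean(x), ci = hw)
}
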