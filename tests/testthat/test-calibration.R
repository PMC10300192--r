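test_that("global rates and local bystander rates are recovered from
           noiseless untreated data", {
  f <- small_fitA()
  est <- c(k_p = f$globals$k_p, k_d = f$globals$k_d, v = f$globals$v)
  expect_true(all(abs(est - table1_truth) / table1_truth < 0.01))
  expect_true(all(abs(f$k_bys - small_dsA()$wells$k_bys_true) < 1e-4))
  # exact data: zero residuals give zero-width intervals
  expect_true(all(f$intervals$globals[, "upper"] -
                    f$intervals$globals[, "lower"] < 1e-8))
  # intervals contain their estimates
  expect_true(all(f$intervals$globals[, "lower"] <=
                    f$intervals$globals[, "estimate"] + 1e-12))
  expect_true(all(f$intervals$globals[, "upper"] >=
                    f$intervals$globals[, "estimate"] - 1e-12))
})

test_that("single-well input triggers an identifiability warning", {
  ds <- small_dsA()
  one <- glucodyn:::.dataset_subset_ids(ds, ds$wells$well_id[1L])
  w <- testthat::capture_warnings(
    fit_dataset_a(one, control = calibration_control(n_starts = 1,
                                                     maxiter = 5)))
  expect_true(any(grepl("single well", w)))
})

test_that("a dataset with no bystander death yields near-zero local rates", {
  spec <- design_spec("custom", seeding = c(low = 0.4, high = 0.8),
                      glucose = c(0.5, 2, 10), doses = 0, replicates = 1,
                      seeding_jitter = 0)
  tr <- truth_params(relation = bystander_relation(0, 0, 0), noise_sd = 0)
  ds <- generate_dataset(spec, tr, seed = 8)
  f <- fit_dataset_a(ds, control = calibration_control(n_starts = 1))
  expect_true(all(f$k_bys < 1e-4))
})

test_that("the exponential-decay relation is recovered exactly from
           exact rates", {
  G0 <- c(0, 0.1, 0.5, 1, 2, 5, 8, 10)
  k <- 0.1 * exp(-0.5 * G0) + 0.01
  f <- fit_kbys_relation(k, G0)
  expect_equal(f$relation$k_bys_0, 0.1, tolerance = 1e-6)
  expect_equal(f$relation$alpha, 0.5, tolerance = 1e-6)
  expect_equal(f$relation$beta, 0.01, tolerance = 1e-6)
  expect_true(all(f$intervals[, "lower"] <= f$intervals[, "estimate"]))
  expect_true(all(f$intervals[, "upper"] >= f$intervals[, "estimate"]))
})

test_that("a flat relation leaves only the level identifiable", {
  G0 <- rep(c(0, 1, 2, 5, 10), each = 2)
  k <- rep(0.06, length(G0))
  f <- suppressWarnings(fit_kbys_relation(k, G0))
  # alpha -> 0 makes k_bys_0 + beta the constant level; the split is free
  lvl <- bystander_rate(0, f$relation)
  expect_true(f$relation$alpha < 1e-3 ||
                abs(bystander_rate(10, f$relation) - 0.06) < 1e-4)
  expect_equal(lvl, 0.06, tolerance = 1e-4)
})

test_that("relation fitting validates its inputs", {
  expect_error(fit_kbys_relation(c(1, 2, 3), c(0, 1, 2)), "at least 4")
  expect_error(fit_kbys_relation(rep(0.1, 5), rep(2, 5)), "degenerate")
  expect_error(fit_kbys_relation(1:4 / 10, 1:5), "equal length")
})

test_that("Wald intervals for the relation have near-nominal coverage", {
  # rates generated from the law plus Gaussian noise; count how often the
  # 95% interval for the baseline offset covers the truth
  G0 <- rep(c(0, 0.1, 0.2, 0.5, 0.8, 1, 2, 5, 8, 10), each = 12)
  truth <- c(k0 = 0.1, a = 0.5, b = 0.01)
  set.seed(314)
  hits <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    k <- truth["k0"] * exp(-truth["a"] * G0) + truth["b"] +
      rnorm(length(G0), 0, 0.01)
    f <- fit_kbys_relation(pmax(k, 0), G0)
    ci <- f$intervals["beta", ]
    if (ci["lower"] <= truth["b"] && truth["b"] <= ci["upper"])
      hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.85)
})

test_that("bystander rate as a function of the inhibition constant is a
           monotone composition", {
  rel <- bystander_relation(0.1, 0.5, 0.01)
  fn <- kbys_as_function_of_gin(G0 = 5, N0 = 4e4, rel)
  expect_equal(fn(0), bystander_rate(5, rel))
  expect_equal(fn(1e6), rel$k_bys_0 + rel$beta, tolerance = 1e-6)
  g <- 10^seq(-6, -2, length.out = 20)
  expect_true(all(diff(fn(g)) >= 0))
})

test_that("per-dose inhibition constants are recovered with the bystander
           rate pinned", {
  f4 <- fixture("fit4", function()
    fit_gin_constrained(small_dsB(), small_fitA()$globals,
                        small_relation()$relation,
                        calibration_control(n_starts = 2)))
  expect_true(all(abs(f4$G_in - gin_truth) / gin_truth < 0.05))
  expect_true(all(f4$intervals[, "lower"] <= f4$G_in))
  expect_true(all(f4$intervals[, "upper"] >= f4$G_in))
})

test_that("inhibition is not identifiable without glucose", {
  spec <- design_spec("custom", seeding = c(low = 0.4), glucose = 0,
                      doses = c(0, 10), replicates = 2, seeding_jitter = 0)
  ds <- generate_dataset(spec, truth_noiseless(), seed = 21)
  expect_error(
    fit_gin_constrained(ds, small_fitA()$globals,
                        small_relation()$relation,
                        calibration_control(n_starts = 1)),
    "identifiab")
})

test_that("the joint stage recovers inhibition constants and local rates", {
  f4 <- fixture("fit4", function()
    fit_gin_constrained(small_dsB(), small_fitA()$globals,
                        small_relation()$relation,
                        calibration_control(n_starts = 2)))
  f5 <- fixture("fit5", function()
    fit_gin_and_local_kbys(small_dsB(), small_fitA()$globals, f4$intervals,
                           calibration_control(n_starts = 1)))
  expect_true(all(abs(f5$G_in - gin_truth) / gin_truth < 0.02))
  truth_kb <- small_dsB()$wells$k_bys_true
  expect_true(all(abs(f5$k_bys - truth_kb) / truth_kb < 0.02))
  # stage-4 bounds contain the stage-5 estimates by construction
  # degenerate (zero-width) stage-4 intervals are widened by 1e-12 before
  # the constrained refit, hence the tolerance
  expect_true(all(f5$G_in >= f4$intervals[, "lower"] - 1e-11))
  expect_true(all(f5$G_in <= f4$intervals[, "upper"] + 1e-11))
  # local rates decrease with accessible initial glucose
  ds <- small_dsB()
  N0 <- ds$wells$initial_confluence * 8e4
  gin <- ifelse(ds$wells$dose == 0, 0,
                f5$G_in[match(ds$wells$dose, f5$doses)])
  gacs0 <- accessible_glucose(ds$wells$G0, N0, gin)
  expect_lt(cor(rank(f5$k_bys), rank(gacs0)), -0.5)
})

test_that("point bounds degenerate the joint stage to per-well fitting", {
  f4 <- fixture("fit4", function()
    fit_gin_constrained(small_dsB(), small_fitA()$globals,
                        small_relation()$relation,
                        calibration_control(n_starts = 2)))
  pt <- f4$intervals
  pt[, "lower"] <- pt[, "upper"] <- pt[, "estimate"]
  f5 <- fit_gin_and_local_kbys(small_dsB(), small_fitA()$globals, pt,
                               calibration_control(n_starts = 1))
  expect_lt(max(abs(f5$G_in - pt[, "estimate"])), 1e-9)
})

test_that("local rates correlate more strongly with accessible than total
           glucose, and the relation refit confirms the decay", {
  f4 <- fixture("fit4", function()
    fit_gin_constrained(small_dsB(), small_fitA()$globals,
                        small_relation()$relation,
                        calibration_control(n_starts = 2)))
  f5 <- fixture("fit5", function()
    fit_gin_and_local_kbys(small_dsB(), small_fitA()$globals, f4$intervals,
                           calibration_control(n_starts = 1)))
  f6 <- refit_relation_accessible(f5, small_dsB(), small_fitA()$globals,
                                  small_relation()$relation)
  expect_true(f6$pattern_ok)
  expect_gt(abs(f6$cor_accessible), abs(f6$cor_total))
  # the refit against accessible glucose recovers the generating relation
  expect_equal(f6$relation$k_bys_0, bystander_relation()$k_bys_0,
               tolerance = 0.02)
  expect_equal(f6$relation$alpha, bystander_relation()$alpha,
               tolerance = 0.02)
})

test_that("untreated-only input makes both correlation targets identical", {
  f <- small_fitA()
  s5 <- structure(list(doses = numeric(0), G_in = numeric(0),
                       k_bys = f$k_bys), class = "stage_b_fit")
  f6 <- refit_relation_accessible(s5, small_dsA(), f$globals,
                                  small_relation()$relation)
  expect_equal(f6$cor_total, f6$cor_accessible)
})

test_that("a flat local-rate pattern raises the no-decay flag and keeps the
           prior relation", {
  ds <- small_dsB()
  prior <- small_relation()$relation
  s5 <- structure(list(doses = c(2, 10), G_in = gin_truth,
                       k_bys = rep(0.1, nrow(ds$wells))),
                  class = "stage_b_fit")
  f6 <- refit_relation_accessible(s5, ds, small_fitA()$globals, prior)
  expect_false(f6$pattern_ok)
  expect_identical(f6$relation, prior)
})

test_that("least-squares intervals match the closed form on a linear
           problem", {
  set.seed(11)
  x <- seq(0, 1, length.out = 20)
  y <- 1.5 + 2 * x + rnorm(20, 0, 0.1)
  X <- cbind(1, x)
  fit <- glucodyn:::.bounded_lsq(function(b) drop(X %*% b) - y,
                                 start = c(1, 1), lower = c(-10, -10),
                                 upper = c(10, 10))
  wi <- glucodyn:::.wald_intervals(fit, 0.95, c("b0", "b1"))
  lfit <- lm(y ~ x)
  expect_equal(unname(fit$par), unname(coef(lfit)), tolerance = 1e-6)
  expect_equal(unname(wi[, c("lower", "upper")]),
               unname(confint(lfit)), tolerance = 1e-4)
})

test_that("bootstrap intervals refuse a single resampling unit", {
  expect_error(
    glucodyn:::.bootstrap_intervals(function(i) c(a = 1), 1L, 10L, 1L),
    "at least 2")
})

test_that("prediction from initial conditions alone reproduces held-out
           noiseless wells", {
  ds <- generate_dataset(
    design_spec("B", replicates = 1,
                seeding = c(mid = 0.55), seeding_jitter = 0),
    truth_noiseless(), seed = 55)
  cal <- list(globals = global_params(), relation = bystander_relation(),
              inhibition = inhibition_params())
  pred <- obs <- NULL
  for (i in seq_len(nrow(ds$wells))) {
    w <- glucodyn:::as_well_list(ds$wells[i, ])[[1L]]
    tc <- predict_course(w, cal$globals, cal$relation, cal$inhibition)
    oc <- well_course(ds, w$well_id)
    pred <- c(pred, tc$live_pct, tc$dead_pct)
    obs <- c(obs, oc$live_pct, oc$dead_pct)
  }
  expect_gte(r_squared(pred, obs), 0.99)
  # unknown dose is refused
  expect_error(predict_course(well("x", 0.5, 5, dose = 7), cal$globals,
                              cal$relation, cal$inhibition),
               "dose")
})

test_that("an untreated well is predicted identically by the baseline path", {
  w <- well("u", 0.5, 2, dose = 0)
  rel <- bystander_relation()
  a <- predict_course(w, global_params(), rel, inhibition_params())
  b <- simulate_well(w, global_params(),
                     k_bys = bystander_rate(2, rel), G_in = 0)
  expect_equal(a$live_pct, b$live_pct, tolerance = 1e-12)
})
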