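test_that("state functions are complementary and match hand evaluation", {
  set.seed(1)
  G <- runif(50, 0, 10)
  t <- runif(50, 0, 4)
  sf <- state_functions(G, t)
  expect_equal(sf$S_p + sf$S_d, rep(1, 50))
  expect_true(all(sf$S_p >= 0 & sf$S_p <= 1))
  expect_true(all(sf$S_d >= 0 & sf$S_d <= 1))

  # zero glucose, late time: death state saturates at 1
  expect_equal(state_functions(0, 50)$S_d, 1, tolerance = 1e-12)
  expect_equal(state_functions(0, 50)$S_p, 0, tolerance = 1e-12)

  # G_acs = G_min: half of the ramp
  expect_equal(state_functions(0.01, 1, G_min = 0.01)$S_d,
               0.5 * tanh(1), tolerance = 1e-12)

  expect_error(state_functions(-1, 1), "G_acs")
  expect_error(state_functions(1, -1), "t must")
  expect_error(state_functions(1, 1, G_min = 0), "G_min")
})

test_that("accessible glucose follows the inhibition law", {
  expect_identical(accessible_glucose(5, 40000, 0), 5)   # no treatment
  expect_identical(accessible_glucose(10, 0, 4.55e-4), 10)  # empty well
  expect_equal(accessible_glucose(10, 50000, 4.55e-4), 10 / 23.75,
               tolerance = 1e-12)

  set.seed(2)
  G <- runif(100, 0, 10); N <- runif(100, 0, 8e4); gin <- runif(100, 0, 1e-2)
  ga <- accessible_glucose(G, N, gin)
  expect_true(all(ga <= G + 1e-12))
  expect_equal(ga[gin * N == 0], G[gin * N == 0])
  expect_true(all(ga[gin * N > 0 & G > 0] < G[gin * N > 0 & G > 0]))
  expect_error(accessible_glucose(-1, 1, 0), ">= 0")
})

test_that("bystander rate follows the exponential decay law", {
  rel <- bystander_relation(0.1, 0.5, 0.01)
  expect_equal(bystander_rate(0, rel), 0.11)
  expect_equal(bystander_rate(1e6, rel), 0.01)
  expect_equal(bystander_rate(2, rel), 0.1 * exp(-1) + 0.01,
               tolerance = 1e-12)
  G <- seq(0, 10, by = 0.1)
  expect_true(all(diff(bystander_rate(G, rel)) <= 0))
  expect_error(bystander_rate(-0.1, rel), ">= 0")
})

test_that("right-hand side terms switch off as expected", {
  p <- global_params()
  # no live cells: nothing moves
  expect_equal(unname(growth_rhs(c(N = 0, D = 1000, G_total = 5), 1, p,
                                 k_bys = 0.5, G_in = 1e-4)),
               c(0, 0, 0))
  # no dead cells: dead-cell accrual is the starvation flux only
  r <- growth_rhs(c(N = 1e4, D = 0, G_total = 0.05), 2, p, k_bys = 2)
  sf <- state_functions(0.05, 2, p$G_min)
  expect_equal(r[["dD"]], p$k_d * 1e4 * sf$S_d)
  # only consumption active
  p0 <- global_params(k_p = 1e-15, k_d = 1e-15)
  r0 <- growth_rhs(c(N = 1e4, D = 0, G_total = 5), 1, p0, k_bys = 0)
  expect_equal(r0[["dN"]], 0, tolerance = 1e-9)
  expect_equal(r0[["dD"]], 0, tolerance = 1e-9)
  expect_equal(r0[["dG_total"]], -p0$v * 1e4 * 5 / (5 + p0$G_star))
  expect_error(growth_rhs(c(N = NaN, D = 0, G_total = 1), 0, p, 0),
               "non-finite")
})

test_that("confluence/cell conversion is linear and invertible", {
  expect_equal(confluence_cells_convert(100, 8e4, "to_cells"), 8e4)
  expect_equal(confluence_cells_convert(0, 8e4, "to_cells"), 0)
  expect_equal(confluence_cells_convert(50, 8e4, "to_cells"), 4e4)
  x <- runif(20, 0, 100)
  expect_equal(
    confluence_cells_convert(
      confluence_cells_convert(x, 8e4, "to_cells"), 8e4, "to_confluence"),
    x)
  expect_error(confluence_cells_convert(101, 8e4, "to_cells"), "\\[0, 100\\]")
})

test_that("forward simulation honours trajectory invariants", {
  set.seed(3)
  p <- global_params()
  for (i in 1:5) {
    w <- well("x", runif(1, 0.1, 0.9), runif(1, 0, 10),
              initial_dead = runif(1, 0, 0.05))
    kb <- runif(1, 0, 1)
    gin <- sample(c(0, 10^runif(1, -5, -3)), 1)
    tc <- simulate_well(w, p, k_bys = kb, G_in = gin)
    expect_true(all(tc$live_pct >= 0 & tc$dead_pct >= 0 & tc$G_total >= 0))
    expect_true(all(diff(tc$dead_pct) >= -1e-8))
    expect_true(all(diff(tc$G_total) <= 1e-12))
    expect_true(all(tc$G_acs <= tc$G_total + 1e-12))
  }
})

test_that("zero-rate parameters freeze the cell populations", {
  p <- global_params(k_p = 1e-15, k_d = 1e-15, v = 1e-15)
  tc <- simulate_well(well("x", 0.5, 5), p, k_bys = 0)
  expect_equal(tc$live_pct, rep(50, nrow(tc)), tolerance = 1e-6)
  expect_equal(tc$dead_pct, rep(1, nrow(tc)), tolerance = 1e-6)
})

test_that("abundant glucose, no death: trajectory matches the logistic law", {
  p <- global_params()
  w <- well("x", 0.1, 10, initial_dead = 0)
  tc <- simulate_well(w, p, k_bys = 0, G_in = 0)
  expect_true(tail(tc$G_acs, 1) > 5)  # premise: glucose stays abundant
  N_cf <- glucodyn:::logistic_growth(tc$time_days, 0.1 * p$theta,
                                     p$k_p, p$theta)
  expect_equal(tc$live_pct, N_cf / p$theta * 100, tolerance = 0.02)
})

test_that("adaptive solver agrees with a fixed-step RK4 oracle", {
  p <- global_params()
  w <- well("x", 0.4, 0.5)
  kb <- 0.3
  gin <- 3.02e-4
  tc <- simulate_well(w, p, k_bys = kb, G_in = gin)
  oracle <- simulate_well(w, p, k_bys = kb, G_in = gin, engine = "r",
                          method = "rk4", hini = 1e-4)
  expect_lt(max(abs(tc$live_pct - oracle$live_pct)), 1e-3)
  expect_lt(max(abs(tc$dead_pct - oracle$dead_pct)), 1e-3)
})

test_that("no inhibition reduces the extended model to the baseline model", {
  p <- global_params()
  w_tr <- well("t", 0.5, 2, dose = 10)
  w_un <- well("u", 0.5, 2, dose = 0)
  a <- simulate_well(w_tr, p, k_bys = 0.2, G_in = 0)
  b <- simulate_well(w_un, p, k_bys = 0.2, G_in = 0)
  expect_equal(a$live_pct, b$live_pct, tolerance = 1e-12)
  expect_equal(a$dead_pct, b$dead_pct, tolerance = 1e-12)
})

test_that("stronger inhibition cannot increase growth or decrease death", {
  p <- global_params()
  # abundant glucose so no trajectory starves within the experiment
  w <- well("x", 0.3, 10)
  gins <- c(0, 1e-4, 3.02e-4, 4.55e-4, 1e-3)
  tcs <- lapply(gins, function(g)
    simulate_well(w, p, k_bys = 0.1, G_in = g))
  for (i in seq_len(length(gins) - 1L)) {
    expect_true(all(tcs[[i + 1L]]$live_pct <= tcs[[i]]$live_pct + 1e-6))
    expect_gte(tail(tcs[[i + 1L]]$dead_pct, 1),
               tail(tcs[[i]]$dead_pct, 1) - 1e-6)
  }
})

test_that("simulation input validation rejects malformed grids", {
  expect_error(simulate_well(well("x", 0.5, 5), times = c(1, 2)), "start at 0")
  expect_error(simulate_well(well("x", 0.5, 5), k_bys = -1), "k_bys")
})
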