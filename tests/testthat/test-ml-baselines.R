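# noisy combined dataset shared across the ML tests
ml_data <- function()
  fixture("ml_ds", function() {
    a <- generate_dataset(design_spec("A", replicates = 1),
                          truth_params(noise_sd = 0.5), seed = 201)
    b <- generate_dataset(design_spec("B", replicates = 1),
                          truth_params(noise_sd = 0.5), seed = 202)
    combine_datasets(a, b)
  })

test_that("the feature table has one row per well and time point with
           self-consistent origin rows", {
  ds <- ml_data()
  ft <- build_feature_table(ds)
  expect_equal(nrow(ft), nrow(ds$wells) * 33)
  expect_equal(ncol(ft), 9)  # ids + 5 features + 2 targets
  t0 <- ft[ft$time == 0, ]
  expect_equal(t0$live, t0$N0)
  expect_equal(t0$dead, t0$D0)
  b_only <- build_feature_table(
    generate_dataset(design_spec("B"), truth_params(noise_sd = 0),
                     seed = 1))
  expect_equal(nrow(b_only), 180 * 33)
})

test_that("well-level splitting is leakage-safe, stratified by dataset, and
           seed-reproducible", {
  # full-size designs: only the well tables matter for splitting
  full <- structure(list(
    wells = rbind(make_design(design_spec("A")),
                  make_design(design_spec("B"))),
    courses = NULL, seed = 1L), class = "confluence_dataset")
  sp <- split_by_well(full, 0.75, seed = 12)
  expect_equal(length(sp$train), 225)
  expect_equal(length(sp$valid), 75)
  a_train <- grepl("^A_", sp$train)
  expect_equal(sum(a_train), 90)    # 75% of 120, within dataset A
  expect_equal(length(intersect(sp$train, sp$valid)), 0)

  sp2 <- split_by_well(full, 0.75, seed = 12)
  expect_identical(sp, sp2)
  sp3 <- split_by_well(full, 0.75, seed = 13)
  expect_false(identical(sp$train, sp3$train))

  expect_error(split_by_well(full, 1.2), "between 0 and 1")
  expect_error(split_by_well(full, 0), "between 0 and 1")
})

test_that("a fully grown tree memorizes its training set", {
  ds <- ml_data()
  ft <- build_feature_table(ds)
  sp <- split_by_well(ds, 0.75, seed = 3)
  tr <- ft[ft$well_id %in% sp$train, ]
  va <- ft[ft$well_id %in% sp$valid, ]
  res <- train_and_score("tree", tr, va, seed = 3)
  expect_equal(round(res$scores["train", "total"], 4), 1.0000)
  expect_error(train_and_score("boost", tr, va), "'arg'")
  expect_error(train_and_score("tree", tr, tr), "leakage")
})

test_that("zero-variance targets are flagged rather than scored", {
  ft <- data.frame(well_id = rep(c("a", "b"), each = 3),
                   N0 = 0.4, D0 = 0.01, G0 = 2, dose = 0,
                   time = rep(0:2, 2), live = 0, dead = 0)
  w <- testthat::capture_warnings(
    sc <- train_and_score("linear", ft[1:3, ], ft[4:6, ])$scores)
  expect_true(any(grepl("zero variance", w)))
  expect_true(all(is.na(sc[, "live"])))
})

test_that("model ranking on synthetic data: forest beats linear out of
           sample", {
  ds <- ml_data()
  ft <- build_feature_table(ds)
  sp <- split_by_well(ds, 0.75, seed = 4)
  tr <- ft[ft$well_id %in% sp$train, ]
  va <- ft[ft$well_id %in% sp$valid, ]
  r_for <- train_and_score("forest", tr, va, seed = 4)
  r_lin <- train_and_score("linear", tr, va, seed = 4)
  expect_gt(r_for$scores["valid", "total"], r_lin$scores["valid", "total"])
})

test_that("without noise the flexible learners barely overfit", {
  a <- generate_dataset(design_spec("A", replicates = 1),
                        truth_params(noise_sd = 0), seed = 301)
  b <- generate_dataset(design_spec("B", replicates = 1),
                        truth_params(noise_sd = 0), seed = 302)
  ds <- combine_datasets(a, b)
  ft <- build_feature_table(ds)
  sp <- split_by_well(ds, 0.75, seed = 5)
  tr <- ft[ft$well_id %in% sp$train, ]
  va <- ft[ft$well_id %in% sp$valid, ]
  for (m in c("knn", "tree", "forest")) {
    sc <- train_and_score(m, tr, va, seed = 5)$scores
    expect_lt(sc["train", "total"] - sc["valid", "total"], 0.15)
  }
})

test_that("repeated evaluation is reproducible and detects no difference
           between clones of the same model", {
  ds <- ml_data()
  lin_clone <- function(tr, va, seed)
    ml_predict("linear", tr, va, seed = seed)
  e1 <- repeated_evaluation(ds, models = "linear", rounds = 3, seed0 = 9,
                            predictors = list(linear2 = lin_clone))
  e2 <- repeated_evaluation(ds, models = "linear", rounds = 3, seed0 = 9,
                            predictors = list(linear2 = lin_clone))
  expect_identical(e1$summary, e2$summary)

  tot <- e1$per_round[e1$per_round$set == "valid" &
                        e1$per_round$channel == "total", ]
  groups <- split(tot$r2, tot$model)
  expect_equal(groups$linear, groups$linear2, tolerance = 1e-12)
  an <- stats_anova_oneway(groups)
  expect_lt(an$F, 1e-10)

  # sanity bound: validation never beats training beyond CI noise
  s <- e1$summary
  for (ch in unique(s$channel)) {
    m_tr <- s$mean[s$model == "linear" & s$set == "train" & s$channel == ch]
    m_va <- s$mean[s$model == "linear" & s$set == "valid" & s$channel == ch]
    ci <- s$ci95[s$model == "linear" & s$set == "valid" & s$channel == ch]
    expect_lte(m_va, m_tr + 2 * ci + 0.05)
  }
})

test_that("learning curves cover the fraction grid and agree with the
           repeated evaluation at full size", {
  ds <- ml_data()
  lc <- learning_curve("linear", ds, fractions = c(0.2, 0.6, 1),
                       rounds = 2, seed0 = 21)
  expect_equal(sort(unique(lc$fraction)), c(0.2, 0.6, 1))
  expect_equal(nrow(lc), 2 * 3 * 6)  # rounds x fractions x set/channel

  ev <- repeated_evaluation(ds, models = "linear", rounds = 2, seed0 = 21)
  for (r in 1:2) {
    lc_val <- lc$r2[lc$round == r & lc$fraction == 1 & lc$set == "valid" &
                      lc$channel == "total"]
    ev_val <- ev$per_round$r2[ev$per_round$round == r &
                                ev$per_round$set == "valid" &
                                ev$per_round$channel == "total"]
    expect_equal(lc_val, ev_val)
  }
  # learning gains improve out-of-sample accuracy for the flexible model
  lc_f <- learning_curve("forest", ds, fractions = c(0.1, 1), rounds = 2,
                         seed0 = 21)
  v_small <- mean(lc_f$r2[lc_f$fraction == 0.1 & lc_f$set == "valid" &
                            lc_f$channel == "total"])
  v_full <- mean(lc_f$r2[lc_f$fraction == 1 & lc_f$set == "valid" &
                           lc_f$channel == "total"])
  expect_gt(relative_improvement(v_small, v_full), 0)
})
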