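#' Build the regression feature table from a confluence dataset
#'
#' One row per (well, time point), with exactly five features -- the initial
#' live and dead confluence (fractions of carrying capacity), the initial
#' glucose concentration, the inhibitor dose, and the time of measurement --
#' and two targets, the live and dead confluence fractions at that time.
#' No further features, feature selection, or dimension reduction.
#'
#' @param dataset A `confluence_dataset`.
#' @return A data frame with columns `well_id`, `dataset_tag`, `N0`, `D0`,
#'   `G0`, `dose`, `time`, and targets `live`, `dead` (all confluences as
#'   fractions in \[0, 1\]).
#' @export
build_feature_table <- function(dataset) {
  wd <- .well_data(dataset)
  tag <- dataset$wells$dataset_tag
  out <- lapply(seq_along(wd), function(i) {
    w <- wd[[i]]
    keep <- is.finite(w$live) & is.finite(w$dead)
    if (!all(keep))
      warning("build_feature_table: dropping ", sum(!keep),
              " incomplete time point(s) in well '", w$well_id, "'")
    data.frame(well_id = w$well_id, dataset_tag = tag[i],
               N0 = w$N0, D0 = w$D0, G0 = w$G0, dose = w$dose,
               time = w$times[keep],
               live = w$live[keep] / 100, dead = w$dead[keep] / 100)
  })
  do.call(rbind, out)
}

#' Combine two confluence datasets
#'
#' @param ... `confluence_dataset` objects with disjoint well ids.
#' @return A single `confluence_dataset`.
#' @export
combine_datasets <- function(...) {
  ds <- list(...)
  stopifnot(all(vapply(ds, inherits, TRUE, "confluence_dataset")))
  wells <- do.call(rbind, lapply(ds, function(d)
    d$wells[, intersect(names(d$wells),
                        Reduce(intersect, lapply(ds, function(x)
                          names(x$wells)))), drop = FALSE]))
  if (anyDuplicated(wells$well_id))
    stop("combine_datasets: duplicated well ids")
  structure(list(wells = wells,
                 courses = do.call(rbind, lapply(ds, `[[`, "courses")),
                 seed = ds[[1L]]$seed),
            class = "confluence_dataset")
}

#' Leakage-safe train/validation split at the well level
#'
#' Splits wells (not rows) into training and validation sets so that all
#' time points of a well land on the same side, performing the split
#' separately within each dataset tag (A and B).
#'
#' @param dataset A `confluence_dataset` (possibly combined A + B).
#' @param train_frac Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return A list with character vectors `train` and `valid` of well ids.
#' @export
split_by_well <- function(dataset, train_frac = 0.75, seed = 1L) {
  if (!is.finite(train_frac) || train_frac <= 0 || train_frac >= 1)
    stop("split_by_well: train_frac must lie strictly between 0 and 1")
  set.seed(as.integer(seed))
  train <- character(0)
  for (tag in unique(dataset$wells$dataset_tag)) {
    ids <- dataset$wells$well_id[dataset$wells$dataset_tag == tag]
    n_train <- round(train_frac * length(ids))
    n_train <- min(max(n_train, 1L), length(ids) - 1L)
    train <- c(train, sample(ids, n_train))
  }
  list(train = train, valid = setdiff(dataset$wells$well_id, train))
}

.ft_subset <- function(ft, ids) ft[ft$well_id %in% ids, , drop = FALSE]

.ml_features <- c("N0", "D0", "G0", "dose", "time")

# inverse-distance-weighted k-nearest-neighbour regression (Euclidean,
# unscaled features); exact-match neighbours short-circuit to their mean.
# Y may have several target columns sharing one distance computation.
.knn_predict <- function(X_train, Y_train, X_new, k = 5L) {
  Y_train <- as.matrix(Y_train)
  k <- min(k, nrow(X_train))
  out <- matrix(NA_real_, nrow(X_new), ncol(Y_train),
                dimnames = list(NULL, colnames(Y_train)))
  chunk <- 512L
  tr_sq <- rowSums(X_train^2)
  for (s in seq(1L, nrow(X_new), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(X_new))
    d2 <- outer(rep(1, length(idx)), tr_sq) -
      2 * X_new[idx, , drop = FALSE] %*% t(X_train) +
      rowSums(X_new[idx, , drop = FALSE]^2)
    d2[d2 < 0] <- 0
    for (j in seq_along(idx)) {
      dj <- d2[j, ]
      nn <- which(dj <= sort.int(dj, partial = k)[k])[seq_len(k)]
      dn <- sqrt(dj[nn])
      out[idx[j], ] <- if (any(dn == 0))
        colMeans(Y_train[nn[dn == 0], , drop = FALSE])
      else colSums(Y_train[nn, , drop = FALSE] / dn) / sum(1 / dn)
    }
  }
  out
}

#' Fit one baseline regressor and predict
#'
#' The four baselines are fitted per target (live and dead separately) at
#' pinned default hyperparameters: ordinary least squares for `"linear"`;
#' inverse-distance-weighted 5-nearest-neighbour regression for `"knn"`;
#' a fully grown regression tree (no complexity pruning) for `"tree"`; and
#' a 100-tree random forest using all five features per split for
#' `"forest"`.
#'
#' @param model_name One of `"linear"`, `"knn"`, `"tree"`, `"forest"`.
#' @param train Feature table (from [build_feature_table()]) to fit on.
#' @param newdata Feature table to predict.
#' @param seed Seed for the stochastic learners.
#' @return A matrix with columns `live` and `dead` of predicted confluence
#'   fractions for `newdata`.
#' @export
ml_predict <- function(model_name, train, newdata, seed = 1L) {
  model_name <- match.arg(model_name, c("linear", "knn", "tree", "forest"))
  X_tr <- as.matrix(train[, .ml_features])
  X_new <- as.matrix(newdata[, .ml_features])
  if (model_name == "knn")
    return(.knn_predict(X_tr, as.matrix(train[, c("live", "dead")]),
                        X_new, k = 5L))
  pred <- sapply(c("live", "dead"), function(target) {
    y <- train[[target]]
    switch(model_name,
      linear = {
        fit <- stats::lm.fit(cbind(1, X_tr), y)
        drop(cbind(1, X_new) %*% fit$coefficients)
      },
      tree = {
        d <- data.frame(y = y, train[, .ml_features])
        fit <- rpart::rpart(y ~ ., data = d, method = "anova",
                            control = rpart::rpart.control(
                              cp = 0, minsplit = 2L, minbucket = 1L,
                              maxdepth = 30L, xval = 0L))
        unname(stats::predict(fit, newdata[, .ml_features]))
      },
      forest = {
        d <- data.frame(y = y, train[, .ml_features])
        fit <- ranger::ranger(y ~ ., data = d, num.trees = 100L,
                              mtry = length(.ml_features),
                              min.node.size = 1L, seed = seed,
                              num.threads = 1L)
        stats::predict(fit, newdata[, .ml_features],
                       num.threads = 1L)$predictions
      })
  })
  pred
}

# score predicted vs observed feature-table targets: live / dead / total R^2
.score_r2 <- function(pred, ft) {
  c(live = r_squared(pred[, "live"], ft$live),
    dead = r_squared(pred[, "dead"], ft$dead),
    total = r_squared(c(pred[, "live"], pred[, "dead"]),
                      c(ft$live, ft$dead)))
}

#' Train one model and score it on training and validation sets
#'
#' @param model_name One of `"linear"`, `"knn"`, `"tree"`, `"forest"`.
#' @param train,valid Disjoint (at well level) feature tables.
#' @param seed Seed for the stochastic learners.
#' @return A list with `scores` (matrix: train/valid rows x live/dead/total
#'   columns) and `predictions` (validation predictions).
#' @export
train_and_score <- function(model_name, train, valid, seed = 1L) {
  if (length(intersect(unique(train$well_id), unique(valid$well_id))) > 0L)
    stop("train_and_score: train and validation share wells (leakage)")
  p_tr <- ml_predict(model_name, train, train, seed = seed)
  p_va <- ml_predict(model_name, train, valid, seed = seed)
  scores <- rbind(train = .score_r2(p_tr, train),
                  valid = .score_r2(p_va, valid))
  list(scores = scores, predictions = p_va)
}

#' Repeated train/validation evaluation
#'
#' Performs `rounds` independent leakage-safe splits and scores each model
#' (and any extra predictor, e.g. the calibrated mechanistic model) on every
#' round with one shared R-squared implementation and identical splits.
#'
#' @param dataset A `confluence_dataset` (typically combined A + B).
#' @param models Character vector of baseline names.
#' @param rounds Number of rounds (>= 2 for confidence intervals).
#' @param seed0 Base seed; round `r` uses `seed0 + r`.
#' @param train_frac Training fraction.
#' @param predictors Optional named list of functions
#'   `function(train_ft, valid_ft, round_seed)` returning a matrix with
#'   columns `live` and `dead` of validation predictions; scored alongside
#'   the baselines.
#' @return A list with `per_round` (long data frame of scores) and `summary`
#'   (mean and 95% CI per model/set/channel).
#' @export
repeated_evaluation <- function(dataset, models = c("linear", "knn", "tree",
                                                    "forest"),
                                rounds = 50L, seed0 = 1L, train_frac = 0.75,
                                predictors = NULL) {
  if (rounds < 2L) stop("repeated_evaluation: rounds must be >= 2")
  ft <- build_feature_table(dataset)
  rows <- list()
  for (r in seq_len(rounds)) {
    sp <- split_by_well(dataset, train_frac, seed = seed0 + r)
    tr <- .ft_subset(ft, sp$train)
    va <- .ft_subset(ft, sp$valid)
    for (m in models) {
      sc <- train_and_score(m, tr, va, seed = seed0 + r)$scores
      rows[[length(rows) + 1L]] <- data.frame(
        round = r, model = m,
        set = rep(rownames(sc), each = ncol(sc)),
        channel = rep(colnames(sc), times = nrow(sc)),
        r2 = as.vector(t(sc)))
    }
    for (m in names(predictors)) {
      pv <- predictors[[m]](tr, va, seed0 + r)
      rows[[length(rows) + 1L]] <- data.frame(
        round = r, model = m, set = "valid",
        channel = c("live", "dead", "total"),
        r2 = unname(.score_r2(pv, va)))
    }
  }
  per_round <- do.call(rbind, rows)
  agg <- stats::aggregate(r2 ~ model + set + channel, per_round,
                          function(x) .mean_ci(x))
  summary <- data.frame(agg[, 1:3], mean = agg$r2[, "mean"],
                        ci95 = agg$r2[, "ci"])
  list(per_round = per_round, summary = summary)
}

#' Learning curves over training-set size
#'
#' For each round, the full training set is subsampled (at the well level)
#' to each requested fraction, the model refitted, and training/validation
#' scores recorded. At fraction 1 and matching seeds, the scores coincide
#' with [repeated_evaluation()].
#'
#' @param model_name Baseline name.
#' @param dataset A `confluence_dataset`.
#' @param fractions Fractions of the training set, in (0, 1].
#' @param rounds Number of rounds.
#' @param seed0 Base seed (shared with [repeated_evaluation()] for
#'   consistency).
#' @param train_frac Training fraction of the outer split.
#' @return Long data frame: `round`, `fraction`, `n_wells`, `set`,
#'   `channel`, `r2`.
#' @export
learning_curve <- function(model_name, dataset,
                           fractions = seq(0.05, 1, by = 0.05),
                           rounds = 50L, seed0 = 1L, train_frac = 0.75) {
  if (any(fractions <= 0 | fractions > 1))
    stop("learning_curve: fractions must lie in (0, 1]")
  ft <- build_feature_table(dataset)
  rows <- list()
  for (r in seq_len(rounds)) {
    sp <- split_by_well(dataset, train_frac, seed = seed0 + r)
    va <- .ft_subset(ft, sp$valid)
    for (f in fractions) {
      ids <- sp$train
      if (f < 1) {
        n_sub <- round(f * length(ids))
        if (n_sub < 1L) {
          warning("learning_curve: fraction ", f, " yields 0 wells; skipped")
          next
        }
        set.seed(seed0 + r + round(1e6 * f))
        ids <- sample(ids, n_sub)
      }
      tr <- .ft_subset(ft, ids)
      sc <- train_and_score(model_name, tr, va, seed = seed0 + r)$scores
      rows[[length(rows) + 1L]] <- data.frame(
        round = r, fraction = f, n_wells = length(ids),
        set = rep(rownames(sc), each = ncol(sc)),
        channel = rep(colnames(sc), times = nrow(sc)),
        r2 = as.vector(t(sc)))
    }
  }
  do.call(rbind, rows)
}
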