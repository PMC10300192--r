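#' Experimental design specification
#'
#' Describes a multi-well confluence experiment: seeding levels, glucose
#' grid, inhibitor dose grid, replicate count and sampling grid. The two
#' built-in presets mirror the study designs: dataset "A" crosses three
#' seeding levels with ten glucose levels (no inhibitor; 120 wells at 4
#' replicates) and dataset "B" crosses three seeding levels with five glucose
#' levels and three Cytochalasin B doses (180 wells at 4 replicates).
#'
#' @param dataset `"A"`, `"B"`, or `"custom"`.
#' @param seeding Named numeric vector of seeding fractions in \[0, 1\].
#' @param glucose Glucose grid, mM.
#' @param doses Dose grid, uM.
#' @param replicates Replicates per condition.
#' @param times Sampling grid, days.
#' @param initial_dead Initial dead-cell confluence fraction.
#' @param seeding_jitter Half-width (confluence fraction) of uniform
#'   replicate-to-replicate jitter applied to the seeding fraction.
#' @return An object of class `design_spec`.
#' @examples
#' design_spec("A")
#' @export
design_spec <- function(dataset = c("A", "B", "custom"),
                        seeding = c(low = 0.40, intermediate = 0.65,
                                    high = 0.80),
                        glucose = NULL, doses = NULL, replicates = 4L,
                        times = default_time_grid(), initial_dead = 0.01,
                        seeding_jitter = 0.03) {
  dataset <- match.arg(dataset)
  if (is.null(glucose))
    glucose <- switch(dataset,
                      A = c(0, 0.1, 0.2, 0.5, 0.8, 1, 2, 5, 8, 10),
                      B = c(0.5, 1, 2, 5, 10),
                      stop("design_spec: 'glucose' required for custom designs"))
  if (is.null(doses))
    doses <- switch(dataset, A = 0, B = c(0, 2, 10),
                    stop("design_spec: 'doses' required for custom designs"))
  if (length(seeding) == 0L || length(glucose) == 0L || length(doses) == 0L)
    stop("design_spec: empty design grid")
  if (any(seeding < 0) || any(seeding > 1))
    stop("design_spec: seeding fractions must lie in [0, 1]")
  if (replicates < 1L) stop("design_spec: replicates must be >= 1")
  if (is.null(names(seeding)))
    names(seeding) <- paste0("s", seq_along(seeding))
  structure(list(dataset = dataset, seeding = seeding, glucose = glucose,
                 doses = doses, replicates = as.integer(replicates),
                 times = times, initial_dead = initial_dead,
                 seeding_jitter = seeding_jitter),
            class = "design_spec")
}

#' Expand a design specification into a well table
#'
#' Full factorial crossing of seeding level, glucose level, dose and
#' replicate, in a deterministic order with deterministic well ids.
#'
#' @param spec A [design_spec()].
#' @return A data frame with one row per well: `well_id`, `dataset_tag`,
#'   `seeding_label`, `initial_confluence` (nominal, before jitter), `G0`,
#'   `dose`, `replicate`, `initial_dead`.
#' @examples
#' nrow(make_design(design_spec("A")))  # 120
#' @export
make_design <- function(spec = design_spec("A")) {
  stopifnot(inherits(spec, "design_spec"))
  g <- expand.grid(replicate = seq_len(spec$replicates),
                   dose = spec$doses, G0 = spec$glucose,
                   seeding_label = names(spec$seeding),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$initial_confluence <- spec$seeding[g$seeding_label]
  g$dataset_tag <- spec$dataset
  g$initial_dead <- spec$initial_dead
  g$well_id <- sprintf("%s_%s_g%s_d%s_r%d", g$dataset_tag, g$seeding_label,
                       formatC(g$G0, format = "fg"),
                       formatC(g$dose, format = "fg"), g$replicate)
  g[, c("well_id", "dataset_tag", "seeding_label", "initial_confluence",
        "G0", "dose", "replicate", "initial_dead")]
}

#' Ground-truth parameters for synthetic data generation
#'
#' @param globals A [global_params()].
#' @param relation A [bystander_relation()] generating each well's bystander
#'   rate from its initial accessible glucose.
#' @param inhibition An [inhibition_params()] map from dose to `G_in`.
#' @param noise_sd SD of additive Gaussian noise on confluence, in percentage
#'   points.
#' @param noise_cv CV of an optional multiplicative lognormal noise component
#'   (0 disables it).
#' @param kbys_cv CV of optional well-level lognormal jitter on the bystander
#'   rate (0 disables it).
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(globals = global_params(),
                         relation = bystander_relation(),
                         inhibition = inhibition_params(),
                         noise_sd = 0.5, noise_cv = 0, kbys_cv = 0) {
  stopifnot(inherits(globals, "global_params"),
            inherits(relation, "bystander_relation"),
            inherits(inhibition, "inhibition_params"))
  if (noise_sd < 0 || noise_cv < 0 || kbys_cv < 0)
    stop("truth_params: noise parameters must be >= 0")
  structure(list(globals = globals, relation = relation,
                 inhibition = inhibition, noise_sd = noise_sd,
                 noise_cv = noise_cv, kbys_cv = kbys_cv),
            class = "truth_params")
}

as_well_list <- function(wells) {
  lapply(seq_len(nrow(wells)), function(i) {
    r <- wells[i, ]
    well(r$well_id, r$initial_confluence, r$G0, r$dose, r$replicate,
         r$dataset_tag,
         if ("initial_dead" %in% names(r)) r$initial_dead else 0.01)
  })
}

#' Generate a synthetic confluence dataset
#'
#' For each well of the design, the bystander rate is evaluated from the
#' truth relation at the well's initial *accessible* glucose (computed with
#' the truth `G_in` for its dose), the forward model is simulated on the
#' design's time grid, and measurement noise is added to the live and dead
#' confluence channels. Results are clipped to \[0, 100\] percent. The whole
#' procedure is reproducible given `seed`.
#'
#' @param design A well table from [make_design()] (or a `design_spec`,
#'   which is expanded first).
#' @param truth A [truth_params()].
#' @param seed Integer seed.
#' @param times Optional override of the sampling grid, days.
#' @return An object of class `confluence_dataset`: a list with `wells` (the
#'   design table plus the realized `initial_confluence`, `k_bys_true`,
#'   `G_in_true` columns) and `courses` (tidy data frame `well_id`,
#'   `time_days`, `live_pct`, `dead_pct`).
#' @examples
#' ds <- generate_dataset(make_design(design_spec("B", replicates = 1)),
#'                        truth_params(noise_sd = 0), seed = 1)
#' @export
generate_dataset <- function(design, truth = truth_params(), seed = 1L,
                             times = default_time_grid()) {
  if (inherits(design, "design_spec")) {
    times <- design$times
    jitter_hw <- design$seeding_jitter
    design <- make_design(design)
  } else jitter_hw <- 0
  stopifnot(is.data.frame(design), inherits(truth, "truth_params"))
  if (nrow(design) == 0L) stop("generate_dataset: empty design")

  set.seed(as.integer(seed) %% .Machine$integer.max)
  wells <- design
  if (jitter_hw > 0) {
    wells$initial_confluence <- pmin(pmax(
      wells$initial_confluence +
        stats::runif(nrow(wells), -jitter_hw, jitter_hw), 0.01), 0.99)
  }
  wells$G_in_true <- gin_for_dose(truth$inhibition, wells$dose)
  N0 <- wells$initial_confluence * truth$globals$theta
  G_acs0 <- accessible_glucose(wells$G0, N0, wells$G_in_true)
  kb <- bystander_rate(G_acs0, truth$relation)
  if (truth$kbys_cv > 0) {
    sdl <- sqrt(log(1 + truth$kbys_cv^2))
    kb <- kb * stats::rlnorm(length(kb), -sdl^2 / 2, sdl)
  }
  wells$k_bys_true <- kb

  courses <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    tc <- tryCatch(
      simulate_well(as_well_list(wells[i, ])[[1L]], truth$globals,
                    k_bys = wells$k_bys_true[i], G_in = wells$G_in_true[i],
                    times = times),
      error = function(e) stop("generate_dataset: well '", wells$well_id[i],
                               "': ", conditionMessage(e)))
    live <- tc$live_pct
    dead <- tc$dead_pct
    if (truth$noise_cv > 0) {
      sdl <- sqrt(log(1 + truth$noise_cv^2))
      live <- live * stats::rlnorm(length(live), -sdl^2 / 2, sdl)
      dead <- dead * stats::rlnorm(length(dead), -sdl^2 / 2, sdl)
    }
    if (truth$noise_sd > 0) {
      live <- live + stats::rnorm(length(live), 0, truth$noise_sd)
      dead <- dead + stats::rnorm(length(dead), 0, truth$noise_sd)
    }
    courses[[i]] <- data.frame(
      well_id = wells$well_id[i], time_days = tc$time_days,
      live_pct = pmin(pmax(live, 0), 100),
      dead_pct = pmin(pmax(dead, 0), 100))
  }
  structure(list(wells = wells, courses = do.call(rbind, courses),
                 seed = as.integer(seed)),
            class = "confluence_dataset")
}

#' @export
print.confluence_dataset <- function(x, ...) {
  cat(sprintf(
    "Confluence dataset: %d wells x %d time points (tags: %s)\n",
    nrow(x$wells), length(unique(x$courses$time_days)),
    paste(unique(x$wells$dataset_tag), collapse = ", ")))
  invisible(x)
}

#' Write / read a confluence dataset
#'
#' The time courses are written as tidy CSV (`well_id`, `time_days`,
#' `live_pct`, `dead_pct`) and the well table plus generation metadata as a
#' JSON sidecar (`<path>.json`).
#'
#' @param dataset A `confluence_dataset`.
#' @param path CSV file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the reconstructed `confluence_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "confluence_dataset"))
  utils::write.csv(dataset$courses, path, row.names = FALSE)
  meta <- list(wells = dataset$wells, seed = dataset$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @param path CSV file path previously written by [write_dataset()].
#' @export
read_dataset <- function(path) {
  courses <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("well_id", "time_days", "live_pct", "dead_pct")
  missing <- setdiff(required, names(courses))
  if (length(missing) > 0L)
    stop("read_dataset: missing column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(courses), required)
  if (length(extra) > 0L)
    warning("read_dataset: ignoring unknown column(s): ",
            paste(extra, collapse = ", "))
  bad <- which(!is.finite(courses$time_days) | !is.finite(courses$live_pct) |
                 !is.finite(courses$dead_pct))
  if (length(bad) > 0L)
    stop("read_dataset: non-numeric values at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("read_dataset: sidecar '", sidecar, "' not found")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  structure(list(wells = as.data.frame(meta$wells),
                 courses = courses[, required],
                 seed = meta$seed),
            class = "confluence_dataset")
}

#' Extract one well's time course from a dataset
#'
#' @param dataset A `confluence_dataset`.
#' @param well_id Well identifier.
#' @return Data frame with `time_days`, `live_pct`, `dead_pct`.
#' @export
well_course <- function(dataset, well_id) {
  tc <- dataset$courses[dataset$courses$well_id == well_id, , drop = FALSE]
  if (nrow(tc) == 0L) stop("well_course: unknown well '", well_id, "'")
  tc[order(tc$time_days), c("time_days", "live_pct", "dead_pct")]
}
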