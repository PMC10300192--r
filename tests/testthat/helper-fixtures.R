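# Shared fixtures: small designs and cached noiseless datasets so that the
# expensive forward simulations run once per test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

truth_noiseless <- function() truth_params(noise_sd = 0)

# reduced untreated design: 3 seedings x 6 glucose x 1 replicate = 18 wells
small_spec_a <- function(replicates = 1L)
  design_spec("A", glucose = c(0, 0.2, 0.5, 1, 2, 5, 10),
              replicates = replicates, seeding_jitter = 0)

# reduced treated design: 3 seedings x 5 glucose x 3 doses x 1 rep = 45 wells
small_spec_b <- function(replicates = 1L)
  design_spec("B", replicates = replicates, seeding_jitter = 0)

small_dsA <- function()
  fixture("dsA", function()
    generate_dataset(small_spec_a(), truth_noiseless(), seed = 101))

small_dsB <- function()
  fixture("dsB", function()
    generate_dataset(small_spec_b(), truth_noiseless(), seed = 102))

# stage-1 fit of the small untreated dataset (noiseless)
small_fitA <- function()
  fixture("fitA", function()
    fit_dataset_a(small_dsA(), control = calibration_control(n_starts = 2)))

small_relation <- function()
  fixture("relA", function()
    fit_kbys_relation(small_fitA()$k_bys, small_dsA()$wells$G0))

table1_truth <- c(k_p = 0.14, k_d = 0.041, v = 4.48e-5)
gin_truth <- c(3.02e-4, 4.55e-4)
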