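# Shared fixtures. The reference experiment and the transfer run are
# expensive, so they are computed once per test session on first use and
# cached for every test that needs them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# the full desk-scale reference run (phantom -> noise -> split -> FBP ->
# training -> inference -> metrics), fixed master seed
ref_run <- function() {
  fixture("ref_run", function() run_reference_experiment(pipeline_config(seed = 1)))
}

# transfer of the reference model to a second scan
transfer_run <- function() {
  fixture("transfer_run", function() {
    rep <- ref_run()
    transfer_experiment(rep$model, rep$config)
  })
}

# a small smooth test image (sum of Gaussian blobs), deterministic
smooth_image <- function(n, seed = 1) {
  set.seed(seed)
  xy <- seq_len(n)
  img <- matrix(0, n, n)
  for (i in 1:4) {
    cx <- runif(1, 0.25 * n, 0.75 * n); cy <- runif(1, 0.25 * n, 0.75 * n)
    s <- runif(1, n / 12, n / 6)
    img <- img + outer(exp(-(xy - cy)^2 / (2 * s^2)),
                       exp(-(xy - cx)^2 / (2 * s^2)))
  }
  img
}

# tiny noisy split-reconstruction dataset for quick training tests
tiny_split_recon <- function(grid = 32, n_angles = 64, counts = 250,
                             seed = 5) {
  fixture(sprintf("tiny_%d_%d_%d_%d", grid, n_angles, counts, seed), function() {
    ph <- phantom_spec("lattice", grid_size = grid, period = 8,
                       wall_attenuation = 0.02, seed = seed)
    acq <- acquisition_spec(n_angles = n_angles, mean_counts = counts,
                            seed = seed + 1)
    gt <- make_phantom(ph)
    sinos <- to_sinograms(simulate_counts(
      forward_project(gt, acquisition_angles(acq)), acq))
    pair <- split_projections(sinos)
    list(gt = gt,
         even = reconstruct_volume(pair$even),
         odd = reconstruct_volume(pair$odd))
  })
}
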