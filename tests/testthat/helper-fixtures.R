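# Shared synthetic fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# small noise-free dataset with eye traces: exact-recovery checks
noiseless_dataset <- function() {
  fixture("noiseless", function() {
    cfg <- synthetic_config(n_neurons = 64, noise_sd = 0,
                            trials_per_condition = 2, seed = 101)
    ds <- generate_population(cfg)
    list(ds = ds, pop = build_pseudopopulation(ds$sessions),
         truth = ground_truth(ds))
  })
}

# small noisy dataset, rates only: subspace checks
noisy_dataset <- function() {
  fixture("noisy", function() {
    cfg <- synthetic_config(n_neurons = 160, noise_sd = 2,
                            trials_per_condition = 2, trials_8dir = 1,
                            include_eye = FALSE, seed = 202)
    ds <- generate_population(cfg)
    list(ds = ds, pop = build_pseudopopulation(ds$sessions),
         truth = ground_truth(ds))
  })
}

# a hand-built trial record
make_trial <- function(rate, motion_onset, direction = 0, speed = 15,
                       contrast = 100, eye = NULL) {
  if (is.null(eye)) eye <- matrix(0, 2, length(rate))
  list(rate = rate, eye = eye, motion_onset = motion_onset,
       direction = direction, speed = speed, contrast = contrast)
}
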