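# Shared small-scale phantom fixtures, built once per test run.

small_spec <- function(...) {
  phantom_spec(grid_shape = c(32, 32, 14), ...)
}

tiny_spec <- function(...) {
  phantom_spec(grid_shape = c(24, 24, 10), ...)
}

# a clean noise-free phantom + series, reused read-only across tests
fx_clean <- local({
  sp <- phantom_spec(grid_shape = c(32, 32, 14), n_volumes = 21,
                     noise_sd = 0, drift_amplitude = 0, seed = 101)
  tp <- make_tissue_phantom(sp)
  ser <- simulate_subject_series(sp, ground_truth(tp$cbf_true, tp$tissue))
  list(spec = sp, tissue = tp$tissue, cbf_true = tp$cbf_true, series = ser)
})

# a noisy full-length phantom with two scheduled corrupted volumes
fx_noisy <- local({
  sp <- phantom_spec(grid_shape = c(32, 32, 14), seed = 202,
                     outlier_schedule = data.frame(volume = c(20, 61),
                                                   type = "noise"))
  tp <- make_tissue_phantom(sp)
  ser <- simulate_subject_series(sp, ground_truth(
    tp$cbf_true, tp$tissue, outlier_indices = c(20L, 61L)))
  list(spec = sp, tissue = tp$tissue, cbf_true = tp$cbf_true, series = ser,
       outlier_pairs = c(10L, 30L))
})
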