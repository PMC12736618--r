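# The end-to-end and cross-plant checks share three seeded 48 h experiment
# runs; they are computed once per test session and cached here.

experiment_cache <- new.env(parent = emptyenv())

acceptance_runs <- function() {
  if (!is.null(experiment_cache$runs)) return(experiment_cache$runs)
  config <- experiment_config(
    total_minutes = 2880, min_phase = 60, max_phase = 180,
    profile = default_plant_profile(),
    acq = acquisition_config(sweeps_per_burst = 20),
    cross_plant = TRUE, variant_shift = 0.3, variant_seed = 11
  )
  experiment_cache$runs <- lapply(1:3, function(s) {
    run_experiment(config, seed = s)$metrics
  })
  experiment_cache$runs
}
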