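#' Acquisition configuration
#'
#' One burst of `sweeps_per_burst` consecutive sweeps is captured every
#' `interval` minutes; the burst must finish within the interval.
#'
#' @param interval Minutes between bursts.
#' @param sweeps_per_burst Number of consecutive sweeps per burst.
#' @param sweep A [sweep_config()].
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(interval = 1, sweeps_per_burst = 100,
                               sweep = sweep_config()) {
  check_scalar_positive(interval, "interval")
  if (!is.numeric(sweeps_per_burst) || length(sweeps_per_burst) != 1L ||
      sweeps_per_burst < 1 || sweeps_per_burst != floor(sweeps_per_burst)) {
    abort_validation("`sweeps_per_burst` must be a positive integer")
  }
  stopifnot(inherits(sweep, "sweep_config"))
  acq <- structure(list(interval = interval,
                        sweeps_per_burst = as.integer(sweeps_per_burst),
                        sweep = sweep),
                   class = "acquisition_config")
  if (burst_duration(acq) >= interval * 60) {
    abort_validation("burst duration must be shorter than the acquisition interval")
  }
  acq
}

#' Duration of one burst
#'
#' @param acq An [acquisition_config()].
#' @return Burst duration in seconds:
#'   `sweeps_per_burst * n_points * dwell`. The defaults (100 sweeps of 230
#'   points at 1 ms dwell) give 23 s.
#' @export
burst_duration <- function(acq) {
  stopifnot(inherits(acq, "acquisition_config"))
  acq$sweeps_per_burst * acq$sweep$n_points * acq$sweep$dwell
}

new_burst_dataset <- function(data, timestamps, labels, manifest) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (is.unsorted(timestamps, strictly = TRUE)) {
    abort_validation("sample timestamps must be strictly increasing")
  }
  if (length(timestamps) != dim(data)[1] || length(labels) != dim(data)[1]) {
    abort_validation("timestamps/labels must match the number of samples")
  }
  label_to_int(labels)
  structure(list(data = data, timestamps = as.numeric(timestamps),
                 labels = as.character(labels), manifest = manifest),
            class = "burst_dataset")
}

#' Number of samples in a burst dataset
#' @param ds A `burst_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(ds) {
  stopifnot(inherits(ds, "burst_dataset"))
  dim(ds$data)[1]
}

#' Subset a burst dataset by sample index
#' @param ds A `burst_dataset`.
#' @param idx Integer or logical index over samples.
#' @return A `burst_dataset` with the selected samples, in the given order.
#' @export
ds_slice <- function(ds, idx) {
  stopifnot(inherits(ds, "burst_dataset"))
  new_burst_dataset(ds$data[idx, , , drop = FALSE], ds$timestamps[idx],
                    ds$labels[idx], ds$manifest)
}

#' @export
print.burst_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<burst_dataset> %d samples x %d sweeps x %d frequencies\n",
              d[1], d[2], d[3]))
  cat(sprintf("  span %.0f..%.0f min | labels: %s | profile: %s\n",
              min(x$timestamps), max(x$timestamps),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", "),
              x$manifest$profile_id %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample summary of a burst dataset
#'
#' @param x A `burst_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per sample: `timestamp`, `label`, and the
#'   mean amplitude (de-quantized) of the burst.
#' @method as_tibble burst_dataset
#' @export
as_tibble.burst_dataset <- function(x, ...) {
  fs <- x$manifest$full_scale
  tibble(
    timestamp = x$timestamps,
    label = x$labels,
    mean_amplitude = apply(x$data, 1, mean) * fs / 65535
  )
}

quantize_amplitude <- function(amp, full_scale) {
  q <- round(amp / full_scale * 65535)  # round-half-to-even
  q[q < 0] <- 0
  q[q > 65535] <- 65535
  storage.mode(q) <- "integer"
  q
}

dequantize_amplitude <- function(counts, full_scale) {
  counts * (full_scale / 65535)
}

#' Generate a labeled burst dataset
#'
#' Renders a schedule and plant profile into the acquisition format: the plant
#' state trajectory is simulated at the acquisition interval, each burst's
#' noiseless sweep is computed from the circuit model at the plant's current
#' Cole parameters, independent Gaussian amplitude noise is added to every
#' sweep, and amplitudes are quantized to unsigned 16-bit counts against
#' `full_scale`. Labels follow the schedule state at each burst timestamp.
#'
#' @param schedule A [light_schedule()].
#' @param profile A [plant_profile()].
#' @param acq An [acquisition_config()].
#' @param comps A [circuit_components()].
#' @param excitation An [excitation_model()].
#' @param full_scale Amplitude mapped to the top quantization count.
#' @param seed Optional integer seed controlling trajectory drift and noise.
#' @return A `burst_dataset`: quantized data array
#'   `(samples x sweeps x n_points)`, timestamps (minutes), labels, and a
#'   manifest recording the acquisition settings.
#' @export
generate_dataset <- function(schedule, profile, acq = acquisition_config(),
                             comps = circuit_components(),
                             excitation = excitation_model(),
                             full_scale = 2, seed = NULL) {
  stopifnot(inherits(schedule, "light_schedule"), inherits(profile, "plant_profile"),
            inherits(acq, "acquisition_config"))
  check_scalar_positive(full_scale, "full_scale")
  with_seed(seed, {
    traj <- simulate_plant_state(schedule, profile, dt = acq$interval)
    n <- nrow(traj)
    S <- acq$sweeps_per_burst
    P <- acq$sweep$n_points
    data <- array(0L, dim = c(n, S, P))
    freqs <- sweep_frequencies(acq$sweep)
    hg <- harmonic_grid(freqs, excitation)
    for (i in seq_len(n)) {
      load <- cole_load(traj$r0[i], traj$r_inf[i], traj$tau[i], traj$alpha[i])
      zp <- plant_impedance(load, hg$freq)
      g <- Mod(network_response(hg$freq, comps, zp))
      amp <- as.numeric(rowsum(g * hg$weight, hg$point))
      amp <- pmax(0, amp - comps$v_diode)
      burst <- matrix(rep(amp, each = S), nrow = S)
      if (profile$noise_sd > 0) {
        burst <- pmax(0, burst + matrix(rnorm(S * P, 0, profile$noise_sd), S, P))
      }
      data[i, , ] <- quantize_amplitude(burst, full_scale)
    }
    manifest <- list(
      format = "plantimp-burst", version = 1L,
      interval = acq$interval, sweeps_per_burst = S, n_points = P,
      f_start = acq$sweep$f_start, f_step = acq$sweep$f_step,
      dwell = acq$sweep$dwell, full_scale = full_scale,
      profile_id = profile$profile_id,
      schedule_digest = schedule_digest(schedule),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    )
    new_burst_dataset(data, traj$t, traj$state, manifest)
  })
}

#' Frequency axis of a dataset
#' @param ds A `burst_dataset`.
#' @return Numeric vector of the `n_points` sweep frequencies, Hz.
#' @export
dataset_frequencies <- function(ds) {
  stopifnot(inherits(ds, "burst_dataset"))
  ds$manifest$f_start + ds$manifest$f_step * (seq_len(ds$manifest$n_points) - 1)
}
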