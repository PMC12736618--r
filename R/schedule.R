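#' Construct a light/dark schedule
#'
#' A schedule is an ordered run of strictly alternating "dark"/"light" phases
#' with positive durations, stored as a tibble with one row per phase and
#' half-open time support `[t_start, t_end)` in minutes.
#'
#' @param states Character vector of phase states, strictly alternating
#'   between `"dark"` and `"light"`.
#' @param durations Positive phase durations, minutes.
#' @param start_time Start of the first phase, minutes.
#' @return A tibble of class `light_schedule` with columns `phase`, `state`,
#'   `duration`, `t_start`, `t_end`.
#' @export
light_schedule <- function(states, durations, start_time = 0) {
  if (length(states) != length(durations) || length(states) == 0) {
    abort_validation("`states` and `durations` must be non-empty and equal length")
  }
  if (!all(states %in% label_levels())) {
    abort_validation("states must be 'dark' or 'light'")
  }
  if (any(durations <= 0)) abort_validation("phase durations must be positive")
  if (length(states) > 1 && any(states[-1] == states[-length(states)])) {
    abort_validation("states must strictly alternate")
  }
  t_end <- start_time + cumsum(durations)
  out <- tibble(
    phase = seq_along(states),
    state = states,
    duration = durations,
    t_start = c(start_time, t_end[-length(t_end)]),
    t_end = t_end
  )
  class(out) <- c("light_schedule", class(out))
  out
}

#' Generate a randomized light schedule
#'
#' Phase durations are drawn uniformly on `[min_phase, max_phase]` minutes,
#' alternating between dark and light, until `total` minutes are covered; the
#' last phase is truncated to fit.
#'
#' @param total Total schedule span, minutes.
#' @param min_phase,max_phase Bounds of the uniform phase-duration draw,
#'   minutes. Defaults cover one to three hours.
#' @param initial_state State of the first phase.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A [light_schedule()].
#' @examples
#' generate_schedule(total = 480, seed = 1)
#' @export
generate_schedule <- function(total, min_phase = 60, max_phase = 180,
                              initial_state = "dark", seed = NULL) {
  check_scalar_positive(total, "total")
  check_scalar_positive(min_phase, "min_phase")
  if (min_phase > max_phase) {
    abort_validation("`min_phase` must not exceed `max_phase`")
  }
  initial_state <- match.arg(initial_state, label_levels())
  with_seed(seed, {
    durations <- numeric(0)
    while (sum(durations) < total) {
      durations <- c(durations, runif(1, min_phase, max_phase))
    }
    excess <- sum(durations) - total
    durations[length(durations)] <- durations[length(durations)] - excess
    durations <- durations[durations > 0]
    states <- rep_len(
      if (initial_state == "dark") label_levels() else rev(label_levels()),
      length(durations)
    )
    light_schedule(states, durations)
  })
}

#' Schedule state at given times
#'
#' @param schedule A [light_schedule()].
#' @param t Vector of times, minutes; each must fall in the schedule span
#'   `[t_start, t_end)`.
#' @return Character vector of states at `t`.
#' @export
schedule_state_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "light_schedule"))
  idx <- findInterval(t, schedule$t_start)
  if (any(idx == 0) || any(t >= max(schedule$t_end))) {
    abort_validation("times fall outside the schedule span")
  }
  schedule$state[idx]
}

#' Internal switch times of a schedule
#'
#' @param schedule A [light_schedule()].
#' @return Times (minutes) at which the light state changes, excluding the
#'   schedule start and end.
#' @export
switch_times <- function(schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  schedule$t_start[-1]
}

schedule_digest <- function(schedule) {
  paste0("n", nrow(schedule), ":",
         substr(paste(sprintf("%.3f", schedule$duration), collapse = ","), 1, 64))
}
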