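#' Per-plant dynamic profile
#'
#' Describes how one plant's Cole impedance responds to light: the steady-state
#' parameter targets under darkness and illumination, the first-order response
#' lag with which parameters relax toward the target after a light switch, a
#' slow multiplicative baseline drift on the resistive parameters, and the
#' amplitude noise of individual sweeps.
#'
#' @param dark_target,light_target [cole_load()] parameter sets the plant
#'   relaxes toward in each state.
#' @param tau_resp Response lag, minutes: the e-folding time of the
#'   exponential relaxation toward the state target.
#' @param drift_sd Per-sqrt-minute standard deviation of the geometric random
#'   walk multiplying the `r0`/`r_inf` baselines (dimensionless log scale).
#' @param noise_sd Additive Gaussian noise SD on sweep amplitudes
#'   (amplitude units).
#' @param profile_id Free-text identifier carried into dataset manifests.
#' @return An object of class `plant_profile`.
#' @export
plant_profile <- function(dark_target, light_target, tau_resp = 5,
                          drift_sd = 5e-4, noise_sd = 0.04,
                          profile_id = "plant-A") {
  stopifnot(inherits(dark_target, "cole_load"), inherits(light_target, "cole_load"))
  check_scalar_positive(tau_resp, "tau_resp")
  check_scalar_nonneg(drift_sd, "drift_sd")
  check_scalar_nonneg(noise_sd, "noise_sd")
  structure(list(dark_target = dark_target, light_target = light_target,
                 tau_resp = tau_resp, drift_sd = drift_sd, noise_sd = noise_sd,
                 profile_id = profile_id),
            class = "plant_profile")
}

#' Default plant profile
#'
#' Dark state: `r0` 20 kOhm, `r_inf` 2 kOhm, `tau` 2 us, `alpha` 0.8 — a
#' dispersion centred inside the 20–249 kHz sweep band, with magnitudes in
#' the kilo-ohm range typical of electrode-coupled plant tissue at these
#' frequencies, comparable to the front end's source and tank impedances so
#' the plant visibly modulates the response. Illumination lowers `r0` by
#' `r0_effect` and `tau` by `tau_effect` (30% and 20% by default),
#' reflecting light-driven increases in ionic mobility.
#'
#' @param r0_effect Relative reduction of `r0` under light (default 0.30).
#' @param tau_effect Relative reduction of `tau` under light (default 0.20).
#' @param ... Passed on to [plant_profile()] (`tau_resp`, `drift_sd`,
#'   `noise_sd`, `profile_id`).
#' @return A [plant_profile()].
#' @export
default_plant_profile <- function(r0_effect = 0.30, tau_effect = 0.20, ...) {
  dark <- cole_load(r0 = 20e3, r_inf = 2e3, tau = 2e-6, alpha = 0.8)
  light <- cole_load(r0 = dark$r0 * (1 - r0_effect), r_inf = dark$r_inf,
                     tau = dark$tau * (1 - tau_effect), alpha = dark$alpha)
  plant_profile(dark, light, ...)
}

#' Simulate the lagged plant-state trajectory
#'
#' Each Cole parameter relaxes exponentially toward its state-dependent target
#' with time constant `tau_resp` (exact discretization:
#' `theta += (1 - exp(-dt/tau_resp)) * (target - theta)`), so after a light
#' switch the impedance approaches the new steady state with a lag of several
#' minutes. A geometric random walk (SD `drift_sd` per sqrt-minute) multiplies
#' the `r0`/`r_inf` baselines, producing the slow drift seen in long
#' recordings. The trajectory starts in the steady state of the first phase.
#'
#' @param schedule A [light_schedule()].
#' @param profile A [plant_profile()].
#' @param dt Time step, minutes.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A tibble with columns `t`, `state`, `r0`, `r_inf`, `tau`, `alpha`,
#'   one row per step from the schedule start to its end.
#' @export
simulate_plant_state <- function(schedule, profile, dt = 1, seed = NULL) {
  stopifnot(inherits(schedule, "light_schedule"), inherits(profile, "plant_profile"))
  check_scalar_positive(dt, "dt")
  t_grid <- seq(min(schedule$t_start), max(schedule$t_end) - dt, by = dt)
  states <- schedule_state_at(schedule, t_grid)
  n <- length(t_grid)
  targets <- list(dark = profile$dark_target, light = profile$light_target)
  par_names <- c("r0", "r_inf", "tau", "alpha")

  with_seed(seed, {
    drift <- if (profile$drift_sd > 0) {
      exp(cumsum(c(0, rnorm(n - 1, 0, profile$drift_sd * sqrt(dt)))))
    } else {
      rep(1, n)
    }
    relax <- 1 - exp(-dt / profile$tau_resp)
    theta <- unlist(targets[[states[1]]][par_names])
    out <- matrix(NA_real_, n, length(par_names),
                  dimnames = list(NULL, par_names))
    out[1, ] <- theta * c(drift[1], drift[1], 1, 1)
    for (i in seq_len(n - 1)) {
      tg <- unlist(targets[[states[i]]][par_names])
      tg[c("r0", "r_inf")] <- tg[c("r0", "r_inf")] * drift[i + 1]
      theta <- theta + relax * (tg - theta)
      out[i + 1, ] <- theta
    }
    out[, "alpha"] <- pmin(pmax(out[, "alpha"], 1e-6), 1)
    tibble(t = t_grid, state = states,
           r0 = out[, "r0"], r_inf = out[, "r_inf"],
           tau = out[, "tau"], alpha = out[, "alpha"])
  })
}

#' Derive a parameter-shifted variant plant
#'
#' Emulates a second plant specimen: every target Cole parameter is multiplied
#' by an independent log-normal factor `exp(N(0, shift))`. The sign of the
#' light-minus-dark difference is preserved for each parameter (factors are
#' swapped between the two targets where a draw would flip it), so the variant
#' responds to light in the same direction but with shifted baselines and
#' effect sizes. `alpha` is clipped back into (0, 1].
#'
#' @param base A [plant_profile()].
#' @param shift Log-scale SD of the multiplicative factors (>= 0); 0 returns
#'   the profile unchanged.
#' @param seed Optional integer seed.
#' @return A new [plant_profile()] with `profile_id` suffixed `"-variant"`.
#' @export
make_variant_profile <- function(base, shift, seed = NULL) {
  stopifnot(inherits(base, "plant_profile"))
  check_scalar_nonneg(shift, "shift")
  if (shift == 0) return(base)
  par_names <- c("r0", "r_inf", "tau", "alpha")
  with_seed(seed, {
    dark <- unlist(base$dark_target[par_names])
    light <- unlist(base$light_target[par_names])
    m_dark <- exp(rnorm(length(par_names), 0, shift))
    m_light <- exp(rnorm(length(par_names), 0, shift))
    m_light[light == dark] <- m_dark[light == dark]  # keep exact equalities
    flip <- sign(light * m_light - dark * m_dark) != sign(light - dark) &
      light != dark
    tmp <- m_dark[flip]
    m_dark[flip] <- m_light[flip]
    m_light[flip] <- tmp
    dark <- dark * m_dark
    light <- light * m_light
    dark["alpha"] <- min(max(dark["alpha"], 1e-6), 1)
    light["alpha"] <- min(max(light["alpha"], 1e-6), 1)
    plant_profile(
      dark_target = cole_load(dark["r0"], dark["r_inf"], dark["tau"], dark["alpha"]),
      light_target = cole_load(light["r0"], light["r_inf"], light["tau"], light["alpha"]),
      tau_resp = base$tau_resp, drift_sd = base$drift_sd,
      noise_sd = base$noise_sd,
      profile_id = paste0(base$profile_id, "-variant")
    )
  })
}
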