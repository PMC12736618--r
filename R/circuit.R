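#' Analog front-end component values
#'
#' Describes the swept-frequency sensing chain: a square-wave source feeding a
#' series resistor, a parallel resonant tank (L, C, damping resistor) at node A,
#' a coupling capacitor to node B where the plant is attached, and the RC of the
#' envelope detector that demodulates the response.
#'
#' @param r_series Series source resistor, ohms.
#' @param l_tank Tank inductance, henry.
#' @param c_tank Tank capacitance, farad.
#' @param r_damp Tank damping resistor, ohms.
#' @param c_couple Coupling capacitor between the tank node and the plant, farad.
#' @param r_env Envelope detector resistor, ohms.
#' @param c_env Envelope detector capacitor, farad.
#' @param v_diode Constant diode drop subtracted by the envelope detector, volts.
#'   The default 0 models an ideal diode.
#' @return An object of class `circuit_components`.
#' @examples
#' comps <- circuit_components()
#' envelope_cutoff(comps$r_env, comps$c_env)  # ~1.6 kHz
#' @export
circuit_components <- function(r_series = 10e3, l_tank = 30e-3, c_tank = 1e-9,
                               r_damp = 4.7e3, c_couple = 10e-9,
                               r_env = 1e6, c_env = 100e-12, v_diode = 0) {
  vals <- list(r_series = r_series, l_tank = l_tank, c_tank = c_tank,
               r_damp = r_damp, c_couple = c_couple,
               r_env = r_env, c_env = c_env, v_diode = v_diode)
  for (nm in setdiff(names(vals), "v_diode")) {
    check_scalar_positive(vals[[nm]], nm)
  }
  check_scalar_nonneg(v_diode, "v_diode")
  structure(vals, class = "circuit_components")
}

#' Cole single-dispersion load parameters
#'
#' The plant is represented as a Cole impedance
#' \deqn{Z(\omega) = R_\infty + (R_0 - R_\infty) / (1 + (j\omega\tau)^\alpha),}
#' the standard minimal parameterization of tissue bioimpedance: `r0` is the
#' low-frequency (ionic, extracellular) resistance, `r_inf` the high-frequency
#' resistance once membranes are shorted, `tau` the characteristic time of the
#' dispersion, and `alpha` its broadening exponent.
#'
#' @param r0 Low-frequency resistance, ohms. Must exceed `r_inf`.
#' @param r_inf High-frequency resistance, ohms.
#' @param tau Dispersion time constant, seconds.
#' @param alpha Dispersion exponent in (0, 1]; `alpha = 1` recovers a single
#'   Debye relaxation.
#' @return An object of class `cole_load`.
#' @examples
#' zl <- cole_load(r0 = 1e6, r_inf = 1e4, tau = 2e-6, alpha = 0.8)
#' plant_impedance(zl, 1e5)
#' @export
cole_load <- function(r0, r_inf, tau, alpha) {
  check_scalar_positive(r0, "r0")
  check_scalar_positive(r_inf, "r_inf")
  check_scalar_positive(tau, "tau")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1) {
    abort_validation("`alpha` must be a single number in (0, 1]")
  }
  if (r0 <= r_inf) {
    abort_validation("`r0` must be strictly greater than `r_inf`")
  }
  structure(list(r0 = unname(r0), r_inf = unname(r_inf), tau = unname(tau),
                 alpha = unname(alpha)),
            class = "cole_load")
}

#' Sweep grid configuration
#'
#' The excitation steps through `n_points` frequencies from `f_start` in
#' increments of `f_step`, dwelling `dwell` seconds at each point while the
#' envelope output is sampled. The defaults give the 230-point grid
#' 20, 21, ..., 249 kHz.
#'
#' @param f_start First frequency, Hz.
#' @param f_stop Last frequency, Hz (inclusive grid endpoint).
#' @param f_step Grid step, Hz.
#' @param dwell Dwell time per frequency point, seconds.
#' @return An object of class `sweep_config` with the derived `n_points`.
#' @export
sweep_config <- function(f_start = 20e3, f_stop = 249e3, f_step = 1e3,
                         dwell = 1e-3) {
  check_scalar_positive(f_step, "f_step")
  check_scalar_positive(dwell, "dwell")
  check_scalar_nonneg(f_start, "f_start")
  if (f_start >= f_stop) abort_validation("`f_start` must be below `f_stop`")
  n_points <- floor((f_stop - f_start) / f_step) + 1L
  structure(list(f_start = f_start, f_stop = f_stop, f_step = f_step,
                 dwell = dwell, n_points = as.integer(n_points)),
            class = "sweep_config")
}

#' Frequency grid of a sweep configuration
#' @param cfg A [sweep_config()].
#' @return Numeric vector of `cfg$n_points` frequencies in Hz.
#' @export
sweep_frequencies <- function(cfg) {
  cfg$f_start + cfg$f_step * (seq_len(cfg$n_points) - 1)
}

#' Excitation model for the square-wave source
#'
#' The microcontroller excites the network with a square wave whose Fourier
#' series has odd harmonics of amplitude `4/(pi*k)`. The default
#' `"fundamental"` model keeps only the first harmonic, which reproduces the
#' band-pass-shaped sweep signal the instrument records; `"square"` sums the
#' per-harmonic response magnitudes (a peak-sum approximation) up to
#' `f_limit`, which is order-correct but accumulates in-band harmonics of the
#' low sweep frequencies.
#'
#' @param type `"fundamental"` (first harmonic only) or `"square"` (odd
#'   harmonics up to `f_limit`).
#' @param f_limit Highest harmonic frequency retained, Hz. The fundamental is
#'   always kept.
#' @return An object of class `excitation_model`.
#' @export
excitation_model <- function(type = c("fundamental", "square"), f_limit = 2e6) {
  type <- match.arg(type)
  check_scalar_positive(f_limit, "f_limit")
  structure(list(type = type, f_limit = f_limit), class = "excitation_model")
}

#' Complex plant impedance of a Cole load
#'
#' Evaluates \eqn{Z(\omega) = R_\infty + (R_0 - R_\infty)/(1 + (j\omega\tau)^\alpha)}
#' at `freq` (vectorized). At DC this is exactly `r0`; as frequency grows the
#' magnitude tends to `r_inf`. For `alpha <= 1` the imaginary part is
#' non-positive (capacitive dispersion).
#'
#' @param params A [cole_load()].
#' @param freq Frequency or vector of frequencies, Hz (non-negative).
#' @return Complex vector of impedances, ohms.
#' @export
plant_impedance <- function(params, freq) {
  stopifnot(inherits(params, "cole_load"))
  if (any(freq < 0)) abort_validation("`freq` must be non-negative")
  jwt <- complex(real = 0, imaginary = 2 * pi * freq * params$tau)
  params$r_inf + (params$r0 - params$r_inf) / (1 + jwt^params$alpha)
}

#' Voltage gain of the coupled tank/plant network
#'
#' Nodal analysis of the measurement chain: source -> `r_series` -> node A;
#' node A to ground through the parallel tank (`l_tank || c_tank || r_damp`);
#' node A -> `c_couple` -> node B; node B to ground through the plant impedance.
#' The reported gain is the measured node voltage over the source voltage.
#'
#' @param freq Frequency or vector of frequencies, Hz (non-negative).
#' @param comps A [circuit_components()].
#' @param z_plant Complex plant impedance (scalar or vector matching `freq`).
#'   `Inf` is the open-circuit sentinel: no plant attached.
#' @param node `"plant"` (node B, across the plant; the default measurement
#'   point) or `"tank"` (node A). With the open-circuit sentinel the node-A
#'   divider gain is returned regardless.
#' @return Complex voltage gain, same length as `freq`.
#' @export
network_response <- function(freq, comps, z_plant, node = c("plant", "tank")) {
  node <- match.arg(node)
  stopifnot(inherits(comps, "circuit_components"))
  if (any(freq < 0)) abort_validation("`freq` must be non-negative")
  n <- max(length(freq), length(z_plant))
  freq <- rep_len(freq, n)
  z_plant <- rep_len(z_plant, n)
  w <- 2 * pi * freq
  open_circuit <- !is.finite(Re(z_plant)) | !is.finite(Im(z_plant))

  out <- complex(n)
  pos <- freq > 0
  if (any(pos)) {
    wp <- w[pos]
    jw <- complex(real = 0, imaginary = wp)
    y_tank <- 1 / (jw * comps$l_tank) + jw * comps$c_tank + 1 / comps$r_damp
    z_tank <- 1 / y_tank
    z_c <- 1 / (jw * comps$c_couple)
    zp <- z_plant[pos]
    oc <- open_circuit[pos]

    # loaded branch from node A through the coupling cap into the plant
    z_branch <- z_c + zp
    z_branch[oc] <- Inf
    z_a <- ifelse(oc, z_tank, (z_tank * z_branch) / (z_tank + z_branch))
    gain_a <- z_a / (comps$r_series + z_a)
    gain_b <- gain_a * zp / z_branch
    gain_b[oc] <- gain_a[oc]
    out[pos] <- if (node == "plant") ifelse(oc, gain_a, gain_b) else gain_a
  }
  # DC: the tank inductor shorts node A and the coupling cap blocks node B
  out[!pos] <- 0
  out
}

#' Envelope detector cutoff frequency
#'
#' The diode/RC envelope detector behaves as a first-order low-pass with
#' cutoff \eqn{1/(2\pi R C)}; the default component values give about 1.6 kHz.
#'
#' @param r_env Detector resistance, ohms.
#' @param c_env Detector capacitance, farad.
#' @return Cutoff frequency, Hz.
#' @examples
#' envelope_cutoff(1e6, 100e-12)
#' @export
envelope_cutoff <- function(r_env, c_env) {
  check_scalar_positive(r_env, "r_env")
  check_scalar_positive(c_env, "c_env")
  1 / (2 * pi * r_env * c_env)
}

# Odd-harmonic expansion of the grid: for each sweep point the harmonic
# frequencies and Fourier weights that contribute to the envelope output.
harmonic_grid <- function(freqs, excitation) {
  if (excitation$type == "fundamental") {
    return(list(freq = freqs, weight = rep(4 / pi, length(freqs)),
                point = seq_along(freqs)))
  }
  k_max <- pmax(1, floor(excitation$f_limit / freqs))
  k_odd <- lapply(k_max, function(km) seq(1, km, by = 2))
  n_per <- lengths(k_odd)
  point <- rep.int(seq_along(freqs), n_per)
  k <- unlist(k_odd)
  list(freq = freqs[point] * k, weight = 4 / (pi * k), point = point)
}

#' Simulated amplitude sweep
#'
#' Produces one envelope-detected amplitude-versus-frequency sweep for a given
#' plant state: for each grid point the retained excitation harmonics are
#' propagated through [network_response()], their response magnitudes summed,
#' the diode drop subtracted, and optional Gaussian measurement noise added.
#' The result resembles the band-pass characteristic of the loaded network.
#'
#' @param cfg A [sweep_config()].
#' @param comps A [circuit_components()].
#' @param load A [cole_load()] describing the plant state.
#' @param excitation An [excitation_model()].
#' @param noise_sd Standard deviation of additive Gaussian amplitude noise
#'   (same arbitrary units as the output); 0 gives a deterministic sweep.
#' @param node Measurement node passed to [network_response()].
#' @return Non-negative numeric vector of length `cfg$n_points`.
#' @export
sweep_response <- function(cfg, comps, load, excitation = excitation_model(),
                           noise_sd = 0, node = "plant") {
  stopifnot(inherits(cfg, "sweep_config"))
  check_scalar_nonneg(noise_sd, "noise_sd")
  freqs <- sweep_frequencies(cfg)
  hg <- harmonic_grid(freqs, excitation)
  zp <- plant_impedance(load, hg$freq)
  g <- Mod(network_response(hg$freq, comps, zp, node = node))
  amp <- as.numeric(rowsum(g * hg$weight, hg$point))
  amp <- pmax(0, amp - comps$v_diode)
  if (noise_sd > 0) {
    amp <- pmax(0, amp + stats::rnorm(length(amp), 0, noise_sd))
  }
  amp
}
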