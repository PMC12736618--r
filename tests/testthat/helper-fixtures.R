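# Shared fixtures: small, fast configurations used across test files.

tiny_acq <- function(sweeps = 4, n_freq = 12) {
  acquisition_config(
    interval = 1, sweeps_per_burst = sweeps,
    sweep = sweep_config(f_start = 20e3, f_stop = 20e3 + (n_freq - 1) * 1e3)
  )
}

tiny_dataset <- function(total = 30, sweeps = 4, n_freq = 12, seed = 99,
                         drift_sd = 0, noise_sd = 0.02, min_phase = 10,
                         max_phase = 10) {
  sch <- generate_schedule(total, min_phase, max_phase, seed = seed)
  prof <- default_plant_profile(drift_sd = drift_sd, noise_sd = noise_sd)
  ds <- generate_dataset(sch, prof, tiny_acq(sweeps, n_freq), seed = seed + 1)
  list(schedule = sch, profile = prof, ds = ds)
}

# Brute-force oracle for the circuit gain: assemble the full 2-node
# admittance matrix and solve the complex linear system, independently of
# the closed-form divider used by network_response().
oracle_gain <- function(freq, comps, z_plant, node = "plant") {
  w <- 2 * pi * freq
  jw <- complex(real = 0, imaginary = w)
  y_rs <- 1 / comps$r_series
  y_tank <- 1 / (jw * comps$l_tank) + jw * comps$c_tank + 1 / comps$r_damp
  y_c <- jw * comps$c_couple
  y_p <- 1 / z_plant
  A <- matrix(c(y_rs + y_tank + y_c, -y_c,
                -y_c, y_c + y_p), 2, 2, byrow = TRUE)
  b <- c(y_rs, 0 + 0i)
  v <- solve(A, b)
  if (node == "plant") v[2] else v[1]
}

# A minimal linear model exposing the attribution interface: F(X) = sum(W*X) + b.
linear_attr_model <- function(T_, F_, seed = 1) {
  set.seed(seed)
  structure(list(W = matrix(rnorm(T_ * F_), T_, F_), b = rnorm(1)),
            class = "linear_attr_model")
}

model_input_gradient.linear_attr_model <- function(model, X) {
  B <- dim(X)[1]
  value <- vapply(seq_len(B), function(b) sum(model$W * X[b, , ]) + model$b, 0)
  grad <- array(0, dim(X))
  for (b in seq_len(B)) grad[b, , ] <- model$W
  list(value = value, grad = grad)
}

# make the S3 method visible to the generic from the package namespace
registerS3method("model_input_gradient", "linear_attr_model",
                 model_input_gradient.linear_attr_model,
                 envir = asNamespace("plantimp"))
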