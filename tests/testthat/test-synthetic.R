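test_that("generated schedules alternate, respect bounds, and reproduce", {
  s <- generate_schedule(240, 60, 60, initial_state = "dark", seed = 5)
  expect_equal(s$state, c("dark", "light", "dark", "light"))
  expect_equal(s$duration, rep(60, 4))
  expect_equal(sum(s$duration), 240)

  s2 <- generate_schedule(1440, 60, 180, seed = 7)
  expect_equal(sum(s2$duration), 1440)
  expect_true(all(head(s2$duration, -1) >= 60 & head(s2$duration, -1) <= 180))
  expect_true(all(s2$state[-1] != head(s2$state, -1)))
  expect_identical(s2, generate_schedule(1440, 60, 180, seed = 7))

  expect_error(generate_schedule(100, 50, 40), class = "plantimp_error_validation")
})

test_that("plant state relaxes exponentially toward state targets", {
  prof <- default_plant_profile(drift_sd = 0)
  sch <- light_schedule(c("dark", "light"), c(60, 60))

  # near-zero lag: trajectory is the per-state step function
  fast <- plant_profile(prof$dark_target, prof$light_target, tau_resp = 1e-6,
                        drift_sd = 0)
  tr <- simulate_plant_state(sch, fast, dt = 1)
  expect_equal(tr$r0[tr$state == "dark"][-1],
               rep(prof$dark_target$r0, sum(tr$state == "dark") - 1))
  expect_equal(tr$r0[tr$state == "light"][-1],
               rep(prof$light_target$r0, sum(tr$state == "light") - 1))

  # constant state: within 1% of target after 5 tau_resp
  const <- light_schedule("light", 60)
  tr2 <- simulate_plant_state(const, prof, dt = 1)
  after <- tr2[tr2$t >= 5 * prof$tau_resp, ]
  expect_true(all(abs(after$r0 - prof$light_target$r0) <=
                    0.01 * abs(prof$dark_target$r0 - prof$light_target$r0) +
                    0.01 * prof$light_target$r0))

  # determinism under a seed, with drift on
  drifty <- default_plant_profile(drift_sd = 0.01)
  expect_identical(simulate_plant_state(sch, drifty, seed = 3),
                   simulate_plant_state(sch, drifty, seed = 3))
})

test_that("generated datasets have burst shape, matching labels, and reproduce", {
  sch <- generate_schedule(120, 30, 30, seed = 11)
  prof <- default_plant_profile(drift_sd = 0)
  acq <- tiny_acq(sweeps = 5, n_freq = 8)
  ds <- generate_dataset(sch, prof, acq, seed = 12)

  expect_equal(dim(ds$data), c(120, 5, 8))
  expect_equal(ds$labels, schedule_state_at(sch, ds$timestamps))
  expect_true(all(diff(ds$timestamps) > 0))
  expect_identical(ds, generate_dataset(sch, prof, acq, seed = 12))

  # zero noise, zero drift, constant state: all sweeps identical
  quiet <- default_plant_profile(drift_sd = 0, noise_sd = 0)
  const <- light_schedule("dark", 10)
  ds0 <- generate_dataset(const, quiet, acq, seed = 1)
  for (i in c(2, 10)) {
    expect_identical(ds0$data[i, 1, ], ds0$data[i, 5, ])
  }
  expect_identical(ds0$data[5, 1, ], ds0$data[10, 1, ])
})

test_that("default burst matches the acquisition format (100 x 230)", {
  sch <- light_schedule(c("dark", "light"), c(2, 1))
  ds <- generate_dataset(sch, default_plant_profile(), acquisition_config(),
                         seed = 2)
  expect_equal(dim(ds$data), c(3, 100, 230))
})

test_that("variant profiles shift parameters but preserve response direction", {
  base <- default_plant_profile()
  expect_identical(make_variant_profile(base, 0, seed = 1), base)

  v <- make_variant_profile(base, 0.3, seed = 11)
  expect_false(identical(v$dark_target$r0, base$dark_target$r0))
  for (nm in c("r0", "r_inf", "tau", "alpha")) {
    expect_equal(unname(sign(v$light_target[[nm]] - v$dark_target[[nm]])),
                 sign(base$light_target[[nm]] - base$dark_target[[nm]]),
                 label = nm)
  }
  expect_identical(make_variant_profile(base, 0.3, seed = 11),
                   make_variant_profile(base, 0.3, seed = 11))
  v2 <- make_variant_profile(base, 0.3, seed = 12)
  expect_false(v2$dark_target$r0 == v$dark_target$r0)
  expect_true(v$dark_target$alpha <= 1 && v$light_target$alpha <= 1)
})

test_that("mean sweep separation grows with the light effect size", {
  cfg <- sweep_config()
  comps <- circuit_components()
  gaps <- vapply(c(0.1, 0.3, 0.5), function(eff) {
    p <- default_plant_profile(r0_effect = eff)
    max(abs(sweep_response(cfg, comps, p$dark_target) -
              sweep_response(cfg, comps, p$light_target)))
  }, 0)
  expect_gt(gaps[1], 0)
  expect_true(all(diff(gaps) > 0))
})

test_that("acquisition invariants reject impossible bursts", {
  expect_error(acquisition_config(sweeps_per_burst = 0),
               class = "plantimp_error_validation")
  # 300 sweeps x 230 points x 1 ms = 69 s > 1 min interval
  expect_error(acquisition_config(interval = 1, sweeps_per_burst = 300),
               class = "plantimp_error_validation")
})
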