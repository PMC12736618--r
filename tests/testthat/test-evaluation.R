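test_that("per-cycle accuracy counts phases exactly", {
  sch <- light_schedule(c("dark", "light"), c(10, 10))
  preds <- tibble::tibble(
    timestamp = 0:19,
    predicted = c(rep("dark", 10), rep("light", 7), "dark", "dark", "dark")
  )
  rep_ <- per_cycle_accuracy(preds, sch)
  expect_equal(rep_$n, c(10L, 10L))
  expect_equal(rep_$accuracy, c(1.0, 0.7))
  expect_equal(overall_accuracy(rep_),
               sum(rep_$n_correct) / sum(rep_$n))
  expect_equal(overall_accuracy(rep_),
               sum(rep_$accuracy * rep_$n) / sum(rep_$n))

  all_right <- tibble::tibble(timestamp = 0:19,
                              predicted = schedule_state_at(sch, 0:19))
  expect_true(all(per_cycle_accuracy(all_right, sch)$accuracy == 1))

  outside <- tibble::tibble(timestamp = c(5, 25), predicted = c("dark", "dark"))
  expect_error(per_cycle_accuracy(outside, sch),
               class = "plantimp_error_validation")
})

test_that("detection delay finds the first stable run after each switch", {
  sch <- light_schedule(c("dark", "light", "dark"), c(20, 20, 20))
  truth <- schedule_state_at(sch, 0:59)

  instant <- tibble::tibble(timestamp = 0:59, predicted = truth)
  d0 <- detection_delay(instant, sch)
  expect_equal(d0$delay_min, c(0, 0))
  expect_equal(d0$direction, c("light", "dark"))

  # flip 7 minutes late after the first switch only
  late <- truth
  late[21:27] <- "dark"
  d7 <- detection_delay(tibble::tibble(timestamp = 0:59, predicted = late), sch)
  expect_equal(d7$delay_min[1], 7)
  expect_equal(d7$delay_min[2], 0)

  # never flips inside the second phase -> sentinel
  stuck <- truth
  stuck[21:40] <- "dark"
  ds <- detection_delay(tibble::tibble(timestamp = 0:59, predicted = stuck), sch)
  expect_true(is.na(ds$delay_min[1]))

  # flicker shorter than stable_run does not count
  flick <- truth
  flick[21:40] <- "dark"
  flick[25:26] <- "light"  # 2-sample blip < stable_run = 3
  df <- detection_delay(tibble::tibble(timestamp = 0:59, predicted = flick),
                        sch, stable_run = 3)
  expect_true(is.na(df$delay_min[1]))
  expect_true(all(df$delay_min >= 0, na.rm = TRUE))
})

test_that("delay is bounded by the phase length when defined", {
  set.seed(71)
  sch <- generate_schedule(300, 30, 60)
  preds <- tibble::tibble(timestamp = 0:299,
                          predicted = sample(c("dark", "light"), 300, TRUE))
  d <- detection_delay(preds, sch)
  ph_len <- diff(c(switch_times(sch), max(sch$t_end)))
  ok <- !is.na(d$delay_min)
  expect_true(all(d$delay_min[ok] >= 0))
  expect_true(all(d$delay_min[ok] < ph_len[ok]))
})

test_that("a scaled-down experiment bundle is complete and reproducible", {
  cfg <- experiment_config(
    total_minutes = 240, min_phase = 25, max_phase = 45,
    profile = default_plant_profile(),
    acq = tiny_acq(sweeps = 4, n_freq = 16),
    training = training_config(max_epochs = 6),
    cross_plant = FALSE, attribution_m = 10
  )
  b1 <- run_experiment(cfg, seed = 5)
  expect_true(all(c("metrics", "model", "history", "cycle_report",
                    "delay_report", "attribution", "importance",
                    "top_features", "band_report") %in% names(b1)))
  expect_equal(dim(b1$attribution$values), c(4, 16))
  expect_equal(nrow(b1$top_features), 10)
  expect_true(b1$metrics$acc_A_val >= 0 && b1$metrics$acc_A_val <= 1)
  expect_equal(sum(b1$cycle_report$n),
               nrow(b1$predictions))

  b2 <- run_experiment(cfg, seed = 5)
  expect_identical(b1$metrics, b2$metrics)
  expect_identical(as.data.frame(b1$cycle_report), as.data.frame(b2$cycle_report))
})

test_that("experiment artifacts are written to the output directory", {
  dir <- withr::local_tempdir()
  cfg <- experiment_config(
    total_minutes = 150, min_phase = 25, max_phase = 40,
    acq = tiny_acq(sweeps = 3, n_freq = 12),
    training = training_config(max_epochs = 3),
    cross_plant = FALSE, attribution_m = 5
  )
  run_experiment(cfg, seed = 6, out_dir = dir)
  for (f in c("history.csv", "cycle_report.csv", "delay_report.csv",
              "metrics.json", "heatmap.csv", "heatmap.png", "trends.csv",
              "trends.png", "top_features.csv", "band_importance.csv",
              "model.rds", "model.json")) {
    expect_true(file.exists(file.path(dir, f)), info = f)
  }
})

test_that("accuracy rises with the light effect size", {
  accs <- vapply(c(0.1, 0.3, 0.5), function(eff) {
    meds <- vapply(1:2, function(s) {
      cfg <- experiment_config(
        total_minutes = 300, min_phase = 25, max_phase = 45,
        profile = default_plant_profile(r0_effect = eff, tau_effect = eff * 2 / 3,
                                        noise_sd = 0.12),
        acq = tiny_acq(sweeps = 3, n_freq = 20),
        training = training_config(max_epochs = 12),
        cross_plant = FALSE, attribution_m = 2
      )
      run_experiment(cfg, seed = s)$metrics$acc_A_val
    }, 0)
    median(meds)
  }, 0)
  expect_true(accs[3] >= accs[1])
})
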