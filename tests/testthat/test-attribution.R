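test_that("integrated gradients are exact for linear models and zero at baseline", {
  lin <- linear_attr_model(5, 7, seed = 61)
  set.seed(62)
  x <- matrix(rnorm(35), 5, 7)
  bl <- matrix(rnorm(35), 5, 7)
  for (m in c(1, 3, 50)) {
    ig <- integrated_gradients(lin, x, bl, m = m)
    expect_equal(ig$values, lin$W * (x - bl), tolerance = 1e-12)
  }
  ig0 <- integrated_gradients(lin, x, x, m = 10)
  expect_true(all(ig0$values == 0))
  expect_error(integrated_gradients(lin, x, matrix(0, 2, 2)),
               class = "plantimp_error_validation")
})

test_that("completeness holds within 2% at m = 200 on a trained toy model", {
  part <- local({
    set.seed(63)
    y <- rep(c(0L, 1L), 8)
    x <- array(rnorm(16 * 5 * 9, sd = 0.4), dim = c(16, 5, 9))
    for (i in 1:16) x[i, , ] <- x[i, , ] + (y[i] - 0.5)
    plantimp:::new_std_partition(x, y, 0:15, ifelse(y == 1, "light", "dark"))
  })
  mod <- build_model(model_config(lstm_units = 4, dense_units = 3, dropout = 0),
                     c(5, 9), seed = 64)
  mod <- train(mod, part, part, training_config(seed = 65, max_epochs = 8))
  for (i in c(1, 2)) {
    x <- matrix(part$x[i, , ], 5, 9)
    ig <- integrated_gradients(mod, x, m = 200)
    delta <- ig$f_x - ig$f_baseline
    expect_lte(abs(sum(ig$values) - delta), 0.02 * abs(delta) + 1e-4)
  }
})

test_that("attributions converge in m", {
  mod <- build_model(model_config(lstm_units = 4, dense_units = 3, dropout = 0),
                     c(5, 9), seed = 66)
  set.seed(67)
  x <- matrix(rnorm(45), 5, 9)
  a50 <- integrated_gradients(mod, x, m = 50)$values
  a500 <- integrated_gradients(mod, x, m = 500)$values
  expect_lt(norm(a50 - a500, "F") / norm(a500, "F"), 0.05)
})

test_that("feature importance reduces columns and conserves totals", {
  vals <- matrix(1, 100, 230)
  attr_mat <- structure(list(values = vals, f_x = 1, f_baseline = 0, m = 50,
                             sample_id = NA), class = "attribution_matrix")
  iv <- feature_importance(attr_mat)
  expect_equal(nrow(iv), 230)
  expect_true(all(iv$importance == 100))

  set.seed(68)
  vals <- matrix(rnorm(60), 10, 6)
  am <- structure(list(values = vals, f_x = 0, f_baseline = 0, m = 1,
                       sample_id = NA), class = "attribution_matrix")
  iv2 <- feature_importance(am, frequencies = 1:6)
  expect_equal(sum(iv2$importance), sum(vals))

  vals3 <- matrix(0, 10, 8); vals3[3, 7] <- 2.5
  am3 <- structure(list(values = vals3, f_x = 0, f_baseline = 0, m = 1,
                        sample_id = NA), class = "attribution_matrix")
  iv3 <- feature_importance(am3, frequencies = 1:8)
  expect_equal(iv3$importance, c(rep(0, 6), 2.5, 0))
})

test_that("top-k ranking is by |importance| with low-index tie-break", {
  iv <- structure(tibble::tibble(index = 1:12, freq_hz = (1:12) * 1e3,
                                 importance = c(0, 0, 0, 0, 3, 0, -1, 0, 3, 0, 0.5, 0)),
                  class = c("importance_vector", class(tibble::tibble())))
  top <- top_k_features(iv, k = 4)
  expect_equal(top$index, c(5, 9, 7, 11))  # ties at |3| broken toward 5
  expect_equal(nrow(top_k_features(iv, k = 10)), 10)
  expect_setequal(top_k_features(iv, k = 12)$index, 1:12)
  expect_error(top_k_features(iv, k = 13), class = "plantimp_error_validation")
})

test_that("band importance aggregates half-open bands and conserves totals", {
  set.seed(69)
  freqs <- sweep_frequencies(sweep_config())
  iv <- structure(tibble::tibble(index = 1:230, freq_hz = freqs,
                                 importance = rnorm(230)),
                  class = c("importance_vector", class(tibble::tibble())))
  rep_default <- band_importance(iv)
  expect_equal(rep_default$low_hz, c(0, 190e3))
  expect_equal(rep_default$n_bins, c(10L, 30L))  # 20..29 kHz overlap; 190..219

  expect_equal(band_importance(iv, list(c(300e3, 400e3)))$importance, 0)

  partition <- band_importance(iv, list(c(20e3, 100e3), c(100e3, 250e3)))
  expect_equal(sum(partition$importance), sum(abs(iv$importance)))
  expect_error(band_importance(iv, list(c(5, 1))),
               class = "plantimp_error_validation")
})

test_that("heatmap and trends exports write full-size artifacts", {
  dir <- withr::local_tempdir()
  vals <- matrix(rnorm(100 * 230), 100, 230)
  am <- structure(list(values = vals, f_x = 0.7, f_baseline = 0.4, m = 50,
                       sample_id = 1), class = "attribution_matrix")
  csv <- file.path(dir, "heat.csv")
  export_heatmap(am, csv)
  back <- as.matrix(utils::read.csv(csv, header = FALSE))
  expect_equal(dim(back), c(100, 230))
  expect_equal(unname(back), vals, tolerance = 1e-6)

  fx <- tiny_dataset(total = 20, sweeps = 3, n_freq = 8)
  preds <- tibble::tibble(timestamp = fx$ds$timestamps,
                          predicted = fx$ds$labels)
  tcsv <- file.path(dir, "trends.csv")
  trend <- export_trends(fx$ds, 1:3, preds, fx$schedule, tcsv)
  expect_equal(nrow(utils::read.csv(tcsv)), 20)
  expect_equal(trend$predicted, fx$ds$labels)
})
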