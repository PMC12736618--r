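# Small architectures keep these tests fast; dims are arbitrary but nontrivial.

toy_partition <- function(n = 20, T_ = 6, F_ = 10, gap = 4, seed = 55) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- array(rnorm(n * T_ * F_, sd = 0.3), dim = c(n, T_, F_))
  for (i in seq_len(n)) x[i, , ] <- x[i, , ] + ifelse(y[i] == 1, gap, -gap) / 2
  plantimp:::new_std_partition(x, y, seq_len(n) - 1,
                               ifelse(y == 1, "light", "dark"))
}

test_that("analytic gradients match finite differences everywhere", {
  set.seed(42)
  cfg <- model_config(lstm_units = 3, dense_units = 2, l2_factor = 0,
                      dropout = 0, attention_dim = 4)
  B <- 2; T_ <- 4; F_ <- 5
  params <- plantimp:::nn_init_params(cfg, c(T_, F_))
  X <- array(rnorm(B * T_ * F_), dim = c(B, T_, F_))
  y <- c(0, 1)
  lossfun <- function(pr, XX) plantimp:::bce_loss(plantimp:::nn_forward(pr, XX)$p, y)

  fw <- plantimp:::nn_forward(params, X, want_cache = TRUE)
  bw <- plantimp:::nn_backward(params, fw$cache, (fw$p - y) / B, want_dx = TRUE)
  eps <- 1e-6
  for (nm in names(params)) {
    for (j in sample(length(params[[nm]]), min(6, length(params[[nm]])))) {
      pp <- params; pp[[nm]][j] <- pp[[nm]][j] + eps
      pm <- params; pm[[nm]][j] <- pm[[nm]][j] - eps
      num <- (lossfun(pp, X) - lossfun(pm, X)) / (2 * eps)
      expect_equal(bw$grads[[nm]][j], num, tolerance = 1e-4,
                   info = sprintf("%s[%d]", nm, j))
    }
  }
  for (j in sample(length(X), 10)) {
    Xp <- X; Xp[j] <- Xp[j] + eps
    Xm <- X; Xm[j] <- Xm[j] - eps
    num <- (lossfun(params, Xp) - lossfun(params, Xm)) / (2 * eps)
    expect_equal(bw$dX[j], num, tolerance = 1e-4)
  }
})

test_that("every trainable tensor receives a nonzero gradient", {
  set.seed(7)
  cfg <- model_config(lstm_units = 4, dense_units = 3, dropout = 0)
  params <- plantimp:::nn_init_params(cfg, c(5, 8))
  B <- 16  # large enough that the ReLU layer is active somewhere
  X <- array(rnorm(B * 5 * 8, sd = 2), dim = c(B, 5, 8))
  y <- rep(c(1, 0), B / 2)
  fw <- plantimp:::nn_forward(params, X, want_cache = TRUE)
  bw <- plantimp:::nn_backward(params, fw$cache, (fw$p - y) / B)
  for (nm in names(params)) {
    expect_gt(max(abs(bw$grads[[nm]])), 0, label = nm)
  }
})

test_that("architecture invariants: sequence width, attention sums, sigmoid range", {
  mod <- build_model(model_config(), c(100, 230), seed = 1)
  set.seed(2)
  X <- array(rnorm(3 * 100 * 230), dim = c(3, 100, 230))
  fw <- plantimp:::nn_forward(mod$params, X, want_cache = TRUE)
  # recurrent output is lstm_units-wide per timestep
  expect_equal(dim(fw$cache$Hd[[100]]), c(3, 16))
  expect_equal(rowSums(fw$alpha), rep(1, 3), tolerance = 1e-6)
  expect_true(all(fw$p > 0 & fw$p < 1))
  aw <- attention_weights(mod, X)
  expect_equal(dim(aw), c(3, 100))

  expect_error(build_model(model_config(), c(0, 10)),
               class = "plantimp_error_validation")
  expect_error(predict(mod, array(0, dim = c(1, 10, 10))),
               class = "plantimp_error_validation")
})

test_that("the classifier overfits a separable toy set and predicts it", {
  part <- toy_partition()
  cfg <- model_config(lstm_units = 8, dense_units = 8, dropout = 0)
  mod <- build_model(cfg, dim(part$x)[2:3], seed = 3)
  mod <- train(mod, part, part, training_config(seed = 4, batch_size = 10))
  h <- tidy(mod)
  expect_lte(attr(h, "stopped_epoch"), 100)
  expect_equal(max(h$accuracy), 1)
  preds <- predict(mod, part)
  expect_equal(preds$predicted, part$labels)
  expect_true(all(preds$prob > 0 & preds$prob < 1))
})

test_that("early stopping halts after patience+1 epochs on a flat loss", {
  part <- toy_partition(n = 8)
  cfg <- model_config(lstm_units = 3, dense_units = 2, dropout = 0)
  mod <- build_model(cfg, dim(part$x)[2:3], seed = 5)
  # zero learning rate: weights frozen, validation loss exactly flat
  tcfg <- training_config(learning_rate = 0, fine_tune_lr = 0,
                          early_stop_patience = 4, seed = 6)
  mod <- train(mod, part, part, tcfg)
  expect_equal(attr(tidy(mod), "stopped_epoch"), 5L)
  expect_equal(attr(tidy(mod), "best_epoch"), 1L)
})

test_that("training is reproducible under a fixed seed", {
  part <- toy_partition(n = 12)
  cfg <- model_config(lstm_units = 4, dense_units = 3)
  run <- function() {
    m <- build_model(cfg, dim(part$x)[2:3], seed = 8)
    train(m, part, part, training_config(seed = 9, max_epochs = 5))
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$history$val_loss, m2$history$val_loss)
  expect_identical(m1$params, m2$params)
})

test_that("probability at the threshold maps to light and duplicates agree", {
  mod <- build_model(model_config(dropout = 0), c(4, 6), seed = 10)
  x <- array(rnorm(2 * 4 * 6), dim = c(2, 4, 6))
  x[2, , ] <- x[1, , ]
  pr <- predict(mod, x)
  expect_identical(pr$prob[1], pr$prob[2])
  pr2 <- predict(mod, x, threshold = pr$prob[1])
  expect_equal(pr2$predicted[1], "light")  # prob >= threshold is light
})

test_that("fine-tuning with zero epochs is the identity and lr is recorded", {
  part <- toy_partition(n = 12)
  cfg <- model_config(lstm_units = 4, dense_units = 3, dropout = 0)
  mod <- build_model(cfg, dim(part$x)[2:3], seed = 11)
  mod <- train(mod, part, part, training_config(seed = 12, max_epochs = 3))

  frozen <- fine_tune(mod, part, part, training_config(max_epochs = 0))
  expect_identical(frozen$params, mod$params)

  tuned <- fine_tune(mod, part, part,
                     training_config(seed = 13, max_epochs = 3))
  expect_equal(unique(tidy(tuned)$lr), 5e-4)
})

test_that("tidy and glance summarize the fit", {
  part <- toy_partition(n = 12)
  mod <- build_model(model_config(lstm_units = 4, dense_units = 3),
                     dim(part$x)[2:3], seed = 14)
  expect_error(glance(mod), class = "plantimp_error_validation")
  mod <- train(mod, part, part, training_config(seed = 15, max_epochs = 4))
  h <- tidy(mod)
  expect_true(all(c("epoch", "loss", "accuracy", "val_loss", "val_accuracy",
                    "lr") %in% names(h)))
  g <- glance(mod)
  expect_equal(nrow(g), 1)
  expect_equal(g$epochs, attr(h, "stopped_epoch"))
})

test_that("model weights roundtrip through save/load", {
  dir <- withr::local_tempdir()
  mod <- build_model(model_config(lstm_units = 3, dense_units = 2), c(4, 5),
                     seed = 16)
  save_model(mod, file.path(dir, "m"))
  expect_true(file.exists(file.path(dir, "m.json")))
  back <- load_model(file.path(dir, "m"))
  expect_identical(back$params, mod$params)
})
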