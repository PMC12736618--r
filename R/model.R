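#' Classifier architecture configuration
#'
#' LSTM layer (16 units, returning the full sequence) -> additive attention
#' pooling over timesteps -> dense ReLU layer (16 units, L2-regularized
#' kernel) -> single sigmoid output. Dropout is applied to the LSTM sequence
#' output and to the dense hidden activations during training.
#'
#' @param lstm_units LSTM hidden size.
#' @param dense_units Hidden dense layer size.
#' @param l2_factor L2 penalty on the hidden dense kernel.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param attention_dim Width of the attention scoring space (defaults to
#'   `lstm_units`).
#' @return An object of class `model_config`.
#' @export
model_config <- function(lstm_units = 16, dense_units = 16, l2_factor = 1e-3,
                         dropout = 0.5, attention_dim = lstm_units) {
  for (nm in c("lstm_units", "dense_units", "attention_dim")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != floor(v)) {
      abort_validation(sprintf("`%s` must be a positive integer", nm))
    }
  }
  check_scalar_nonneg(l2_factor, "l2_factor")
  if (dropout < 0 || dropout >= 1) abort_validation("`dropout` must be in [0, 1)")
  structure(list(lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units),
                 l2_factor = l2_factor, dropout = dropout,
                 attention_dim = as.integer(attention_dim)),
            class = "model_config")
}

#' Training protocol configuration
#'
#' Adam with binary cross-entropy, early stopping on validation loss, and
#' learning-rate reduction on validation-loss plateau.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param fine_tune_lr Reduced learning rate used by [fine_tune()]; must be
#'   below `learning_rate`.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before training stops.
#' @param plateau_factor Multiplier applied to the learning rate on plateau.
#' @param plateau_patience Plateau length (epochs) triggering the reduction.
#' @param min_lr Floor for the reduced learning rate.
#' @param seed Optional integer seed for weight init, shuffling and dropout.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-3, fine_tune_lr = 5e-4,
                            batch_size = 32, max_epochs = 100,
                            early_stop_patience = 10, plateau_factor = 0.5,
                            plateau_patience = 5, min_lr = 1e-5, seed = NULL) {
  check_scalar_nonneg(learning_rate, "learning_rate")
  check_scalar_nonneg(fine_tune_lr, "fine_tune_lr")
  # lr = 0 is a degenerate no-update mode useful for callback testing
  if (learning_rate > 0 && fine_tune_lr >= learning_rate) {
    abort_validation("`fine_tune_lr` must be below `learning_rate`")
  }
  structure(list(learning_rate = learning_rate, fine_tune_lr = fine_tune_lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 min_lr = min_lr, seed = seed),
            class = "training_config")
}

#' Build an untrained classifier
#'
#' @param cfg A [model_config()].
#' @param input_shape Integer pair `(timesteps, features)` — the burst shape,
#'   e.g. `c(100, 230)`.
#' @param seed Optional seed for weight initialization.
#' @return An object of class `plant_classifier`.
#' @export
build_model <- function(cfg = model_config(), input_shape = c(100L, 230L),
                        seed = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  if (length(input_shape) != 2L || any(input_shape < 1)) {
    abort_validation("`input_shape` must be (timesteps, features), both >= 1")
  }
  input_shape <- as.integer(input_shape)
  params <- with_seed(seed, nn_init_params(cfg, input_shape))
  structure(list(cfg = cfg, input_shape = input_shape, params = params,
                 history = NULL),
            class = "plant_classifier")
}

#' @export
print.plant_classifier <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "<plant_classifier> input (%d, %d) | LSTM %d + attention %d + dense %d | %d parameters%s\n",
    x$input_shape[1], x$input_shape[2], x$cfg$lstm_units, x$cfg$attention_dim,
    x$cfg$dense_units, np,
    if (is.null(x$history)) " (untrained)" else sprintf(" | trained %d epochs",
                                                       nrow(x$history))))
  invisible(x)
}

partition_x <- function(part) {
  if (inherits(part, "std_partition")) part$x
  else if (is.array(part) && length(dim(part)) == 3L) part
  else abort_validation("expected a std_partition or a 3-d array")
}

check_input_shape <- function(model, x) {
  d <- dim(x)
  if (d[2] != model$input_shape[1] || d[3] != model$input_shape[2]) {
    abort_validation(sprintf(
      "input shape (%d, %d) does not match model input (%d, %d)",
      d[2], d[3], model$input_shape[1], model$input_shape[2]))
  }
}

eval_partition <- function(params, part, batch = 256L) {
  x <- partition_x(part)
  n <- dim(x)[1]
  p <- numeric(n)
  for (s in seq(1, n, by = batch)) {
    idx <- s:min(s + batch - 1, n)
    p[idx] <- nn_forward(params, x[idx, , , drop = FALSE])$p
  }
  p
}

run_training <- function(model, train, val, tcfg, lr0, plateau_patience) {
  x <- partition_x(train); y <- train$y
  check_input_shape(model, x)
  if (dim(x)[1] == 0 || dim(partition_x(val))[1] == 0) {
    abort_validation("train and validation partitions must be non-empty")
  }
  params <- model$params
  cfg <- model$cfg
  state <- adam_init(params)
  lr <- lr0
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  wait_stop <- 0L; wait_plateau <- 0L
  hist <- list()
  n <- dim(x)[1]

  epoch <- 0L
  while (epoch < tcfg$max_epochs) {
    epoch <- epoch + 1L
    idx <- sample.int(n)
    batch_losses <- c(); batch_correct <- 0L
    for (s in seq(1, n, by = tcfg$batch_size)) {
      bi <- idx[s:min(s + tcfg$batch_size - 1, n)]
      xb <- x[bi, , , drop = FALSE]; yb <- y[bi]
      masks <- nn_dropout_masks(length(bi), cfg)
      fw <- nn_forward(params, xb, masks = masks, want_cache = TRUE)
      loss <- bce_loss(fw$p, yb) + cfg$l2_factor * sum(params$W1^2)
      dz2 <- (fw$p - yb) / length(bi)
      bw <- nn_backward(params, fw$cache, dz2)
      bw$grads$W1 <- bw$grads$W1 + 2 * cfg$l2_factor * params$W1
      upd <- adam_step(params, bw$grads, state, lr)
      params <- upd$params; state <- upd$state
      batch_losses <- c(batch_losses, loss)
      batch_correct <- batch_correct + sum((fw$p >= 0.5) == (yb == 1))
    }
    p_val <- eval_partition(params, val)
    val_loss <- bce_loss(p_val, val$y) + cfg$l2_factor * sum(params$W1^2)
    val_acc <- mean((p_val >= 0.5) == (val$y == 1))
    hist[[epoch]] <- tibble(epoch = epoch, loss = mean(batch_losses),
                            accuracy = batch_correct / n,
                            val_loss = val_loss, val_accuracy = val_acc,
                            lr = lr)

    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best_params <- params; best_epoch <- epoch
      wait_stop <- 0L; wait_plateau <- 0L
    } else {
      wait_stop <- wait_stop + 1L
      wait_plateau <- wait_plateau + 1L
      if (wait_plateau >= plateau_patience && lr > tcfg$min_lr) {
        lr <- max(tcfg$min_lr, lr * tcfg$plateau_factor)
        wait_plateau <- 0L
      }
      if (wait_stop >= tcfg$early_stop_patience) break
    }
  }

  history <- dplyr::bind_rows(hist)
  attr(history, "stopped_epoch") <- epoch
  attr(history, "best_epoch") <- best_epoch
  class(history) <- c("training_history", class(history))
  model$params <- best_params
  model$history <- history
  model
}

#' Train the classifier
#'
#' Mini-batch Adam on binary cross-entropy over the standardized training
#' partition, with per-epoch validation. Early stopping halts training after
#' `early_stop_patience` epochs without validation-loss improvement and the
#' best-validation-loss weights are restored; the learning rate is halved
#' after `plateau_patience` stagnant epochs (not below `min_lr`). With a
#' fixed `tcfg$seed` the run is fully reproducible.
#'
#' @param model A [build_model()] classifier.
#' @param train,val `std_partition`s from [standardize()].
#' @param tcfg A [training_config()].
#' @return The trained `plant_classifier`; `$history` holds the per-epoch
#'   `training_history` tibble (attributes `stopped_epoch`, `best_epoch`).
#' @export
train <- function(model, train, val, tcfg = training_config()) {
  stopifnot(inherits(model, "plant_classifier"), inherits(tcfg, "training_config"))
  with_seed(tcfg$seed,
            run_training(model, train, val, tcfg, tcfg$learning_rate,
                         tcfg$plateau_patience))
}

#' Fine-tune a trained classifier on a new plant
#'
#' Continues training all weights (nothing frozen) on data from a different
#' specimen at the reduced learning rate `tcfg$fine_tune_lr`, with a fresh
#' optimizer state and the same callback machinery (plateau patience
#' tightened to 3). With `tcfg$max_epochs = 0` the model is returned
#' unchanged.
#'
#' @inheritParams train
#' @param train,val Standardized partitions of the new plant's data (fit with
#'   their own training statistics).
#' @return The fine-tuned `plant_classifier`.
#' @export
fine_tune <- function(model, train, val, tcfg = training_config()) {
  stopifnot(inherits(model, "plant_classifier"), inherits(tcfg, "training_config"))
  if (tcfg$max_epochs == 0) return(model)
  with_seed(tcfg$seed,
            run_training(model, train, val, tcfg, tcfg$fine_tune_lr,
                         plateau_patience = 3L))
}

#' Predict light/dark state probabilities
#'
#' @param object A trained `plant_classifier`.
#' @param newdata A `std_partition` or a `(samples x timesteps x features)`
#'   array in standardized units.
#' @param threshold Probability threshold; `prob >= threshold` maps to
#'   `"light"`.
#' @param ... Unused.
#' @return A tibble with `timestamp` (if available), `prob` (probability of
#'   light) and `predicted` (`"dark"`/`"light"`).
#' @export
predict.plant_classifier <- function(object, newdata, threshold = 0.5, ...) {
  x <- partition_x(newdata)
  check_input_shape(object, x)
  p <- eval_partition(object$params, newdata)
  out <- tibble(
    timestamp = if (inherits(newdata, "std_partition")) newdata$timestamps
                else NA_real_,
    prob = p,
    predicted = ifelse(p >= threshold, "light", "dark")
  )
  if (inherits(newdata, "std_partition")) out$label <- newdata$labels
  out
}

#' Attention weights for a batch
#'
#' @param model A `plant_classifier`.
#' @param newdata A `std_partition` or 3-d array.
#' @return Matrix `(samples x timesteps)` of attention weights; rows sum to 1.
#' @export
attention_weights <- function(model, newdata) {
  x <- partition_x(newdata)
  check_input_shape(model, x)
  nn_forward(model$params, x)$alpha
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted classifier
#'
#' @param x A trained `plant_classifier`.
#' @param ... Unused.
#' @return The `training_history` tibble: `epoch`, `loss`, `accuracy`,
#'   `val_loss`, `val_accuracy`, `lr`.
#' @method tidy plant_classifier
#' @export
tidy.plant_classifier <- function(x, ...) {
  if (is.null(x$history)) abort_validation("model has not been trained")
  x$history
}

#' One-row summary of a fitted classifier
#'
#' @param x A trained `plant_classifier`.
#' @param ... Unused.
#' @return A one-row tibble: parameter count, epochs run, best epoch, best
#'   validation loss and the validation accuracy at the best epoch.
#' @method glance plant_classifier
#' @export
glance.plant_classifier <- function(x, ...) {
  if (is.null(x$history)) abort_validation("model has not been trained")
  h <- x$history
  be <- attr(h, "best_epoch")
  tibble(
    n_parameters = sum(vapply(x$params, length, 0L)),
    epochs = attr(h, "stopped_epoch"),
    best_epoch = be,
    best_val_loss = if (be >= 1) h$val_loss[be] else NA_real_,
    val_accuracy = if (be >= 1) h$val_accuracy[be] else NA_real_
  )
}

#' Save / load classifier weights
#'
#' Weights and architecture are written as a JSON sidecar (config, shapes)
#' plus an RDS file with the numeric tensors.
#'
#' @param model A `plant_classifier`.
#' @param path Basename; writes `<path>.rds` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "plant_classifier"))
  sidecar <- list(config = unclass(model$cfg),
                  input_shape = model$input_shape,
                  tensors = lapply(model$params, function(p)
                    if (is.matrix(p)) dim(p) else length(p)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  saveRDS(model, paste0(path, ".rds"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  readRDS(paste0(path, ".rds"))
}
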