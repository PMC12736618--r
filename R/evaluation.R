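#' Per-cycle classification accuracy
#'
#' Assigns each prediction to the schedule phase containing its timestamp and
#' reports counts and accuracy per phase (light/dark cycle) plus the overall
#' accuracy.
#'
#' @param predictions Tibble with `timestamp` and `predicted` columns (from
#'   [predict.plant_classifier()]).
#' @param schedule The [light_schedule()] providing ground truth.
#' @return A `cycle_report` tibble: `phase`, `state`, `t_start`, `t_end`,
#'   `n`, `n_correct`, `accuracy`; attribute `overall_accuracy`.
#' @export
per_cycle_accuracy <- function(predictions, schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  t <- predictions$timestamp
  truth <- schedule_state_at(schedule, t)  # errors if outside the span
  phase <- findInterval(t, schedule$t_start)
  correct <- predictions$predicted == truth
  agg <- tibble(phase = phase, correct = correct) |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(n = dplyr::n(), n_correct = sum(.data$correct),
                     .groups = "drop")
  out <- dplyr::left_join(
    tibble(phase = schedule$phase, state = schedule$state,
           t_start = schedule$t_start, t_end = schedule$t_end),
    agg, by = "phase")
  out$n[is.na(out$n)] <- 0L
  out$n_correct[is.na(out$n_correct)] <- 0L
  out$accuracy <- ifelse(out$n > 0, out$n_correct / out$n, NA_real_)
  attr(out, "overall_accuracy") <- sum(out$n_correct) / sum(out$n)
  class(out) <- c("cycle_report", class(out))
  out
}

#' Overall accuracy of a cycle report
#' @param report A `cycle_report`.
#' @return Overall accuracy in `[0, 1]`.
#' @export
overall_accuracy <- function(report) {
  stopifnot(inherits(report, "cycle_report"))
  attr(report, "overall_accuracy")
}

#' Detection delay after each light switch
#'
#' For every internal switch of the schedule, the delay is the time from the
#' switch until the start of the first run of `stable_run` consecutive
#' predictions matching the new state, looking only at samples inside the new
#' phase. `NA` marks phases where no such run occurs before the next switch
#' (detection missed).
#'
#' @param predictions Tibble with `timestamp` and `predicted`; should come
#'   from unfiltered per-minute predictions, otherwise delays shorter than
#'   the transition-filter window are unobservable.
#' @param schedule The [light_schedule()].
#' @param stable_run Consecutive correct predictions required to call a
#'   detection (guards against single-sample flicker).
#' @return A `delay_report` tibble: `switch_time`, `direction`
#'   (state switched to), `delay_min`.
#' @export
detection_delay <- function(predictions, schedule, stable_run = 3) {
  stopifnot(inherits(schedule, "light_schedule"))
  sw <- switch_times(schedule)
  rows <- purrr::map(seq_along(sw), function(i) {
    s <- sw[i]
    new_state <- schedule$state[i + 1]
    phase_end <- schedule$t_end[i + 1]
    sel <- predictions$timestamp >= s & predictions$timestamp < phase_end
    pp <- predictions[sel, ]
    pp <- pp[order(pp$timestamp), ]
    ok <- pp$predicted == new_state
    delay <- NA_real_
    if (length(ok) >= stable_run) {
      runs <- stats::filter(as.numeric(ok), rep(1, stable_run), sides = 1)
      hit <- which(runs == stable_run)[1]
      if (!is.na(hit)) delay <- pp$timestamp[hit - stable_run + 1] - s
    }
    tibble(switch_time = s, direction = new_state, delay_min = delay)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("delay_report", class(out))
  out
}

#' Experiment configuration
#'
#' Bundles every knob of an end-to-end run: schedule generation, plant
#' profile, acquisition, preprocessing, model and training settings, and the
#' cross-plant scenario (train on plant A, evaluate zero-shot on a
#' parameter-shifted plant B, fine-tune on B, re-evaluate).
#'
#' @param total_minutes Simulated span per plant, minutes.
#' @param min_phase,max_phase Phase-duration bounds, minutes.
#' @param profile A [plant_profile()].
#' @param acq An [acquisition_config()].
#' @param comps A [circuit_components()].
#' @param excitation An [excitation_model()].
#' @param filter_window Post-transition removal window, minutes.
#' @param split A [split_spec()].
#' @param model_cfg A [model_config()].
#' @param training A [training_config()].
#' @param cross_plant Run the second-plant scenario?
#' @param variant_shift Log-normal shift of the variant profile.
#' @param variant_seed Seed for drawing the variant profile.
#' @param full_scale Quantization full scale.
#' @param attribution_m Integrated-gradients path steps.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(total_minutes = 2880, min_phase = 60,
                              max_phase = 180,
                              profile = default_plant_profile(),
                              acq = acquisition_config(),
                              comps = circuit_components(),
                              excitation = excitation_model(),
                              filter_window = 10, split = split_spec(),
                              model_cfg = model_config(),
                              training = training_config(),
                              cross_plant = TRUE, variant_shift = 0.3,
                              variant_seed = 11, full_scale = 2,
                              attribution_m = 50) {
  structure(list(total_minutes = total_minutes, min_phase = min_phase,
                 max_phase = max_phase, profile = profile, acq = acq,
                 comps = comps, excitation = excitation,
                 filter_window = filter_window, split = split,
                 model_cfg = model_cfg, training = training,
                 cross_plant = cross_plant, variant_shift = variant_shift,
                 variant_seed = variant_seed, full_scale = full_scale,
                 attribution_m = attribution_m),
            class = "experiment_config")
}

prepare_plant <- function(schedule, profile, config) {
  ds <- generate_dataset(schedule, profile, config$acq, config$comps,
                         config$excitation, full_scale = config$full_scale)
  filtered <- filter_transitions(ds, schedule, config$filter_window)
  parts <- chronological_split(filtered, config$split)
  std <- standardize(parts$train, val = parts$val, test = parts$test)
  list(ds = ds, filtered = filtered, parts = parts, std = std)
}

accuracy_of <- function(preds) mean(preds$predicted == preds$label)

#' Run the end-to-end experiment
#'
#' Simulates plant A under a random light schedule, filters transition
#' samples, splits chronologically, standardizes on the training block,
#' trains the classifier, and evaluates per-cycle accuracy, detection delay
#' and integrated-gradients attribution. With `config$cross_plant` the
#' trained model is then evaluated zero-shot on a parameter-shifted plant B
#' and fine-tuned on B's training block. All randomness derives from `seed`.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed for the whole run.
#' @param out_dir Optional directory; when given, reports (CSV/JSON), plots
#'   (PNG) and model weights are written there.
#' @return A list bundle: `metrics` (tibble with `acc_A_val`, `acc_A_test`,
#'   and in cross-plant mode `acc_B_zero_shot`, `acc_B_finetuned`), `model`,
#'   `history`, `cycle_report`, `delay_report`, `attribution`, `importance`,
#'   `top_features`, `band_report`, `schedule`, plus the plant-B counterparts
#'   when enabled.
#' @export
run_experiment <- function(config = experiment_config(), seed = 1,
                           out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(seed)
  schedule_a <- generate_schedule(config$total_minutes, config$min_phase,
                                  config$max_phase)
  plant_a <- prepare_plant(schedule_a, config$profile, config)

  tcfg <- config$training
  tcfg$seed <- NULL  # RNG stream already seeded for the whole run
  input_shape <- dim(plant_a$std$train$x)[2:3]
  model <- build_model(config$model_cfg, input_shape)
  model <- train(model, plant_a$std$train, plant_a$std$val, tcfg)

  preds_val <- predict(model, plant_a$std$val)
  preds_test <- predict(model, plant_a$std$test)
  acc_a_val <- accuracy_of(preds_val)
  acc_a_test <- accuracy_of(preds_test)

  eval_preds <- dplyr::bind_rows(preds_val, preds_test)
  cycle_rep <- per_cycle_accuracy(eval_preds, schedule_a)

  # delay is measured on unfiltered predictions so sub-window delays show up
  std_all <- standardize(plant_a$parts$train, all = plant_a$ds,
                         stats = plant_a$std$stats)$all
  preds_all <- predict(model, std_all)
  delay_rep <- detection_delay(preds_all, schedule_a)

  x1 <- matrix(plant_a$std$test$x[1, , ], nrow = input_shape[1])
  attr_mat <- integrated_gradients(model, x1, m = config$attribution_m,
                                   sample_id = plant_a$std$test$timestamps[1])
  freqs <- dataset_frequencies(plant_a$ds)
  iv <- feature_importance(attr_mat, frequencies = freqs)
  topf <- top_k_features(iv, k = min(10, nrow(iv)))
  bands <- band_importance(iv)

  metrics <- tibble(acc_A_val = acc_a_val, acc_A_test = acc_a_test,
                    n_val = nrow(preds_val), n_test = nrow(preds_test))
  bundle <- list(metrics = metrics, model = model, history = tidy(model),
                 cycle_report = cycle_rep, delay_report = delay_rep,
                 attribution = attr_mat, importance = iv,
                 top_features = topf, band_report = bands,
                 schedule = schedule_a, dataset = plant_a$ds,
                 predictions = eval_preds)

  if (config$cross_plant) {
    variant <- make_variant_profile(config$profile, config$variant_shift,
                                    seed = config$variant_seed)
    schedule_b <- generate_schedule(config$total_minutes, config$min_phase,
                                    config$max_phase)
    plant_b <- prepare_plant(schedule_b, variant, config)
    # zero-shot: plant B's raw data through plant A's scaler, as deployed
    b_test_in_a <- standardize(plant_b$parts$test,
                               stats = plant_a$std$stats)$train
    zero_shot <- predict(model, b_test_in_a)
    acc_b_zero <- accuracy_of(zero_shot)
    model_b <- fine_tune(model, plant_b$std$train, plant_b$std$val, tcfg)
    tuned <- predict(model_b, plant_b$std$test)
    acc_b_tuned <- accuracy_of(tuned)
    bundle$metrics <- dplyr::mutate(bundle$metrics,
                                    acc_B_zero_shot = acc_b_zero,
                                    acc_B_finetuned = acc_b_tuned,
                                    n_test_b = nrow(tuned))
    bundle$model_b <- model_b
    bundle$history_b <- tidy(model_b)
    bundle$schedule_b <- schedule_b
    bundle$cycle_report_b <- per_cycle_accuracy(tuned, schedule_b)
  }

  if (!is.null(out_dir)) write_bundle(bundle, config, out_dir)
  bundle
}

write_bundle <- function(bundle, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  utils::write.csv(bundle$history, fp("history.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$cycle_report), fp("cycle_report.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$delay_report), fp("delay_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(bundle$metrics), fp("metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  export_heatmap(bundle$attribution, fp("heatmap.csv"), fp("heatmap.png"),
                 frequencies = bundle$importance$freq_hz)
  export_trends(bundle$dataset, bundle$top_features$index,
                bundle$predictions, bundle$schedule,
                fp("trends.csv"), fp("trends.png"))
  utils::write.csv(bundle$top_features, fp("top_features.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$band_report, fp("band_importance.csv"),
                   row.names = FALSE)
  save_model(bundle$model, fp("model"))
  if (!is.null(bundle$model_b)) save_model(bundle$model_b, fp("model_b"))
  invisible(out_dir)
}

#' Training curves plot
#'
#' @param object A `training_history` tibble.
#' @param ... Unused.
#' @return A ggplot object with loss and accuracy panels.
#' @method autoplot training_history
#' @export
autoplot.training_history <- function(object, ...) {
  long <- tidyr::pivot_longer(as.data.frame(object),
                              c("loss", "val_loss", "accuracy", "val_accuracy"),
                              names_to = "metric", values_to = "value")
  long$panel <- ifelse(grepl("loss", long$metric), "loss", "accuracy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' Per-cycle accuracy bars
#'
#' @param object A `cycle_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cycle_report
#' @export
autoplot.cycle_report <- function(object, ...) {
  df <- as.data.frame(object)
  df <- df[df$n > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$phase), y = .data$accuracy,
                                   fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(dark = "grey25", light = "gold")) +
    ggplot2::labs(x = "cycle (phase)", y = "accuracy",
                  title = "Per-cycle classification accuracy") +
    ggplot2::theme_minimal()
}
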