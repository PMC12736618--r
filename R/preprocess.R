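#' Chronological split fractions
#'
#' @param train_frac,val_frac,test_frac Fractions in (0,1) summing to 1.
#'   Defaults: the first 60% of the time series for training, the next 20%
#'   for validation, the final 20% for testing.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_frac = 0.60, val_frac = 0.20, test_frac = 0.20) {
  fr <- c(train_frac, val_frac, test_frac)
  if (any(fr <= 0) || any(fr >= 1) || abs(sum(fr) - 1) > 1e-9) {
    abort_validation("split fractions must lie in (0,1) and sum to 1")
  }
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac), class = "split_spec")
}

#' Drop post-transition samples
#'
#' Removes every sample whose timestamp falls in the half-open window
#' `[t_switch, t_switch + window)` after any light switch, discarding the
#' transient interval in which the plant has not yet reached its steady-state
#' response. `window = 0` is the identity.
#'
#' @param ds A `burst_dataset`.
#' @param schedule The [light_schedule()] that generated it.
#' @param window Removal window, minutes (default 10).
#' @return The filtered `burst_dataset`, original order preserved.
#' @export
filter_transitions <- function(ds, schedule, window = 10) {
  stopifnot(inherits(ds, "burst_dataset"))
  check_scalar_nonneg(window, "window")
  sw <- switch_times(schedule)
  if (length(sw) == 0 || window == 0) return(ds)
  t <- ds$timestamps
  inside <- Reduce(`|`, lapply(sw, function(s) t >= s & t < s + window))
  ds_slice(ds, !inside)
}

#' Chronological train/validation/test split
#'
#' Splits a time-ordered dataset into contiguous blocks: the first
#' `floor(N * train_frac)` samples train, the next `floor(N * val_frac)`
#' validate, and the remainder tests — no shuffling, so no look-ahead leakage.
#'
#' @param ds A `burst_dataset` (time-ordered by construction).
#' @param spec A [split_spec()].
#' @return Named list of `burst_dataset`s: `train`, `val`, `test`.
#' @export
chronological_split <- function(ds, spec = split_spec()) {
  stopifnot(inherits(ds, "burst_dataset"), inherits(spec, "split_spec"))
  N <- n_samples(ds)
  n_train <- floor(N * spec$train_frac)
  n_val <- floor(N * spec$val_frac)
  n_test <- N - n_train - n_val
  if (n_train < 1 || n_val < 1 || n_test < 1) {
    abort_validation("too few samples for non-empty train/val/test partitions")
  }
  list(
    train = ds_slice(ds, seq_len(n_train)),
    val = ds_slice(ds, n_train + seq_len(n_val)),
    test = ds_slice(ds, n_train + n_val + seq_len(n_test))
  )
}

new_std_partition <- function(x, y, timestamps, labels) {
  structure(list(x = x, y = y, timestamps = timestamps, labels = labels),
            class = "std_partition")
}

#' @export
print.std_partition <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<std_partition> %d samples x %d timesteps x %d features\n",
              d[1], d[2], d[3]))
  invisible(x)
}

partition_to_array <- function(ds) {
  dequantize_amplitude(ds$data, ds$manifest$full_scale)
}

#' Fit-on-train standardization
#'
#' Computes the per-frequency mean and standard deviation on the training
#' partition (pooling all sweeps of all training bursts) and transforms every
#' supplied partition to zero mean / unit variance per frequency bin. Bins
#' that are constant in training map to 0. Statistics come from the training
#' data only, so validation and test remain untouched by their own moments.
#'
#' @param train Training `burst_dataset`.
#' @param ... Further `burst_dataset`s (e.g. validation, test) transformed
#'   with the training statistics; names are preserved.
#' @param stats Optional precomputed statistics (as returned in `$stats`) to
#'   apply instead of fitting on `train`.
#' @return A list with one `std_partition` per input dataset (first element
#'   named `train`) and `stats`, a tibble with `feature`, `mean`, `sd`.
#' @export
standardize <- function(train, ..., stats = NULL) {
  stopifnot(inherits(train, "burst_dataset"))
  if (n_samples(train) == 0) abort_validation("training partition is empty")
  parts <- c(list(train = train), list(...))
  if (is.null(names(parts)) || any(names(parts)[-1] == "")) {
    names(parts) <- c("train", paste0("part", seq_along(parts))[-1])
  }
  P <- dim(train$data)[3]
  if (is.null(stats)) {
    xtr <- partition_to_array(train)
    flat <- matrix(xtr, ncol = P)  # (samples*sweeps) x features
    mu <- colMeans(flat)
    sdv <- sqrt(colMeans(sweep(flat, 2, mu)^2))  # population SD, as a scaler fits
    stats <- tibble(feature = seq_len(P), mean = mu, sd = sdv)
  }
  sd_safe <- ifelse(stats$sd > 0, stats$sd, 1)
  out <- lapply(parts, function(ds) {
    x <- partition_to_array(ds)
    for (p in seq_len(P)) {
      x[, , p] <- (x[, , p] - stats$mean[p]) / sd_safe[p]
    }
    if (any(stats$sd == 0)) x[, , stats$sd == 0] <- 0
    new_std_partition(x, label_to_int(ds$labels), ds$timestamps, ds$labels)
  })
  c(out, list(stats = stats))
}

#' Class balance report
#'
#' Counts dark/light samples per partition and flags any partition whose
#' minority-class fraction falls below `threshold` — a warning sign for
#' training a classifier that should not lean on the majority class.
#'
#' @param ... Named `burst_dataset` or `std_partition` objects.
#' @param threshold Minority fraction below which a partition is flagged.
#' @return A tibble with columns `partition`, `n_dark`, `n_light`, `n`,
#'   `minority_frac`, `flagged`.
#' @export
class_balance_report <- function(..., threshold = 0.35) {
  parts <- list(...)
  nms <- names(parts)
  if (is.null(nms)) nms <- paste0("part", seq_along(parts))
  rows <- purrr::map2(parts, nms, function(p, nm) {
    labels <- if (inherits(p, "std_partition")) p$labels else p$labels
    n_dark <- sum(labels == "dark")
    n_light <- sum(labels == "light")
    n <- n_dark + n_light
    minority <- if (n > 0) min(n_dark, n_light) / n else 0
    tibble(partition = nm, n_dark = n_dark, n_light = n_light, n = n,
           minority_frac = minority, flagged = n == 0 | minority < threshold)
  })
  dplyr::bind_rows(rows)
}
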