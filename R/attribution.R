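#' Model output and input-gradient (generic)
#'
#' Implementations return, for a batch of inputs, the scalar model output per
#' sample and the gradient of that output with respect to every input entry.
#' [integrated_gradients()] is written against this interface, so any object
#' providing it can be attributed.
#'
#' @param model The model object.
#' @param X Input array `(batch x timesteps x features)`.
#' @return A list with `value` (numeric, length batch) and `grad` (array of
#'   `dim(X)`).
#' @export
model_input_gradient <- function(model, X) {
  UseMethod("model_input_gradient")
}

#' @export
model_input_gradient.plant_classifier <- function(model, X) {
  check_input_shape(model, X)
  fw <- nn_forward(model$params, X, want_cache = TRUE)
  # attribute the output probability: dp/dz2 = p (1 - p)
  bw <- nn_backward(model$params, fw$cache, fw$p * (1 - fw$p), want_dx = TRUE)
  list(value = fw$p, grad = bw$dX)
}

#' Integrated-gradients attribution for one sample
#'
#' Moves the input along the straight path from `baseline` to `x`, averaging
#' the model's input gradients at `m` evenly spaced points (right-Riemann
#' approximation) and scaling by `x - baseline`:
#' \deqn{IG_i = (x_i - x'_i) \cdot \frac{1}{m} \sum_{k=1}^{m}
#'   \partial F\big(x' + \tfrac{k}{m}(x - x')\big) / \partial x_i.}
#' As `m` grows the attributions satisfy the completeness identity
#' \eqn{\sum_i IG_i = F(x) - F(x')}; for a linear model they are exact for
#' any `m`. The default baseline is the all-zero input, i.e. the training-set
#' mean in standardized units.
#'
#' @param model An object with a [model_input_gradient()] method.
#' @param x Input sample, `(timesteps x features)` matrix in standardized
#'   units.
#' @param baseline Baseline input of the same shape (default all zeros).
#' @param m Number of path steps.
#' @param sample_id Optional identifier stored with the result.
#' @return An `attribution_matrix`: list with `values` (timesteps x
#'   features), `f_x`, `f_baseline`, `m`, `sample_id`.
#' @export
integrated_gradients <- function(model, x, baseline = NULL, m = 50,
                                 sample_id = NA) {
  if (!is.matrix(x)) abort_validation("`x` must be a (timesteps x features) matrix")
  if (is.null(baseline)) baseline <- matrix(0, nrow(x), ncol(x))
  if (!identical(dim(baseline), dim(x))) {
    abort_validation("`baseline` shape must match `x`")
  }
  if (m < 1) abort_validation("`m` must be >= 1")
  T_ <- nrow(x); F_ <- ncol(x)
  diffs <- x - baseline
  Xpath <- array(0, dim = c(m, T_, F_))
  for (k in seq_len(m)) Xpath[k, , ] <- baseline + (k / m) * diffs
  mg <- model_input_gradient(model, Xpath)
  avg_grad <- apply(mg$grad, c(2, 3), mean)
  Xends <- array(0, dim = c(2, T_, F_))
  Xends[1, , ] <- x
  Xends[2, , ] <- baseline
  f_ends <- model_input_gradient(model, Xends)$value
  structure(list(values = diffs * avg_grad, f_x = f_ends[1],
                 f_baseline = f_ends[2], m = m, sample_id = sample_id),
            class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf("<attribution_matrix> %d x %d | m = %d | F(x) = %.4f, F(baseline) = %.4f\n",
              nrow(x$values), ncol(x$values), x$m, x$f_x, x$f_baseline))
  invisible(x)
}

#' Per-frequency importance from an attribution matrix
#'
#' Reduces the `(timesteps x features)` attribution to one value per
#' frequency bin by summing (default) or averaging over time. The sum
#' reduction conserves the matrix total.
#'
#' @param attr An `attribution_matrix`.
#' @param frequencies Optional frequency axis, Hz (length = features).
#' @param reduction `"sum"` or `"mean"` over timesteps.
#' @return An `importance_vector` tibble: `index`, `freq_hz`, `importance`.
#' @export
feature_importance <- function(attr, frequencies = NULL,
                               reduction = c("sum", "mean")) {
  stopifnot(inherits(attr, "attribution_matrix"))
  reduction <- match.arg(reduction)
  v <- colSums(attr$values)
  if (reduction == "mean") v <- v / nrow(attr$values)
  P <- length(v)
  if (is.null(frequencies)) frequencies <- sweep_frequencies(sweep_config())[seq_len(P)]
  if (length(frequencies) != P) {
    abort_validation("`frequencies` length must equal the feature count")
  }
  out <- tibble(index = seq_len(P), freq_hz = frequencies, importance = v)
  class(out) <- c("importance_vector", class(out))
  out
}

#' Top-k most influential frequency bins
#'
#' Ranks bins by descending absolute importance (ties broken toward the lower
#' index) and returns the first `k`.
#'
#' @param iv An `importance_vector`.
#' @param k Number of bins to return.
#' @return A tibble of `k` rows: `rank`, `index`, `freq_hz`, `importance`.
#' @export
top_k_features <- function(iv, k = 10) {
  stopifnot(inherits(iv, "importance_vector"))
  if (k > nrow(iv)) abort_validation("`k` exceeds the number of frequency bins")
  ord <- order(-abs(iv$importance), iv$index)[seq_len(k)]
  out <- iv[ord, c("index", "freq_hz", "importance")]
  out <- tibble::add_column(out, rank = seq_len(k), .before = 1)
  tibble::as_tibble(out)
}

#' Aggregate importance over frequency bands
#'
#' Sums absolute importance over bins whose frequency lies in each half-open
#' band `[low, high)`. The default bands are the low end of the sweep and the
#' upper-band region often flagged as influential; bands outside the grid
#' aggregate to 0, and bands partitioning the grid conserve the total.
#'
#' @param iv An `importance_vector`.
#' @param bands List of numeric pairs `c(low_hz, high_hz)`.
#' @return A tibble: `low_hz`, `high_hz`, `n_bins`, `importance`.
#' @export
band_importance <- function(iv, bands = list(c(0, 30e3), c(190e3, 220e3))) {
  stopifnot(inherits(iv, "importance_vector"))
  rows <- purrr::map(bands, function(b) {
    if (length(b) != 2 || b[1] > b[2]) {
      abort_validation("each band must be c(low, high) with low <= high")
    }
    sel <- iv$freq_hz >= b[1] & iv$freq_hz < b[2]
    tibble(low_hz = b[1], high_hz = b[2], n_bins = sum(sel),
           importance = sum(abs(iv$importance[sel])))
  })
  dplyr::bind_rows(rows)
}

#' Export an attribution heatmap
#'
#' Writes the raw `(timesteps x features)` matrix as CSV and, if `png_path`
#' is given, a heatmap figure (timesteps on the vertical axis, frequency on
#' the horizontal).
#'
#' @param attr An `attribution_matrix`.
#' @param csv_path Output CSV path for the raw matrix.
#' @param png_path Optional output PNG path.
#' @param frequencies Optional frequency axis, Hz.
#' @return `csv_path`, invisibly.
#' @export
export_heatmap <- function(attr, csv_path, png_path = NULL, frequencies = NULL) {
  stopifnot(inherits(attr, "attribution_matrix"))
  utils::write.table(attr$values, csv_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(png_path)) {
    p <- autoplot.attribution_matrix(attr, frequencies = frequencies)
    ggplot2::ggsave(png_path, p, width = 8, height = 4, dpi = 120)
  }
  invisible(csv_path)
}

#' Heatmap of an attribution matrix
#'
#' @param object An `attribution_matrix`.
#' @param frequencies Optional frequency axis, Hz.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot attribution_matrix
#' @export
autoplot.attribution_matrix <- function(object, frequencies = NULL, ...) {
  vals <- object$values
  P <- ncol(vals)
  if (is.null(frequencies)) frequencies <- seq_len(P)
  df <- tidyr::expand_grid(timestep = seq_len(nrow(vals)), bin = seq_len(P))
  df$freq <- frequencies[df$bin]
  df$attribution <- as.numeric(t(vals))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$timestep,
                                   fill = .data$attribution)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "frequency", y = "timestep (sweep)",
                  fill = "attribution",
                  title = "Integrated-gradients attribution") +
    ggplot2::theme_minimal()
}

#' Per-frequency importance profile plot
#'
#' @param object An `importance_vector`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot importance_vector
#' @export
autoplot.importance_vector <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_hz / 1e3,
                                       y = .data$importance)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "frequency (kHz)", y = "summed attribution",
                  title = "Per-frequency importance") +
    ggplot2::theme_minimal()
}

#' Export top-feature amplitude trends
#'
#' For every sample, averages the de-quantized burst amplitude over the given
#' frequency bins and writes a timeline CSV (timestamp, mean amplitude, true
#' and predicted labels) plus, optionally, a figure with light/dark phase
#' shading and prediction markers.
#'
#' @param ds A `burst_dataset`.
#' @param top_indices Integer frequency-bin indices (e.g. from
#'   [top_k_features()]).
#' @param predictions Tibble from [predict.plant_classifier()] aligned to
#'   `ds` samples (matched by timestamp; samples without a prediction get
#'   `NA`).
#' @param schedule The [light_schedule()] for phase shading.
#' @param csv_path Output CSV path.
#' @param png_path Optional output PNG path.
#' @return The trends tibble, invisibly.
#' @export
export_trends <- function(ds, top_indices, predictions, schedule,
                          csv_path, png_path = NULL) {
  stopifnot(inherits(ds, "burst_dataset"))
  amp <- dequantize_amplitude(ds$data[, , top_indices, drop = FALSE],
                              ds$manifest$full_scale)
  trend <- tibble(
    timestamp = ds$timestamps,
    mean_amplitude = apply(amp, 1, mean),
    label = ds$labels,
    predicted = predictions$predicted[match(ds$timestamps,
                                            predictions$timestamp)]
  )
  utils::write.csv(trend, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    p <- ggplot2::ggplot(trend) +
      ggplot2::geom_rect(
        data = as.data.frame(schedule[schedule$state == "light", ]),
        ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end),
        ymin = -Inf, ymax = Inf, fill = "gold", alpha = 0.25) +
      ggplot2::geom_line(ggplot2::aes(x = .data$timestamp,
                                      y = .data$mean_amplitude)) +
      ggplot2::geom_point(
        data = trend[!is.na(trend$predicted), ],
        ggplot2::aes(x = .data$timestamp, y = .data$mean_amplitude,
                     color = .data$predicted), size = 0.6) +
      ggplot2::labs(x = "time (min)", y = "mean amplitude (top bins)",
                    color = "predicted",
                    title = "Dominant-frequency amplitude trend") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(png_path, p, width = 9, height = 3.5, dpi = 120)
  }
  invisible(trend)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
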