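#' @keywords internal
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif predict
#' @importFrom utils head tail
"_PACKAGE"

abort_validation <- function(msg) {
  abort(msg, class = "plantimp_error_validation")
}

abort_format <- function(msg) {
  abort(msg, class = "plantimp_error_format")
}

abort_integrity <- function(msg) {
  abort(msg, class = "plantimp_error_integrity")
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_validation(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

check_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort_validation(sprintf("`%s` must be a single non-negative finite number", name))
  }
  invisible(x)
}

# Seed handling: `seed = NULL` draws from the current RNG stream so callers
# can compose several stochastic steps under one outer seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(seed)
  code
}

label_levels <- function() c("dark", "light")

label_to_int <- function(labels) {
  if (!all(labels %in% label_levels())) {
    abort_validation("labels must be 'dark' or 'light'")
  }
  as.integer(labels == "light")
}
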