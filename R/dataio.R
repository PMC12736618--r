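#' Encode one sweep as a transmission payload
#'
#' Each frequency point is encoded as a little-endian unsigned 16-bit integer,
#' so a 230-point sweep occupies 460 bytes — the per-packet payload of the
#' acquisition protocol.
#'
#' @param values Integer vector of quantized amplitudes in `[0, 65535]`.
#' @return Raw vector of `2 * length(values)` bytes.
#' @export
encode_sweep <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values)) ||
      any(values != floor(values))) {
    abort_validation("sweep values must be integers")
  }
  if (any(values < 0 | values > 65535)) {
    abort(sprintf("sweep values outside [0, 65535]: %s",
                  paste(head(values[values < 0 | values > 65535], 3), collapse = ", ")),
          class = "plantimp_error_range")
  }
  writeBin(as.integer(values), raw(), size = 2L, endian = "little")
}

#' Decode a sweep payload
#'
#' Exact inverse of [encode_sweep()].
#'
#' @param payload Raw vector of `2 * n_points` bytes.
#' @param n_points Expected number of frequency points.
#' @return Integer vector of `n_points` amplitudes in `[0, 65535]`.
#' @export
decode_sweep <- function(payload, n_points) {
  if (!is.raw(payload)) abort_format("payload must be a raw vector")
  if (length(payload) != 2L * n_points) {
    abort_format(sprintf("payload has %d bytes; expected %d",
                         length(payload), 2L * n_points))
  }
  readBin(payload, "integer", n = n_points, size = 2L, signed = FALSE,
          endian = "little")
}

CONTAINER_MAGIC <- "PLANTIMPB1"

#' Write a burst dataset container
#'
#' Self-describing binary container: a magic string, a JSON manifest (with the
#' array dimensions appended), then timestamps as doubles, labels as single
#' bytes (0 = dark, 1 = light), and the quantized amplitude array as
#' little-endian unsigned 16-bit integers in R column-major order.
#'
#' @param ds A `burst_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "burst_dataset"))
  manifest <- ds$manifest
  manifest$n_samples <- dim(ds$data)[1]
  mjson <- charToRaw(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(CONTAINER_MAGIC), con)
  writeBin(length(mjson), con, size = 4L, endian = "little")
  writeBin(mjson, con)
  writeBin(ds$timestamps, con, size = 8L, endian = "little")
  writeBin(as.integer(label_to_int(ds$labels)), con, size = 1L)
  writeBin(as.integer(ds$data), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a burst dataset container
#'
#' Reads a file written by [write_dataset()] and validates internal
#' consistency (magic, manifest dimensions versus stored payload, strictly
#' increasing timestamps); inconsistencies raise an integrity error.
#'
#' @param path File path.
#' @return A `burst_dataset`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(CONTAINER_MAGIC)))
  if (!identical(magic, CONTAINER_MAGIC)) {
    abort_integrity("not a plantimp burst container")
  }
  mlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(mlen) != 1L || is.na(mlen) || mlen <= 0) {
    abort_integrity("corrupt manifest length")
  }
  manifest <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", mlen)),
                                 simplifyVector = TRUE)
  req <- c("n_samples", "sweeps_per_burst", "n_points", "full_scale")
  if (!all(req %in% names(manifest))) {
    abort_integrity("manifest missing required fields")
  }
  n <- manifest$n_samples; S <- manifest$sweeps_per_burst; P <- manifest$n_points
  timestamps <- readBin(con, "double", n, size = 8L, endian = "little")
  labels_raw <- readBin(con, "integer", n, size = 1L, signed = FALSE)
  values <- readBin(con, "integer", n * S * P + 1L, size = 2L, signed = FALSE,
                    endian = "little")
  if (length(timestamps) != n || length(labels_raw) != n ||
      length(values) != n * S * P) {
    abort_integrity("stored payload does not match manifest dimensions")
  }
  if (n > 1 && is.unsorted(timestamps, strictly = TRUE)) {
    abort_integrity("timestamps not strictly increasing")
  }
  if (!all(labels_raw %in% c(0L, 1L))) abort_integrity("invalid label bytes")
  manifest$n_samples <- NULL
  new_burst_dataset(array(values, dim = c(n, S, P)), timestamps,
                    label_levels()[labels_raw + 1L], as.list(manifest))
}

#' Export a per-sample CSV index of a container
#'
#' One row per sample with its timestamp, label, burst shape, the byte offset
#' of its amplitude block inside the binary container, and the mean amplitude
#' — a human-readable index for inspection; the bulk data stays binary.
#'
#' @param ds A `burst_dataset`.
#' @param container_path Path of the container the offsets refer to (as
#'   written by [write_dataset()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_dataset_csv <- function(ds, container_path, path) {
  stopifnot(inherits(ds, "burst_dataset"))
  manifest <- ds$manifest
  manifest$n_samples <- dim(ds$data)[1]
  mjson <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)
  n <- n_samples(ds); S <- dim(ds$data)[2]; P <- dim(ds$data)[3]
  header_bytes <- nchar(CONTAINER_MAGIC) + 4L + nchar(mjson, type = "bytes") +
    8L * n + n
  tab <- as_tibble(ds)
  tab$container <- container_path
  tab$sweeps <- S
  tab$n_points <- P
  # column-major layout: sample i's block is strided; offset of its first value
  tab$byte_offset <- header_bytes + 2L * (seq_len(n) - 1L)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
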