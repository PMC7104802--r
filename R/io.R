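#' Read one channel from an EDF/EDF+ file
#'
#' Minimal reader for the European Data Format: parses the fixed-width
#' ASCII headers, decodes the 16-bit little-endian data records of the
#' requested channel and rescales them to physical units using the
#' per-channel calibration (physical/digital min/max). Channels may have
#' different sampling rates; the requested channel's own rate is used.
#'
#' @param path Path to an EDF file.
#' @param channel Channel label (exact match after whitespace trimming).
#' @return An [eeg_signal] in physical units.
#' @export
read_edf <- function(path, channel) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(nchars) trimws(rawToChar(readBin(con, "raw", nchars)))
  version <- hdr(8)
  if (!identical(version, "0")) {
    abort(sprintf("Not an EDF file (version field '%s').", version),
          class = "tfhfo_format_error")
  }
  hdr(80); hdr(80); hdr(8); hdr(8)           # patient, recording, date, time
  header_bytes <- as.integer(hdr(8))
  hdr(44)                                    # reserved
  n_records <- as.integer(hdr(8))
  record_duration <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  if (is.na(ns) || ns < 1 || is.na(n_records) || is.na(header_bytes)) {
    abort("Malformed EDF header.", class = "tfhfo_format_error")
  }
  fields <- function(nchars) vapply(seq_len(ns), function(i) hdr(nchars), "")
  labels <- fields(16)
  fields(80); fields(8)                      # transducer, physical dimension
  phys_min <- as.numeric(fields(8))
  phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8))
  dig_max <- as.numeric(fields(8))
  fields(80)                                 # prefiltering
  spr <- as.integer(fields(8))               # samples per record
  fields(32)                                 # reserved
  ci <- which(labels == trimws(channel))
  if (length(ci) != 1L) {
    abort(sprintf("Channel '%s' not found. Available channels: %s",
                  channel, paste(labels, collapse = ", ")),
          class = "tfhfo_format_error")
  }
  seek(con, header_bytes)
  rec_len <- sum(spr)
  out <- numeric(n_records * spr[ci])
  offset <- c(0, cumsum(spr))[ci]
  for (r in seq_len(n_records)) {
    rec <- readBin(con, "integer", n = rec_len, size = 2, signed = TRUE,
                   endian = "little")
    if (length(rec) < rec_len) {
      abort("Truncated EDF data record.", class = "tfhfo_format_error")
    }
    out[((r - 1) * spr[ci] + 1):(r * spr[ci])] <-
      rec[(offset + 1):(offset + spr[ci])]
  }
  gain <- (phys_max[ci] - phys_min[ci]) / (dig_max[ci] - dig_min[ci])
  phys <- (out - dig_min[ci]) * gain + phys_min[ci]
  if (!all(is.finite(phys))) {
    abort("EDF channel contains non-finite samples after calibration.",
          class = "tfhfo_data_error")
  }
  eeg_signal(phys, spr[ci] / record_duration, channel = trimws(channel))
}

signal_sidecar <- function(signal, extra = list()) {
  c(list(sampling_rate = signal$sampling_rate,
         n_samples = length(signal$samples),
         channel = signal$channel, start_s = signal$start_s), extra)
}

read_sidecar <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort(sprintf("Missing sidecar '%s'.", sidecar),
          class = "tfhfo_format_error")
  }
  jsonlite::read_json(sidecar, simplifyVector = TRUE)
}

check_samples <- function(x, meta, path) {
  if (!is.null(meta$n_samples) && length(x) != meta$n_samples) {
    abort(sprintf("'%s': %d samples on disk but sidecar declares %d.",
                  path, length(x), meta$n_samples),
          class = "tfhfo_format_error")
  }
  if (!all(is.finite(x))) {
    abort(sprintf("'%s' contains NaN/Inf samples.", path),
          class = "tfhfo_data_error")
  }
  invisible(x)
}

#' Read and write signals as delimited text or flat binary
#'
#' Text signals are one sample per line at 15 significant digits; binary
#' signals are little-endian float64, a lossless round-trip. Both carry a
#' JSON sidecar `<path>.json` with at least `sampling_rate` and
#' `n_samples`; a missing sidecar or a sample-count mismatch is an error,
#' as are non-finite samples.
#'
#' @param path Data file path (sidecar at `<path>.json`).
#' @param signal An [eeg_signal] to write.
#' @param extra Named list merged into the sidecar (e.g. seed, SNR).
#' @return Readers return an [eeg_signal]; writers return `path`
#'   invisibly.
#' @export
read_signal_text <- function(path) {
  meta <- read_sidecar(path)
  x <- as.numeric(readLines(path))
  check_samples(x, meta, path)
  eeg_signal(x, meta$sampling_rate, channel = meta$channel %||% "chan",
             start_s = meta$start_s %||% 0)
}

#' @rdname read_signal_text
#' @export
write_signal_text <- function(signal, path, extra = list()) {
  stopifnot(is_signal(signal))
  writeLines(format(signal$samples, digits = 15, trim = TRUE,
                    scientific = TRUE), path)
  jsonlite::write_json(signal_sidecar(signal, extra), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_signal_text
#' @export
read_signal_binary <- function(path) {
  meta <- read_sidecar(path)
  n <- file.info(path)$size / 8
  x <- readBin(path, "double", n = n, size = 8, endian = "little")
  check_samples(x, meta, path)
  eeg_signal(x, meta$sampling_rate, channel = meta$channel %||% "chan",
             start_s = meta$start_s %||% 0)
}

#' @rdname read_signal_text
#' @export
write_signal_binary <- function(signal, path, extra = list()) {
  stopifnot(is_signal(signal))
  writeBin(signal$samples, path, size = 8, endian = "little")
  jsonlite::write_json(signal_sidecar(signal, extra), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

events_columns <- c("channel", "t_center_s", "f_center_hz", "t_start_s",
                    "t_end_s", "f_low_hz", "f_high_hz", "duration_ms",
                    "amplitude_au", "threshold_level", "band")

#' Read and write detected-event tables as CSV
#'
#' Comma-delimited with a mandatory header row and '.' decimal separator;
#' columns: `channel, t_center_s, f_center_hz, t_start_s, t_end_s,
#' f_low_hz, f_high_hz, duration_ms, amplitude_au, threshold_level, band`.
#'
#' @param events Events tibble from [detect_hfos()].
#' @param path CSV file path.
#' @return `read_events_csv()` returns an events tibble;
#'   `write_events_csv()` returns `path` invisibly.
#' @export
write_events_csv <- function(events, path) {
  ev <- as_tibble(events)[, events_columns]
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(events_columns, names(ev))
  if (length(missing)) {
    abort(sprintf("Event CSV is missing columns: %s",
                  paste(missing, collapse = ", ")),
          class = "tfhfo_format_error")
  }
  as_hfo_events(as_tibble(ev))
}

#' Read and write simulation ground truth as CSV
#'
#' Columns: `event_index, t_center_s, f0_hz, n_cycles, fwhm_s`.
#'
#' @param truth Truth tibble from [simulate_hfo_train()].
#' @param path CSV file path.
#' @return `read_truth_csv()` returns a tibble; the writer returns `path`
#'   invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  cols <- c("event_index", "t_center_s", "f0_hz", "n_cycles", "fwhm_s")
  utils::write.csv(as_tibble(truth)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a performance report as JSON
#'
#' @param report An `hfo_performance` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "hfo_performance"))
  out <- report[setdiff(names(report), "errors")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a detector configuration from a YAML file
#'
#' The file mirrors the fields of [detector_config()]; `morlet` may be a
#' nested mapping with the fields of [morlet_params()]. Missing fields
#' keep their defaults.
#'
#' @param path YAML file path.
#' @return A [detector_config].
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  morlet <- do.call(morlet_params, raw$morlet %||% list())
  raw$morlet <- NULL
  if (!is.null(raw$band)) raw$band <- as.numeric(raw$band)
  do.call(detector_config, c(raw, list(morlet = morlet)))
}
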