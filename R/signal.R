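#' Single-channel EEG signal
#'
#' A lightweight container for a uniformly sampled single-channel amplitude
#' series. All package functions that consume raw signals accept this class.
#'
#' @param samples Numeric vector of sample amplitudes (arbitrary units or
#'   microvolts). Must be finite and non-empty.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel Channel label.
#' @param start_s Absolute time of the first sample, in seconds.
#'
#' @return An object of class `eeg_signal`: a list with elements `samples`,
#'   `sampling_rate`, `channel` and `start_s`.
#' @examples
#' s <- eeg_signal(sin(2 * pi * 10 * seq(0, 1, by = 1 / 500)), 500)
#' s
#' @export
eeg_signal <- function(samples, sampling_rate, channel = "chan", start_s = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    abort("`samples` must contain at least one sample.", class = "tfhfo_input_error")
  }
  if (!all(is.finite(samples))) {
    abort("`samples` must be finite (no NA/NaN/Inf).", class = "tfhfo_input_error")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be a single positive number (Hz).",
          class = "tfhfo_input_error")
  }
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         channel = as.character(channel), start_s = as.numeric(start_s)),
    class = "eeg_signal"
  )
}

#' @export
print.eeg_signal <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf("<eeg_signal> channel '%s': %d samples @ %g Hz (%.3f s, start %.3f s)\n",
              x$channel, length(x$samples), x$sampling_rate, dur, x$start_s))
  invisible(x)
}

#' @export
length.eeg_signal <- function(x) length(x$samples)

is_signal <- function(x) inherits(x, "eeg_signal")

as_signal <- function(x, sampling_rate = NULL, ...) {
  if (is_signal(x)) return(x)
  if (is.null(sampling_rate)) {
    abort("A numeric vector needs `sampling_rate` to be interpreted as a signal.",
          class = "tfhfo_input_error")
  }
  eeg_signal(x, sampling_rate, ...)
}

#' Time grid of a signal
#'
#' @param x An [eeg_signal].
#' @return Numeric vector of absolute sample times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(is_signal(x))
  x$start_s + (seq_along(x$samples) - 1) / x$sampling_rate
}
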