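#' Morlet continuous-wavelet transform parameters
#'
#' The analyzing wavelet is a Gaussian-windowed complex sinusoid whose shape
#' constant fixes the number of carrier cycles per envelope: with `nco`
#' cycles, the envelope standard deviation at analysis frequency `f` is
#' `sigma = nco / (2 * pi * f)`. The default `nco = 5` is the classical
#' Morlet choice (`2 * pi * f0 = 5`). Analysis frequencies run on a uniform
#' grid from `f_min` to `f_max` in steps of `f_step`.
#'
#' The default grid covers 40-500 Hz (ripple and fast-ripple bands) and
#' deliberately extends below the 80-Hz ripple edge so that low-frequency
#' spike/background energy forms structures attached to the lower image
#' border, where the border-clearing step of the detector removes them.
#'
#' Rows are spaced uniformly in *scale* (1/f) by default. The wavelet's
#' response to a pure tone at `f0` is `exp(-nco^2 * (1 - f0/f)^2 / 2)` —
#' a Gaussian that is exactly symmetric in `1/f` but skewed toward high
#' frequencies on a linear-frequency axis (its bandwidth grows with `f`).
#' On a scale-uniform grid an HFO blob is therefore symmetric about its
#' carrier row and its unweighted binary centroid is an unbiased frequency
#' estimate; on a linear grid the centroid is pulled several percent above
#' the carrier. `spacing = "linear"` (with `f_step`) remains available for
#' display purposes.
#'
#' @param nco Number of cycles (dimensionless, > 0).
#' @param f_min,f_max Frequency grid limits in Hz; `0 < f_min < f_max`.
#' @param n_freqs Number of grid rows for scale-uniform spacing.
#' @param spacing `"scale"` (uniform in 1/f, default) or `"linear"`.
#' @param f_step Grid step in Hz for `spacing = "linear"`.
#' @return A list of class `morlet_params`.
#' @export
morlet_params <- function(nco = 5, f_min = 40, f_max = 500, n_freqs = 231,
                          spacing = c("scale", "linear"), f_step = 2) {
  spacing <- match.arg(spacing)
  check_positive(nco, "nco")
  check_positive(f_min, "f_min")
  check_positive(f_step, "f_step")
  if (n_freqs < 2) {
    abort("`n_freqs` must be at least 2.", class = "tfhfo_parameter_error")
  }
  if (f_max <= f_min) {
    abort("`f_max` must exceed `f_min`.", class = "tfhfo_parameter_error")
  }
  structure(list(nco = nco, f_min = f_min, f_max = f_max,
                 n_freqs = as.integer(n_freqs), spacing = spacing,
                 f_step = f_step),
            class = "morlet_params")
}

morlet_freqs <- function(params) {
  if (identical(params$spacing, "linear")) {
    seq(params$f_min, params$f_max, by = params$f_step)
  } else {
    rev(1 / seq(1 / params$f_max, 1 / params$f_min,
                length.out = params$n_freqs))
  }
}

#' Discrete Morlet wavelet kernel at one analysis frequency
#'
#' Builds the sampled complex analytic Morlet kernel at `f_center`:
#' a Gaussian envelope of standard deviation `nco / (2 * pi * f_center)`
#' carrying `exp(2i * pi * f_center * t)`, truncated at +/- 4 sigma, and
#' normalized to unit gain so that a pure sinusoid of amplitude A at
#' `f_center` yields coefficient magnitude ~ A. The real part is the
#' classical real-valued Morlet wavelet.
#'
#' @param f_center Analysis frequency (Hz); must not exceed the Nyquist
#'   frequency `sampling_rate / 2`.
#' @param sampling_rate Sampling rate (Hz).
#' @param nco Number of cycles (default 5).
#' @return Complex vector of odd length `2L + 1` centered on its envelope
#'   peak, with attributes `sigma_s` (envelope SD, s) and `half_length`
#'   (`L`, samples).
#' @export
morlet_wavelet <- function(f_center, sampling_rate, nco = 5) {
  check_positive(f_center, "f_center")
  check_positive(sampling_rate, "sampling_rate")
  if (f_center > sampling_rate / 2) {
    abort(sprintf("`f_center` (%g Hz) exceeds the Nyquist frequency (%g Hz).",
                  f_center, sampling_rate / 2),
          class = "tfhfo_parameter_error")
  }
  sigma <- nco / (2 * pi * f_center)
  L <- ceiling(4 * sigma * sampling_rate)
  t <- (-L:L) / sampling_rate
  env <- exp(-t^2 / (2 * sigma^2))
  # a unit cosine projects onto the analytic kernel with gain sum(env) / 2
  kern <- env * exp(2i * pi * f_center * t) / (sum(env) / 2)
  attr(kern, "sigma_s") <- sigma
  attr(kern, "half_length") <- L
  kern
}

# Precompute kernel FFTs for a fixed window length so repeated transforms
# (sliding windows) reuse them. Kernels are embedded circularly so output
# column j aligns with input sample j; linear (zero-padded) convolution is
# guaranteed by padding past n + max kernel half-length.
cwt_plan <- function(n, sampling_rate, params = morlet_params()) {
  freqs <- morlet_freqs(params)
  if (max(freqs) > sampling_rate / 2) {
    abort("Frequency grid exceeds the Nyquist frequency of the signal.",
          class = "tfhfo_parameter_error")
  }
  kernels <- lapply(freqs, morlet_wavelet, sampling_rate = sampling_rate,
                    nco = params$nco)
  max_half <- max(vapply(kernels, attr, 0, which = "half_length"))
  if (n < 2 * max_half + 1) {
    abort(sprintf(
      "Signal too short for the longest wavelet kernel (%d < %d samples).",
      n, 2 * max_half + 1), class = "tfhfo_input_error")
  }
  npad <- stats::nextn(n + 2 * max_half + 1, c(2, 3, 5))
  K <- matrix(0i, nrow = npad, ncol = length(freqs))
  for (j in seq_along(kernels)) {
    k <- kernels[[j]]
    L <- attr(k, "half_length")
    col <- complex(npad)
    col[1:(L + 1)] <- k[(L + 1):(2 * L + 1)]          # center + right half
    col[(npad - L + 1):npad] <- k[1:L]                # left half, wrapped
    K[, j] <- col
  }
  K <- stats::mvfft(K)
  list(freqs = freqs, npad = npad, K = K, n = n,
       sampling_rate = sampling_rate)
}

cwt_with_plan <- function(x, plan) {
  n <- length(x)
  stopifnot(n == plan$n)
  X <- fft(c(x, numeric(plan$npad - n)))
  Y <- stats::mvfft(plan$K * X, inverse = TRUE) / plan$npad
  t(Mod(Y[seq_len(n), , drop = FALSE]))
}

#' Morlet time-frequency map of a signal
#'
#' Convolves the signal with unit-gain complex Morlet kernels on the
#' frequency grid of `params` (FFT-accelerated, zero-padded at the edges)
#' and returns coefficient magnitudes. The transform is linear in the input
#' and produces one column per signal sample. Edge columns carry the usual
#' wavelet roll-off artifacts; the detector removes border-attached
#' structures downstream rather than trimming here.
#'
#' @param signal An [eeg_signal] (or numeric vector with `sampling_rate`).
#' @param params A [morlet_params] object.
#' @param sampling_rate Required when `signal` is a bare numeric vector.
#' @return An object of class `tf_map`: list with `times` (s, absolute),
#'   `freqs` (Hz, ascending) and `coeffs` (nonnegative magnitude matrix,
#'   `length(freqs)` x `length(times)`).
#' @examples
#' fs <- 2000
#' s <- eeg_signal(cos(2 * pi * 100 * seq(0, 1, by = 1 / fs)), fs)
#' m <- tf_cwt(s, morlet_params(f_min = 80, f_max = 200, f_step = 4))
#' @export
tf_cwt <- function(signal, params = morlet_params(), sampling_rate = NULL) {
  signal <- as_signal(signal, sampling_rate)
  plan <- cwt_plan(length(signal$samples), signal$sampling_rate, params)
  coeffs <- cwt_with_plan(signal$samples, plan)
  new_tf_map(signal_times(signal), plan$freqs, coeffs)
}

new_tf_map <- function(times, freqs, coeffs) {
  stopifnot(nrow(coeffs) == length(freqs), ncol(coeffs) == length(times))
  structure(list(times = times, freqs = freqs, coeffs = coeffs),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf(
    "<tf_map> %d freqs (%g-%g Hz) x %d times (%.3f-%.3f s), max %.4g au\n",
    length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
    min(x$times), max(x$times), max(x$coeffs)))
  invisible(x)
}

#' Instantaneous amplitude spectrum from a time-frequency map
#'
#' Extracts the map column nearest to time `t`: the instantaneous amplitude
#' spectral density at that moment.
#'
#' @param map A [tf_cwt()] result.
#' @param t Time (s) within the map's time range.
#' @return A tibble with columns `f_hz` and `amplitude_au`.
#' @export
spectrum_slice <- function(map, t) {
  stopifnot(inherits(map, "tf_map"))
  if (t < min(map$times) || t > max(map$times)) {
    abort(sprintf("t = %g s lies outside the map window [%g, %g] s.",
                  t, min(map$times), max(map$times)),
          class = "tfhfo_range_error")
  }
  j <- which.min(abs(map$times - t))
  tibble(f_hz = map$freqs, amplitude_au = map$coeffs[, j])
}

#' Tidy a time-frequency map into long format
#'
#' @param x A `tf_map`.
#' @param ... Unused.
#' @return Tibble with columns `t_s`, `f_hz`, `amplitude_au`.
#' @export
tidy.tf_map <- function(x, ...) {
  tibble(
    t_s = rep(x$times, each = length(x$freqs)),
    f_hz = rep(x$freqs, times = length(x$times)),
    amplitude_au = as.vector(x$coeffs)
  )
}

#' Write a time-frequency map as delimited text
#'
#' Frequencies as rows, times as columns; first row holds times (s), first
#' column holds frequencies (Hz), comma-delimited.
#'
#' @param map A `tf_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tf_map <- function(map, path) {
  stopifnot(inherits(map, "tf_map"))
  m <- cbind(map$freqs, map$coeffs)
  header <- paste(c("f_hz", format(map$times, digits = 12, trim = TRUE)),
                  collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(m, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
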