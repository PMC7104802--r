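#' Simulate a train of Gaussian-envelope HFO events
#'
#' Builds the benchmark HFO train: `n_events` sinusoid-under-Gaussian
#' events of unit envelope amplitude, one per second, each centered at the
#' half-second mark of its slot. Carrier frequencies are drawn uniformly on
#' `band`; each event's FWHM duration spans 5, 6 or 7 carrier cycles
#' (uniformly chosen), so briefer events accompany higher frequencies.
#' Optionally a Gaussian spike can be superimposed under each event for
#' spike+HFO fixtures.
#'
#' @param n_events Number of events (default 300).
#' @param rate Event rate (events per second, default 1); together with
#'   `n_events` this fixes the signal duration unless `duration_s` is
#'   given.
#' @param duration_s Total signal duration (s); defaults to
#'   `n_events / rate`.
#' @param sampling_rate Sampling rate (Hz, default 2000).
#' @param band Length-2 numeric: carrier frequency range (Hz), within
#'   (0, Nyquist).
#' @param n_cycles_choices Integer set of FWHM cycle counts (default 5:7).
#' @param amplitude Envelope peak amplitude (au, default 1).
#' @param spike Optional [spike_params] to superimpose under each event.
#' @param seed Optional RNG seed for reproducibility.
#' @return A list with `signal` (an [eeg_signal]) and `events` (tibble:
#'   `event_index`, `t_center_s`, `f0_hz`, `n_cycles`, `fwhm_s`,
#'   `amplitude_au`).
#' @examples
#' sim <- simulate_hfo_train(n_events = 10, seed = 1)
#' sim$events
#' @export
simulate_hfo_train <- function(n_events = 300, rate = 1, duration_s = NULL,
                               sampling_rate = 2000, band = c(80, 250),
                               n_cycles_choices = c(5, 6, 7),
                               amplitude = 1, spike = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration_s)) duration_s <- n_events / rate
  if (n_events / rate > duration_s + 1e-9) {
    abort("`n_events / rate` exceeds the signal duration.",
          class = "tfhfo_parameter_error")
  }
  if (band[1] <= 0 || band[2] >= sampling_rate / 2) {
    abort("`band` must lie within (0, Nyquist).",
          class = "tfhfo_parameter_error")
  }
  n <- round(duration_s * sampling_rate)
  x <- numeric(n)
  centers <- (seq_len(n_events) - 1) / rate + 0.5 / rate
  f0 <- runif(n_events, band[1], band[2])
  ncyc <- sample(n_cycles_choices, n_events, replace = TRUE)
  fwhm <- ncyc / f0
  sigma <- fwhm_to_sigma(fwhm)
  for (k in seq_len(n_events)) {
    half <- 5 * sigma[k]
    i0 <- max(1, floor((centers[k] - half) * sampling_rate) + 1)
    i1 <- min(n, ceiling((centers[k] + half) * sampling_rate) + 1)
    t <- (seq(i0, i1) - 1) / sampling_rate - centers[k]
    x[i0:i1] <- x[i0:i1] + amplitude * exp(-t^2 / (2 * sigma[k]^2)) *
      cos(2 * pi * f0[k] * t)
    if (!is.null(spike)) {
      x[i0:i1] <- x[i0:i1] + spike_waveform(t, spike)
    }
  }
  list(
    signal = eeg_signal(x, sampling_rate, channel = "sim"),
    events = tibble(event_index = seq_len(n_events), t_center_s = centers,
                    f0_hz = f0, n_cycles = ncyc, fwhm_s = fwhm,
                    amplitude_au = amplitude)
  )
}

#' Generate peak-normalized pink noise
#'
#' Pink (1/f-power) noise by spectral shaping: the Fourier transform of
#' white Gaussian noise is weighted by `1/sqrt(f)` (zero DC), inverted, and
#' the result scaled so that the maximum absolute amplitude is exactly 1.
#' Its log-log power spectrum has slope -1, resembling the EEG background.
#'
#' @param duration_s Duration (s, default 300).
#' @param sampling_rate Sampling rate (Hz, default 2000).
#' @param seed Optional RNG seed.
#' @return An [eeg_signal] with `max(abs(samples)) == 1`.
#' @export
generate_pink_noise <- function(duration_s = 300, sampling_rate = 2000,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * sampling_rate)
  w <- rnorm(n)
  W <- fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * sampling_rate / n  # two-sided frequency magnitude
  shape <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x <- x / max(abs(x))
  eeg_signal(x, sampling_rate, channel = "noise")
}

#' Mix an HFO train with noise at a fixed SNR
#'
#' The combined signal is `hfo + f * noise` with
#' `f = 2^|SNR_dB / 3| * RMS(hfo) / RMS(noise)`, RMS values taken over the
#' full signals. At 0 dB the two RMS amplitudes are equal; each 3-dB drop
#' doubles the noise weight (an amplitude-ratio convention of
#' `10 * log10`).
#'
#' @param hfo_signal,noise [eeg_signal]s of equal length and rate.
#' @param snr_db Signal-to-noise ratio in dB (typically -9, -6, -3, 0).
#' @return A list with `signal` (the mixture, an [eeg_signal]) and
#'   `mixture` (tibble: `snr_db`, `noise_scale`, `rms_hfo`, `rms_noise`).
#' @export
mix_at_snr <- function(hfo_signal, noise, snr_db) {
  stopifnot(is_signal(hfo_signal), is_signal(noise))
  if (length(hfo_signal$samples) != length(noise$samples) ||
      hfo_signal$sampling_rate != noise$sampling_rate) {
    abort("HFO and noise signals must share length and sampling rate.",
          class = "tfhfo_input_error")
  }
  rms_h <- sqrt(mean(hfo_signal$samples^2))
  rms_n <- sqrt(mean(noise$samples^2))
  f <- 2^abs(snr_db / 3) * rms_h / rms_n
  mixed <- eeg_signal(hfo_signal$samples + f * noise$samples,
                      hfo_signal$sampling_rate,
                      channel = sprintf("mix_%+gdB", snr_db))
  list(signal = mixed,
       mixture = tibble(snr_db = snr_db, noise_scale = f,
                        rms_hfo = rms_h, rms_noise = rms_n))
}
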