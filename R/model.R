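#' Convert between Gaussian FWHM and standard deviation
#'
#' Event durations are quoted at full width at half maximum (FWHM) of the
#' Gaussian envelope; internally the envelope is parameterized by its
#' standard deviation, with `fwhm = 2 * sqrt(2 * log(2)) * sigma`.
#'
#' @param fwhm,sigma Duration in seconds.
#' @return The converted value in seconds.
#' @examples
#' sigma_to_fwhm(fwhm_to_sigma(0.05)) # 0.05
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' @rdname fwhm_to_sigma
#' @export
sigma_to_fwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

#' Parameters of the Gaussian spike model
#'
#' The interictal spike (sharp transient) is modeled as a Gaussian bump
#' `A * exp(-t^2 / (2 * sigma^2))`. Duration is supplied as FWHM of the
#' Gaussian; `sigma` may be given instead.
#'
#' @param amplitude Peak amplitude `A` (au, >= 0).
#' @param fwhm Duration at full width half maximum (s). Ignored if `sigma`
#'   is given.
#' @param sigma Envelope standard deviation (s, > 0).
#' @return A list of class `spike_params` with fields `amplitude`, `sigma`,
#'   `fwhm`.
#' @examples
#' spike_params(amplitude = 2.5, fwhm = 0.05)
#' @export
spike_params <- function(amplitude = 2.5, fwhm = 0.05, sigma = NULL) {
  if (is.null(sigma)) sigma <- fwhm_to_sigma(fwhm)
  check_positive(sigma, "sigma")
  check_nonnegative(amplitude, "amplitude")
  structure(list(amplitude = amplitude, sigma = sigma,
                 fwhm = sigma_to_fwhm(sigma)),
            class = "spike_params")
}

#' Parameters of the Gaussian-envelope HFO model
#'
#' A high-frequency oscillation is modeled as a sinusoid at carrier
#' frequency `f0` under a Gaussian envelope:
#' `A * exp(-(t + delay)^2 / (2 * sigma^2)) * cos(2 * pi * f0 * (t + delay))`.
#' The delay shifts the envelope center relative to the time origin (e.g.
#' the spike peak). Duration may be given as FWHM in seconds or as a number
#' of oscillation cycles at `f0` spanning the FWHM.
#'
#' @param amplitude Envelope peak amplitude `A` (au, >= 0).
#' @param f0 Carrier frequency (Hz, > 0).
#' @param fwhm Envelope duration at FWHM (s). Ignored if `sigma` or
#'   `n_cycles` is given.
#' @param n_cycles Number of carrier cycles within the FWHM; sets
#'   `fwhm = n_cycles / f0`.
#' @param sigma Envelope standard deviation (s, > 0).
#' @param delay Envelope-center offset (s); the envelope peaks at
#'   `t = -delay`.
#' @return A list of class `hfo_params` with fields `amplitude`, `f0`,
#'   `sigma`, `fwhm`, `delay`.
#' @examples
#' hfo_params(amplitude = 1, f0 = 100, n_cycles = 4, delay = 0.015)
#' @export
hfo_params <- function(amplitude = 1, f0 = 100, fwhm = 0.04, n_cycles = NULL,
                       sigma = NULL, delay = 0) {
  check_positive(f0, "f0")
  if (!is.null(n_cycles)) fwhm <- n_cycles / f0
  if (is.null(sigma)) sigma <- fwhm_to_sigma(fwhm)
  check_positive(sigma, "sigma")
  check_nonnegative(amplitude, "amplitude")
  structure(list(amplitude = amplitude, f0 = f0, sigma = sigma,
                 fwhm = sigma_to_fwhm(sigma), delay = delay),
            class = "hfo_params")
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name),
          class = "tfhfo_parameter_error")
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative finite number.", name),
          class = "tfhfo_parameter_error")
  }
  invisible(x)
}

#' Analytic waveforms of the spike/HFO model
#'
#' Closed-form time-domain waveforms evaluated on a caller-supplied time
#' grid (seconds). `spike_waveform()` is the Gaussian spike,
#' `hfo_waveform()` the Gaussian-envelope sinusoid (with its envelope-center
#' delay applied), and `combined_waveform()` their elementwise sum — an HFO
#' riding on a spike.
#'
#' @param t Numeric vector of times (s); must be finite.
#' @param params,spike,hfo Parameter objects from [spike_params()] /
#'   [hfo_params()].
#' @return Numeric vector of amplitudes (au), same length as `t`.
#' @examples
#' t <- seq(-0.2, 0.2, by = 5e-4)
#' x <- combined_waveform(t, spike_params(), hfo_params(delay = 0.015))
#' @export
spike_waveform <- function(t, params = spike_params()) {
  stopifnot(inherits(params, "spike_params"))
  check_time_grid(t)
  params$amplitude * exp(-t^2 / (2 * params$sigma^2))
}

#' @rdname spike_waveform
#' @export
hfo_waveform <- function(t, params = hfo_params()) {
  stopifnot(inherits(params, "hfo_params"))
  check_time_grid(t)
  ts <- t + params$delay
  params$amplitude * exp(-ts^2 / (2 * params$sigma^2)) *
    cos(2 * pi * params$f0 * ts)
}

#' @rdname spike_waveform
#' @export
combined_waveform <- function(t, spike = spike_params(), hfo = hfo_params()) {
  spike_waveform(t, spike) + hfo_waveform(t, hfo)
}

check_time_grid <- function(t) {
  if (!is.numeric(t) || !all(is.finite(t))) {
    abort("The evaluation grid must be numeric and finite.",
          class = "tfhfo_input_error")
  }
  invisible(t)
}

#' Analytic one-sided amplitude spectra of the model
#'
#' Closed-form magnitude spectra of the model waveforms, evaluated on a
#' caller-supplied frequency grid (Hz). The Fourier transform of a Gaussian
#' envelope is again a Gaussian; by the modulation theorem the HFO spectrum
#' is a Gaussian of weight `A * sqrt(pi / 2) * sigma` centered at the
#' carrier `f0`, and the spike contributes a zero-centered Gaussian of
#' weight `A * sqrt(2 * pi) * sigma`. Only magnitudes are modeled (one-sided
#' amplitude spectral density); the envelope delay affects phase only and
#' therefore does not appear.
#'
#' @param f Numeric vector of frequencies (Hz); must be finite.
#' @param params,spike,hfo Parameter objects from [spike_params()] /
#'   [hfo_params()].
#' @return Numeric vector of spectral amplitudes (au x s), same length as
#'   `f`.
#' @examples
#' f <- seq(0, 300, by = 0.5)
#' y <- combined_spectrum(f, spike_params(), hfo_params())
#' f[which.max(y)] # 0: the spike dominates at DC
#' @export
hfo_spectrum <- function(f, params = hfo_params()) {
  stopifnot(inherits(params, "hfo_params"))
  check_time_grid(f)
  params$amplitude * sqrt(pi / 2) * params$sigma *
    exp(-2 * pi^2 * params$sigma^2 * (f - params$f0)^2)
}

#' @rdname hfo_spectrum
#' @export
combined_spectrum <- function(f, spike = spike_params(), hfo = hfo_params()) {
  stopifnot(inherits(spike, "spike_params"))
  check_time_grid(f)
  spike_term <- spike$amplitude * sqrt(2 * pi) * spike$sigma *
    exp(-2 * pi^2 * spike$sigma^2 * f^2)
  spike_term + hfo_spectrum(f, hfo)
}

#' Demonstration waveform and spectrum of the canonical model event
#'
#' Evaluates the canonical spike + HFO event (2.5-au spike of 50-ms FWHM;
#' 1-au, 100-Hz HFO with four cycles in its 40-ms FWHM, delayed by 15 ms)
#' on dense grids. Useful for plotting and as the demo output of the
#' command-line interface.
#'
#' @param spike,hfo Parameter objects; defaults are the canonical event.
#' @return A list with tibbles `waveform` (`t_s`, `spike`, `hfo`,
#'   `combined`) and `spectrum` (`f_hz`, `spike`, `hfo`, `combined`).
#' @export
model_demo <- function(spike = spike_params(amplitude = 2.5, fwhm = 0.05),
                       hfo = hfo_params(amplitude = 1, f0 = 100,
                                        n_cycles = 4, delay = 0.015)) {
  t <- seq(-0.25, 0.25, by = 1 / 5000)
  f <- seq(0, 300, by = 0.25)
  w_spike <- spike_waveform(t, spike)
  w_hfo <- hfo_waveform(t, hfo)
  list(
    waveform = tibble(
      t_s = t,
      spike = w_spike,
      hfo = w_hfo,
      combined = w_spike + w_hfo
    ),
    spectrum = {
      s_spike <- spike$amplitude * sqrt(2 * pi) * spike$sigma *
        exp(-2 * pi^2 * spike$sigma^2 * f^2)
      s_hfo <- hfo_spectrum(f, hfo)
      tibble(f_hz = f, spike = s_spike, hfo = s_hfo,
             combined = s_spike + s_hfo)
    }
  )
}
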