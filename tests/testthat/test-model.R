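test_that("spike waveform matches the Gaussian closed form", {
  p <- spike_params(amplitude = 2.5, fwhm = 0.05)
  expect_equal(spike_waveform(0, p), 2.5)
  # half maximum at half the FWHM
  expect_equal(spike_waveform(0.025, p), 1.25)
  expect_equal(spike_waveform(-0.025, p), 1.25)
  # even in t, vanishing tails
  t <- seq(-0.3, 0.3, by = 1e-3)
  expect_equal(spike_waveform(t, p), rev(spike_waveform(t, p)))
  expect_lt(spike_waveform(10, p), 1e-12)
  expect_error(spike_params(sigma = -1), class = "tfhfo_parameter_error")
})

test_that("fwhm/sigma conversion round-trips to machine precision", {
  for (fwhm in c(1e-3, 0.04, 0.05, 2)) {
    expect_identical(sigma_to_fwhm(fwhm_to_sigma(fwhm)), fwhm)
  }
})

test_that("HFO waveform has envelope peak, zero crossings and bound", {
  p <- hfo_params(amplitude = 1, f0 = 100, fwhm = 0.04, delay = 0)
  expect_equal(hfo_waveform(0, p), 1)
  # quarter-period zero crossing at 2.5 ms for 100 Hz
  expect_equal(hfo_waveform(0.0025, p), 0, tolerance = 1e-12)
  t <- seq(-0.5, 0.5, by = 1e-4)
  expect_true(all(abs(hfo_waveform(t, p)) <= 1 + 1e-12))
  # envelope-center delay shifts the peak to t = -delay
  pd <- hfo_params(amplitude = 1, f0 = 100, n_cycles = 4, delay = 0.015)
  expect_equal(hfo_waveform(-0.015, pd), 1)
  # four oscillations inside the FWHM: 4 carrier periods span the FWHM
  expect_equal(pd$fwhm * pd$f0, 4)
  expect_error(hfo_params(f0 = -5), class = "tfhfo_parameter_error")
})

test_that("combined waveform is the elementwise sum and peaks near 3.3 au", {
  sp <- spike_params(amplitude = 2.5, fwhm = 0.05)
  hp <- hfo_params(amplitude = 1, f0 = 100, n_cycles = 4, delay = 0.015)
  t <- seq(-0.25, 0.25, by = 1e-5)
  expect_equal(combined_waveform(t, sp, hp),
               spike_waveform(t, sp) + hfo_waveform(t, hp))
  # additive identities
  expect_equal(combined_waveform(t, spike_params(amplitude = 0), hp),
               hfo_waveform(t, hp))
  expect_equal(combined_waveform(t, sp, hfo_params(amplitude = 0)),
               spike_waveform(t, sp))
  # dense-grid peak of the canonical event (frozen from direct evaluation)
  peak <- max(combined_waveform(t, sp, hp))
  expect_equal(peak, 3.2725, tolerance = 1e-3)
  expect_lt(abs(t[which.max(combined_waveform(t, sp, hp))]), 0.01)
})

test_that("closed-form HFO spectrum agrees with the FFT oracle", {
  hp <- hfo_params(amplitude = 1, f0 = 100, n_cycles = 4, delay = 0)
  # value at the center and symmetry about f0
  expect_equal(hfo_spectrum(100, hp), sqrt(pi / 2) * hp$sigma)
  expect_equal(hfo_spectrum(100 + 7, hp), hfo_spectrum(100 - 7, hp))
  fs <- 20000
  t <- seq(-2, 2 - 1 / fs, by = 1 / fs)
  or <- fft_spectrum_oracle(hfo_waveform(t, hp), fs)
  i0 <- which.min(abs(or$f - 100))
  expect_lt(abs(or$amp[i0] - hfo_spectrum(or$f[i0], hp)) /
              hfo_spectrum(100, hp), 0.01)
  # whole-curve agreement near the peak
  sel <- abs(or$f - 100) < 30
  expect_lt(max(abs(or$amp[sel] - hfo_spectrum(or$f[sel], hp))) /
              hfo_spectrum(100, hp), 0.01)
})

test_that("combined spectrum has the spike Gaussian plus the HFO bump", {
  sp <- spike_params(amplitude = 2.5, fwhm = 0.05)
  hp <- hfo_params(amplitude = 1, f0 = 100, n_cycles = 4, delay = 0.015)
  f <- seq(0, 300, by = 0.25)
  y <- combined_spectrum(f, sp, hp)
  # spike-only: maximal at f = 0
  y0 <- combined_spectrum(f, sp, hfo_params(amplitude = 1e-300))
  expect_equal(which.max(y0), 1L)
  expect_equal(y0[1], 2.5 * sqrt(2 * pi) * sp$sigma, tolerance = 1e-6)
  # second local maximum at the carrier
  local_max <- which(diff(sign(diff(y))) == -2) + 1
  expect_true(any(abs(f[local_max] - 100) <= 0.5))
  # FFT oracle on the full signal; the delay must not change magnitudes
  fs <- 20000
  t <- seq(-2, 2 - 1 / fs, by = 1 / fs)
  or <- fft_spectrum_oracle(combined_waveform(t, sp, hp), fs)
  sel <- or$f > 70 & or$f < 130
  pred <- combined_spectrum(or$f[sel], sp, hp)
  expect_lt(max(abs(or$amp[sel] - pred)) / max(pred), 0.01)
})

test_that("time delay leaves the spectrum magnitude unchanged", {
  fs <- 20000
  t <- seq(-2, 2 - 1 / fs, by = 1 / fs)
  a <- fft_spectrum_oracle(
    hfo_waveform(t, hfo_params(f0 = 120, n_cycles = 5, delay = 0)), fs)
  b <- fft_spectrum_oracle(
    hfo_waveform(t, hfo_params(f0 = 120, n_cycles = 5, delay = 0.015)), fs)
  sel <- a$f > 80 & a$f < 160
  expect_equal(a$amp[sel], b$amp[sel], tolerance = 1e-6)
})

test_that("analytic spectrum integrates like the FFT spectrum", {
  hp <- hfo_params(amplitude = 1, f0 = 150, n_cycles = 6, delay = 0)
  fs <- 20000
  t <- seq(-2, 2 - 1 / fs, by = 1 / fs)
  or <- fft_spectrum_oracle(hfo_waveform(t, hp), fs)
  sel <- or$f > 50 & or$f < 250
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(trap(or$f[sel], or$amp[sel]),
               trap(or$f[sel], hfo_spectrum(or$f[sel], hp)),
               tolerance = 0.01)
})
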