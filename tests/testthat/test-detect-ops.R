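test_that("initial threshold is the baseline RMS with degenerate fallbacks", {
  fs <- 1000
  cfg <- detector_config(baseline_s = 15)
  # constant signal -> |c|
  s <- eeg_signal(rep(-0.7, 20 * fs), fs)
  expect_equal(initial_threshold(s, cfg), 0.7)
  # unit sinewave -> 1/sqrt(2)
  t <- seq(0, 20, by = 1 / fs)
  expect_equal(initial_threshold(eeg_signal(sin(2 * pi * 5 * t), fs), cfg),
               1 / sqrt(2), tolerance = 1e-3)
  # two-pass oracle on a pink-noise fixture
  pn <- generate_pink_noise(20, fs, seed = 9)
  x <- pn$samples[1:(15 * fs)]
  mu <- mean(x)
  expect_equal(initial_threshold(pn, cfg),
               sqrt(mu^2 + mean((x - mu)^2)), tolerance = 1e-12)
  # short signal warns and uses everything
  expect_warning(initial_threshold(eeg_signal(rnorm(100), fs), cfg),
                 "baseline")
  # all-zero baseline warns and degrades to machine epsilon
  expect_warning(
    thr <- initial_threshold(eeg_signal(rep(0, 16 * fs), fs), cfg),
    "epsilon")
  expect_equal(thr, .Machine$double.eps)
})

test_that("threshold schedule is the stated geometric progression", {
  s <- threshold_schedule(1, 15, 0.8)
  expect_length(s, 15)
  expect_equal(s[1], 1)
  expect_equal(s[2], 0.8)
  expect_equal(s, 0.8^(0:14))
  expect_true(all(diff(s) < 0))
})

test_that("intensity cutoff and saturation behave and are monotone", {
  set.seed(2)
  m <- matrix(abs(rnorm(300)), 15, 20)
  # cutoff: zero below, identity above
  cut <- apply_intensity_threshold(m, 0.5)
  expect_true(all(cut[m < 0.5] == 0))
  expect_equal(cut[m >= 0.5], m[m >= 0.5])
  # lower level keeps a superset of pixels
  expect_true(all((apply_intensity_threshold(m, 0.2) > 0) >=
                    (cut > 0)))
  # saturation clip: identity above max, zero level flattens, monotone
  expect_equal(saturate_image(m, max(m) + 1), m)
  expect_true(all(saturate_image(m, 0) == 0))
  expect_true(all(saturate_image(m, 0.3) <= saturate_image(m, 0.6)))
})

test_that("border clearing removes border-attached structure only", {
  img <- matrix(0, 20, 30)
  img[8:12, 10:14] <- 5          # interior blob
  out <- clear_border_structures(img)
  expect_equal(out, img)          # preserved exactly on zero background
  # border-attached ridge removed
  img2 <- img
  img2[1:20, 3] <- 4
  out2 <- clear_border_structures(img2)
  expect_true(all(out2[, 3] == 0))
  expect_equal(out2[8:12, 10:14], img[8:12, 10:14])
  # uniform image flattens (no structure survives)
  expect_true(all(clear_border_structures(matrix(2, 10, 10)) ==
                    clear_border_structures(matrix(2, 10, 10))[1, 1]))
  # interior peak on a raised background survives as residual
  img3 <- matrix(1, 15, 15)
  img3[7:9, 7:9] <- 3
  out3 <- clear_border_structures(img3)
  expect_equal(out3[8, 8], 2)     # peak minus background floor
  expect_true(all(out3[1, ] == 0))
})

test_that("grayscale reconstruction matches a brute-force iterate", {
  set.seed(4)
  mask <- matrix(abs(rnorm(150)), 10, 15)
  marker <- pmin(mask, quantile(mask, 0.3))
  rec <- tfhfo:::cpp_reconstruct_dilate(marker, mask)
  # brute force: iterate dilation-then-clip to a fixed point
  dil <- function(m) {
    out <- m
    nr <- nrow(m)
    nc <- ncol(m)
    for (dr in -1:1) for (dc in -1:1) {
      sh <- matrix(-Inf, nr, nc)
      rr <- which(seq_len(nr) + dr >= 1 & seq_len(nr) + dr <= nr)
      cc <- which(seq_len(nc) + dc >= 1 & seq_len(nc) + dc <= nc)
      sh[rr, cc] <- m[rr + dr, cc + dc]
      out <- pmax(out, sh)
    }
    out
  }
  J <- marker
  repeat {
    J2 <- pmin(dil(J), mask)
    if (identical(J2, J)) break
    J <- J2
  }
  expect_equal(rec, J)
  expect_true(all(rec >= marker - 1e-12) && all(rec <= mask + 1e-12))
})

test_that("Otsu threshold equals the exhaustive-search oracle", {
  set.seed(3)
  for (i in 1:6) {
    img <- matrix(c(rnorm(400, 0, 0.2), rnorm(100 * i, 3, 0.5)),
                  ncol = 20)[1:20, , drop = FALSE]
    expect_identical(otsu_threshold(img), otsu_oracle(img))
  }
  # two-valued image: mask recovers the 1s
  tv <- matrix(rep(c(0, 1), each = 50), 10, 10)
  expect_identical(otsu_binarize(tv), tv == 1)
  # constant image: empty mask
  expect_true(all(!otsu_binarize(matrix(4, 8, 8))))
})

test_that("blob labeling matches the flood-fill oracle on random masks", {
  set.seed(6)
  for (p in c(0.1, 0.3, 0.5)) {
    for (rep in 1:4) {
      mask <- matrix(runif(32 * 32) < p, 32, 32)
      lab <- tfhfo:::cpp_label_blobs(mask)
      expect_identical(attr(lab, "n"), flood_fill_count(mask))
    }
  }
})

test_that("blob analysis returns centroids, boxes and amplitudes", {
  freqs <- seq(10, 100, by = 10)
  times <- seq(0, 0.9, by = 0.1)
  co <- matrix(0, 10, 10)
  co[4:6, 4:6] <- 2
  map <- tfhfo:::new_tf_map(times, freqs, co)
  mask <- co > 0
  b <- blob_analysis(mask, map)
  expect_equal(nrow(b), 1L)
  expect_equal(b$t_center_s, times[5])
  expect_equal(b$f_center_hz, freqs[5])
  expect_equal(b$t_start_s, times[4])
  expect_equal(b$t_end_s, times[6])
  expect_equal(b$amplitude_au, 2)
  # two diagonally-touching pixels form one blob under 8-connectivity
  m2 <- matrix(FALSE, 10, 10)
  m2[3, 3] <- m2[4, 4] <- TRUE
  expect_equal(nrow(blob_analysis(m2, map)), 1L)
  # empty mask -> empty tibble
  expect_equal(nrow(blob_analysis(matrix(FALSE, 10, 10), map)), 0L)
})

test_that("C_thresh averages the quiet columns with fallback to the level", {
  freqs <- seq(80, 100, by = 2)
  times <- seq(0, 0.9, length.out = 20)
  co <- matrix(0.4, length(freqs), 20)
  map <- tfhfo:::new_tf_map(times, freqs, co)
  cfg <- detector_config()
  # uniform sub-level map -> its own value
  expect_equal(compute_cthresh(map, 1, cfg), 0.4)
  # no quiet column -> the level itself
  expect_equal(compute_cthresh(map, 0.1, cfg), 0.1)
  # loud columns are excluded from the average
  co2 <- co
  co2[3, 1:5] <- 2
  map2 <- tfhfo:::new_tf_map(times, freqs, co2)
  expect_equal(compute_cthresh(map2, 1, cfg), 0.4)
  # noise-only map: close to the plain band mean
  set.seed(8)
  pn <- generate_pink_noise(1, 2000, seed = 8)
  m <- tf_cwt(pn)
  rows <- m$freqs >= 80 & m$freqs <= 100
  lvl <- max(m$coeffs[rows, ]) * 1.01
  expect_equal(compute_cthresh(m, lvl, cfg), mean(m$coeffs[rows, ]))
})

test_that("validation applies the three criteria with strict inequalities", {
  cfg <- detector_config(n_osc = 4.5, amp_factor = 3.5)
  blob <- tibble::tibble(t_center_s = 0.5, f_center_hz = 100,
                         t_start_s = 0.475, t_end_s = 0.525,
                         f_low_hz = 90, f_high_hz = 110,
                         amplitude_au = 1, area_px = 50)
  # 50 ms at 100 Hz passes the duration bound of 45 ms
  expect_true(validate_candidate(blob, 0.1, cfg)$accepted)
  # out-of-band frequency
  b2 <- blob
  b2$f_center_hz <- 70
  expect_equal(validate_candidate(b2, 0.1, cfg)$reason, "frequency")
  # duration exactly at the bound fails (strict)
  b3 <- blob
  b3$t_start_s <- 0
  b3$t_end_s <- 4.5 / 100
  expect_equal(validate_candidate(b3, 0.1, cfg)$reason, "duration")
  # amplitude exactly 3.5 * C_thresh fails (strict)
  expect_equal(validate_candidate(blob, 1 / 3.5, cfg)$reason, "amplitude")
  expect_true(validate_candidate(blob, 1 / 3.5 - 1e-9, cfg)$accepted)
})

test_that("deduplication flags boxes containing earlier centroids", {
  acc <- tibble::tibble(t_center_s = 0.5, f_center_hz = 100)
  inside <- tibble::tibble(t_start_s = 0.4, t_end_s = 0.6,
                           f_low_hz = 80, f_high_hz = 120)
  outside <- tibble::tibble(t_start_s = 0.7, t_end_s = 0.9,
                            f_low_hz = 80, f_high_hz = 120)
  expect_true(is_duplicate(inside, acc))
  expect_false(is_duplicate(outside, acc))
  expect_false(is_duplicate(inside, acc[0, ]))
  # engulfing box at a lower threshold is still a duplicate
  big <- tibble::tibble(t_start_s = 0, t_end_s = 1,
                        f_low_hz = 40, f_high_hz = 500)
  expect_true(is_duplicate(big, acc))
})
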