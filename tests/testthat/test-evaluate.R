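mk_events <- function(t, f, amp = 1) {
  tibble::tibble(channel = "x", t_center_s = t, f_center_hz = f,
                 t_start_s = t - 0.02, t_end_s = t + 0.02,
                 f_low_hz = f - 10, f_high_hz = f + 10,
                 duration_ms = 40, amplitude_au = amp,
                 threshold_level = 1L, band = "ripple")
}

test_that("nearby detections merge transitively and idempotently", {
  tol <- match_tolerance(0.05, 5)
  # 10 ms / 2 Hz apart -> one event
  ev <- mk_events(c(0.5, 0.51), c(100, 102), amp = c(1, 3))
  m <- merge_nearby_detections(ev, tol)
  expect_equal(nrow(m), 1L)
  # amplitude-weighted centroid, box union, max amplitude
  expect_equal(m$t_center_s, (0.5 * 1 + 0.51 * 3) / 4)
  expect_equal(m$f_center_hz, (100 * 1 + 102 * 3) / 4)
  expect_equal(m$t_start_s, 0.48)
  expect_equal(m$t_end_s, 0.53)
  expect_equal(m$amplitude_au, 3)
  # 200 ms apart -> two events
  ev2 <- mk_events(c(0.5, 0.7), c(100, 100))
  expect_equal(nrow(merge_nearby_detections(ev2, tol)), 2L)
  # idempotence on a chained cluster plus singletons
  ev3 <- mk_events(c(0.5, 0.54, 0.58, 0.9), c(100, 103, 106, 200))
  m3 <- merge_nearby_detections(ev3, tol)
  m33 <- merge_nearby_detections(m3, tol)
  expect_equal(as.data.frame(m3), as.data.frame(m33))
})

test_that("matching is one-to-one, tolerance-bounded and oracle-optimal", {
  tol <- match_tolerance(0.05, 5)
  truth <- tibble::tibble(t_center_s = c(0.5, 1.5, 2.5),
                          f0_hz = c(100, 150, 200))
  # exact hit: zero errors
  m <- match_events(mk_events(0.5, 100), truth, tol)
  expect_equal(m$tp, 1L)
  expect_equal(m$errors$dt_s, 0)
  expect_equal(m$errors$df_hz, 0)
  expect_equal(sort(m$fn), c(2L, 3L))
  # 60 ms off -> FP
  m2 <- match_events(mk_events(0.56, 100), truth, tol)
  expect_length(m2$tp, 0L)
  expect_equal(m2$fp, 1L)
  # error sign convention: truth minus detection
  m3 <- match_events(mk_events(0.52, 103), truth, tol)
  expect_equal(m3$errors$dt_s, -0.02)
  expect_equal(m3$errors$df_hz, -3)
  # greedy assignment matches the exhaustive oracle on a 10-event toy set
  set.seed(12)
  tt <- tibble::tibble(t_center_s = seq(0.5, 9.5, by = 1) +
                         runif(10, -0.02, 0.02),
                       f0_hz = runif(10, 90, 240))
  dd <- mk_events(tt$t_center_s + runif(10, -0.03, 0.03),
                  tt$f0_hz + runif(10, -4, 4))
  dd <- dd[sample(10), ]
  got <- match_events(dd, tt, tol)
  oracle <- assignment_oracle(tt, dd, tol)
  expect_equal(length(got$tp), oracle$n)
  # enlarging the tolerance never decreases TP
  wider <- match_events(dd, tt, match_tolerance(0.1, 10))
  expect_gte(length(wider$tp), length(got$tp))
})

test_that("metrics reproduce the counts identity and reference arithmetic", {
  # the -9 dB reference column: 193 TP, 7 FP out of 300 truths
  p <- performance_from_counts(193, 7, 300)
  expect_equal(p$ppv, 0.965)
  expect_equal(p$sensitivity, 193 / 300)
  expect_equal(round(p$sensitivity, 3), 0.643)
  expect_equal(round(p$f_measure, 3), 0.772)
  expect_equal(p$tp + p$fn, p$n_truth)
  # degenerate zero case
  z <- performance_from_counts(0, 0, 300)
  expect_equal(c(z$ppv, z$sensitivity, z$f_measure), c(0, 0, 0))
  # perfect case
  one <- performance_from_counts(300, 0, 300)
  expect_equal(one$f_measure, 1)
  # F is the harmonic mean: symmetric and below the arithmetic mean
  p2 <- performance_from_counts(150, 50, 300)
  expect_equal(p2$f_measure,
               2 * p2$ppv * p2$sensitivity / (p2$ppv + p2$sensitivity))
  expect_lte(p2$f_measure, (p2$ppv + p2$sensitivity) / 2)
})

test_that("evaluation conserves events and tidies into tibbles", {
  tol <- match_tolerance()
  truth <- tibble::tibble(t_center_s = c(0.5, 1.5, 2.5, 3.5),
                          f0_hz = c(100, 150, 200, 120))
  ev <- mk_events(c(0.5, 1.51, 9.0), c(101, 149, 100))
  rep <- evaluate_detections(ev, truth, tol)
  expect_equal(rep$tp + rep$fn, rep$n_truth)
  expect_equal(rep$tp + rep$fp, nrow(ev))
  g <- glance(rep)
  expect_s3_class(g, "tbl_df")
  expect_equal(nrow(g), 1L)
  expect_equal(g$tp, 2L)
  expect_equal(g$fp, 1L)
  td <- tidy(rep)
  expect_equal(nrow(td), 2L)
  expect_named(td, c("event_index", "detection_index", "dt_s", "df_hz"))
})
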