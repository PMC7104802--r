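#' Detector configuration
#'
#' Collects all tunable parameters of the time-frequency computer-vision
#' detector. Defaults are the ripple-band operating point: 1-s analysis
#' windows with 200-ms overlap, an initial intensity threshold equal to the
#' RMS of the first 15 s of the raw channel, a geometric schedule of 15
#' saturation levels with common ratio 0.8, a validated band of 80-250 Hz,
#' a minimum of 4.5 oscillations within the blob duration, and an amplitude
#' criterion of 3.5 times the sub-threshold 80-100-Hz coefficient mean
#' (C_thresh). For fast ripples set `band = c(250, 500)`.
#'
#' @param window_s Analysis window length (s).
#' @param overlap_s Overlap between consecutive windows (s); must be
#'   positive and smaller than `window_s`.
#' @param n_thresholds Number of saturation levels in the schedule (>= 1).
#' @param threshold_ratio Common ratio of the geometric schedule (0-1).
#' @param baseline_s Duration of the initial-threshold baseline (s).
#' @param band Length-2 numeric, validated frequency band (Hz),
#'   `band[1] < band[2]`.
#' @param n_osc Minimum number of oscillations at the blob's centroid
#'   frequency that its duration must exceed.
#' @param amp_factor Amplitude criterion multiplier on C_thresh.
#' @param cthresh_band Length-2 numeric (Hz): rows used for the C_thresh
#'   reference mean.
#' @param morlet A [morlet_params] object controlling the transform.
#' @param time_decimation Integer >= 1: the detection image keeps every
#'   `time_decimation`-th map column (default 2, i.e. 1-ms pixels at
#'   2 kHz). Blob centroids remain sub-pixel; coarser pixels speed the
#'   image morphology with no practical loss against the 50-ms matching
#'   tolerance.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(window_s = 1.0, overlap_s = 0.2,
                            n_thresholds = 15, threshold_ratio = 0.8,
                            baseline_s = 15, band = c(80, 250),
                            n_osc = 4.5, amp_factor = 3.5,
                            cthresh_band = c(80, 100),
                            morlet = morlet_params(),
                            time_decimation = 2) {
  if (!(overlap_s > 0 && overlap_s < window_s)) {
    abort("`overlap_s` must satisfy 0 < overlap_s < window_s.",
          class = "tfhfo_parameter_error")
  }
  if (!(threshold_ratio > 0 && threshold_ratio < 1)) {
    abort("`threshold_ratio` must lie strictly between 0 and 1.",
          class = "tfhfo_parameter_error")
  }
  if (n_thresholds < 1) {
    abort("`n_thresholds` must be >= 1.", class = "tfhfo_parameter_error")
  }
  if (length(band) != 2L || band[1] >= band[2]) {
    abort("`band` must be c(low, high) with low < high.",
          class = "tfhfo_parameter_error")
  }
  check_positive(n_osc, "n_osc")
  check_positive(amp_factor, "amp_factor")
  structure(list(window_s = window_s, overlap_s = overlap_s,
                 n_thresholds = as.integer(n_thresholds),
                 threshold_ratio = threshold_ratio, baseline_s = baseline_s,
                 band = as.numeric(band), n_osc = n_osc,
                 amp_factor = amp_factor,
                 cthresh_band = as.numeric(cthresh_band), morlet = morlet,
                 time_decimation = max(1L, as.integer(time_decimation))),
            class = "detector_config")
}

band_label <- function(config) {
  if (config$band[2] <= 250) "ripple" else "fast_ripple"
}

#' Initial intensity threshold from the raw channel baseline
#'
#' The starting point of the saturation-level schedule is the root mean
#' square of the first `baseline_s` seconds of the raw signal, adapting the
#' schedule to the channel's overall amplitude. Shorter signals use the
#' full signal (with a warning); an all-zero baseline degrades to machine
#' epsilon (with a warning).
#'
#' @param signal An [eeg_signal].
#' @param config A [detector_config].
#' @return The threshold (au), a single number.
#' @export
initial_threshold <- function(signal, config = detector_config()) {
  stopifnot(is_signal(signal))
  n_base <- round(config$baseline_s * signal$sampling_rate)
  if (length(signal$samples) < n_base) {
    warn(sprintf(
      "Signal shorter than the %g-s baseline; using the full signal for the initial threshold.",
      config$baseline_s))
    n_base <- length(signal$samples)
  }
  x <- signal$samples[seq_len(n_base)]
  thr <- sqrt(mean(x^2))
  if (thr == 0) {
    warn("Degenerate (all-zero) baseline; initial threshold set to machine epsilon.")
    thr <- .Machine$double.eps
  }
  thr
}

#' Geometric schedule of saturation levels
#'
#' `thresh_i = ratio^(i-1) * thresh0` for `i = 1..n`: a strictly decreasing
#' geometric progression starting at the initial threshold.
#'
#' @param thresh0 Initial threshold (au).
#' @param n_thresholds Number of levels.
#' @param ratio Common ratio (0-1).
#' @return Numeric vector of length `n_thresholds`.
#' @examples
#' threshold_schedule(1, 15, 0.8)
#' @export
threshold_schedule <- function(thresh0, n_thresholds = 15, ratio = 0.8) {
  thresh0 * ratio^(seq_len(n_thresholds) - 1)
}

map_or_matrix <- function(x) {
  if (inherits(x, "tf_map")) x$coeffs else x
}

rewrap <- function(x, template) {
  if (inherits(template, "tf_map")) {
    new_tf_map(template$times, template$freqs, x)
  } else {
    x
  }
}

#' Apply an intensity threshold to a time-frequency image
#'
#' The detection pipeline's per-level thresholding: pixels below `level`
#' are set to zero while pixels at or above it keep their grayscale value.
#' High levels of the schedule retain only the strongest structures;
#' descending levels progressively reveal fainter high-frequency blobs
#' that would otherwise be shadowed by stronger low-frequency energy.
#'
#' @param map A `tf_map` or bare numeric matrix.
#' @param level Intensity level (au).
#' @return Same type as `map`.
#' @export
apply_intensity_threshold <- function(map, level) {
  m <- map_or_matrix(map)
  rewrap(ifelse(m >= level, m, 0), map)
}

#' Saturate (clip) a time-frequency image at an intensity level
#'
#' Display-style saturation: coefficients at or above `level` are set to
#' `level`, flattening strong low-frequency energy so fainter
#' high-frequency structure becomes visible. Useful for inspection plots;
#' the detection pipeline itself uses [apply_intensity_threshold()].
#'
#' @param map A `tf_map` or bare numeric matrix.
#' @param level Saturation level (au).
#' @return Same type as `map`, clipped.
#' @export
saturate_image <- function(map, level) {
  m <- map_or_matrix(map)
  rewrap(pmin(m, level), map)
}

#' Suppress bright structures connected to the image border
#'
#' Removes every connected bright structure that touches any border of the
#' image using grayscale morphological reconstruction by dilation from a
#' border-seeded marker; the reconstruction is subtracted so that
#' border-connected structures drop to zero while interior isolated maxima
#' survive as residuals above their surrounding background level. On
#' time-frequency maps this discards wavelet edge artifacts at the window
#' extremities and the low-frequency energy attached to the bottom of the
#' image.
#'
#' @param image A `tf_map` or numeric matrix.
#' @return Same type as `image`.
#' @export
clear_border_structures <- function(image) {
  m <- map_or_matrix(image)
  rewrap(cpp_clear_border(m), image)
}

#' Otsu threshold and binarization
#'
#' Computes the threshold maximizing the between-class variance over a
#' 256-bin histogram of the image, then returns the mask `image >
#' threshold`. A constant image yields an all-`FALSE` mask
#' (`otsu_threshold()` returns `NA`).
#'
#' @param image A `tf_map` or numeric matrix.
#' @return `otsu_threshold()`: a single number (or `NA`).
#'   `otsu_binarize()`: a logical matrix of the image's dimensions.
#' @export
otsu_threshold <- function(image) {
  cpp_otsu_threshold(map_or_matrix(image))
}

#' @rdname otsu_threshold
#' @export
otsu_binarize <- function(image) {
  m <- map_or_matrix(image)
  thr <- cpp_otsu_threshold(m)
  if (is.na(thr)) {
    matrix(FALSE, nrow(m), ncol(m))
  } else {
    m > thr
  }
}

#' Connected-component blob analysis of a binary mask
#'
#' Labels 8-connected components of `mask` and summarizes each as a blob:
#' unweighted area centroid and bounding box in pixel coordinates,
#' converted to seconds and Hz through the map's grids, with the blob
#' amplitude sampled from the grayscale map at the pixel nearest the
#' centroid.
#'
#' @param mask Logical matrix (frequencies x times).
#' @param map The `tf_map` the mask was derived from.
#' @return A tibble with one row per blob: `t_center_s`, `f_center_hz`,
#'   `t_start_s`, `t_end_s`, `f_low_hz`, `f_high_hz`, `amplitude_au`,
#'   `area_px`.
#' @export
blob_analysis <- function(mask, map) {
  stopifnot(inherits(map, "tf_map"),
            nrow(mask) == length(map$freqs),
            ncol(mask) == length(map$times))
  lab <- cpp_label_blobs(mask)
  st <- cpp_blob_stats(lab, attr(lab, "n"))
  blobs_to_tibble(st, map)
}

# Shared pixel -> (s, Hz) conversion for blob stat matrices
# (columns: area, row_centroid, col_centroid, row_min, row_max, col_min,
# col_max; 1-based pixels, rows index frequency, columns index time).
blobs_to_tibble <- function(st, map) {
  if (nrow(st) == 0L) {
    return(tibble(t_center_s = numeric(), f_center_hz = numeric(),
                  t_start_s = numeric(), t_end_s = numeric(),
                  f_low_hz = numeric(), f_high_hz = numeric(),
                  amplitude_au = numeric(), area_px = numeric()))
  }
  grid_at <- function(grid, idx) {
    approx(seq_along(grid), grid, xout = idx, rule = 2)$y
  }
  r_near <- pmin(pmax(round(st[, 2]), 1), length(map$freqs))
  c_near <- pmin(pmax(round(st[, 3]), 1), length(map$times))
  tibble(
    t_center_s = grid_at(map$times, st[, 3]),
    f_center_hz = grid_at(map$freqs, st[, 2]),
    t_start_s = map$times[st[, 6]],
    t_end_s = map$times[st[, 7]],
    f_low_hz = map$freqs[st[, 4]],
    f_high_hz = map$freqs[st[, 5]],
    amplitude_au = map$coeffs[cbind(r_near, c_near)],
    area_px = st[, 1]
  )
}

#' Sub-threshold in-band coefficient mean (C_thresh)
#'
#' The amplitude reference of the validation step: the mean of wavelet
#' coefficients in the `cthresh_band` rows (default 80-100 Hz), computed
#' over the quiet time intervals — the columns whose in-band coefficients
#' all lie below the current intensity level. Restricting to quiet columns
#' makes C_thresh a background-amplitude estimate that excludes the events
#' under test. If no column qualifies the level itself is returned
#' (conservative fallback).
#'
#' @param map A `tf_map`.
#' @param level Current intensity level (au).
#' @param config A [detector_config].
#' @return C_thresh (au), a single number.
#' @export
compute_cthresh <- function(map, level, config = detector_config()) {
  stopifnot(inherits(map, "tf_map"))
  rows <- which(map$freqs >= config$cthresh_band[1] &
                  map$freqs <= config$cthresh_band[2])
  if (length(rows) == 0L) {
    abort("The C_thresh band contains no frequency-grid rows.",
          class = "tfhfo_parameter_error")
  }
  v <- map$coeffs[rows, , drop = FALSE]
  quiet <- apply(v, 2, max) < level
  if (!any(quiet)) level else mean(v[, quiet])
}

#' Validate an HFO candidate blob
#'
#' A blob is accepted as an HFO when (1) its centroid frequency lies
#' strictly inside the configured band, (2) its duration (bounding-box
#' width) strictly exceeds `n_osc` oscillation periods at the centroid
#' frequency, and (3) its centroid amplitude strictly exceeds
#' `amp_factor * c_thresh`. The first failed criterion is reported.
#'
#' @param blob A one-row tibble as produced by [blob_analysis()].
#' @param c_thresh Amplitude reference from [compute_cthresh()].
#' @param config A [detector_config].
#' @return A list with `accepted` (logical) and `reason` (`NA` when
#'   accepted, otherwise `"frequency"`, `"duration"` or `"amplitude"`).
#' @export
validate_candidate <- function(blob, c_thresh, config = detector_config()) {
  f <- blob$f_center_hz
  if (!(f > config$band[1] && f < config$band[2])) {
    return(list(accepted = FALSE, reason = "frequency"))
  }
  if (!((blob$t_end_s - blob$t_start_s) > config$n_osc / f)) {
    return(list(accepted = FALSE, reason = "duration"))
  }
  if (!(blob$amplitude_au > config$amp_factor * c_thresh)) {
    return(list(accepted = FALSE, reason = "amplitude"))
  }
  list(accepted = TRUE, reason = NA_character_)
}

#' Duplicate test against previously accepted events
#'
#' A newly detected blob is a duplicate when its bounding box contains the
#' centroid (in both time and frequency) of any previously accepted event.
#' Applied across saturation levels within a window and across overlapping
#' windows, this prevents a faint blob that dilates at lower levels from
#' being marked again as a spuriously large event.
#'
#' @param blob One-row tibble with `t_start_s`, `t_end_s`, `f_low_hz`,
#'   `f_high_hz`.
#' @param accepted Tibble of accepted events with `t_center_s`,
#'   `f_center_hz`.
#' @return `TRUE` if `blob` duplicates an accepted event.
#' @export
is_duplicate <- function(blob, accepted) {
  if (is.null(accepted) || nrow(accepted) == 0L) return(FALSE)
  any(accepted$t_center_s >= blob$t_start_s &
        accepted$t_center_s <= blob$t_end_s &
        accepted$f_center_hz >= blob$f_low_hz &
        accepted$f_center_hz <= blob$f_high_hz)
}

empty_events <- function() {
  tibble(channel = character(), t_center_s = numeric(),
         f_center_hz = numeric(), t_start_s = numeric(),
         t_end_s = numeric(), f_low_hz = numeric(), f_high_hz = numeric(),
         duration_ms = numeric(), amplitude_au = numeric(),
         threshold_level = integer(), band = character())
}

# Run the full level schedule on one analysis window. `plan` may carry a
# precomputed CWT plan for the window length; `t0` is the absolute start
# time of the window; `prior` holds events accepted in earlier windows
# (absolute times) for cross-window deduplication.
detect_window_impl <- function(x, sampling_rate, t0, schedule, config,
                               plan = NULL, channel = "chan",
                               prior = NULL) {
  if (is.null(plan)) {
    plan <- cwt_plan(length(x), sampling_rate, config$morlet)
  }
  coeffs <- cwt_with_plan(x, plan)
  dec <- config$time_decimation %||% 1L
  if (dec > 1L) {
    cols <- seq(1L, length(x), by = dec)
    coeffs <- coeffs[, cols, drop = FALSE]
    times <- t0 + (cols - 1) / sampling_rate
  } else {
    times <- t0 + (seq_along(x) - 1) / sampling_rate
  }
  map <- new_tf_map(times, plan$freqs, coeffs)
  # C_thresh is a per-window background estimate: quiet columns are those
  # whose in-band coefficients stay below the initial threshold
  # (schedule[1]), so the reference does not decay with the level schedule.
  c_thresh <- compute_cthresh(map, schedule[1], config)
  per_level <- cpp_detect_levels(coeffs, schedule)
  st <- do.call(rbind, lapply(seq_along(per_level), function(i) {
    b <- per_level[[i]]$blobs
    if (nrow(b) == 0L) return(NULL)
    cbind(b, i)
  }))
  if (is.null(st) || nrow(st) == 0L) return(empty_events())
  cand <- blobs_to_tibble(st[, 1:7, drop = FALSE], map)
  cand$threshold_level <- as.integer(st[, 8])
  # validation criteria are vectorizable; candidates are then scanned in
  # level order (then time) for sequential deduplication
  valid <- cand$f_center_hz > config$band[1] &
    cand$f_center_hz < config$band[2] &
    (cand$t_end_s - cand$t_start_s) > config$n_osc / cand$f_center_hz &
    cand$amplitude_au > config$amp_factor * c_thresh
  cand <- cand[valid, ]
  if (nrow(cand) == 0L) return(empty_events())
  cand <- cand[order(cand$threshold_level, cand$t_center_s,
                     cand$f_center_hz), ]
  tc <- cand$t_center_s
  fc <- cand$f_center_hz
  t0v <- cand$t_start_s
  t1v <- cand$t_end_s
  f0v <- cand$f_low_hz
  f1v <- cand$f_high_hz
  pt <- prior$t_center_s
  pf <- prior$f_center_hz
  keep <- logical(nrow(cand))
  acc_t <- numeric(0)
  acc_f <- numeric(0)
  for (b in seq_len(nrow(cand))) {
    dup <- any(acc_t >= t0v[b] & acc_t <= t1v[b] &
                 acc_f >= f0v[b] & acc_f <= f1v[b])
    if (!dup && length(pt)) {
      dup <- any(pt >= t0v[b] & pt <= t1v[b] &
                   pf >= f0v[b] & pf <= f1v[b])
    }
    if (!dup) {
      keep[b] <- TRUE
      acc_t <- c(acc_t, tc[b])
      acc_f <- c(acc_f, fc[b])
    }
  }
  ev <- cand[keep, ]
  tibble(
    channel = channel,
    t_center_s = ev$t_center_s,
    f_center_hz = ev$f_center_hz,
    t_start_s = ev$t_start_s,
    t_end_s = ev$t_end_s,
    f_low_hz = ev$f_low_hz,
    f_high_hz = ev$f_high_hz,
    duration_ms = 1000 * (ev$t_end_s - ev$t_start_s),
    amplitude_au = ev$amplitude_au,
    threshold_level = ev$threshold_level,
    band = if (nrow(ev)) band_label(config) else character(0)
  )
}

#' Detect HFOs in one analysis window
#'
#' Runs the full per-window pipeline on a signal window: Morlet transform,
#' then for each saturation level of `schedule` the image is clipped,
#' border-connected structures are suppressed, the result is
#' Otsu-binarized, blobs are extracted and validated against the frequency,
#' duration and amplitude criteria, and duplicates across levels are
#' discarded.
#'
#' @param signal An [eeg_signal] holding the window samples (absolute start
#'   time taken from `start_s`).
#' @param schedule Numeric vector of saturation levels, from
#'   [threshold_schedule()].
#' @param config A [detector_config].
#' @return A tibble of accepted events (see [detect_hfos()] for columns).
#' @export
detect_window <- function(signal, schedule, config = detector_config()) {
  stopifnot(is_signal(signal))
  if (length(signal$samples) < round(config$window_s * signal$sampling_rate)) {
    warn("Window shorter than `window_s`; processing it as-is.")
  }
  detect_window_impl(signal$samples, signal$sampling_rate, signal$start_s,
                     schedule, config, channel = signal$channel)
}

#' Detect HFOs in a continuous signal
#'
#' Slides analysis windows of `window_s` seconds with `overlap_s` overlap
#' across the signal, computes the initial threshold from the channel
#' baseline, runs the per-window computer-vision pipeline at every level of
#' the geometric saturation schedule, and deduplicates events across
#' overlapping windows. All times are absolute seconds.
#'
#' @param signal An [eeg_signal].
#' @param config A [detector_config].
#' @return A tibble of class `hfo_events`, one row per detected HFO, with
#'   columns `channel`, `t_center_s`, `f_center_hz`, `t_start_s`,
#'   `t_end_s`, `f_low_hz`, `f_high_hz`, `duration_ms`, `amplitude_au`,
#'   `threshold_level`, `band`, sorted by `t_center_s`.
#' @examples
#' \donttest{
#' sim <- simulate_hfo_train(n_events = 5, duration_s = 5, seed = 1)
#' ev <- detect_hfos(sim$signal)
#' }
#' @export
detect_hfos <- function(signal, config = detector_config(),
                        sampling_rate = NULL) {
  if (is.numeric(signal) && length(signal) == 0L) {
    return(as_hfo_events(empty_events(), config))
  }
  signal <- as_signal(signal, sampling_rate)
  fs <- signal$sampling_rate
  n <- length(signal$samples)
  if (n < 2L) {
    return(as_hfo_events(empty_events(), config))
  }
  if (all(signal$samples == signal$samples[1])) {
    warn("Flat (degenerate) channel; no events detected.")
    return(as_hfo_events(empty_events(), config))
  }
  thresh0 <- initial_threshold(signal, config)
  schedule <- threshold_schedule(thresh0, config$n_thresholds,
                                 config$threshold_ratio)
  n_win <- round(config$window_s * fs)
  step <- config$window_s - config$overlap_s
  if (n <= n_win) {
    ev <- detect_window(signal, schedule, config)
    return(as_hfo_events(ev[order(ev$t_center_s), ], config))
  }
  starts <- seq(0, n / fs - config$window_s, by = step)
  if (max(starts) + config$window_s < n / fs - 1e-9) {
    starts <- c(starts, n / fs - config$window_s)
  }
  plan <- cwt_plan(n_win, fs, config$morlet)
  accepted <- empty_events()
  for (t0 in starts) {
    i0 <- round(t0 * fs) + 1
    x <- signal$samples[i0:(i0 + n_win - 1)]
    ev <- detect_window_impl(x, fs, signal$start_s + (i0 - 1) / fs,
                             schedule, config, plan = plan,
                             channel = signal$channel, prior = accepted)
    accepted <- bind_rows(accepted, ev)
  }
  as_hfo_events(accepted[order(accepted$t_center_s), ], config)
}

as_hfo_events <- function(x, config = NULL) {
  x <- as_tibble(x)
  class(x) <- c("hfo_events", class(x))
  attr(x, "config") <- config
  x
}
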