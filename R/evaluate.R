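#' Matching tolerance in time and frequency
#'
#' @param dt Time tolerance (s, default 0.05).
#' @param df Frequency tolerance (Hz, default 5).
#' @return A list of class `match_tolerance`.
#' @export
match_tolerance <- function(dt = 0.05, df = 5) {
  check_positive(dt, "dt")
  check_positive(df, "df")
  structure(list(dt = dt, df = df), class = "match_tolerance")
}

#' Merge nearby detections into single events
#'
#' Detections lying within the time AND frequency tolerances of one
#' another (transitively) are unioned into one event: the merged centroid
#' is the amplitude-weighted mean of member centroids, the bounding box is
#' the union of member boxes, the amplitude the member maximum and the
#' threshold level the member minimum. Iterated to a fixed point, so the
#' operation is idempotent. This absorbs repeat detections of one HFO
#' arising from window overlap and baseline changes.
#'
#' @param events Events tibble (from [detect_hfos()] or compatible).
#' @param tol A [match_tolerance].
#' @return Merged events tibble, sorted by `t_center_s`.
#' @export
merge_nearby_detections <- function(events, tol = match_tolerance()) {
  ev <- as_tibble(events)
  if (nrow(ev) <= 1L) return(events)
  repeat {
    comp <- close_pair_components(ev$t_center_s, ev$f_center_hz,
                                  tol$dt, tol$df)
    if (max(comp) == nrow(ev)) break
    ev <- dplyr::group_by(ev, .group = comp) %>%
      dplyr::summarise(
        channel = .data$channel[1],
        t_center_s = sum(.data$t_center_s * .data$amplitude_au) /
          sum(.data$amplitude_au),
        f_center_hz = sum(.data$f_center_hz * .data$amplitude_au) /
          sum(.data$amplitude_au),
        t_start_s = min(.data$t_start_s),
        t_end_s = max(.data$t_end_s),
        f_low_hz = min(.data$f_low_hz),
        f_high_hz = max(.data$f_high_hz),
        amplitude_au = max(.data$amplitude_au),
        threshold_level = min(.data$threshold_level),
        band = .data$band[1],
        .groups = "drop"
      ) %>%
      dplyr::select(-".group") %>%
      dplyr::mutate(duration_ms = 1000 * (.data$t_end_s - .data$t_start_s),
                    .after = "f_high_hz")
  }
  as_hfo_events(ev[order(ev$t_center_s), ], attr(events, "config"))
}

# Union-find over pairs within (dt, df) of each other; returns component id
# per row.
close_pair_components <- function(t, f, dt, df) {
  n <- length(t)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(t)
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in (a + 1):n) {
      j <- ord[b]
      if (t[j] - t[i] > dt) break
      if (abs(f[i] - f[j]) <= df) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

#' Match detections to ground-truth events
#'
#' Greedy nearest-first one-to-one assignment: among all
#' detection-truth pairs within both tolerances, the pair with the
#' smallest tolerance-normalized distance is matched first and removed,
#' until no pair remains. Matched detections are true positives, unmatched
#' detections false positives, unmatched truths false negatives.
#' Localization errors are reported as truth minus detection.
#'
#' @param events Detections tibble with `t_center_s`, `f_center_hz`.
#' @param truth Ground-truth tibble with `t_center_s`, `f0_hz` (as
#'   produced by [simulate_hfo_train()]).
#' @param tol A [match_tolerance].
#' @return A list with `tp`, `fp` (detection row indices), `fn` (truth row
#'   indices) and `errors` (tibble: `event_index`, `detection_index`,
#'   `dt_s`, `df_hz`).
#' @export
match_events <- function(events, truth, tol = match_tolerance()) {
  ev <- as_tibble(events)
  tr <- as_tibble(truth)
  nd <- nrow(ev)
  nt <- nrow(tr)
  if (nd == 0L || nt == 0L) {
    return(list(tp = integer(), fp = seq_len(nd), fn = seq_len(nt),
                errors = tibble(event_index = integer(),
                                detection_index = integer(),
                                dt_s = numeric(), df_hz = numeric())))
  }
  dt_mat <- outer(tr$t_center_s, ev$t_center_s, "-")
  df_mat <- outer(tr$f0_hz, ev$f_center_hz, "-")
  ok <- abs(dt_mat) <= tol$dt & abs(df_mat) <= tol$df
  dist <- sqrt((dt_mat / tol$dt)^2 + (df_mat / tol$df)^2)
  dist[!ok] <- Inf
  matched_t <- integer()
  matched_d <- integer()
  errs <- list()
  while (any(is.finite(dist))) {
    k <- which.min(dist)  # first minimum: deterministic tie-break
    i <- (k - 1) %% nt + 1
    j <- (k - 1) %/% nt + 1
    matched_t <- c(matched_t, i)
    matched_d <- c(matched_d, j)
    errs[[length(errs) + 1L]] <- tibble(
      event_index = i, detection_index = j,
      dt_s = dt_mat[i, j], df_hz = df_mat[i, j])
    dist[i, ] <- Inf
    dist[, j] <- Inf
  }
  list(tp = matched_d, fp = setdiff(seq_len(nd), matched_d),
       fn = setdiff(seq_len(nt), matched_t),
       errors = if (length(errs)) bind_rows(errs) else
         tibble(event_index = integer(), detection_index = integer(),
                dt_s = numeric(), df_hz = numeric()))
}

#' Performance metrics against ground truth
#'
#' Computes the standard detector metrics from matched results: positive
#' prediction value `PPV = TP / (TP + FP)`, `sensitivity = TP / (TP + FN)`,
#' their harmonic mean (F-measure), and mean/SD localization errors over
#' true positives (truth minus detection). Undefined ratios (0/0) are 0 by
#' convention.
#'
#' @param events Detections tibble (ideally merged first with
#'   [merge_nearby_detections()]).
#' @param truth Ground-truth tibble from [simulate_hfo_train()].
#' @param tol A [match_tolerance].
#' @return An object of class `hfo_performance`: list with counts
#'   (`n_truth`, `tp`, `fp`, `fn`), metrics (`ppv`, `sensitivity`,
#'   `f_measure`), localization-error summaries and the per-match `errors`
#'   tibble. Use [glance()] for a one-row tibble, [tidy()] for per-match
#'   errors.
#' @export
evaluate_detections <- function(events, truth, tol = match_tolerance()) {
  m <- match_events(events, truth, tol)
  performance_from_counts(length(m$tp), length(m$fp), nrow(as_tibble(truth)),
                          errors = m$errors)
}

#' Build a performance report from raw counts
#'
#' @param tp,fp Number of true and false positives.
#' @param n_truth Number of ground-truth events (`TP + FN`).
#' @param errors Optional per-match error tibble with `dt_s`, `df_hz`.
#' @return An `hfo_performance` object.
#' @examples
#' glance(performance_from_counts(193, 7, 300))
#' @export
performance_from_counts <- function(tp, fp, n_truth, errors = NULL) {
  fn <- n_truth - tp
  stopifnot(fn >= 0)
  ratio <- function(num, den) if (den > 0) num / den else 0
  ppv <- ratio(tp, tp + fp)
  sens <- ratio(tp, n_truth)
  f <- if (ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else 0
  if (is.null(errors)) {
    errors <- tibble(event_index = integer(), detection_index = integer(),
                     dt_s = numeric(), df_hz = numeric())
  }
  structure(
    list(n_truth = n_truth, tp = tp, fp = fp, fn = fn,
         ppv = ppv, sensitivity = sens, f_measure = f,
         mean_dt_s = mean_or_na(errors$dt_s),
         sd_dt_s = sd_or_na(errors$dt_s),
         mean_df_hz = mean_or_na(errors$df_hz),
         sd_df_hz = sd_or_na(errors$df_hz),
         mean_abs_dt_s = mean_or_na(abs(errors$dt_s)),
         mean_abs_df_hz = mean_or_na(abs(errors$df_hz)),
         errors = errors),
    class = "hfo_performance"
  )
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
sd_or_na <- function(x) if (length(x) > 1) sd(x) else NA_real_

#' @export
print.hfo_performance <- function(x, ...) {
  cat(sprintf(
    "<hfo_performance> n_truth=%d TP=%d FP=%d FN=%d | PPV=%.3f Sens=%.3f F=%.3f\n",
    x$n_truth, x$tp, x$fp, x$fn, x$ppv, x$sensitivity, x$f_measure))
  if (is.finite(x$mean_dt_s %||% NA)) {
    cat(sprintf("  localization: dt %.4f +/- %.4f s, df %.2f +/- %.2f Hz\n",
                x$mean_dt_s, x$sd_dt_s %||% NA, x$mean_df_hz,
                x$sd_df_hz %||% NA))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname evaluate_detections
#' @param x An `hfo_performance` object.
#' @param ... Unused.
#' @export
glance.hfo_performance <- function(x, ...) {
  tibble(n_truth = x$n_truth, tp = x$tp, fp = x$fp, fn = x$fn,
         ppv = x$ppv, sensitivity = x$sensitivity,
         f_measure = x$f_measure, mean_dt_s = x$mean_dt_s,
         sd_dt_s = x$sd_dt_s, mean_df_hz = x$mean_df_hz,
         sd_df_hz = x$sd_df_hz, mean_abs_dt_s = x$mean_abs_dt_s,
         mean_abs_df_hz = x$mean_abs_df_hz)
}

#' @rdname evaluate_detections
#' @export
tidy.hfo_performance <- function(x, ...) {
  x$errors
}

#' Run the simulation benchmark end to end
#'
#' Generates the HFO train and pink noise once, then for every requested
#' SNR mixes, detects, merges nearby detections and evaluates against the
#' ground truth. Optionally also runs the noise-free train
#' (`include_hfos_only`) and the pure-noise signal (`include_noise_only`).
#'
#' @param snr_db Numeric vector of SNRs (dB).
#' @param seed RNG seed; the noise stream is derived from it.
#' @param config A [detector_config].
#' @param tol A [match_tolerance].
#' @param include_hfos_only,include_noise_only Add the noise-free /
#'   pure-noise conditions.
#' @param n_events,duration_s,sampling_rate Passed to the generators.
#' @return A list with `results` (one-row-per-condition tibble of glance
#'   metrics plus a `condition` column), `reports` (named list of
#'   `hfo_performance`), and `truth`.
#' @export
benchmark_detector <- function(snr_db = c(-9, -6, -3, 0), seed = 42,
                               config = detector_config(),
                               tol = match_tolerance(),
                               include_hfos_only = FALSE,
                               include_noise_only = FALSE,
                               n_events = 300, duration_s = NULL,
                               sampling_rate = 2000) {
  sim <- simulate_hfo_train(n_events = n_events, duration_s = duration_s,
                            sampling_rate = sampling_rate, seed = seed)
  noise <- generate_pink_noise(
    duration_s = length(sim$signal$samples) / sampling_rate,
    sampling_rate = sampling_rate, seed = seed + 1L)
  conditions <- list()
  for (s in snr_db) {
    conditions[[sprintf("%+g dB", s)]] <- mix_at_snr(sim$signal, noise, s)$signal
  }
  if (include_hfos_only) conditions[["hfos_only"]] <- sim$signal
  if (include_noise_only) conditions[["noise_only"]] <- noise
  reports <- list()
  rows <- list()
  for (nm in names(conditions)) {
    ev <- detect_hfos(conditions[[nm]], config) %>%
      merge_nearby_detections(tol)
    truth <- if (identical(nm, "noise_only")) {
      tibble(t_center_s = numeric(), f0_hz = numeric())
    } else {
      sim$events
    }
    rep <- evaluate_detections(ev, truth, tol)
    reports[[nm]] <- rep
    rows[[nm]] <- dplyr::bind_cols(tibble(condition = nm), glance(rep))
  }
  list(results = bind_rows(rows), reports = reports, truth = sim$events)
}
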