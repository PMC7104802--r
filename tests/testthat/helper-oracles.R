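# Independent oracles used to check the package's computational paths.

# One-sided amplitude spectrum of a sampled waveform via the DFT:
# |X(f)| * dt approximates the continuous-time Fourier magnitude.
fft_spectrum_oracle <- function(x, fs) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f <= fs / 2
  list(f = f[keep], amp = (Mod(stats::fft(x)) / fs)[keep])
}

# Brute-force Otsu: loop over every candidate split of the same 256-bin
# histogram the implementation uses, computing the between-class variance
# from scratch at each split.
otsu_oracle <- function(image) {
  x <- as.vector(image)
  nb <- 256L
  mn <- min(x)
  mx <- max(x)
  if (mx <= mn) return(NA_real_)
  w <- (mx - mn) / nb
  b <- pmin(floor((x - mn) / (mx - mn) * nb), nb - 1)
  counts <- tabulate(b + 1L, nbins = nb)
  mid <- mn + (seq_len(nb) - 0.5) * w
  best <- -Inf
  kbest <- NA_integer_
  for (k in seq_len(nb - 1)) {
    w0 <- sum(counts[1:k])
    w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:k] * mid[1:k]) / w0
    mu1 <- sum(counts[(k + 1):nb] * mid[(k + 1):nb]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) {
      best <- v
      kbest <- k
    }
  }
  mn + kbest * w
}

# Recursive flood fill (8-connectivity) counting connected components.
flood_fill_count <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (c0 in seq_len(nc)) {
    for (r0 in seq_len(nr)) {
      if (!mask[r0, c0] || seen[r0, c0]) next
      count <- count + 1L
      stack <- list(c(r0, c0))
      seen[r0, c0] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dr in -1:1) {
          for (dc in -1:1) {
            r <- p[1] + dr
            c <- p[2] + dc
            if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
                mask[r, c] && !seen[r, c]) {
              seen[r, c] <- TRUE
              stack[[length(stack) + 1L]] <- c(r, c)
            }
          }
        }
      }
    }
  }
  count
}

# Exhaustive min-cost one-to-one assignment between truths and detections
# restricted to pairs within tolerance; used at small n to validate the
# greedy matcher. Returns the maximum number of matches and, among
# solutions of that size, the minimum total normalized distance.
assignment_oracle <- function(truth, events, tol) {
  nt <- nrow(truth)
  nd <- nrow(events)
  dt <- outer(truth$t_center_s, events$t_center_s, "-")
  df <- outer(truth$f0_hz, events$f_center_hz, "-")
  ok <- abs(dt) <= tol$dt & abs(df) <= tol$df
  d <- sqrt((dt / tol$dt)^2 + (df / tol$df)^2)
  best <- list(n = -1L, cost = Inf)
  recurse <- function(i, used, n, cost) {
    if (i > nt) {
      if (n > best$n || (n == best$n && cost < best$cost)) {
        best <<- list(n = n, cost = cost)
      }
      return(invisible())
    }
    recurse(i + 1L, used, n, cost)  # leave truth i unmatched
    for (j in seq_len(nd)) {
      if (!used[j] && ok[i, j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, n + 1L, cost + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nd), 0L, 0)
  best
}

# Small simulated fixture: a single HFO at a known location mixed with
# pink noise, long enough for the 15-s baseline.
single_hfo_fixture <- function(f0 = 88, center = 0.5, snr_db = 0,
                               duration_s = 16, fs = 2000, seed = 11) {
  set.seed(seed)
  n <- duration_s * fs
  t <- (seq_len(n) - 1) / fs
  sigma <- fwhm_to_sigma(6 / f0)
  x <- exp(-(t - center)^2 / (2 * sigma^2)) * cos(2 * pi * f0 * (t - center))
  hfo <- eeg_signal(x, fs)
  noise <- generate_pink_noise(duration_s, fs, seed = seed + 1)
  list(signal = mix_at_snr(hfo, noise, snr_db)$signal, f0 = f0,
       center = center)
}
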