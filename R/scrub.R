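#' Detect burst artifacts with a robust sliding-window threshold
#'
#' Automates the manual pass over the raw trace: the signal is scanned with
#' a short window (0.25 s, advanced by half a window) and a window is
#' flagged when either its RMS or its broadband (> 15 Hz high-passed) RMS
#' exceeds `median + k_mad * MAD` of that statistic over the whole signal.
#' Adjacent flagged windows are merged; merged-interval edges are then
#' refined at 25 ms resolution against the same robust threshold so that a
#' flag tracks the burst rather than the window grid.
#'
#' Both thresholds are relative, so detection is invariant to rescaling the
#' signal. A constant signal (zero MAD) produces no flags.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate, Hz.
#' @param window Detection window length, s (default 0.25).
#' @param k_mad Robust threshold multiplier (default 6).
#' @return An `artifact_mask`: two-column matrix of merged half-open
#'   `[start_s, end_s)` intervals.
#' @export
detect_artifacts <- function(x, fs, window = 0.25, k_mad = 6) {
  n <- length(x)
  wlen <- round(window * fs)
  if (n < wlen) stop("signal shorter than one detection window")
  step <- max(1L, round(wlen / 2))
  starts <- seq(1L, n - wlen + 1L, by = step)

  broad <- highpass_fft(x, fs, 15)
  win_stat <- function(sig) {
    vapply(starts, function(s) {
      seg <- sig[s:(s + wlen - 1L)]
      sqrt(mean(seg^2))
    }, numeric(1))
  }
  rms_w <- win_stat(x)
  rms_b <- win_stat(broad)

  # floor keeps numerically-silent statistics (e.g. broadband power of a
  # constant trace) from tripping on round-off; relative, so detection
  # stays amplitude-scale invariant
  floor_v <- 1e-6 * sqrt(mean(x^2))
  flag_stat <- function(v) {
    med <- stats::median(v)
    mad <- stats::mad(v)
    thr <- if (mad == 0) 5 * med else med + k_mad * mad
    v > max(thr, floor_v)
  }
  flagged <- flag_stat(rms_w) | flag_stat(rms_b)
  if (!any(flagged)) {
    return(empty_mask())
  }
  iv <- cbind((starts[flagged] - 1L) / fs,
              (starts[flagged] - 1L + wlen) / fs)
  iv <- merge_intervals(iv)

  iv <- refine_mask_edges(iv, x, broad, fs, k_mad)
  colnames(iv) <- c("start_s", "end_s")
  class(iv) <- c("artifact_mask", class(iv))
  iv
}

empty_mask <- function() {
  m <- matrix(numeric(0), ncol = 2,
              dimnames = list(NULL, c("start_s", "end_s")))
  class(m) <- c("artifact_mask", class(m))
  m
}

# trim merged window-level intervals to where a short-scale (25 ms) rolling
# RMS still exceeds the robust threshold; keeps window-level flags when the
# short-scale pass finds nothing (degenerate bursts)
refine_mask_edges <- function(iv, x, broad, fs, k_mad) {
  flen <- max(2L, round(0.025 * fs))
  short_rms <- function(sig) {
    cs <- cumsum(c(0, sig^2))
    m <- length(sig) - flen + 1L
    sqrt((cs[(flen + 1L):(length(sig) + 1L)] - cs[1L:m]) / flen)
  }
  sr_x <- short_rms(x)
  sr_b <- short_rms(broad)
  thr <- function(v) {
    med <- stats::median(v); mad <- stats::mad(v)
    if (mad == 0) Inf else med + k_mad * mad
  }
  tx <- thr(sr_x); tb <- thr(sr_b)
  hot <- (sr_x > tx) | (sr_b > tb)            # indexed by window start sample
  n <- length(x)
  out <- iv
  for (k in seq_len(nrow(iv))) {
    i0 <- max(1L, floor(iv[k, 1L] * fs) + 1L)
    i1 <- min(length(hot), floor(iv[k, 2L] * fs))
    if (i1 <= i0) next
    h <- which(hot[i0:i1])
    if (!length(h)) next                       # keep coarse interval
    out[k, 1L] <- (i0 + h[1L] - 2L) / fs
    out[k, 2L] <- min((i0 + h[length(h)] - 1L + flen) / fs, n / fs)
  }
  merge_intervals(out)
}

# zero-phase FFT brick-wall high-pass (detection statistic only)
highpass_fft <- function(x, fs, f_cut) {
  n <- length(x)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  X[f < f_cut] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Scrub a full recording phase by phase
#'
#' Runs [detect_artifacts()] on the pooled epochs of each task phase and
#' maps the flagged intervals back to session time, one mask per channel.
#' Thresholding per phase matters on both sides: phases legitimately
#' differ in amplitude (elevated maze theta), so a session-wide robust
#' threshold reads a sustained high-amplitude phase as one long artifact;
#' but a single 4-s maze epoch is too little context when a burst covers
#' half of it, so all epochs of a phase share one threshold.
#'
#' @param rec A [recording()].
#' @param epochs An epoch set from [extract_epochs()].
#' @param window,k_mad Passed to [detect_artifacts()].
#' @return Named list of `artifact_mask`es, one per channel, in session
#'   time.
#' @export
scrub_recording <- function(rec, epochs, window = 0.25, k_mad = 6) {
  fs <- rec$fs
  masks <- lapply(rec$channels, function(ch) {
    iv <- NULL
    for (ph in unique(epochs$phase)) {
      eps <- epochs[epochs$phase == ph, , drop = FALSE]
      segs <- lapply(seq_len(nrow(eps)), function(k) {
        epoch_signal(rec, eps[k, ], ch)
      })
      pooled <- unlist(segs, use.names = FALSE)
      if (length(pooled) < round(window * fs)) next
      m <- detect_artifacts(pooled, fs, window = window, k_mad = k_mad)
      if (!nrow(m)) next
      # map concatenated-time intervals back through the epoch offsets
      lens <- vapply(segs, length, integer(1)) / fs
      offs <- cumsum(c(0, lens))
      for (r in seq_len(nrow(m))) {
        for (k in seq_len(nrow(eps))) {
          a <- max(m[r, 1L], offs[k]); b <- min(m[r, 2L], offs[k + 1L])
          if (b - a > 1 / fs) {
            iv <- rbind(iv, c(eps$t_start[k] + a - offs[k],
                              eps$t_start[k] + b - offs[k]))
          }
        }
      }
    }
    if (is.null(iv)) iv <- matrix(numeric(0), ncol = 2)
    m <- merge_intervals(iv)
    colnames(m) <- c("start_s", "end_s")
    class(m) <- c("artifact_mask", class(m))
    m
  })
  stats::setNames(masks, rec$channels)
}

#' Recovered-signal summary after artifact scrubbing
#'
#' The share of an epoch that survives artifact removal, obtained by
#' comparing signal length with and without the flagged intervals.
#'
#' @param mask An `artifact_mask` (or list of masks per channel).
#' @param n Signal length in samples.
#' @param fs Sampling rate, Hz.
#' @param channel Label used in the report.
#' @return A `data.frame` with `channel`, `clean_seconds`, `total_seconds`,
#'   `recovered_fraction`.
#' @export
recovered_fraction <- function(mask, n, fs, channel = "ch1") {
  if (is.list(mask) && !inherits(mask, "artifact_mask")) {
    out <- mapply(function(m, ch) recovered_fraction(m, n, fs, ch),
                  mask, names(mask), SIMPLIFY = FALSE)
    return(do.call(rbind, out))
  }
  total <- n / fs
  iv <- merge_intervals(unclass(mask))
  if (nrow(iv)) {
    iv[, 1L] <- pmax(iv[, 1L], 0)
    iv[, 2L] <- pmin(iv[, 2L], total)
    flagged <- sum(pmax(iv[, 2L] - iv[, 1L], 0))
  } else flagged <- 0
  data.frame(channel = channel,
             clean_seconds = total - flagged,
             total_seconds = total,
             recovered_fraction = (total - flagged) / total)
}

#' Drop analysis windows that touch flagged intervals
#'
#' Spectral analysis runs on fixed-length windows; any window overlapping a
#' flagged artifact interval is excluded outright (no splicing, which would
#' manufacture spectral discontinuities).
#'
#' @param mask An `artifact_mask`.
#' @param windows Two-column matrix of half-open `[start_s, end_s)` analysis
#'   windows.
#' @return The retained rows of `windows`.
#' @export
mask_windows <- function(mask, windows) {
  if (!nrow(windows)) return(windows)
  iv <- unclass(mask)
  if (!nrow(iv)) return(windows)
  keep <- vapply(seq_len(nrow(windows)), function(k) {
    !any(windows[k, 1L] < iv[, 2L] & iv[, 1L] < windows[k, 2L])
  }, logical(1))
  windows[keep, , drop = FALSE]
}

#' Convert an artifact mask to a per-sample logical vector
#'
#' @param mask An `artifact_mask`.
#' @param n Signal length in samples.
#' @param fs Sampling rate, Hz.
#' @return Logical vector, `TRUE` on clean samples.
#' @export
clean_sample_mask <- function(mask, n, fs) {
  keep <- rep(TRUE, n)
  iv <- unclass(mask)
  for (k in seq_len(nrow(iv))) {
    i0 <- max(1L, floor(iv[k, 1L] * fs) + 1L)
    i1 <- min(n, floor(iv[k, 2L] * fs))
    if (i1 >= i0) keep[i0:i1] <- FALSE
  }
  keep
}
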