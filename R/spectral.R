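#' Multitaper parameters
#'
#' @param window_s Sliding-window length, s (default 2).
#' @param overlap_s Overlap between consecutive windows, s (default 1).
#' @param n_tapers Number of DPSS tapers K (default 3).
#' @param time_bandwidth Time-bandwidth product NW (default 2; K must not
#'   exceed 2NW - 1).
#' @return A `spectral_params` list.
#' @export
spectral_params <- function(window_s = 2, overlap_s = 1, n_tapers = 3,
                            time_bandwidth = 2) {
  stopifnot(window_s > 0, overlap_s >= 0)
  if (overlap_s >= window_s) stop("overlap must be shorter than the window")
  if (n_tapers > 2 * time_bandwidth - 1) {
    stop("n_tapers must not exceed 2 * time_bandwidth - 1")
  }
  structure(list(window_s = window_s, overlap_s = overlap_s,
                 n_tapers = n_tapers, time_bandwidth = time_bandwidth),
            class = "spectral_params")
}

# cache tapers: eigendecomposition is the slow part and (n, nw, k) repeats
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed as the leading eigenvectors of the symmetric tridiagonal matrix
#' whose eigenvectors are the DPSS (diagonal `((n-1-2t)/2)^2 cos(2*pi*W)`,
#' off-diagonal `t(n-t)/2`), each normalised to unit energy with the usual
#' sign convention (non-negative mean for symmetric tapers, positive initial
#' slope otherwise).
#'
#' @param n Taper length, samples.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers.
#' @return `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  W <- nw / n
  tt <- 0:(n - 1L)
  diag_v <- ((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * W)
  off_v <- (tt[-1L] * (n - tt[-1L])) / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diag_v
  A[cbind(seq_len(n - 1L), 2:n)] <- off_v
  A[cbind(2:n, seq_len(n - 1L))] <- off_v
  eig <- eigen(A, symmetric = TRUE)
  H <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    h <- H[, j]
    h <- h / sqrt(sum(h^2))
    if (j %% 2L == 1L) {                       # symmetric order
      if (sum(h) < 0) h <- -h
    } else {
      if (h[2L] - h[1L] < 0) h <- -h
    }
    H[, j] <- h
  }
  .dpss_cache[[key]] <- H
  H
}

#' Sliding analysis windows over an epoch
#'
#' @param duration Epoch length, s.
#' @param params A [spectral_params()].
#' @param offset Start of the epoch in absolute seconds (for masking against
#'   a session-level artifact mask).
#' @return Two-column matrix of half-open `[start_s, end_s)` windows,
#'   full-length windows only.
#' @export
sliding_windows <- function(duration, params = spectral_params(),
                            offset = 0) {
  step <- params$window_s - params$overlap_s
  starts <- seq(0, duration - params$window_s, by = step)
  starts <- starts[starts + params$window_s <= duration + 1e-9]
  cbind(start_s = offset + starts, end_s = offset + starts + params$window_s)
}

# per-window multitaper eigenspectra: returns complex matrix
# [n_freq x (n_windows*k)] of tapered FFTs, plus the frequency grid
mt_eigenspectra <- function(x, fs, params, windows, t0 = 0) {
  wlen <- round(params$window_s * fs)
  if (is.null(windows)) {
    windows <- sliding_windows(length(x) / fs, params, offset = t0)
  }
  if (!nrow(windows)) stop("no clean analysis windows available")
  H <- dpss_tapers(wlen, params$time_bandwidth, params$n_tapers)
  nfft <- wlen
  nf <- nfft %/% 2L + 1L
  out <- matrix(0+0i, nf, nrow(windows) * params$n_tapers)
  col <- 1L
  for (k in seq_len(nrow(windows))) {
    i0 <- floor((windows[k, 1L] - t0) * fs)
    seg <- x[(i0 + 1L):(i0 + wlen)]
    if (anyNA(seg)) stop("analysis window out of signal bounds")
    for (j in seq_len(params$n_tapers)) {
      X <- stats::fft(seg * H[, j])[seq_len(nf)]
      out[, col] <- X
      col <- col + 1L
    }
  }
  list(spec = out, freqs = seq(0, fs / 2, length.out = nf),
       n_windows = nrow(windows), nfft = nfft)
}

#' Multitaper power spectral density
#'
#' Averages DPSS-tapered periodograms over tapers and sliding windows.
#' One-sided density scaling: for a unit-energy taper the integral of the
#' PSD over the frequency grid recovers the signal variance.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param params A [spectral_params()].
#' @param windows Optional pre-selected window matrix (e.g. from
#'   [mask_windows()]); `NULL` uses every full window.
#' @param t0 Time of `x[1]` in the window matrix's clock, s.
#' @return A `psd_result`: list with `freqs`, `power`, `n_windows`,
#'   `normalization` (`"raw"`).
#' @export
multitaper_psd <- function(x, fs, params = spectral_params(),
                           windows = NULL, t0 = 0) {
  es <- mt_eigenspectra(x, fs, params, windows, t0)
  pw <- rowMeans(Mod(es$spec)^2) / fs
  nf <- length(es$freqs)
  scale <- rep(2, nf)                          # one-sided
  scale[1L] <- 1
  if (es$nfft %% 2L == 0L) scale[nf] <- 1
  structure(list(freqs = es$freqs, power = pw * scale,
                 n_windows = es$n_windows, normalization = "raw"),
            class = "psd_result")
}

#' Normalise a PSD by the epoch's RMS value
#'
#' @param psd A `psd_result` with `normalization == "raw"`.
#' @param x The epoch signal the PSD came from (clean samples only); its
#'   RMS is the divisor. A precomputed scalar RMS may be passed instead.
#' @return The normalised `psd_result` (`normalization == "rms"`).
#' @export
rms_normalize <- function(psd, x) {
  stopifnot(inherits(psd, "psd_result"))
  if (psd$normalization != "raw") stop("PSD already RMS-normalised")
  rms <- if (length(x) == 1L) x else sqrt(mean(x^2))
  if (!is.finite(rms) || rms <= 0) stop("signal RMS must be positive")
  psd$power <- psd$power / rms
  psd$normalization <- "rms"
  psd
}

#' Multitaper magnitude-squared coherence
#'
#' `|<Sxy>|^2 / (<Sxx> <Syy>)` with averaging over tapers and windows.
#' At least two window-taper estimates are required; a single estimate
#' yields coherence identically 1 and is rejected.
#'
#' @param x,y Equal-length signals.
#' @param fs Sampling rate, Hz.
#' @param params A [spectral_params()].
#' @param windows Optional pre-selected window matrix.
#' @param t0 Time of the signals' first sample, s.
#' @return A `coherence_result`: list with `freqs`, `coherence`,
#'   `n_windows`.
#' @export
multitaper_coherence <- function(x, y, fs, params = spectral_params(),
                                 windows = NULL, t0 = 0) {
  stopifnot(length(x) == length(y))
  ex <- mt_eigenspectra(x, fs, params, windows, t0)
  ey <- mt_eigenspectra(y, fs, params, windows, t0)
  if (ncol(ex$spec) < 2L) {
    stop("coherence needs at least 2 window-taper estimates")
  }
  sxx <- rowMeans(Mod(ex$spec)^2)
  syy <- rowMeans(Mod(ey$spec)^2)
  sxy <- rowMeans(ex$spec * Conj(ey$spec))
  coh <- Mod(sxy)^2 / (sxx * syy)
  coh[!is.finite(coh)] <- 0
  structure(list(freqs = ex$freqs, coherence = pmin(coh, 1),
                 n_windows = ex$n_windows),
            class = "coherence_result")
}

#' Peak value inside a frequency band
#'
#' Maximum of a PSD or coherence curve over a closed band; ties resolve to
#' the lowest frequency.
#'
#' @param result A `psd_result` or `coherence_result`.
#' @param band Numeric `c(lo, hi)` in Hz (default theta, 5-12).
#' @return List with `freq`, `value`, `band`.
#' @export
peak_in_band <- function(result, band = c(5, 12)) {
  vals <- if (inherits(result, "psd_result")) result$power
          else if (inherits(result, "coherence_result")) result$coherence
          else stop("unsupported result type")
  sel <- which(result$freqs >= band[1L] & result$freqs <= band[2L])
  if (!length(sel)) stop("frequency grid does not intersect band")
  i <- sel[which.max(vals[sel])]               # which.max: first max wins
  list(freq = result$freqs[i], value = vals[i], band = band)
}
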