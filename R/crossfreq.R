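#' Analytic signal via the frequency domain
#'
#' Zeroes the negative-frequency half of the spectrum and doubles the
#' positive half, giving the complex analytic signal whose angle is the
#' instantaneous phase and whose modulus the instantaneous amplitude.
#'
#' @param x Real, band-limited signal.
#' @return Complex vector, same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) band-pass applied with zero phase delay: the
#' kernel is convolved with its own time reverse, which is exactly the
#' forward-backward (squared magnitude) response, and the centred
#' convolution is returned at input length. The order is sized for a
#' transition width of 20% of the bandwidth (and at least three cycles of
#' the low cutoff); narrow transitions matter because the modulation index
#' downstream is scale-invariant, so even heavily attenuated leakage from a
#' neighbouring band can masquerade as coupling.
#'
#' @param x Signal.
#' @param fs Sampling rate, Hz.
#' @param f_lo,f_hi Band edges, Hz; `0 < f_lo < f_hi < fs/2`.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, fs, f_lo, f_hi) {
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < fs / 2)) {
    stop("band must satisfy 0 < f_lo < f_hi < fs/2")
  }
  n <- length(x)
  trans <- 0.2 * (f_hi - f_lo)
  ord <- round(max(3 * fs / f_lo, 3.3 * fs / trans))  # Hamming main lobe
  ord <- min(ord, max(2L, n %/% 3L))
  if (ord %% 2L == 1L) ord <- ord + 1L        # type-I linear phase
  b <- signal::fir1(ord, c(f_lo, f_hi) / (fs / 2), type = "pass")
  g <- stats::convolve(b, b, type = "open")    # b (x) rev(b): zero phase
  L <- length(b)
  full <- stats::convolve(x, rev(g), type = "open")
  full[L:(L + n - 1L)]
}

#' Instantaneous phase and amplitude envelope
#'
#' @param x A band-limited signal (e.g. the output of
#'   [bandpass_zero_phase()]).
#' @return List with `phase` (radians in `[-pi, pi)`, 0 at the peak of a
#'   cosine-aligned oscillation) and `envelope` (>= 0).
#' @export
phase_and_envelope <- function(x) {
  a <- analytic_signal(x)
  ph <- Arg(a)
  ph[ph >= pi] <- -pi                          # half-open convention
  list(phase = ph, envelope = Mod(a))
}

#' Frequency-band grid for comodulogram scans
#'
#' @param phase_freqs Centre frequencies of the slow (phase-providing)
#'   bands, Hz (default 2-12 in 1 Hz steps).
#' @param phase_bw Full bandwidth of each phase band, Hz (default 2,
#'   i.e. centre +/- 1).
#' @param amp_freqs Centre frequencies of the fast (amplitude-providing)
#'   bands, Hz (default 20-120 in 5 Hz steps).
#' @param amp_bw Full bandwidth of each amplitude band, Hz (default 10,
#'   i.e. centre +/- 5).
#' @return A `band_grid` list.
#' @export
band_grid <- function(phase_freqs = 2:12, phase_bw = 2,
                      amp_freqs = seq(20, 120, by = 5), amp_bw = 10) {
  stopifnot(all(phase_freqs > phase_bw / 2),
            max(phase_freqs) + phase_bw / 2 < min(amp_freqs) - amp_bw / 2)
  structure(list(phase_freqs = phase_freqs, phase_bw = phase_bw,
                 amp_freqs = amp_freqs, amp_bw = amp_bw),
            class = "band_grid")
}

#' Phase-binned amplitude distribution
#'
#' Sums the instantaneous amplitude into phase bins (18 bins of 20 degrees
#' by default) and normalises by the grand total, yielding a discrete
#' distribution over phase.
#'
#' @param phase Phase series, radians in `[-pi, pi)` (exact `pi` wraps to
#'   the first bin).
#' @param amplitude Non-negative amplitude series, same length.
#' @param n_bins Number of phase bins (default 18).
#' @return A `phase_amp_dist`: list with `weights` (sums to 1), `n_bins`,
#'   `edges`.
#' @export
phase_amplitude_histogram <- function(phase, amplitude, n_bins = 18L) {
  stopifnot(length(phase) == length(amplitude), length(phase) >= 1L)
  total <- sum(amplitude)
  if (total <= 0) stop("all-zero amplitude: distribution undefined")
  idx <- bin_phase(phase, n_bins)
  w <- bin_weighted_sums(idx, amplitude, n_bins) / total
  structure(list(weights = w, n_bins = n_bins,
                 edges = seq(-pi, pi, length.out = n_bins + 1L)),
            class = "phase_amp_dist")
}

bin_phase <- function(phase, n_bins) {
  idx <- floor((phase + pi) / (2 * pi / n_bins)) + 1L
  idx[idx > n_bins] <- 1L                      # phase == pi wraps around
  idx[idx < 1L] <- 1L
  idx
}

bin_weighted_sums <- function(idx, amplitude, n_bins) {
  rs <- rowsum(amplitude, idx)
  w <- numeric(n_bins)
  w[as.integer(rownames(rs))] <- rs[, 1L]
  w
}

#' Normalised-entropy modulation index
#'
#' Shannon entropy `H = -sum p log p` of the phase-binned amplitude
#' distribution, normalised against the maximum possible entropy `log(N)`:
#' `MI = (log(N) - H) / log(N)`. 0 for a uniform distribution (no
#' coupling), 1 when all amplitude falls in one phase bin. The log base
#' cancels in the ratio; natural log is used.
#'
#' @param dist A `phase_amp_dist` (or a bare weight vector summing to 1).
#' @return MI in `[0, 1]`.
#' @export
modulation_index <- function(dist) {
  p <- if (inherits(dist, "phase_amp_dist")) dist$weights else dist
  n <- length(p)
  nz <- p > 0
  H <- -sum(p[nz] * log(p[nz]))
  (log(n) - H) / log(n)
}

# shared decomposition: phase-bin indices per phase band and amplitude
# envelope per amplitude band, restricted to clean samples
cfc_decompose <- function(phase_signal, amp_signal, fs, grid,
                          clean = NULL, n_bins = 18L) {
  n <- length(phase_signal)
  stopifnot(length(amp_signal) == n)
  if (is.null(clean)) clean <- rep(TRUE, n)
  min_clean <- 10 / min(grid$phase_freqs)      # 10 slow cycles
  if (sum(clean) / fs < min_clean) {
    stop("insufficient clean data: need at least ", min_clean,
         " s at the lowest phase frequency")
  }
  bins <- lapply(grid$phase_freqs, function(f) {
    bp <- bandpass_zero_phase(phase_signal, fs,
                              f - grid$phase_bw / 2, f + grid$phase_bw / 2)
    bin_phase(phase_and_envelope(bp)$phase, n_bins)
  })
  envs <- lapply(grid$amp_freqs, function(f) {
    bp <- bandpass_zero_phase(amp_signal, fs,
                              f - grid$amp_bw / 2, f + grid$amp_bw / 2)
    phase_and_envelope(bp)$envelope
  })
  list(bins = bins, envs = envs, clean = clean, n_bins = n_bins, n = n)
}

mi_from_parts <- function(bins_clean, env_clean, n_bins) {
  total <- sum(env_clean)
  if (total <= 0) return(0)
  modulation_index(bin_weighted_sums(bins_clean, env_clean, n_bins) / total)
}

#' Phase-amplitude comodulogram
#'
#' Modulation index for every (phase band, amplitude band) pair of a
#' [band_grid()]. The phase and amplitude signals may be the same channel
#' (within-region coupling) or different channels (cross-region coupling);
#' artifact-masked samples are excluded from the histogram (the filtering
#' and Hilbert transform run on the full trace).
#'
#' @param phase_signal Signal providing the slow phase.
#' @param amp_signal Signal providing the fast amplitude.
#' @param fs Sampling rate, Hz.
#' @param grid A [band_grid()].
#' @param clean Optional logical vector, `TRUE` on clean samples (e.g. from
#'   [clean_sample_mask()]).
#' @param n_bins Phase bins (default 18).
#' @return A `comodulogram`: list with `mi` (`n_amp x n_phase` matrix,
#'   dimnames = frequencies) and `grid`.
#' @export
comodulogram <- function(phase_signal, amp_signal, fs,
                         grid = band_grid(), clean = NULL, n_bins = 18L) {
  parts <- cfc_decompose(phase_signal, amp_signal, fs, grid, clean, n_bins)
  ck <- parts$clean
  mi <- matrix(0, length(grid$amp_freqs), length(grid$phase_freqs),
               dimnames = list(grid$amp_freqs, grid$phase_freqs))
  for (pj in seq_along(grid$phase_freqs)) {
    b <- parts$bins[[pj]][ck]
    for (ai in seq_along(grid$amp_freqs)) {
      mi[ai, pj] <- mi_from_parts(b, parts$envs[[ai]][ck], n_bins)
    }
  }
  structure(list(mi = mi, grid = grid), class = "comodulogram")
}

#' Surrogate z-scores for a comodulogram
#'
#' Builds a null by circularly time-shifting every amplitude envelope by a
#' per-surrogate random offset of at least 1 s (destroying the phase-
#' amplitude pairing while preserving both marginals), recomputing the MI
#' matrix for each of `n_surrogates` shifts, and standardising the observed
#' MI against the surrogate mean and SD per cell.
#'
#' @inheritParams comodulogram
#' @param n_surrogates Number of surrogate shifts (default 100).
#' @param seed Integer RNG seed; results are deterministic given it.
#' @param min_shift_s Minimum shift, s (default 1).
#' @return A `z_comodulogram`: list with `z`, `mi`, `surrogate_mean`,
#'   `surrogate_sd` (matrices), `n_surrogates`, `grid`.
#' @export
surrogate_zscores <- function(phase_signal, amp_signal, fs,
                              grid = band_grid(), n_surrogates = 100L,
                              seed = 1L, clean = NULL, n_bins = 18L,
                              min_shift_s = 1) {
  parts <- cfc_decompose(phase_signal, amp_signal, fs, grid, clean, n_bins)
  n <- parts$n
  ck <- parts$clean
  lo <- round(min_shift_s * fs)
  hi <- n - lo
  if (hi <= lo) stop("signal too short for the minimum surrogate shift")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shifts <- sample.int(hi - lo, n_surrogates, replace = TRUE) + lo

  na <- length(grid$amp_freqs); np <- length(grid$phase_freqs)
  dn <- list(grid$amp_freqs, grid$phase_freqs)
  obs <- matrix(0, na, np, dimnames = dn)
  surr <- array(0, c(na, np, n_surrogates))
  bins_clean <- lapply(parts$bins, `[`, ck)
  for (pj in seq_len(np)) {
    b <- bins_clean[[pj]]
    for (ai in seq_len(na)) {
      obs[ai, pj] <- mi_from_parts(b, parts$envs[[ai]][ck], n_bins)
    }
  }
  for (s in seq_len(n_surrogates)) {
    sh <- shifts[s]
    for (ai in seq_len(na)) {
      env_s <- circular_shift(parts$envs[[ai]], sh)[ck]
      for (pj in seq_len(np)) {
        surr[ai, pj, s] <- mi_from_parts(bins_clean[[pj]], env_s, n_bins)
      }
    }
  }
  mu <- apply(surr, c(1, 2), mean)
  sd <- apply(surr, c(1, 2), stats::sd)
  z <- (obs - mu) / sd
  degenerate <- !is.finite(z)
  if (any(degenerate)) {
    warning("zero surrogate SD in ", sum(degenerate), " cell(s); z set to 0")
    z[degenerate] <- 0
  }
  dimnames(z) <- dimnames(mu) <- dimnames(sd) <- dn
  structure(list(z = z, mi = obs, surrogate_mean = mu, surrogate_sd = sd,
                 n_surrogates = n_surrogates, grid = grid),
            class = "z_comodulogram")
}

circular_shift <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0L) return(x)
  c(x[(n - k + 1L):n], x[1L:(n - k)])
}

#' Grid cell holding the maximum of a comodulogram
#'
#' @param com A `comodulogram` or `z_comodulogram`.
#' @return List with `phase_freq`, `amp_freq`, `value`.
#' @export
comodulogram_peak <- function(com) {
  m <- if (inherits(com, "z_comodulogram")) com$z else com$mi
  i <- which(m == max(m), arr.ind = TRUE)[1L, ]
  list(phase_freq = com$grid$phase_freqs[i[2L]],
       amp_freq = com$grid$amp_freqs[i[1L]],
       value = max(m))
}
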