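#' Theta-gamma coupling parameters for synthetic LFP
#'
#' Describes one generative condition: a theta oscillation whose phase
#' modulates the amplitude of a gamma oscillation, on top of a 1/f^alpha
#' broadband floor. `coupling_strength` is the fraction of the gamma
#' amplitude that is phase-modulated: 0 gives a constant gamma envelope,
#' 1 makes the envelope vanish at the anti-preferred phase.
#'
#' @param f_theta Theta frequency, Hz.
#' @param f_gamma Gamma frequency, Hz (must stay below Nyquist when used).
#' @param coupling_strength In `[0, 1]`.
#' @param theta_amp,gamma_amp Oscillation amplitudes (signal units).
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha noise.
#' @param noise_amp Noise RMS (signal units).
#' @param phi0 Phase offset of the envelope maximum, radians.
#' @param phase_jitter Wiener phase-drift rate, rad^2/s (default 1). In
#'   vivo theta is quasi-periodic: its phase wanders on a seconds
#'   timescale, which is precisely what makes time-shift surrogates a
#'   valid null. A strictly periodic oscillator (`phase_jitter = 0`) stays
#'   phase-locked to its own shifted envelope, so shift surrogates cannot
#'   zero out its coupling. The default broadens the theta line by well
#'   under the 2 Hz analysis bandwidth.
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(f_theta = 8, f_gamma = 60, coupling_strength = 0.8,
                          theta_amp = 1, gamma_amp = 0.5,
                          noise_exponent = 1.5, noise_amp = 0.3,
                          phi0 = 0, phase_jitter = 1) {
  if (coupling_strength < 0 || coupling_strength > 1) {
    stop("coupling_strength must lie in [0, 1]")
  }
  if (f_theta >= f_gamma) stop("f_theta must be below f_gamma")
  stopifnot(f_theta > 0, theta_amp >= 0, gamma_amp >= 0, noise_amp >= 0)
  structure(list(f_theta = f_theta, f_gamma = f_gamma,
                 coupling_strength = coupling_strength,
                 theta_amp = theta_amp, gamma_amp = gamma_amp,
                 noise_exponent = noise_exponent, noise_amp = noise_amp,
                 phi0 = phi0, phase_jitter = phase_jitter),
            class = "coupling_spec")
}

#' Shake-artifact parameters
#'
#' Burst artifacts emulate the rat shaking or knocking the headstage:
#' short damped oscillations far above the background amplitude, arriving
#' as a Poisson process.
#'
#' @param rate Events per second (>= 0).
#' @param duration_mean Mean burst duration, s. Durations are drawn
#'   Gamma(shape 4) around this mean, so bursts are fairly uniform in length.
#' @param burst_freq Oscillation frequency inside a burst, Hz.
#' @param burst_amp_factor Burst amplitude as a multiple of the background
#'   RMS (> 1).
#' @return An `artifact_spec` list.
#' @export
artifact_spec <- function(rate = 0.1, duration_mean = 1.5, burst_freq = 12,
                          burst_amp_factor = 10) {
  stopifnot(rate >= 0, duration_mean > 0, burst_freq > 0)
  if (burst_amp_factor <= 1) stop("burst_amp_factor must exceed 1")
  structure(list(rate = rate, duration_mean = duration_mean,
                 burst_freq = burst_freq,
                 burst_amp_factor = burst_amp_factor),
            class = "artifact_spec")
}

#' 1/f^alpha background noise
#'
#' White Gaussian noise shaped in the frequency domain to a power-law
#' spectrum and rescaled to the requested RMS.
#'
#' @param n Number of samples.
#' @param fs Sampling rate, Hz.
#' @param alpha Spectral exponent.
#' @param rms Target RMS.
#' @return Numeric vector of length `n`.
#' @keywords internal
pink_noise <- function(n, fs, alpha = 1.5, rms = 1) {
  if (rms == 0 || n < 2L) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]       # fold to physical frequency
  g <- numeric(n)
  nz <- f > 0
  g[nz] <- f[nz]^(-alpha / 2)
  x <- Re(stats::fft(W * g, inverse = TRUE)) / n
  s <- sqrt(mean(x^2))
  if (s == 0) return(numeric(n))
  x * (rms / s)
}

#' Generate a phase-amplitude-coupled LFP trace
#'
#' Returns the standard multiplicative coupling model
#' \deqn{x(t) = A_\theta \sin(2\pi f_\theta t) +
#'   A_\gamma [(1-c) + c (1 + \cos(2\pi f_\theta t + \phi_0))/2]
#'   \sin(2\pi f_\gamma t) + \epsilon(t)}
#' with `c = coupling_strength` and 1/f^alpha noise `epsilon`.
#'
#' @param spec A [coupling_spec()].
#' @param duration Seconds of signal.
#' @param fs Sampling rate, Hz.
#' @param seed Integer RNG seed (the generator is deterministic given it).
#' @return A single-channel [recording()].
#' @export
generate_coupled_signal <- function(spec, duration, fs, seed = 1L) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (spec$f_gamma >= fs / 2) {
    stop("f_gamma at or above Nyquist (", fs / 2, " Hz): aliasing")
  }
  n <- round(duration * fs)
  if (n < 2L) stop("need at least 2 samples")
  t <- (seq_len(n) - 1L) / fs
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  jit_sd <- sqrt(spec$phase_jitter / fs)
  drift_th <- if (jit_sd > 0) cumsum(stats::rnorm(n, 0, jit_sd)) else 0
  drift_g <- if (jit_sd > 0) cumsum(stats::rnorm(n, 0, jit_sd)) else 0
  ph_th <- 2 * pi * spec$f_theta * t + drift_th
  c_ <- spec$coupling_strength
  env <- spec$gamma_amp *
    ((1 - c_) + c_ * (1 + cos(ph_th + spec$phi0)) / 2)
  x <- spec$theta_amp * sin(ph_th) +
    env * sin(2 * pi * spec$f_gamma * t + drift_g) +
    pink_noise(n, fs, spec$noise_exponent, spec$noise_amp)
  recording(x, fs, "ch1")
}

# save/restore the global RNG state so generators are pure in `seed`
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Inject shake-burst artifacts with known ground truth
#'
#' Burst onsets follow a Poisson process at `spec$rate`; each burst is a
#' damped oscillation (envelope decaying to 40% of its onset value over the
#' burst duration) whose onset amplitude is `burst_amp_factor` times the
#' background RMS. The same events hit every channel, as a head-shake moves
#' the whole headstage.
#'
#' @param rec A [recording()].
#' @param spec An [artifact_spec()].
#' @param seed Integer RNG seed.
#' @return A list with elements `recording` (contaminated copy) and
#'   `ground_truth` (per-channel list of merged half-open `[start_s, end_s)`
#'   intervals).
#' @export
inject_artifacts <- function(rec, spec, seed = 1L) {
  stopifnot(inherits(rec, "recording"), inherits(spec, "artifact_spec"))
  n <- n_samples(rec)
  if (n < 1L) stop("empty recording")
  dur <- rec_duration(rec)
  gt <- stats::setNames(
    rep(list(matrix(numeric(0), ncol = 2,
                    dimnames = list(NULL, c("start_s", "end_s")))),
        length(rec$channels)),
    rec$channels)
  if (spec$rate == 0) {
    return(list(recording = rec, ground_truth = gt))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_ev <- stats::rpois(1L, spec$rate * dur)
  if (n_ev == 0L) return(list(recording = rec, ground_truth = gt))
  onsets <- sort(stats::runif(n_ev, 0, dur))
  lens <- stats::rgamma(n_ev, shape = 4, scale = spec$duration_mean / 4)
  lens <- pmax(lens, 2 / rec$fs)
  ends <- pmin(onsets + lens, dur)
  phases <- stats::runif(n_ev, 0, 2 * pi)
  samples <- rec$samples
  bg_rms <- apply(samples, 1L, function(x) sqrt(mean(x^2)))
  for (e in seq_len(n_ev)) {
    i0 <- floor(onsets[e] * rec$fs)
    i1 <- min(floor(ends[e] * rec$fs), n)
    if (i1 <= i0) next
    idx <- (i0 + 1L):i1
    tt <- (idx - idx[1L]) / rec$fs
    blen <- ends[e] - onsets[e]
    envelope <- exp(-tt * log(2.5) / blen)   # decays to 0.4 over the burst
    # sqrt(2) so the onset RMS (not the sine peak) sits at
    # burst_amp_factor x background RMS
    wave <- sqrt(2) * envelope * sin(2 * pi * spec$burst_freq * tt +
                                       phases[e])
    for (ch in seq_len(nrow(samples))) {
      samples[ch, idx] <- samples[ch, idx] +
        spec$burst_amp_factor * bg_rms[ch] * wave
    }
  }
  iv <- merge_intervals(cbind(onsets, ends))
  colnames(iv) <- c("start_s", "end_s")
  for (ch in rec$channels) gt[[ch]] <- iv
  list(recording = recording(samples, rec$fs, rec$channels),
       ground_truth = gt)
}

#' Merge overlapping half-open intervals
#' @param iv Two-column matrix of `[start, end)` rows.
#' @return Sorted, merged matrix.
#' @keywords internal
merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) for (k in 2L:nrow(iv)) {
    last <- nrow(out)
    if (iv[k, 1L] <= out[last, 2L]) {
      out[last, 2L] <- max(out[last, 2L], iv[k, 2L])
    } else {
      out <- rbind(out, iv[k, , drop = FALSE])
    }
  }
  out
}

#' Session layout and generative parameters for a synthetic water-maze
#' recording
#'
#' The session is one continuous two-channel recording: a pre-maze baseline,
#' then for each trial a swim period (ending at the platform-reach event)
#' followed by a platform period. Each task phase carries its own
#' [coupling_spec()] and theta-coherence target between the two channels.
#'
#' @param fs Sampling rate, Hz (default 1000).
#' @param pre_maze_duration Baseline length, s (default 60).
#' @param n_trials Number of trials.
#' @param trial_durations Swim duration per trial, s (recycled if scalar).
#' @param platform_duration Platform period per trial, s (default 15).
#' @param coupling Named list of [coupling_spec()]s for `pre_maze`, `maze`,
#'   `platform`; a single spec is recycled to all phases.
#' @param theta_coherence Target between-channel theta coherence in `[0, 1]`;
#'   scalar or named per-phase vector.
#' @param artifacts An [artifact_spec()] or `NULL` for a clean session.
#' @param channels Two channel labels.
#' @param seed Integer RNG seed.
#' @return A `session_spec` list.
#' @export
session_spec <- function(fs = 1000, pre_maze_duration = 60, n_trials = 4,
                         trial_durations = 20, platform_duration = 15,
                         coupling = coupling_spec(),
                         theta_coherence = 0.6,
                         artifacts = NULL,
                         channels = c("dCA1", "dlSTR"),
                         seed = 1L) {
  phases <- c("pre_maze", "maze", "platform")
  if (inherits(coupling, "coupling_spec")) {
    coupling <- stats::setNames(rep(list(coupling), 3L), phases)
  }
  if (!all(phases %in% names(coupling))) {
    stop("coupling must name specs for pre_maze, maze and platform")
  }
  trial_durations <- rep(trial_durations, length.out = n_trials)
  if (length(theta_coherence) == 1L && is.null(names(theta_coherence))) {
    theta_coherence <- stats::setNames(rep(theta_coherence, 3L), phases)
  }
  if (!all(phases %in% names(theta_coherence))) {
    stop("theta_coherence must be scalar or named per phase")
  }
  if (any(theta_coherence < 0 | theta_coherence > 1)) {
    stop("theta_coherence must lie in [0, 1]")
  }
  stopifnot(pre_maze_duration > 0, platform_duration > 0,
            all(trial_durations > 0), length(channels) == 2L)
  structure(list(fs = fs, pre_maze_duration = pre_maze_duration,
                 n_trials = n_trials, trial_durations = trial_durations,
                 platform_duration = platform_duration,
                 coupling = coupling, theta_coherence = theta_coherence,
                 artifacts = artifacts, channels = channels,
                 seed = as.integer(seed)),
            class = "session_spec")
}

# narrowband unit-RMS Gaussian process around f0 (half-bandwidth bw/2)
narrowband_noise <- function(n, fs, f0, bw = 2) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  g <- as.numeric(abs(f - f0) <= bw / 2)
  x <- Re(stats::fft(W * g, inverse = TRUE)) / n
  s <- sqrt(mean(x^2))
  if (s == 0) return(numeric(n))
  x / s
}

# Mixing weight w so that two channels built as
#   theta_amp * (w*s + sqrt(1-w^2)*u_i) + noise
# reach a target theta-band coherence. With unit-RMS narrowband processes
# of half-bandwidth bw the theta spectral density is theta_rms^2/bw and the
# noise density at f_theta follows the 1/f^alpha normalisation; coherence
# = w^4 * (Dt/(Dt+Dn))^2, inverted for w and capped at 1.
coherence_mix_weight <- function(target, theta_rms, f_theta, bw,
                                 noise_amp, alpha, fs, n) {
  if (target <= 0) return(0)
  Dt <- theta_rms^2 / bw
  Dn <- 0
  if (noise_amp > 0) {
    f <- seq(fs / n, fs / 2, by = fs / n)
    dens <- f^(-alpha)
    dens <- dens / (sum(dens) * fs / n) * noise_amp^2  # integrates to rms^2
    Dn <- dens[which.min(abs(f - f_theta))]
  }
  w2 <- sqrt(target) * (Dt + Dn) / Dt
  sqrt(min(w2, 1))
}

#' Generate a synthetic two-channel water-maze session
#'
#' Each phase segment gets an amplitude-sustained theta oscillation whose
#' stochastic phase comes from a narrowband process mixing a shared and a
#' per-channel independent component (the mixing weight is solved for the
#' phase's coherence target), a gamma oscillation whose envelope is
#' modulated by the channel's own instantaneous theta phase, and a 1/f
#' background. Artifacts,
#' if requested, are injected over the assembled session.
#'
#' @param spec A [session_spec()].
#' @return List with `recording`, `events` (an [event_table()]) and
#'   `ground_truth` (artifact intervals per channel plus the per-phase
#'   generative parameters).
#' @export
generate_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  segs <- list(list(phase = "pre_maze", dur = spec$pre_maze_duration))
  for (k in seq_len(spec$n_trials)) {
    segs[[length(segs) + 1L]] <- list(phase = "maze",
                                      dur = spec$trial_durations[k],
                                      trial = k)
    segs[[length(segs) + 1L]] <- list(phase = "platform",
                                      dur = spec$platform_duration,
                                      trial = k)
  }

  fs <- spec$fs
  ch_sig <- list(numeric(0), numeric(0))
  ev_trial <- integer(0); ev_name <- character(0); ev_t <- numeric(0)
  t_cursor <- 0
  theta_bw <- 2

  for (seg in segs) {
    cs <- spec$coupling[[seg$phase]]
    n <- round(seg$dur * fs)
    t <- (seq_len(n) - 1L) / fs
    theta_rms <- cs$theta_amp / sqrt(2)      # sinusoid-equivalent amplitude
    w <- coherence_mix_weight(spec$theta_coherence[[seg$phase]], theta_rms,
                              cs$f_theta, theta_bw, cs$noise_amp,
                              cs$noise_exponent, fs, n)
    shared <- narrowband_noise(n, fs, cs$f_theta, theta_bw)
    for (ch in 1:2) {
      indep <- narrowband_noise(n, fs, cs$f_theta, theta_bw)
      # envelope-normalised theta: amplitude-sustained oscillation with a
      # stochastic (narrowband) phase, as in maze-running LFP; the mixing
      # weight sets the between-channel phase correlation
      mix <- w * shared + sqrt(1 - w^2) * indep
      ph <- Arg(analytic_signal(mix))
      theta <- cs$theta_amp * cos(ph)
      c_ <- cs$coupling_strength
      env <- cs$gamma_amp * ((1 - c_) + c_ * (1 + cos(ph + cs$phi0)) / 2)
      gamma <- env * sin(2 * pi * cs$f_gamma * t + stats::runif(1, 0, 2 * pi))
      x <- theta + gamma + pink_noise(n, fs, cs$noise_exponent, cs$noise_amp)
      ch_sig[[ch]] <- c(ch_sig[[ch]], x)
    }
    if (seg$phase == "maze") {
      ev_trial <- c(ev_trial, seg$trial, seg$trial)
      ev_name <- c(ev_name, "trial_start", "platform_reach")
      ev_t <- c(ev_t, t_cursor, t_cursor + seg$dur)
    }
    t_cursor <- t_cursor + n / fs
  }

  rec <- recording(rbind(ch_sig[[1L]], ch_sig[[2L]]), fs, spec$channels)
  events <- event_table(ev_trial, ev_name, ev_t)
  phase_params <- lapply(spec$coupling, unclass)
  if (!is.null(spec$artifacts)) {
    inj <- inject_artifacts(rec, spec$artifacts, seed = spec$seed + 1L)
    rec <- inj$recording
    gt_art <- inj$ground_truth
  } else {
    gt_art <- stats::setNames(
      rep(list(matrix(numeric(0), ncol = 2,
                      dimnames = list(NULL, c("start_s", "end_s")))), 2L),
      spec$channels)
  }
  list(recording = rec, events = events,
       ground_truth = list(artifact_intervals = gt_art,
                           phase_coupling = phase_params,
                           theta_coherence = spec$theta_coherence))
}
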