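#' Pipeline configuration
#'
#' Gathers every tunable constant of the analysis chain with the task's
#' defaults: 4 s maze window before platform reach, 60 s pre-maze baseline,
#' 15 s platform epochs, 0.25 s scrub windows at k_mad = 6, 2 s / 1 s
#' overlap multitaper windows with 3 tapers, theta band 5-12 Hz, and the
#' comodulogram grid with 100 circular-shift surrogates.
#'
#' @param maze_window,pre_maze_duration,platform_duration Epoching, s.
#' @param scrub_window,k_mad Artifact detection parameters.
#' @param spectral A [spectral_params()].
#' @param theta_band Peak-extraction band, Hz.
#' @param grid A [band_grid()] for cross-frequency scanning.
#' @param n_surrogates Surrogates per comodulogram (default 100).
#' @param cfc_phases Task phases to scan for coupling.
#' @param cfc_pairings List of `c(phase_channel, amp_channel)` pairs; `NULL`
#'   means all four combinations of the two channels.
#' @param do_cfc Run the cross-frequency stage (the slowest one).
#' @param target_fs Decimate to this rate first; `NULL` keeps the input rate.
#' @param seed Integer seed for the surrogate RNG.
#' @return A `run_config` list.
#' @export
run_config <- function(maze_window = 4, pre_maze_duration = 60,
                       platform_duration = 15,
                       scrub_window = 0.25, k_mad = 6,
                       spectral = spectral_params(),
                       theta_band = c(5, 12),
                       grid = band_grid(),
                       n_surrogates = 100L,
                       cfc_phases = "maze",
                       cfc_pairings = NULL,
                       do_cfc = TRUE,
                       target_fs = NULL,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

# full-length analysis windows inside the epochs of one phase, minus any
# that touch an artifact interval
phase_clean_windows <- function(epochs, phase, params, mask,
                                drop_short = TRUE) {
  eps <- epochs[epochs$phase == phase, , drop = FALSE]
  if (drop_short) eps <- eps[!eps$short, , drop = FALSE]
  win <- lapply(seq_len(nrow(eps)), function(k) {
    sliding_windows(eps$t_end[k] - eps$t_start[k], params,
                    offset = eps$t_start[k])
  })
  win <- do.call(rbind, win)
  if (is.null(win) || !nrow(win)) return(NULL)
  mask_windows(mask, win)
}

# cross-frequency scan over the pooled epochs of one phase; filtering and
# the Hilbert transform run per epoch (no cross-epoch discontinuities) and
# surrogate shifts are drawn per epoch
cfc_phase_scan <- function(phase_segs, amp_segs, fs, grid, n_surrogates,
                           seed, n_bins = 18L) {
  parts <- lapply(seq_along(phase_segs), function(k) {
    cfc_decompose(phase_segs[[k]], amp_segs[[k]], fs, grid,
                  clean = NULL, n_bins = n_bins)
  })
  np <- length(grid$phase_freqs); na <- length(grid$amp_freqs)
  dn <- list(grid$amp_freqs, grid$phase_freqs)
  bins <- lapply(seq_len(np), function(pj) {
    unlist(lapply(parts, function(p) p$bins[[pj]]), use.names = FALSE)
  })
  envs <- lapply(seq_len(na), function(ai) {
    lapply(parts, function(p) p$envs[[ai]])     # keep per-epoch for shifts
  })
  obs <- matrix(0, na, np, dimnames = dn)
  for (pj in seq_len(np)) for (ai in seq_len(na)) {
    obs[ai, pj] <- mi_from_parts(bins[[pj]],
                                 unlist(envs[[ai]], use.names = FALSE),
                                 n_bins)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  seg_len <- vapply(phase_segs, length, integer(1))
  lo <- pmin(round(fs), floor(seg_len / 3))     # >= 1 s or a third of epoch
  surr <- array(0, c(na, np, n_surrogates))
  for (s in seq_len(n_surrogates)) {
    sh <- vapply(seq_along(seg_len), function(k) {
      sample.int(max(seg_len[k] - 2L * lo[k], 1L), 1L) + as.integer(lo[k])
    }, integer(1))
    for (ai in seq_len(na)) {
      env_s <- unlist(lapply(seq_along(envs[[ai]]), function(k) {
        circular_shift(envs[[ai]][[k]], sh[k])
      }), use.names = FALSE)
      for (pj in seq_len(np)) {
        surr[ai, pj, s] <- mi_from_parts(bins[[pj]], env_s, n_bins)
      }
    }
  }
  mu <- apply(surr, c(1, 2), mean)
  sdm <- apply(surr, c(1, 2), stats::sd)
  z <- (obs - mu) / sdm
  z[!is.finite(z)] <- 0
  dimnames(z) <- dn
  list(mi = obs, z = z, surrogate_mean = mu, surrogate_sd = sdm,
       n_surrogates = n_surrogates, grid = grid)
}

#' Run the full water-maze LFP analysis on one session
#'
#' Stages: optional decimation, task-phase epoching, per-channel artifact
#' scrubbing with a recovered-signal report, RMS-normalised multitaper PSD
#' and between-channel coherence per phase with theta peaks, per-epoch
#' theta peaks fed into a one-way ANOVA across phases (with Bonferroni
#' follow-ups), and theta-gamma comodulograms with surrogate z-scores for
#' the requested channel pairings. Deterministic given the config seed.
#'
#' @param rec A two-channel [recording()].
#' @param events An [event_table()].
#' @param config A [run_config()].
#' @return A `session_report` list; see the vignette for the layout.
#' @export
run_pipeline <- function(rec, events, config = run_config()) {
  stopifnot(inherits(rec, "recording"), length(rec$channels) == 2L)
  if (!is.null(config$target_fs) && config$target_fs != rec$fs) {
    rec <- decimate_recording(rec, config$target_fs)
  }
  fs <- rec$fs
  epochs <- extract_epochs(rec, events,
                           maze_window = config$maze_window,
                           platform_duration = config$platform_duration,
                           pre_maze_duration = config$pre_maze_duration)

  masks <- scrub_recording(rec, epochs, window = config$scrub_window,
                           k_mad = config$k_mad)
  scrub <- recovered_fraction(masks, n_samples(rec), fs)
  union_mask <- merge_intervals(do.call(rbind, lapply(masks, unclass)))

  # per-phase pooled spectra; pre-maze split into sub-epochs so every phase
  # contributes several independent peak observations to the phase ANOVA
  n_sub <- max(2L, sum(epochs$phase == "maze"))
  pre <- epochs[epochs$phase == "pre_maze", ]
  sub_len <- (pre$t_end - pre$t_start) / n_sub
  sub_pre <- data.frame(phase = "pre_maze", trial_id = seq_len(n_sub),
                        t_start = pre$t_start + (seq_len(n_sub) - 1) * sub_len,
                        t_end = pre$t_start + seq_len(n_sub) * sub_len,
                        short = FALSE)
  epochs_obs <- rbind(sub_pre, epochs[epochs$phase != "pre_maze", ])

  phases <- c("pre_maze", "maze", "platform")
  spectra <- list(); peaks <- list(); coh <- list()
  peak_obs <- list()
  for (ph in phases) {
    for (ch in rec$channels) {
      x <- channel_signal(rec, ch)
      win <- phase_clean_windows(epochs, ph, config$spectral, masks[[ch]])
      if (is.null(win) || !nrow(win)) next
      psd <- multitaper_psd(x, fs, config$spectral, windows = win)
      cl <- clean_sample_mask(masks[[ch]], length(x), fs)
      psd <- rms_normalize(psd, sqrt(mean(x[cl]^2)))
      spectra[[ph]][[ch]] <- psd
      peaks[[ph]][[ch]] <- peak_in_band(psd, config$theta_band)
    }
    winu <- phase_clean_windows(epochs, ph, config$spectral, union_mask)
    if (!is.null(winu) && nrow(winu)) {
      co <- multitaper_coherence(channel_signal(rec, 1L),
                                 channel_signal(rec, 2L),
                                 fs, config$spectral, windows = winu)
      coh[[ph]] <- co
      peaks[[ph]]$coherence <- peak_in_band(co, config$theta_band)
    }
    # per-epoch (observation-level) theta peaks for the phase ANOVA
    eps <- epochs_obs[epochs_obs$phase == ph & !epochs_obs$short, ]
    for (k in seq_len(nrow(eps))) {
      for (ch in rec$channels) {
        win <- phase_clean_windows(eps[k, ], ph, config$spectral,
                                   masks[[ch]])
        if (is.null(win) || !nrow(win)) next
        x <- channel_signal(rec, ch)
        p <- multitaper_psd(x, fs, config$spectral, windows = win)
        cl <- clean_sample_mask(masks[[ch]], length(x), fs)
        p <- rms_normalize(p, sqrt(mean(x[cl]^2)))
        peak_obs[[length(peak_obs) + 1L]] <- data.frame(
          phase = ph, channel = ch, measure = "psd",
          value = peak_in_band(p, config$theta_band)$value)
      }
      winu <- phase_clean_windows(eps[k, ], ph, config$spectral, union_mask)
      if (!is.null(winu) && nrow(winu) &&
          nrow(winu) * config$spectral$n_tapers >= 2L) {
        co <- multitaper_coherence(channel_signal(rec, 1L),
                                   channel_signal(rec, 2L),
                                   fs, config$spectral, windows = winu)
        peak_obs[[length(peak_obs) + 1L]] <- data.frame(
          phase = ph, channel = "pair", measure = "coherence",
          value = peak_in_band(co, config$theta_band)$value)
      }
    }
  }
  peak_obs <- do.call(rbind, peak_obs)

  anova_tables <- list()
  for (ch in rec$channels) {
    d <- peak_obs[peak_obs$channel == ch & peak_obs$measure == "psd", ]
    g <- split(d$value, d$phase)
    g <- g[vapply(g, length, integer(1)) >= 2L]
    if (length(g) >= 2L) {
      anova_tables[[paste0("psd_", ch)]] <-
        list(anova = one_way_anova(g), pairwise = bonferroni_pairwise(g))
    }
  }
  dco <- peak_obs[peak_obs$measure == "coherence", ]
  gco <- split(dco$value, dco$phase)
  gco <- gco[vapply(gco, length, integer(1)) >= 2L]
  if (length(gco) >= 2L) {
    anova_tables$coherence <-
      list(anova = one_way_anova(gco), pairwise = bonferroni_pairwise(gco))
  }

  cfc <- list()
  if (isTRUE(config$do_cfc)) {
    pairings <- config$cfc_pairings
    if (is.null(pairings)) {
      chs <- rec$channels
      pairings <- list(c(chs[1], chs[1]), c(chs[2], chs[1]),
                       c(chs[1], chs[2]), c(chs[2], chs[2]))
    }
    seed_k <- config$seed
    for (ph in config$cfc_phases) {
      eps <- epochs[epochs$phase == ph & !epochs$short, , drop = FALSE]
      if (!nrow(eps)) next
      for (pr in pairings) {
        segs_p <- lapply(seq_len(nrow(eps)), function(k) {
          epoch_signal(rec, eps[k, ], pr[1])
        })
        segs_a <- lapply(seq_len(nrow(eps)), function(k) {
          epoch_signal(rec, eps[k, ], pr[2])
        })
        key <- paste0(ph, ":", pr[1], "->", pr[2])
        seed_k <- seed_k + 1L
        cfc[[key]] <- cfc_phase_scan(segs_p, segs_a, fs, config$grid,
                                     config$n_surrogates, seed = seed_k)
      }
    }
  }

  structure(list(epochs = epochs, masks = masks, scrub = scrub,
                 spectra = spectra, coherence = coh, peaks = peaks,
                 peak_observations = peak_obs, anova = anova_tables,
                 cfc = cfc, config = config, fs = fs),
            class = "session_report")
}

#' Write a small demonstration dataset
#'
#' Emits a compact two-channel synthetic session (about 70 s) with
#' phase-dependent coupling and a few shake artifacts, plus simulated trial
#' logs: the recording (float32 + JSON sidecar), the event table (CSV), the
#' artifact ground truth (JSON) and behaviour logs (CSV).
#'
#' @param out_dir Writable directory (created if missing).
#' @param seed Integer RNG seed.
#' @return Named list of file paths.
#' @export
demo_dataset <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- coupling_spec(coupling_strength = 0.3, theta_amp = 1)
  maze <- coupling_spec(coupling_strength = 0.8, theta_amp = 2)
  spec <- session_spec(
    fs = 1000, pre_maze_duration = 30, n_trials = 2, trial_durations = 10,
    platform_duration = 10,
    coupling = list(pre_maze = base, maze = maze, platform = base),
    theta_coherence = c(pre_maze = 0.3, maze = 0.7, platform = 0.5),
    artifacts = artifact_spec(rate = 0.05, duration_mean = 1),
    seed = seed)
  ses <- generate_session(spec)
  paths <- list(
    recording = file.path(out_dir, "session.f32"),
    events = file.path(out_dir, "events.csv"),
    ground_truth = file.path(out_dir, "ground_truth.json"),
    behavior = file.path(out_dir, "trials.csv"))
  write_recording(ses$recording, paths$recording)
  write_event_table(ses$events, paths$events)
  gt <- ses$ground_truth
  gt$artifact_intervals <- lapply(gt$artifact_intervals, function(m) {
    as.data.frame(m)
  })
  jsonlite::write_json(gt, paths$ground_truth, auto_unbox = TRUE, digits = NA)
  utils::write.csv(simulate_trial_logs(seed = seed), paths$behavior,
                   row.names = FALSE, quote = FALSE)
  paths
}
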