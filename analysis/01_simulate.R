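#!/usr/bin/env Rscript

# Build the synthetic study: one two-channel water-maze session per "rat"
# (4 animals), with elevated theta amplitude/coherence and stronger
# theta-gamma coupling inside the maze, plus shake-burst artifacts, and
# simulated double-H trial logs for an instrumented and a sham group.
# Writes the raw recordings and all metadata under results/data/.

library(mazelfp)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

n_rats <- 4
for (r in seq_len(n_rats)) {
  base <- coupling_spec(theta_amp = 1, gamma_amp = 0.5,
                        coupling_strength = 0.3)
  maze <- coupling_spec(theta_amp = 2, gamma_amp = 0.5,
                        coupling_strength = 0.8)
  spec <- session_spec(
    fs = 1000, pre_maze_duration = 60, n_trials = 4,
    trial_durations = 12, platform_duration = 15,
    coupling = list(pre_maze = base, maze = maze, platform = base),
    theta_coherence = c(pre_maze = 0.3, maze = 0.6, platform = 0.4),
    artifacts = artifact_spec(rate = 0.03, duration_mean = 1,
                              burst_amp_factor = 10),
    seed = 100 + r)
  ses <- generate_session(spec)
  write_recording(ses$recording, file.path(out, sprintf("rat%02d.f32", r)))
  write_event_table(ses$events,
                    file.path(out, sprintf("rat%02d_events.csv", r)))
  jsonlite::write_json(
    lapply(ses$ground_truth$artifact_intervals, as.data.frame),
    file.path(out, sprintf("rat%02d_artifacts.json", r)),
    auto_unbox = TRUE, digits = NA)
  cat(sprintf("rat %d: %.0f s of signal, %d artifact bursts\n", r,
              ncol(ses$recording$samples) / 1000,
              nrow(ses$ground_truth$artifact_intervals[[1]])))
}

# behaviour: two groups of rats across 4 training sessions
beh <- do.call(rbind, lapply(seq_len(2 * n_rats), function(r) {
  cbind(rat = r, group = if (r <= n_rats) "wireless" else "sham",
        simulate_trial_logs(n_sessions = 4, trials_per_session = 4,
                            seed = 200 + r))
}))
write.csv(beh, file.path(out, "behavior.csv"), row.names = FALSE)
cat(sprintf("behaviour: %d trials from %d rats\n", nrow(beh), 2 * n_rats))
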