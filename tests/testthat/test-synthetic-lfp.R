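test_that("coupled-signal generator honours its analytic envelope", {
  # full coupling, no noise, no phase drift: envelope hits gamma_amp at the
  # preferred phase and 0 at the anti-preferred phase
  fs <- 1000
  spec <- coupling_spec(f_theta = 8, f_gamma = 64, coupling_strength = 1,
                        theta_amp = 0, gamma_amp = 1, noise_amp = 0,
                        phase_jitter = 0)
  x <- channel_signal(generate_coupled_signal(spec, 2, fs, seed = 1), 1)
  t <- (seq_along(x) - 1) / fs
  env <- (1 + cos(2 * pi * 8 * t)) / 2
  expect_lt(max(abs(abs(x) - env * abs(sin(2 * pi * 64 * t)))), 1e-12)
  expect_equal(max(env), 1)
  expect_lt(min(env), 1e-3)   # trough between sample points at 8 Hz / 1 kHz

  # c = 0: constant envelope
  spec0 <- coupling_spec(coupling_strength = 0, theta_amp = 0,
                         gamma_amp = 1, noise_amp = 0, phase_jitter = 0)
  x0 <- channel_signal(generate_coupled_signal(spec0, 2, fs, seed = 1), 1)
  expect_equal(sd(Mod(analytic_signal(x0))[100:1900]), 0, tolerance = 1e-3)
})

test_that("generator validates sampling and coupling bounds", {
  expect_error(coupling_spec(coupling_strength = 1.2), "0, 1")
  expect_error(coupling_spec(f_theta = 70, f_gamma = 60), "below")
  expect_error(
    generate_coupled_signal(coupling_spec(f_gamma = 600), 1, 1000),
    "Nyquist")
})

test_that("generated spectrum peaks at the generative frequencies", {
  x <- coupled_trace(seed = 2, duration = 30, noise_amp = 0.05)
  psd <- multitaper_psd(x, 1000)
  th <- peak_in_band(psd, c(4, 15))
  gm <- peak_in_band(psd, c(40, 90))
  expect_lt(abs(th$freq - 8), 1)
  expect_lt(abs(gm$freq - 60), 2)
})

test_that("generation is deterministic in the seed", {
  s <- coupling_spec()
  a <- generate_coupled_signal(s, 5, 1000, seed = 9)
  b <- generate_coupled_signal(s, 5, 1000, seed = 9)
  d <- generate_coupled_signal(s, 5, 1000, seed = 10)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, d$samples))

  spec <- session_spec(pre_maze_duration = 5, n_trials = 1,
                       trial_durations = 5, platform_duration = 5, seed = 3)
  expect_identical(generate_session(spec)$recording$samples,
                   generate_session(spec)$recording$samples)
})

test_that("artifact injection matches its Poisson budget and ground truth", {
  spec <- artifact_spec(rate = 0.1, duration_mean = 1.5,
                        burst_amp_factor = 10)
  rec <- generate_coupled_signal(coupling_spec(coupling_strength = 0.3),
                                 100, 1000, seed = 4)
  # rate 0: identity
  none <- inject_artifacts(rec, artifact_spec(rate = 0), seed = 1)
  expect_identical(none$recording$samples, rec$samples)
  expect_equal(nrow(none$ground_truth[[1]]), 0L)

  # total artifact time ~ rate * duration_mean * T over seeds
  fracs <- vapply(1:8, function(s) {
    inj <- inject_artifacts(rec, spec, seed = s)
    gt <- inj$ground_truth[[1]]
    sum(gt[, 2] - gt[, 1]) / 100
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.15), 0.05)

  # flagged-window RMS far above clean RMS at 10x bursts
  inj <- inject_artifacts(rec, spec, seed = 2)
  x <- channel_signal(inj$recording, 1)
  truth <- !clean_sample_mask(
    structure(inj$ground_truth[[1]], class = "artifact_mask"),
    length(x), 1000)
  expect_gt(sqrt(mean(x[truth]^2)) / sqrt(mean(x[!truth]^2)), 5)
})

test_that("session layout produces the requested events and epochs", {
  spec <- session_spec(pre_maze_duration = 10, n_trials = 4,
                       trial_durations = 6, platform_duration = 15,
                       seed = 5)
  ses <- generate_session(spec)
  ev <- ses$events
  expect_equal(sum(ev$event == "platform_reach"), 4L)
  ep <- extract_epochs(ses$recording, ev, pre_maze_duration = 10)
  plat <- ep[ep$phase == "platform", ]
  expect_equal(nrow(plat), 4L)
  expect_equal(plat$t_end - plat$t_start, rep(15, 4))
  expect_equal(rec_duration <- ncol(ses$recording$samples) / 1000,
               10 + 4 * (6 + 15))
})

test_that("full shared theta gives near-unit theta coherence", {
  spec <- session_spec(fs = 1000, pre_maze_duration = 40, n_trials = 1,
                       trial_durations = 5, platform_duration = 5,
                       theta_coherence = 1.0, seed = 6)
  ses <- generate_session(spec)
  x <- channel_signal(ses$recording, 1)[1:40000]
  y <- channel_signal(ses$recording, 2)[1:40000]
  co <- multitaper_coherence(x, y, 1000)
  expect_gt(peak_in_band(co, c(5, 12))$value, 0.95)
})
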