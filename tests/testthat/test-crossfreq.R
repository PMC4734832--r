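test_that("zero-phase band-pass preserves in-band tones and kills
           out-of-band ones", {
  fs <- 1000
  t <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 8 * t)
  y <- bandpass_zero_phase(x, fs, 7, 9)
  mid <- 2000:8000
  expect_lt(abs(sd(y[mid]) / sd(x[mid]) - 1), 0.05)
  cc <- ccf(x[mid], y[mid], lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)    # zero phase delay

  stop_band <- bandpass_zero_phase(x, fs, 50, 70)
  expect_lt(sqrt(mean(stop_band^2)) / sqrt(mean(x^2)), 0.01)
  expect_equal(bandpass_zero_phase(numeric(1000), fs, 7, 9), numeric(1000))
  expect_error(bandpass_zero_phase(x, fs, 9, 7), "band")
  expect_error(bandpass_zero_phase(x, fs, 100, 600), "band")
})

test_that("analytic signal yields the expected phase and envelope", {
  fs <- 500
  t <- (0:(6 * fs - 1)) / fs
  x <- 2.5 * sin(2 * pi * 8 * t)
  pe <- phase_and_envelope(x)
  mid <- 500:2500
  expect_lt(max(abs(pe$envelope[mid] - 2.5) / 2.5), 0.02)
  expect_true(all(pe$envelope >= 0))
  expect_true(all(pe$phase >= -pi & pe$phase < pi))
  # phase advances by 2 pi f / fs per sample (mod 2 pi)
  dph <- diff(pe$phase[mid]) %% (2 * pi)
  expect_lt(max(abs(dph - 2 * pi * 8 / fs)), 1e-3)
  # cosine-aligned oscillation has phase 0 at its peak
  xc <- cos(2 * pi * 8 * t)
  pc <- phase_and_envelope(xc)
  peak_idx <- which.max(xc[500:1000]) + 499
  expect_lt(abs(pc$phase[peak_idx]), 0.05)
})

test_that("phase-amplitude histogram bins and normalises correctly", {
  n_bins <- 18
  centers <- seq(-pi + pi / n_bins, pi - pi / n_bins, length.out = n_bins)
  # constant amplitude over uniform phase: ~ 1/18 everywhere
  ph <- rep(centers, 50)
  d <- phase_amplitude_histogram(ph, rep(1, length(ph)))
  expect_equal(d$weights, rep(1 / 18, 18), tolerance = 1e-12)
  expect_equal(sum(d$weights), 1)

  # amplitude confined to one bin
  amp <- as.numeric(bin_idx <- findInterval(ph, d$edges,
                                            rightmost.closed = TRUE) == 6)
  d2 <- phase_amplitude_histogram(ph, amp)
  expect_equal(d2$weights[6], 1)
  expect_equal(sum(d2$weights > 0), 1L)

  # hand-computed: 2 samples per bin, all amplitude 1 except 19 on one
  # bin's pair -> that bin holds (19 + 1) / (35 + 19) = 20/54
  ph3 <- rep(centers, 2)
  amp3 <- rep(1, 36)
  amp3[5] <- 19
  d3 <- phase_amplitude_histogram(ph3, amp3)
  expect_equal(d3$weights[5], 20 / 54, tolerance = 1e-12)

  # phase exactly pi wraps into the first bin
  d4 <- phase_amplitude_histogram(c(pi, -pi), c(1, 1))
  expect_equal(d4$weights[1], 1)
  expect_error(phase_amplitude_histogram(ph, rep(0, length(ph))), "zero")
})

test_that("modulation index matches a brute-force entropy oracle", {
  expect_equal(modulation_index(rep(1 / 18, 18)), 0)
  expect_equal(modulation_index(c(1, rep(0, 17))), 1)
  expect_equal(modulation_index(c(0.5, 0.5, rep(0, 16))),
               1 - log(2) / log(18), tolerance = 1e-12)
  set.seed(11)
  for (k in 1:200) {
    p <- random_simplex(18)
    mi <- modulation_index(p)
    expect_equal(mi, mi_oracle(p), tolerance = 1e-12)
    expect_gte(mi, 0)
    expect_lte(mi, 1)
  }
})

test_that("MI is invariant to amplitude scaling and phase-bin rotation", {
  x <- coupled_trace(seed = 13, duration = 20)
  bp <- bandpass_zero_phase(x, 1000, 7, 9)
  pe <- phase_and_envelope(bp)
  env <- phase_and_envelope(bandpass_zero_phase(x, 1000, 50, 70))$envelope
  d <- phase_amplitude_histogram(pe$phase, env)
  mi <- modulation_index(d)
  d_scaled <- phase_amplitude_histogram(pe$phase, 1000 * env)
  expect_equal(modulation_index(d_scaled), mi, tolerance = 1e-12)
  rotated <- c(d$weights[6:18], d$weights[1:5])
  expect_equal(modulation_index(rotated), mi, tolerance = 1e-12)
})

test_that("comodulogram finds the generative coupling cell", {
  x <- coupled_trace(seed = 3, duration = 60, c = 0.8)
  com <- comodulogram(x, x, 1000)
  pk <- comodulogram_peak(com)
  expect_lte(abs(pk$phase_freq - 8), 1)         # one grid step
  expect_lte(abs(pk$amp_freq - 60), 5)
  expect_true(all(com$mi >= 0 & com$mi <= 1))
  # within-channel pairing equals the cross-channel path on a duplicate
  com2 <- comodulogram(x, x + 0, 1000)
  expect_identical(com$mi, com2$mi)
})

test_that("clean-sample masks drop artifact samples from the histogram", {
  x <- coupled_trace(seed = 6, duration = 30)
  clean <- rep(TRUE, length(x))
  clean[1:5000] <- FALSE
  g <- true_cell_grid()
  m_all <- comodulogram(x, x, 1000, grid = g)
  m_masked <- comodulogram(x, x, 1000, grid = g, clean = clean)
  expect_false(identical(m_all$mi, m_masked$mi))
  expect_error(comodulogram(x, x, 1000, grid = g,
                            clean = c(clean[1:6000],
                                      rep(FALSE, length(x) - 6000))),
               "insufficient")
})

test_that("surrogate z-scores are deterministic and detect coupling", {
  x <- coupled_trace(seed = 5, duration = 60, c = 0.8)
  g <- true_cell_grid()
  z1 <- surrogate_zscores(x, x, 1000, grid = g, n_surrogates = 50,
                          seed = 21)
  z2 <- surrogate_zscores(x, x, 1000, grid = g, n_surrogates = 50,
                          seed = 21)
  expect_identical(z1$z, z2$z)
  expect_gt(z1$z[1, 1], 3)
  expect_true(all(z1$surrogate_sd > 0))
})

test_that("uncoupled signals stay inside the surrogate null", {
  x0 <- coupled_trace(seed = 17, duration = 40, c = 0)
  g <- band_grid(phase_freqs = c(6, 8, 10),
                 amp_freqs = c(40, 60, 80), amp_bw = 20)
  z <- surrogate_zscores(x0, x0, 1000, grid = g, n_surrogates = 100,
                         seed = 9)
  expect_lt(max(z$z), 3)
})

test_that("mean MI rises monotonically with coupling strength", {
  g <- true_cell_grid()
  mean_mi <- vapply(c(0, 0.3, 0.6, 0.9), function(cc) {
    mean(vapply(1:10, function(s) {
      x <- coupled_trace(seed = s, duration = 30, c = cc)
      comodulogram(x, x, 1000, grid = g)$mi[1, 1]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_mi) > 0))
})
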