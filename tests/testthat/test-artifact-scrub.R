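test_that("clean recordings are left almost untouched", {
  flagged <- vapply(1:4, function(s) {
    x <- coupled_trace(seed = s, duration = 40, c = 0.3)
    1 - recovered_fraction(detect_artifacts(x, 1000),
                           length(x), 1000)$recovered_fraction
  }, numeric(1))
  expect_lt(mean(flagged), 0.02)
})

test_that("injected bursts are found with high recall and localisation", {
  fs <- 1000
  hits <- lapply(1:5, function(s) {
    rec <- generate_coupled_signal(coupling_spec(coupling_strength = 0.3),
                                   100, fs, seed = s)
    inj <- inject_artifacts(rec, artifact_spec(rate = 0.1,
                                               duration_mean = 1.5,
                                               burst_amp_factor = 10),
                            seed = s + 40)
    x <- channel_signal(inj$recording, 1)
    mask <- detect_artifacts(x, fs)
    gt <- inj$ground_truth[[1]]
    truth <- !clean_sample_mask(structure(gt, class = "artifact_mask"),
                                length(x), fs)
    det <- !clean_sample_mask(mask, length(x), fs)
    # flagged samples within one 0.25 s window of a true interval
    pad <- gt
    pad[, 1] <- pad[, 1] - 0.25
    pad[, 2] <- pad[, 2] + 0.25
    near <- !clean_sample_mask(structure(pad, class = "artifact_mask"),
                               length(x), fs)
    c(recall = sum(det & truth) / sum(truth),
      near = sum(det & near) / sum(det))
  })
  hits <- do.call(rbind, hits)
  expect_gt(mean(hits[, "recall"]), 0.90)
  expect_gt(mean(hits[, "near"]), 0.95)
})

test_that("degenerate signals produce no flags", {
  expect_equal(nrow(detect_artifacts(numeric(1000), 1000)), 0L)
  expect_equal(nrow(detect_artifacts(rep(3, 1000), 1000)), 0L)
  expect_error(detect_artifacts(numeric(10), 1000), "shorter")
})

test_that("detection is invariant to amplitude rescaling", {
  rec <- generate_coupled_signal(coupling_spec(coupling_strength = 0.3),
                                 30, 1000, seed = 7)
  inj <- inject_artifacts(rec, artifact_spec(rate = 0.1), seed = 3)
  x <- channel_signal(inj$recording, 1)
  m1 <- detect_artifacts(x, 1000)
  m2 <- detect_artifacts(137.5 * x, 1000)
  expect_equal(unclass(m1), unclass(m2))
})

test_that("recovered fraction is interval arithmetic", {
  fs <- 100
  n <- 100 * fs
  expect_equal(recovered_fraction(detect_artifacts(numeric(n), fs),
                                  n, fs)$recovered_fraction, 1)
  full <- structure(cbind(0, 100), class = "artifact_mask")
  expect_equal(recovered_fraction(full, n, fs)$recovered_fraction, 0)
  m <- structure(cbind(c(10, 50), c(15, 60)), class = "artifact_mask")
  expect_equal(recovered_fraction(m, n, fs)$recovered_fraction, 0.85)
})

test_that("analysis windows overlapping flags are dropped whole", {
  win <- sliding_windows(10, spectral_params())   # 9 windows of 2 s
  none <- structure(matrix(numeric(0), ncol = 2), class = "artifact_mask")
  expect_equal(nrow(mask_windows(none, win)), nrow(win))
  flag <- structure(cbind(4.6, 4.7), class = "artifact_mask")
  kept <- mask_windows(flag, win)
  # windows [3,5), [4,6) both touch the flag
  expect_equal(nrow(kept), nrow(win) - 2L)
  all_flag <- structure(cbind(0, 10), class = "artifact_mask")
  expect_equal(nrow(mask_windows(all_flag, win)), 0L)
  expect_error(multitaper_psd(rnorm(1000), 100,
                              windows = mask_windows(all_flag, win)),
               "no clean")
})

test_that("scrubbing recovers the injected clean fraction", {
  # recovered_fraction(detect(inject(f))) ~ 1 - f for moderate burst loads
  fs <- 1000
  for (f in c(0.05, 0.15)) {
    got <- vapply(1:6, function(s) {
      rec <- generate_coupled_signal(coupling_spec(coupling_strength = 0.3),
                                     100, fs, seed = s + 7)
      inj <- inject_artifacts(rec,
                              artifact_spec(rate = f / 1.5,
                                            duration_mean = 1.5,
                                            burst_amp_factor = 10),
                              seed = s)
      gt <- inj$ground_truth[[1]]
      truef <- sum(gt[, 2] - gt[, 1]) / 100
      rf <- recovered_fraction(
        detect_artifacts(channel_signal(inj$recording, 1), fs),
        100 * fs, fs)$recovered_fraction
      rf - (1 - truef)             # deviation from the true clean share
    }, numeric(1))
    expect_lt(mean(abs(got)), 0.03)
  }
})
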