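test_that("recording round-trips through float32 + sidecar", {
  set.seed(1)
  rec <- recording(matrix(rnorm(2000), nrow = 2), 500, c("dCA1", "dlSTR"))
  path <- tempfile(fileext = ".f32")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(dim(back$samples), c(2L, 1000L))
  expect_identical(back$channels, rec$channels)
  expect_equal(back$fs, 500)
  # float32 storage: first read is within single precision of the input,
  # and a second write/read cycle is bit-identical (idempotent)
  expect_equal(back$samples, rec$samples, tolerance = 1e-6,
               ignore_attr = TRUE)
  path2 <- tempfile(fileext = ".f32")
  write_recording(back, path2)
  expect_identical(read_recording(path2)$samples, back$samples)
})

test_that("recording IO rejects inconsistent inputs", {
  rec <- recording(matrix(1:10 / 10, nrow = 1), 100)
  path <- tempfile()
  write_recording(rec, path)
  expect_error(read_recording(tempfile()), "sidecar")

  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$fs_hz <- 0
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_recording(path), "fs_hz")

  bad <- recording(matrix(c(1, NaN), nrow = 1), 100)
  expect_error(write_recording(bad, tempfile()), "non-finite")
  expect_error(recording(matrix(1:4, 2), 0), "fs")
  expect_error(recording(matrix(1:4, 2), 100, c("a", "a")), "unique")
})

test_that("decimation preserves a slow sinusoid and rejects bad factors", {
  fs <- 10000
  t <- (0:(2 * fs - 1)) / fs
  rec <- recording(matrix(sin(2 * pi * 9 * t), nrow = 1), fs)
  dec <- decimate_recording(rec, 1000)
  expect_equal(dec$fs, 1000)
  x <- channel_signal(dec, 1)
  interior <- x[200:1800]
  ref <- sin(2 * pi * 9 * (199:1799) / 1000)
  amp <- sqrt(mean(interior^2)) / sqrt(mean(ref^2))
  expect_lt(abs(amp - 1), 0.01)

  expect_identical(decimate_recording(rec, fs), rec)
  expect_error(decimate_recording(rec, 3000), "non-integer")
})

test_that("epoch extraction follows the task-phase layout", {
  rec <- recording(matrix(0, nrow = 1, ncol = 200 * 100), 100)
  ev <- event_table(trial_id = c(1, 1, 2, 2),
                    event = rep(c("trial_start", "platform_reach"), 2),
                    t_s = c(20, 30, 60, 61.5))
  ep <- suppressWarnings(extract_epochs(rec, ev, pre_maze_duration = 15))
  pre <- ep[ep$phase == "pre_maze", ]
  expect_equal(c(pre$t_start, pre$t_end), c(0, 15))
  m1 <- ep[ep$phase == "maze" & ep$trial_id == 1, ]
  expect_equal(c(m1$t_start, m1$t_end), c(26, 30))   # 4 s before platform
  expect_false(m1$short)
  m2 <- ep[ep$phase == "maze" & ep$trial_id == 2, ]
  expect_equal(c(m2$t_start, m2$t_end), c(60, 61.5)) # truncated to trial
  expect_true(m2$short)
  p1 <- ep[ep$phase == "platform" & ep$trial_id == 1, ]
  expect_equal(c(p1$t_start, p1$t_end), c(30, 45))
})

test_that("epoch counts and end-of-recording clipping", {
  rec <- recording(matrix(0, nrow = 1, ncol = 100 * 100), 100)
  ev <- event_table(trial_id = rep(1:4, each = 2),
                    event = rep(c("trial_start", "platform_reach"), 4),
                    t_s = c(10, 18, 30, 38, 50, 58, 70, 95))
  expect_warning(ep <- extract_epochs(rec, ev, pre_maze_duration = 10),
                 "clipped")
  expect_equal(sum(ep$phase == "pre_maze"), 1L)
  expect_equal(sum(ep$phase == "maze"), 4L)
  expect_equal(sum(ep$phase == "platform"), 4L)
  p4 <- ep[ep$phase == "platform" & ep$trial_id == 4, ]
  expect_equal(p4$t_end, 100)
})

test_that("epoch slicing is half-open and duplicates no samples", {
  fs <- 100
  rec <- recording(matrix(seq_len(1000), nrow = 1), fs)
  ev <- event_table(1, c("trial_start", "platform_reach"), c(1, 6))
  ep <- extract_epochs(rec, ev, maze_window = 4, platform_duration = 2,
                       pre_maze_duration = 2)
  segs <- lapply(seq_len(nrow(ep)), function(k) epoch_signal(rec, ep[k, ], 1))
  maze <- segs[[which(ep$phase == "maze")]]
  plat <- segs[[which(ep$phase == "platform")]]
  expect_equal(length(maze), 4 * fs)
  # maze [2,6) and platform [6,8): adjacent, disjoint
  expect_equal(maze[length(maze)], 600)
  expect_equal(plat[1], 601)
})

test_that("event tables validate and round-trip via CSV", {
  expect_error(event_table(1, c("trial_start", "platform_reach"), c(5, 4)),
               "after")
  expect_error(event_table(1, "splashdown", 1), "unknown event")
  ev <- event_table(c(1, 1), c("trial_start", "platform_reach"), c(2, 9))
  f <- tempfile(fileext = ".csv")
  write_event_table(ev, f)
  expect_equal(read_event_table(f), ev)
})
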