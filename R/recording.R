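#' Construct a multichannel LFP recording
#'
#' A `recording` bundles a channel-by-sample matrix with its sampling rate
#' and channel labels. Signal units are nominal microvolts; nothing in the
#' pipeline depends on the absolute scale.
#'
#' @param samples Numeric matrix, `n_channels x n_samples`, or a numeric
#'   vector for a single channel.
#' @param fs Sampling rate in Hz (> 0).
#' @param channels Character vector of unique channel labels, one per row
#'   (e.g. `c("dCA1", "dlSTR")`).
#' @return An object of class `recording` with fields `samples`, `fs`,
#'   `channels`.
#' @export
recording <- function(samples, fs, channels = NULL) {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1L)
  }
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (is.null(channels)) {
    channels <- paste0("ch", seq_len(nrow(samples)))
  }
  channels <- as.character(channels)
  if (length(channels) != nrow(samples)) {
    stop("one channel label per sample row required")
  }
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  rownames(samples) <- channels
  structure(
    list(samples = samples, fs = fs, channels = channels),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channel(s) [%s], %d samples @ %g Hz (%.2f s)\n",
    length(x$channels), paste(x$channels, collapse = ", "),
    ncol(x$samples), x$fs, ncol(x$samples) / x$fs
  ))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$samples)

rec_duration <- function(rec) ncol(rec$samples) / rec$fs

#' Extract one channel of a recording as a numeric vector
#'
#' @param rec A [recording()].
#' @param channel Channel label or integer index.
#' @return Numeric vector of samples.
#' @export
channel_signal <- function(rec, channel) {
  if (is.character(channel)) {
    idx <- match(channel, rec$channels)
    if (is.na(idx)) stop("unknown channel: ", channel)
  } else {
    idx <- as.integer(channel)
    if (idx < 1L || idx > nrow(rec$samples)) stop("channel index out of range")
  }
  as.numeric(rec$samples[idx, ])
}

#' Write a recording as raw float32 samples plus a JSON sidecar
#'
#' Samples are stored channel-interleaved-by-block (channel 1's full trace,
#' then channel 2's, ...) as little-endian float32; the sidecar
#' (`<path>.json`) records `fs_hz`, `n_channels`, `n_samples`,
#' `channel_labels`, `dtype` and `byte_order`.
#'
#' @param rec A [recording()].
#' @param path Destination for the binary samples; sidecar written next to it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  if (anyNA(rec$samples) || any(!is.finite(rec$samples))) {
    stop("refusing to write non-finite samples")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$samples)), con, size = 4L, endian = "little")
  meta <- list(
    fs_hz = rec$fs,
    n_channels = nrow(rec$samples),
    n_samples = ncol(rec$samples),
    channel_labels = rec$channels,
    dtype = "float32",
    byte_order = "little"
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Path to the binary sample file; `<path>.json` must exist.
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar metadata: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("fs_hz", "n_channels", "n_samples", "channel_labels")) {
    if (is.null(meta[[f]])) stop("sidecar missing field: ", f)
  }
  if (meta$fs_hz <= 0) stop("sidecar fs_hz must be positive")
  n_total <- meta$n_channels * meta$n_samples
  raw <- readBin(path, what = "numeric", n = n_total + 1L,
                 size = 4L, endian = "little")
  if (length(raw) != n_total) {
    stop("sample count mismatch: sidecar promises ", n_total,
         " values, file holds ", length(raw))
  }
  samples <- matrix(raw, nrow = meta$n_channels, byrow = TRUE)
  recording(samples, meta$fs_hz, meta$channel_labels)
}

#' Event tables
#'
#' An event table is a data frame with columns `trial_id` (integer),
#' `event` (`"trial_start"` or `"platform_reach"`) and `t_s` (seconds from
#' recording start). Within each trial the platform-reach time must follow
#' the trial start.
#'
#' @param trial_id Integer vector.
#' @param event Character vector of event names.
#' @param t_s Numeric vector of event times in seconds.
#' @return A validated `data.frame`.
#' @export
event_table <- function(trial_id, event, t_s) {
  ev <- data.frame(trial_id = as.integer(trial_id),
                   event = as.character(event),
                   t_s = as.numeric(t_s))
  bad <- setdiff(unique(ev$event), c("trial_start", "platform_reach"))
  if (length(bad)) stop("unknown event type(s): ", paste(bad, collapse = ", "))
  for (id in unique(ev$trial_id)) {
    tr <- ev[ev$trial_id == id, ]
    ts <- tr$t_s[tr$event == "trial_start"]
    pr <- tr$t_s[tr$event == "platform_reach"]
    if (length(ts) && length(pr) && any(pr <= ts)) {
      stop("trial ", id, ": platform_reach must come after trial_start")
    }
  }
  ev[order(ev$trial_id, ev$t_s), , drop = FALSE]
}

#' @rdname event_table
#' @param path CSV path with header `trial_id,event,t_s`.
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("trial_id", "event", "t_s") %in% names(df))) {
    stop("event CSV must have columns trial_id,event,t_s")
  }
  event_table(df$trial_id, df$event, df$t_s)
}

#' @rdname event_table
#' @param events An event table.
#' @export
write_event_table <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Anti-alias decimation to a lower sampling rate
#'
#' Zero-phase FIR low-pass (windowed-sinc cut at 80% of the target Nyquist,
#' kernel convolved with its own reverse so the passband stays flat and the
#' phase delay is zero) followed by downsampling. The decimation factor
#' must be an integer.
#'
#' @param rec A [recording()].
#' @param target_fs Target sampling rate in Hz; `rec$fs %% target_fs == 0`.
#' @return A [recording()] at `target_fs`.
#' @export
decimate_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "recording"))
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop("non-integer decimation factor: ", rec$fs, " -> ", target_fs)
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  n <- ncol(rec$samples)
  ord <- min(10L * factor, max(2L, n %/% 3L))
  if (ord %% 2L == 1L) ord <- ord + 1L
  b <- signal::fir1(ord, 0.8 / factor, type = "low")
  g <- stats::convolve(b, b, type = "open")
  L <- length(b)
  keep <- seq(1L, n, by = factor)
  dec <- t(apply(rec$samples, 1L, function(x) {
    full <- stats::convolve(x, rev(g), type = "open")
    full[L:(L + n - 1L)][keep]
  }))
  recording(dec, target_fs, rec$channels)
}

#' Cut task-phase epochs out of a recording
#'
#' One `pre_maze` epoch covering the session baseline, then per trial a
#' `maze` epoch spanning the `maze_window` seconds before the platform is
#' reached and a `platform` epoch starting at the platform-reach time.
#' Intervals are half-open `[t_start, t_end)` in seconds; sample index
#' conversion uses `floor(t * fs)`, 0-based.
#'
#' Maze epochs that would start before the trial start are truncated to the
#' trial bounds and flagged `short = TRUE`; platform epochs running past the
#' end of the recording are clipped with a warning.
#'
#' @param rec A [recording()].
#' @param events An [event_table()].
#' @param maze_window Seconds of swim data before platform reach (default 4).
#' @param platform_duration Platform consolidation epoch length in seconds
#'   (default 15).
#' @param pre_maze_duration Baseline epoch length in seconds (default 60).
#' @return An `epoch_set`: a data frame with columns `phase`, `trial_id`,
#'   `t_start`, `t_end`, `short`.
#' @export
extract_epochs <- function(rec, events, maze_window = 4,
                           platform_duration = 15, pre_maze_duration = 60) {
  stopifnot(inherits(rec, "recording"))
  dur <- rec_duration(rec)
  rows <- list(data.frame(phase = "pre_maze", trial_id = NA_integer_,
                          t_start = 0, t_end = min(pre_maze_duration, dur),
                          short = FALSE))
  for (id in unique(events$trial_id)) {
    tr <- events[events$trial_id == id, ]
    ts <- tr$t_s[tr$event == "trial_start"]
    pr <- tr$t_s[tr$event == "platform_reach"]
    if (!length(ts) || !length(pr)) next
    ts <- ts[1L]; pr <- pr[1L]
    m_start <- pr - maze_window
    short <- FALSE
    if (m_start < ts) {           # platform reached within the window
      m_start <- ts
      short <- TRUE
    }
    rows[[length(rows) + 1L]] <- data.frame(
      phase = "maze", trial_id = id, t_start = m_start, t_end = pr,
      short = short)
    p_end <- pr + platform_duration
    if (p_end > dur) {
      warning("platform epoch for trial ", id, " clipped to recording end")
      p_end <- dur
    }
    rows[[length(rows) + 1L]] <- data.frame(
      phase = "platform", trial_id = id, t_start = pr, t_end = p_end,
      short = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("epoch_set", class(out))
  out
}

#' Slice the samples of one epoch from a recording
#'
#' @param rec A [recording()].
#' @param epoch One row of an `epoch_set` (or anything with `t_start`,
#'   `t_end`).
#' @param channel Channel label or index.
#' @return Numeric vector of samples in `[t_start, t_end)`.
#' @export
epoch_signal <- function(rec, epoch, channel) {
  i0 <- floor(epoch$t_start * rec$fs)        # 0-based
  i1 <- floor(epoch$t_end * rec$fs)
  i1 <- min(i1, n_samples(rec))
  if (i1 <= i0) stop("empty epoch slice")
  channel_signal(rec, channel)[(i0 + 1L):i1]
}
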