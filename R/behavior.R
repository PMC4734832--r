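#' Double-H water-maze trial log
#'
#' A trial's zone-visit record: each row of `zones` is one entry into a
#' labelled maze zone at a given time. The five error zones (incorrect
#' arms off the trained path) are configuration, since their identity
#' depends on the trained trajectory.
#'
#' @param trial_id Trial identifier.
#' @param zones Data frame with columns `t_s` (non-decreasing entry times,
#'   s) and `zone` (labels).
#' @param goal_arm_time Time the goal arm was reached, s, or `NA`.
#' @param platform_time Time the platform was reached, s, or `NA`.
#' @param error_zones Character vector of exactly 5 error-zone labels.
#' @return A `trial_log` list.
#' @export
trial_log <- function(trial_id, zones, goal_arm_time = NA,
                      platform_time = NA,
                      error_zones = paste0("E", 1:5)) {
  stopifnot(is.data.frame(zones), all(c("t_s", "zone") %in% names(zones)))
  if (length(unique(error_zones)) != 5L) {
    stop("exactly 5 distinct error zones required")
  }
  if (is.unsorted(zones$t_s)) stop("zone entry times must be non-decreasing")
  structure(list(trial_id = trial_id,
                 zones = data.frame(t_s = as.numeric(zones$t_s),
                                    zone = as.character(zones$zone)),
                 goal_arm_time = goal_arm_time,
                 platform_time = platform_time,
                 error_zones = as.character(error_zones)),
            class = "trial_log")
}

#' Score initial and repetitive errors for one trial
#'
#' An initial error is the first entry into any of the 5 error zones; every
#' further entry into a zone already visited counts as a repetitive error.
#' Consecutive duplicate labels collapse only when their entry times are
#' identical (a double-logged crossing); otherwise each entry counts.
#'
#' @param log A [trial_log()].
#' @param known_zones All legal zone labels; defaults to the log's error
#'   zones plus the standard non-error zones.
#' @return List with `initial` and `repetitive` counts.
#' @export
score_errors <- function(log,
                         known_zones = c(log$error_zones, "start",
                                         "corridor", "goal_arm",
                                         "platform")) {
  stopifnot(inherits(log, "trial_log"))
  z <- log$zones
  unknown <- setdiff(unique(z$zone), known_zones)
  if (length(unknown)) {
    stop("unknown zone label(s): ", paste(unknown, collapse = ", "))
  }
  if (nrow(z) > 1L) {
    dup <- z$zone[-1L] == z$zone[-nrow(z)] & z$t_s[-1L] == z$t_s[-nrow(z)]
    z <- z[c(TRUE, !dup), , drop = FALSE]
  }
  entries <- z$zone[z$zone %in% log$error_zones]
  initial <- length(unique(entries))
  list(initial = initial, repetitive = length(entries) - initial)
}

#' Goal-arm and platform latencies for one trial
#'
#' @param log A [trial_log()].
#' @param trial_start Trial release time, s.
#' @return List with `goal_arm_latency` and `platform_latency` in seconds
#'   (`NA` with `reached = FALSE` when the event never happened).
#' @export
latencies <- function(log, trial_start = 0) {
  stopifnot(inherits(log, "trial_log"))
  g <- log$goal_arm_time; p <- log$platform_time
  if (!is.na(g) && g < trial_start) stop("goal-arm time precedes trial start")
  if (!is.na(p) && p < trial_start) stop("platform time precedes trial start")
  if (!is.na(g) && !is.na(p) && p < g) {
    stop("platform reached before goal arm: impossible in this maze")
  }
  list(goal_arm_latency = if (is.na(g)) NA_real_ else g - trial_start,
       platform_latency = if (is.na(p)) NA_real_ else p - trial_start,
       goal_reached = !is.na(g),
       platform_reached = !is.na(p))
}

#' Simulate plausible trial logs across training sessions
#'
#' Emulates procedural learning in the double-H maze: error counts fall
#' geometrically and latencies shrink across sessions, with Poisson /
#' log-normal trial-to-trial variability. Used to exercise the behaviour
#' scoring and the session x group ANOVA without video data.
#'
#' @param n_sessions Training sessions (default 4).
#' @param trials_per_session Trials per session (default 4).
#' @param initial_error_rate Mean error-zone entries on session 1.
#' @param learning_rate Per-session multiplicative decay of errors and
#'   latencies (default 0.55).
#' @param base_latency Mean platform latency on session 1, s.
#' @param seed Integer RNG seed.
#' @return Data frame with one row per trial: `session`, `trial`,
#'   `initial_errors`, `repetitive_errors`, `goal_arm_latency`,
#'   `platform_latency`.
#' @export
simulate_trial_logs <- function(n_sessions = 4, trials_per_session = 4,
                                initial_error_rate = 5, learning_rate = 0.55,
                                base_latency = 40, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  error_zones <- paste0("E", 1:5)
  rows <- list()
  for (s in seq_len(n_sessions)) {
    decay <- learning_rate^(s - 1)
    for (tr in seq_len(trials_per_session)) {
      n_err <- stats::rpois(1L, initial_error_rate * decay)
      visits <- if (n_err > 0) {
        sample(error_zones, n_err, replace = TRUE)
      } else character(0)
      lat_p <- stats::rlnorm(1L, log(base_latency * decay + 3), 0.25)
      lat_g <- lat_p * stats::runif(1L, 0.6, 0.9)
      t_entries <- sort(stats::runif(length(visits), 0, lat_g))
      lg <- trial_log(tr,
                      data.frame(t_s = t_entries, zone = visits),
                      goal_arm_time = lat_g, platform_time = lat_p,
                      error_zones = error_zones)
      sc <- score_errors(lg)
      rows[[length(rows) + 1L]] <- data.frame(
        session = s, trial = tr,
        initial_errors = sc$initial, repetitive_errors = sc$repetitive,
        goal_arm_latency = lat_g, platform_latency = lat_p)
    }
  }
  do.call(rbind, rows)
}
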