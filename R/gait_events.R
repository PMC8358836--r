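# Gait event detection from foot marker kinematics.
#
# Heel strike and toe off are recovered from the vertical kinematics of the
# foot centre (midpoint of heel and toe markers): during stance the foot is
# essentially stationary, so its vertical velocity sits near zero; swing
# shows large vertical velocity. Heel strike is placed at the local minimum
# of foot-centre height within each low-velocity window, toe off at the end
# of that window.

detect_foot <- function(heel, toe, v_thresh, smooth_cutoff, min_window_s) {
  fs <- heel$fs
  z_raw <- (heel$pos[, 3] + toe$pos[, 3]) / 2
  n <- length(z_raw)
  if (stats::sd(z_raw) < 1e-6) stopf("no events detected: flat foot trace")
  # light zero-phase smoothing so marker noise does not fragment the
  # low-velocity stance windows; event timing uses the raw position
  z <- z_raw
  if (!is.null(smooth_cutoff) && smooth_cutoff > 0 && smooth_cutoff < fs / 2) {
    bf <- signal::butter(2, smooth_cutoff / (fs / 2), type = "low")
    z <- as.numeric(signal::filtfilt(bf, z_raw))
  }
  v <- c(0, (z[3:n] - z[1:(n - 2)]) * fs / 2, 0)  # central difference, mm/s
  low <- abs(v) < v_thresh
  low[c(1L, n)] <- FALSE
  runs <- logical_runs(low)
  runs <- runs[runs$length >= max(2L, round(min_window_s * fs)), , drop = FALSE]
  if (nrow(runs) < 3L) stopf("no events detected")
  if (any(runs$length > 0.9 * n)) stopf("no events detected: no swing phases")
  # first and last windows are partial cycles at the record boundary; discard
  runs <- runs[-c(1L, nrow(runs)), , drop = FALSE]
  # the smoothed velocity crosses the threshold slightly after touchdown, so
  # the minimum search extends a few samples before the window start
  back <- round(0.05 * fs)
  hs <- numeric(nrow(runs))
  to <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    s0 <- max(1L, runs$start[i] - back)
    seg <- z_raw[s0:runs$end[i]]
    # which.min keeps the earliest of tied minima, the deterministic choice
    hs[i] <- heel$t[s0 + which.min(seg) - 1L]
    to[i] <- heel$t[runs$end[i]]
  }
  list(hs = hs, to = to)
}

#' Detect heel-strike and toe-off events from foot markers
#'
#' Foot-velocity event detection: the vertical position of each foot centre
#' (heel/toe midpoint) is smoothed, differentiated by central difference, and
#' segmented into low-velocity stance windows (`|v_z| < v_thresh`). Heel
#' strike is the local minimum of foot-centre height within a window; toe off
#' is the departure from the window. The first and last partial windows are
#' discarded.
#'
#' @param heel_left,toe_left,heel_right,toe_right [marker_trace()] objects,
#'   all on the same time base and sampling rate, covering at least 3 s.
#' @param v_thresh Stance velocity threshold in mm/s (default 50).
#' @param smooth_cutoff Low-pass cutoff (Hz) applied to foot height before
#'   differentiation; `NULL` or 0 disables.
#' @param min_window_s Minimum stance-window duration in seconds; shorter
#'   low-velocity runs are treated as noise.
#'
#' @return An object of class `gait_events` with strictly increasing event
#'   times (s): `heel_strikes_left`, `heel_strikes_right`, `toe_offs_left`,
#'   `toe_offs_right`.
#' @export
detect_gait_events <- function(heel_left, toe_left, heel_right, toe_right,
                               v_thresh = 50, smooth_cutoff = 10,
                               min_window_s = 0.1) {
  traces <- list(heel_left, toe_left, heel_right, toe_right)
  n <- length(heel_left$t)
  fs <- heel_left$fs
  for (tr in traces) {
    if (length(tr$t) != n || abs(tr$fs - fs) > 1e-9) {
      stopf("all traces must have the same length and sampling rate")
    }
  }
  if (n / fs < 3) stopf("need at least 3 s of data")
  L <- detect_foot(heel_left, toe_left, v_thresh, smooth_cutoff, min_window_s)
  R <- detect_foot(heel_right, toe_right, v_thresh, smooth_cutoff, min_window_s)
  if (length(L$hs) < 2L || length(R$hs) < 2L) {
    stopf("fewer than 2 heel strikes detected per foot")
  }
  ev <- structure(
    list(heel_strikes_left = L$hs, heel_strikes_right = R$hs,
         toe_offs_left = L$to, toe_offs_right = R$to),
    class = "gait_events")
  # alternation check is advisory: violations indicate missed events and are
  # flagged downstream, not fatal here
  m <- merge_heel_strikes(ev)
  if (any(m$side[-1] == m$side[-nrow(m)])) {
    attr(ev, "alternation_violations") <-
      sum(m$side[-1] == m$side[-nrow(m)])
  }
  ev
}

merge_heel_strikes <- function(events) {
  d <- rbind(
    data.frame(time = events$heel_strikes_left, side = "left"),
    data.frame(time = events$heel_strikes_right, side = "right")
  )
  d[order(d$time), , drop = FALSE]
}

#' Step times from gait events
#'
#' A step is the interval from one foot's heel contact to the contralateral
#' heel contact. Heel strikes of both feet are merged and time-sorted;
#' `step_time[i] = HS[i+1] - HS[i]`. Where two consecutive strikes come from
#' the same foot (a missed contralateral event) the interval is flagged as a
#' gap and excluded from summary statistics.
#'
#' @param events A `gait_events` object, or a data.frame with columns `time`
#'   and `side`.
#' @return An object of class `step_series`: a data.frame with columns
#'   `onset` (heel-strike time of the step, s), `step_time` (s), `side`
#'   (leading foot) and `gap` (logical flag). Attribute `n_gaps` counts
#'   flagged intervals.
#' @export
compute_step_times <- function(events) {
  m <- if (inherits(events, "gait_events")) merge_heel_strikes(events)
       else events[order(events$time), , drop = FALSE]
  if (nrow(m) < 2L) stopf("need at least 2 heel strikes")
  if (any(diff(m$time) <= 0)) stopf("heel strikes contain duplicates")
  n <- nrow(m)
  out <- data.frame(
    onset = m$time[-n],
    step_time = diff(m$time),
    side = m$side[-n],
    gap = m$side[-n] == m$side[-1]
  )
  attr(out, "n_gaps") <- sum(out$gap)
  class(out) <- c("step_series", "data.frame")
  out
}

#' Summary statistics of a step series
#'
#' Mean and standard deviation of the valid (non-gap) step times, the inputs
#' to subject-specific metronome construction.
#'
#' @param steps A `step_series` from [compute_step_times()].
#' @return List with `mean_step_time`, `sd_step_time`, `n_steps`, `n_gaps`.
#' @export
step_summary <- function(steps) {
  ok <- !steps$gap
  if (!any(ok)) stopf("no valid steps (all intervals flagged as gaps)")
  list(mean_step_time = mean(steps$step_time[ok]),
       sd_step_time = stats::sd(steps$step_time[ok]),
       n_steps = sum(ok), n_gaps = sum(steps$gap))
}
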