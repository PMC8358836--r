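# Parameterization of the perturbation response of the deviation series
# D(t), and aggregation of torus occupancy by trial phase.
#
# Four parameters describe resilience: lag time (perturbation onset to the
# first sustained exit beyond T_2s), peak time (exit to maximum deviation),
# peak magnitude (that maximum, mm), and COM recovery time (maximum back to
# sustained residence within T_2s).

#' Resilience parameters of a deviation series
#'
#' An excursion is a run of samples labelled outside `T_2s` (i.e. `T3` or
#' `OUT`). The trajectory counts as deviated if some excursion at or after
#' `perturb_onset` lasts at least `min_excursion` seconds. The recovery
#' point is the earliest time at or after the peak from which the trajectory
#' stays inside `T_2s` for `n_cycles` walking cycles, permitting up to
#' `n_outliers` excursions of at most `outlier_max` seconds each.
#'
#' @param dev A `deviation_series` from [classify_trajectory()].
#' @param perturb_onset Perturbation onset time (s).
#' @param cycle_duration One walking cycle (s); conventionally 2x the
#'   subject's baseline mean step time (a stride). See `cycle_steps` in
#'   [default_config()] to switch to a single step.
#' @param min_excursion Minimum duration of a qualifying excursion (s,
#'   default 0.1).
#' @param outlier_max Maximum duration of a tolerated outlier excursion in
#'   the recovery window (s, default 0.01; one sample at 100 Hz).
#' @param n_outliers Number of tolerated outlier excursions (default 4).
#' @param n_cycles Number of clean cycles defining recovery (default 5).
#' @param peak_window Peak search horizon after the exit (s, default 60).
#'
#' @return Object of class `resilience_metrics`: list with `deviated`
#'   (logical) and, when deviated, `lag_time`, `peak_time`, `peak_magnitude`
#'   (mm), `com_recovery_time`, plus absolute times `t_exit`, `t_peak`,
#'   `t_recovery` (all s; `NA` when undefined). If no recovery occurs before
#'   the record ends, `t_recovery` is `NA` with a warning.
#' @export
compute_resilience <- function(dev, perturb_onset, cycle_duration,
                               min_excursion = 0.1, outlier_max = 0.01,
                               n_outliers = 4, n_cycles = 5,
                               peak_window = 60) {
  fs <- attr(dev, "fs")
  if (is.null(fs)) fs <- 1 / stats::median(diff(dev$t))
  post <- dev$t >= perturb_onset
  if (!any(post)) stopf("deviation series does not cover perturb_onset")
  t <- dev$t[post]
  D <- dev$D[post]
  outside <- !(dev$label[post] %in% c("T1", "T2"))
  na_metrics <- function() {
    structure(list(deviated = FALSE, lag_time = NA_real_, peak_time = NA_real_,
                   peak_magnitude = NA_real_, com_recovery_time = NA_real_,
                   t_exit = NA_real_, t_peak = NA_real_, t_recovery = NA_real_),
              class = "resilience_metrics")
  }
  runs <- logical_runs(outside)
  if (nrow(runs) == 0L) return(na_metrics())
  min_len <- max(1L, ceiling(min_excursion * fs - 1e-9))
  qual <- which(runs$length >= min_len)
  if (length(qual) == 0L) return(na_metrics())
  first <- qual[1]
  t_exit <- t[runs$start[first]]
  lag_time <- t_exit - perturb_onset
  # peak of D(t) within the bounded search window after the exit
  win <- t >= t_exit & t <= min(t[length(t)], t_exit + peak_window)
  i_peak <- which(win)[which.max(D[win])]
  t_peak <- t[i_peak]
  peak_magnitude <- D[i_peak]
  peak_time <- t_peak - t_exit
  # recovery scan over excursion runs: the clean window [s, s + W) may
  # intersect at most n_outliers runs, each no longer than outlier_max
  max_out <- max(0L, floor(outlier_max * fs + 1e-9))
  W <- round(n_cycles * cycle_duration * fs)
  n <- length(t)
  long_runs <- runs[runs$length > max_out, , drop = FALSE]
  s <- i_peak
  t_recovery <- NA_real_
  repeat {
    if (s + W - 1L > n) break  # record too short to certify recovery
    e <- s + W - 1L
    inter <- runs$end >= s & runs$start <= e
    bad_long <- long_runs$end >= s & long_runs$start <= e
    if (any(bad_long)) {
      s <- max(s + 1L, long_runs$end[bad_long][1] + 1L)
      next
    }
    if (sum(inter) > n_outliers) {
      first_in <- which(inter)[1]
      s <- max(s + 1L, runs$end[first_in] + 1L)
      next
    }
    t_recovery <- t[s]
    break
  }
  if (is.na(t_recovery)) warnf("unrecovered within trial")
  structure(list(deviated = TRUE, lag_time = lag_time, peak_time = peak_time,
                 peak_magnitude = peak_magnitude,
                 com_recovery_time = if (is.na(t_recovery)) NA_real_ else t_recovery - t_peak,
                 t_exit = t_exit, t_peak = t_peak, t_recovery = t_recovery),
            class = "resilience_metrics")
}

#' @export
print.resilience_metrics <- function(x, ...) {
  if (!x$deviated) {
    cat("<resilience_metrics: no deviation from steady state>\n")
  } else {
    cat(sprintf(paste0("<resilience_metrics: lag %.2f s, peak %.2f s, ",
                       "magnitude %.1f mm, recovery %s>\n"),
                x$lag_time, x$peak_time, x$peak_magnitude,
                if (is.na(x$com_recovery_time)) "unrecovered"
                else sprintf("%.2f s", x$com_recovery_time)))
  }
  invisible(x)
}

#' Segment a cued-walking trial into phases around the perturbation
#'
#' Three half-open, non-overlapping windows tiling the trial exactly:
#' `CW1 = [start, onset)`, `CW2 = [onset, recovery)`,
#' `CW3 = [recovery, end)`. If `t_recovery` is missing, `CW2` extends to the
#' end of the trial and `CW3` is empty, with a warning.
#'
#' @param trial_span Numeric length-2, start and end of the trial (s).
#' @param perturb_onset Perturbation onset (s), within the span.
#' @param t_recovery COM recovery time point (s) or `NA`.
#' @return Named list of `c(start, end)` windows `CW1`, `CW2`, `CW3`.
#' @export
segment_phases <- function(trial_span, perturb_onset, t_recovery) {
  a <- trial_span[1]; b <- trial_span[2]
  if (perturb_onset < a || perturb_onset > b) {
    stopf("perturb_onset outside the trial span")
  }
  if (is.na(t_recovery)) {
    warnf("no recovery point: CW3 is empty")
    t_recovery <- b
  }
  if (t_recovery < perturb_onset || t_recovery > b) {
    stopf("t_recovery outside [perturb_onset, end of trial]")
  }
  list(CW1 = c(a, perturb_onset), CW2 = c(perturb_onset, t_recovery),
       CW3 = c(t_recovery, b))
}

#' Torus occupancy of a deviation series within a time window
#'
#' Percentage of samples labelled `T1`, `T2`, `T3` and `OUT` (beyond
#' `T_3s`) within the half-open window; the four percentages sum to 100.
#'
#' @param dev A `deviation_series`.
#' @param window Numeric length-2 `c(start, end)` in seconds.
#' @return Named numeric vector of percentages `(T1, T2, T3, OUT)`.
#' @export
occupancy <- function(dev, window) {
  sel <- dev$t >= window[1] & dev$t < window[2]
  if (!any(sel)) stopf("empty window: no samples in [%g, %g)", window[1], window[2])
  tab <- 100 * table(dev$label[sel]) / sum(sel)
  stats::setNames(as.numeric(tab), names(tab))
}
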