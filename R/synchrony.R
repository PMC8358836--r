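# Footfall-beat asynchrony and the recovery of synchronization after a
# rhythm perturbation.
#
# Asynchrony is interval-based: produced step time minus the nominal
# inter-beat interval. Recovery is declared when 3-step moving-window means
# of the asynchrony re-enter the pre-perturbation band (mean +/- 2 SD of the
# 10 steps preceding the perturbation) and stay there for 8 consecutive
# windows - the window count that exactly tiles 10 steps (5 gait cycles).

#' Step-time asynchrony relative to the metronome
#'
#' `asyn[i] = step_time[i] - base_ibi`; positive means the step was longer
#' than the nominal beat interval. Gap-flagged steps (missed events) are
#' dropped.
#'
#' @param steps A `step_series` from [compute_step_times()].
#' @param base_ibi Nominal inter-beat interval (s), i.e. the subject's mean
#'   baseline step time.
#' @return Object of class `asynchrony_series`: data.frame with
#'   `step_index`, `t` (step onset, s), `asyn` (s).
#' @export
compute_asynchrony <- function(steps, base_ibi) {
  ok <- !steps$gap
  out <- data.frame(step_index = which(ok), t = steps$onset[ok],
                    asyn = steps$step_time[ok] - base_ibi)
  class(out) <- c("asynchrony_series", "data.frame")
  out
}

#' Recovery of footfall synchrony after the perturbation
#'
#' Pre-perturbation limits come from the `n_pre` steps immediately before
#' `perturb_step`: the band is their mean asynchrony `+/- band_sd` standard
#' deviations (set `center = "zero"` to centre the band at zero instead).
#' The peak adjustment is the largest `|asyn|` at or after `perturb_step`.
#' Moving `window`-step means are scanned from the peak; the recovery step
#' is the middle step of the first window whose mean lies in the band for
#' `n_windows` consecutive windows. A subject with no window run in band is
#' flagged `synchronized = FALSE`. A subject made a measurable adjustment
#' (`adjusted = TRUE`) when some post-perturbation window mean departs from
#' the pre-perturbation mean by more than three standard deviations of the
#' whole pre-perturbation asynchrony series - a sustained-departure
#' criterion that single-step noise outliers cannot trip.
#'
#' @param asyn An `asynchrony_series`.
#' @param perturb_step Row index of the first step at/after the perturbation
#'   onset.
#' @param n_pre Number of pre-perturbation steps (default 10).
#' @param window Moving-window width in steps (default 3).
#' @param n_windows Consecutive in-band windows required (default 8).
#' @param band_sd Band half-width in pre-perturbation SDs (default 2).
#' @param center Band centre: `"pre_mean"` (default) or `"zero"`.
#'
#' @return Object of class `synchrony_metrics`: list with `pre_mean`,
#'   `pre_sd` (s), `peak_step` (row index), `peak_adjustment` (s),
#'   `recovery_step`, `synchrony_recovery_time` (s), `synchronized`,
#'   `adjusted` (logicals), `t_peak`, `t_recovery` (s).
#' @export
synchrony_recovery <- function(asyn, perturb_step, n_pre = 10, window = 3,
                               n_windows = 8, band_sd = 2,
                               center = c("pre_mean", "zero")) {
  center <- match.arg(center)
  n <- nrow(asyn)
  if (perturb_step - 1L < n_pre) stopf("need %d steps before the perturbation", n_pre)
  if (n - perturb_step + 1L < window + n_windows + 2L) {
    stopf("too few steps after the perturbation")
  }
  pre <- asyn$asyn[(perturb_step - n_pre):(perturb_step - 1L)]
  pre_mean <- mean(pre)
  pre_sd <- stats::sd(pre)
  mid <- if (center == "pre_mean") pre_mean else 0
  lo <- mid - band_sd * pre_sd
  hi <- mid + band_sd * pre_sd
  post <- perturb_step:n
  peak_step <- post[which.max(abs(asyn$asyn[post]))]
  peak_adjustment <- abs(asyn$asyn[peak_step])
  # sustained-departure test for a measurable adjustment, on a stable
  # pre-perturbation scale (all pre-onset steps)
  pre_all <- asyn$asyn[seq_len(perturb_step - 1L)]
  post_starts <- perturb_step:(n - window + 1L)
  post_wmean <- vapply(post_starts,
                       function(s) mean(asyn$asyn[s:(s + window - 1L)]),
                       numeric(1))
  adjusted <- any(abs(post_wmean - mean(pre_all)) > 3 * stats::sd(pre_all))
  # moving-window means, windows starting at the peak step, advancing one
  # step at a time
  starts <- peak_step:(n - window + 1L)
  wmean <- vapply(starts, function(s) mean(asyn$asyn[s:(s + window - 1L)]),
                  numeric(1))
  inband <- wmean >= lo & wmean <= hi
  recovery_step <- NA_integer_
  if (length(inband) >= n_windows) {
    runs <- logical_runs(inband)
    ok <- runs[runs$length >= n_windows, , drop = FALSE]
    if (nrow(ok) > 0L) {
      recovery_step <- starts[ok$start[1]] + (window - 1L) %/% 2L
    }
  }
  synchronized <- !is.na(recovery_step)
  structure(list(
    pre_mean = pre_mean, pre_sd = pre_sd,
    peak_step = peak_step, peak_adjustment = peak_adjustment,
    recovery_step = recovery_step,
    synchrony_recovery_time =
      if (synchronized) asyn$t[recovery_step] - asyn$t[peak_step] else NA_real_,
    synchronized = synchronized, adjusted = adjusted,
    t_peak = asyn$t[peak_step],
    t_recovery = if (synchronized) asyn$t[recovery_step] else NA_real_),
    class = "synchrony_metrics")
}

#' @export
print.synchrony_metrics <- function(x, ...) {
  cat(sprintf(paste0("<synchrony_metrics: peak adjustment %.3f s at step %d, ",
                     "%s%s>\n"),
              x$peak_adjustment, x$peak_step,
              if (x$synchronized)
                sprintf("recovered in %.2f s", x$synchrony_recovery_time)
              else "not recovered",
              if (x$adjusted) "" else " (no measurable adjustment)"))
  invisible(x)
}
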