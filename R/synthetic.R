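# Synthetic gait generator with known ground truth.
#
# Emulates the data streams of a treadmill cueing experiment: a
# quasi-periodic vertical sacrum oscillation locked to step events, foot
# markers with stance plateaus, and - for cued walking - first-order
# correction of step timing toward a perturbed beat grid plus a transient
# COM deviation of known amplitude and decay. Every generated trial carries
# a truth record so each pipeline stage can be validated against the
# generating parameters.

#' Synthetic subject model
#'
#' Ground-truth parameters of one synthetic subject.
#'
#' @param mean_step_time Mean step time (s, default 0.6).
#' @param step_sd Within-subject step-time SD (s, default 0.013).
#' @param com_amplitude Amplitude of the sacral vertical oscillation (mm,
#'   default 15; one oscillation per step).
#' @param noise_sd SD of band-limited (< 8 Hz) marker/measurement noise
#'   added to the sacrum signal (mm, default 0.3, sub-millimetre optical
#'   capture accuracy).
#' @param asymmetry Left/right step asymmetry of the sacral oscillation as a
#'   fraction of its amplitude (default 0.05): left-led oscillations are
#'   scaled by `1 + asymmetry/2`, right-led by `1 - asymmetry/2`, the
#'   bilateral asymmetry every walker shows.
#' @param waveform_warp Phase-warp coefficient of the per-step oscillation
#'   (default 0.97): the vertical bump is `sin(phi + warp * sin(phi))`, an
#'   asymmetric rise/fall like real sacral motion. `0` gives a pure
#'   sinusoid.
#' @param amp_mod,amp_mod_freq Slow bounded amplitude modulation of the
#'   oscillation: fractional depth (default 0.35) and frequency (Hz, default
#'   0.07), emulating breathing/postural sway of the oscillation envelope.
#'   The modulation is sinusoidal, hence bounded, so baseline walking stays
#'   within its steady-state boundary.
#' @param alpha First-order step-timing correction gain in `[0, 1]`
#'   (default 0.6); `alpha = 0` is the non-adjusting phenotype.
#' @param transient_peak Peak COM deviation injected after the perturbation,
#'   expressed in reconstructed state space (mm, default 28); the transient
#'   is slow relative to the embedding delay, so the injected signal
#'   amplitude is `transient_peak / sqrt(3)`. `0` gives the no-deviation
#'   phenotype.
#' @param transient_rise Rise time of the transient to its peak (s,
#'   default 1.5).
#' @param transient_decay Exponential decay time constant after the peak (s,
#'   default 2.5).
#' @param response_lag Delay from perturbation onset to the start of the COM
#'   transient (s, default 1.0).
#' @param foot_noise_sd Marker noise on foot trajectories (mm, default 0).
#' @param seed Integer seed for this subject's trials.
#' @return Object of class `subject_model`.
#' @export
subject_model <- function(mean_step_time = 0.6, step_sd = 0.013,
                          com_amplitude = 15, noise_sd = 0.3,
                          asymmetry = 0.05, waveform_warp = 0.97,
                          amp_mod = 0.35, amp_mod_freq = 0.07,
                          alpha = 0.6, transient_peak = 28,
                          transient_rise = 1.5, transient_decay = 2.5,
                          response_lag = 1.0, foot_noise_sd = 0, seed = 1) {
  stopifnot(mean_step_time > 0, step_sd >= 0, com_amplitude > 0,
            noise_sd >= 0, asymmetry >= 0, waveform_warp >= 0,
            amp_mod >= 0, amp_mod < 1, amp_mod_freq > 0,
            alpha >= 0, alpha <= 1,
            transient_peak >= 0, transient_rise > 0, transient_decay > 0)
  structure(list(mean_step_time = mean_step_time, step_sd = step_sd,
                 com_amplitude = com_amplitude, noise_sd = noise_sd,
                 asymmetry = asymmetry, waveform_warp = waveform_warp,
                 amp_mod = amp_mod, amp_mod_freq = amp_mod_freq,
                 alpha = alpha, transient_peak = transient_peak,
                 transient_rise = transient_rise,
                 transient_decay = transient_decay,
                 response_lag = response_lag, foot_noise_sd = foot_noise_sd,
                 seed = as.integer(seed)),
            class = "subject_model")
}

# transient shape, unit peak: gamma-like rise to 1 at s = tau_r, then
# exponential decay with time constant tau_d
transient_shape <- function(s, tau_r, tau_d) {
  g <- numeric(length(s))
  up <- s > 0 & s <= tau_r
  dn <- s > tau_r
  g[up] <- (s[up] / tau_r) * exp(1 - s[up] / tau_r)
  g[dn] <- exp(-(s[dn] - tau_r) / tau_d)
  g
}

# band-limited noise: low-pass filtered white noise rescaled to unit SD
bandlimited_noise <- function(n, fs, cutoff = 8) {
  w <- stats::rnorm(n)
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  x <- as.numeric(signal::filtfilt(bf, w))
  x / stats::sd(x)
}

# foot vertical profile from that foot's heel-strike schedule; stance is a
# shallow quadratic with its minimum exactly at heel strike (heel-rocker
# rise), swing a sinusoidal clearance bump
foot_profile <- function(t, hs, stance_frac = 0.65, z0 = 40, h_st = 6,
                         a_sw = 50) {
  z <- rep(z0, length(t))
  for (i in seq_len(length(hs) - 1L)) {
    stride <- hs[i + 1L] - hs[i]
    t_to <- hs[i] + stance_frac * stride
    st <- t >= hs[i] & t < t_to
    z[st] <- z0 + h_st * ((t[st] - hs[i]) / (t_to - hs[i]))^2
    sw <- t >= t_to & t < hs[i + 1L]
    s <- (t[sw] - t_to) / (hs[i + 1L] - t_to)
    z[sw] <- z0 + h_st * (1 - s) + a_sw * sin(pi * s)
  }
  z
}

#' Generate one synthetic walking trial
#'
#' Produces foot markers (heel and toe per foot), the sacrum trace and the
#' corresponding COM signal for a baseline (`"BW"`) or cued (`"CW"`) trial,
#' together with the ground-truth record. For cued trials the step times
#' follow a first-order phase-error correction toward the (perturbed) beat
#' grid, `e_i = (1 - alpha) (e_{i-1} + delta_i)` with
#' `asyn_i = alpha (e_{i-1} + delta_i)` and `delta_i` the added delay of
#' interval `i`, and a COM transient of known peak and decay is added after
#' the perturbation.
#'
#' @param model A [subject_model()].
#' @param kind `"BW"` or `"CW"`.
#' @param duration Trial duration (s, >= 30; default 360).
#' @param track A [build_metronome()] track; required for `"CW"`.
#' @param fs Sampling rate (Hz, default 100).
#' @param trial Trial label stored on the COM signal (default `"BW1"` for
#'   baseline, `"CW"` for cued).
#' @param seed Seed for this trial; default derives from the model seed.
#' @return List with `markers` (named list of [marker_trace()]: `heel_left`,
#'   `toe_left`, `heel_right`, `toe_right`, `sacrum`), `com`
#'   (a [com_signal()]) and `truth` (generating schedule and parameters).
#' @export
generate_trial <- function(model, kind = c("BW", "CW"), duration = 360,
                           track = NULL, fs = 100, trial = NULL,
                           seed = model$seed) {
  kind <- match.arg(kind)
  if (duration < 30) stopf("duration must be at least 30 s for embedding")
  if (kind == "CW" && is.null(track)) stopf("cued trials require a metronome track")
  if (is.null(trial)) trial <- if (kind == "BW") "BW1" else "CW"
  set.seed(seed)
  base <- model$mean_step_time
  asyn_clean <- NULL
  if (kind == "BW") {
    n_steps <- ceiling((duration + 2) / base) + 2L
    step_times <- rtruncnorm4(n_steps, base, model$step_sd)
    onsets <- 1.0 + c(0, cumsum(step_times))
  } else {
    ibis <- track$ibis
    delta <- ibis - track$base_ibi
    n_int <- length(ibis)
    e <- 0
    asyn_clean <- numeric(n_int)
    for (i in seq_len(n_int)) {
      asyn_clean[i] <- model$alpha * (e + delta[i])
      e <- (1 - model$alpha) * (e + delta[i])
    }
    step_times <- track$base_ibi + asyn_clean +
      rtruncnorm4(n_int, 0, model$step_sd)
    onsets <- track$onsets[1] + 0.1 + c(0, cumsum(step_times))
    # the trunk keeps its own smooth rhythm while the feet adjust: the COM
    # oscillation phase follows a nominal (uncorrected) step schedule, so
    # the perturbation reaches the COM only through the injected transient
    nominal <- track$onsets[1] + 0.1 +
      c(0, cumsum(base + rtruncnorm4(n_int, 0, model$step_sd)))
  }
  if (kind == "BW") nominal <- onsets
  sides <- rep(c("left", "right"), length.out = length(onsets))
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  n <- length(t)
  # step phase: one full oscillation per step, linearly interpolated between
  # step onsets and extrapolated at the nominal rate beyond the schedule
  pad_pre <- nominal[1] - base * (ceiling(nominal[1] / base):1)
  last <- nominal[length(nominal)]
  pad_post <- last + base * seq_len(max(1L, ceiling((duration - last) / base) + 1L))
  knots <- c(pad_pre, nominal, pad_post)
  phase <- stats::approx(knots, 2 * pi * (seq_along(knots) - 1), xout = t)$y
  # bilateral asymmetry: alternate the oscillation amplitude step by step
  side_sign <- 1 - 2 * (floor(phase / (2 * pi)) %% 2)
  amp <- model$com_amplitude * (1 + model$asymmetry / 2 * side_sign)
  # slow bounded envelope modulation, random phase per trial
  if (model$amp_mod > 0) {
    amp <- amp * (1 + model$amp_mod *
                    sin(2 * pi * model$amp_mod_freq * t +
                          stats::runif(1, 0, 2 * pi)))
  }
  # asymmetric per-step bump via phase warping
  x <- amp * sin(phase + model$waveform_warp * sin(phase))
  if (model$noise_sd > 0) {
    x <- x + model$noise_sd * bandlimited_noise(n, fs)
  }
  t0 <- NA_real_
  if (kind == "CW" && model$transient_peak > 0) {
    t0 <- perturbation_onset_time(track) + model$response_lag
    x <- x + model$transient_peak / sqrt(3) *
      transient_shape(t - t0, model$transient_rise, model$transient_decay)
  }
  sacrum_z <- 1000 + x
  hs_left <- onsets[sides == "left"]
  hs_right <- onsets[sides == "right"]
  # extend each foot's schedule by one virtual stride so the profile covers
  # the whole record
  ext <- function(hs) {
    stride <- 2 * base
    c(hs[1] - stride, hs, hs[length(hs)] + stride)
  }
  zl <- foot_profile(t, ext(hs_left))
  zr <- foot_profile(t, ext(hs_right))
  if (model$foot_noise_sd > 0) {
    zl <- zl + stats::rnorm(n, 0, model$foot_noise_sd)
    zr <- zr + stats::rnorm(n, 0, model$foot_noise_sd)
  }
  mk <- function(label, y_off, z, x_off) {
    marker_trace(label, t, cbind(x_off, y_off, z), fs)
  }
  markers <- list(
    heel_left  = mk("heel_left", -60, zl, -100),
    toe_left   = mk("toe_left",   90, zl, -100),
    heel_right = mk("heel_right", -60, zr, 100),
    toe_right  = mk("toe_right",  90, zr, 100),
    sacrum     = marker_trace("sacrum", t, cbind(0, 0, sacrum_z), fs))
  truth <- list(
    kind = kind, seed = seed, model = unclass(model),
    step_onsets = onsets, step_times = diff(onsets), sides = sides,
    hs_left = hs_left, hs_right = hs_right,
    asyn_clean = asyn_clean, transient_t0 = t0,
    transient_peak = model$transient_peak,
    perturb_onset = if (kind == "CW") perturbation_onset_time(track) else NA_real_)
  list(markers = markers,
       com = com_signal(t, sacrum_z, fs, trial),
       truth = truth)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject parameters from cohort-level distributions (step time
#' 0.6 +/- 0.01 s between subjects, within-subject SD around 0.013 s,
#' state-space transient peak around 28 +/- 13.5 mm, correction gains in
#' [0.3, 0.8]) with reproducible per-subject seeds. The first
#' `n_no_deviation` subjects get `transient_peak = 0` (no COM deviation);
#' the first `n_no_adjust` of those additionally get `alpha = 0`
#' (non-adjusting), mirroring the behavioural phenotypes of a young-adult
#' cohort.
#'
#' @param n_subjects Cohort size (default 20).
#' @param seed Master seed.
#' @param n_no_deviation Subjects with no injected COM transient (default 5).
#' @param n_no_adjust Subjects (among those) with zero correction gain
#'   (default 2).
#' @return List of [subject_model()] objects with names `S01`, `S02`, ...
#' @export
generate_cohort <- function(n_subjects = 20, seed = 1, n_no_deviation = 5,
                            n_no_adjust = 2) {
  if (n_subjects < 1) stopf("n_subjects must be >= 1")
  if (n_no_adjust > n_no_deviation || n_no_deviation > n_subjects) {
    stopf("phenotype counts inconsistent with cohort size")
  }
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  mean_step <- rtruncnorm4(n_subjects, 0.6, 0.01)
  step_sd <- pmax(0.005, rtruncnorm4(n_subjects, 0.013, 0.003))
  com_amp <- stats::runif(n_subjects, 10, 20)
  alpha <- stats::runif(n_subjects, 0.3, 0.8)
  peak <- pmin(60, pmax(8, stats::rnorm(n_subjects, 28, 13.5)))
  tau_r <- stats::runif(n_subjects, 1.0, 2.0)
  tau_d <- stats::runif(n_subjects, 1.5, 4.0)
  lag <- stats::runif(n_subjects, 0.5, 1.5)
  peak[seq_len(n_no_deviation)] <- 0
  alpha[seq_len(n_no_adjust)] <- 0
  cohort <- lapply(seq_len(n_subjects), function(i) {
    m <- subject_model(mean_step_time = mean_step[i], step_sd = step_sd[i],
                       com_amplitude = com_amp[i], alpha = alpha[i],
                       transient_peak = if (peak[i] > 0) peak[i] else 0,
                       transient_rise = tau_r[i], transient_decay = tau_d[i],
                       response_lag = lag[i], seed = subject_seeds[i])
    m
  })
  names(cohort) <- sprintf("S%02d", seq_len(n_subjects))
  cohort
}

#' Analytic geometric-decay prediction of the synchrony recovery step
#'
#' Under first-order correction the post-perturbation asynchrony decays as
#' `|peak| (1 - alpha)^n`; the predicted recovery is the first step `n`
#' (after the peak) at which it stays within the band.
#'
#' @param peak Peak asynchrony magnitude (s).
#' @param alpha Correction gain in `(0, 1]`.
#' @param band Band half-width (s), e.g. `2 * step_sd`.
#' @return Integer number of steps from the peak to predicted recovery.
#' @export
predict_recovery_steps <- function(peak, alpha, band) {
  if (peak <= band) return(0L)
  if (alpha >= 1) return(1L)
  if (alpha <= 0) return(NA_integer_)
  as.integer(ceiling(log(band / peak) / log(1 - alpha)))
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf(paste0("<subject_model: step %.3f (%.3f) s, alpha %.2f, ",
                     "transient peak %.1f mm, seed %d>\n"),
              x$mean_step_time, x$step_sd, x$alpha, x$transient_peak, x$seed))
  invisible(x)
}

#' Write a truth record to JSON
#'
#' @param truth The `truth` element of [generate_trial()] output.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}
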