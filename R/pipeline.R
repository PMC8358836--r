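# End-to-end orchestration: events -> step times -> metronome ->
# preprocessing -> embedding -> torus -> resilience + occupancy ->
# synchrony, as one pure dataflow over a declarative configuration.

#' Default pipeline configuration
#'
#' All tunable constants of the pipeline in one nested list. The defaults
#' are the constants of the analysis protocol: 4th-order 5 Hz zero-phase
#' low-pass with 5 s start-up trim; AMI/FNN embedding parameter estimation
#' (R_tol 15, A_tol 2, FNN < 1%); 3-dimensional torus with 50 angular
#' neighbours and 1/2/3 sigma levels; excursions of at least 0.1 s beyond
#' T_2s, recovery over 5 clean cycles permitting 4 outliers of at most
#' 0.01 s; synchrony band of +/- 2 SD over the 10 pre-perturbation steps,
#' 3-step windows, 8 consecutive windows; 5 perturbed intervals at 20x the
#' step-time SD around 180 s.
#'
#' @return Nested named list; see the sections for the meaning of each
#'   constant.
#' @export
default_config <- function() {
  list(
    fs = 100,
    filter = list(order = 4, cutoff = 5, trim = 5),
    events = list(v_thresh = 50, smooth_cutoff = 10, min_window_s = 0.1),
    embedding = list(max_lag = 200, max_dim = 10, r_tol = 15, a_tol = 2,
                     fnn_threshold = 0.01, n_max = 1500, m_torus = 3),
    torus = list(n_neighbors = 50, k_levels = c(1, 2, 3),
                 sd_about = "reference"),
    resilience = list(min_excursion = 0.1, outlier_max = 0.01,
                      n_outliers = 4, n_cycles = 5, cycle_steps = 2,
                      peak_window = 60),
    synchrony = list(n_pre = 10, window = 3, n_windows = 8, band_sd = 2,
                     center = "pre_mean"),
    stimulus = list(n_perturb = 5, perturb_onset = 180, sd_multiplier = 20,
                    consecutive = TRUE, tone_freq = 440, tone_duration = 0.1),
    stats = list(n_boot = 5000),
    seed = 1
  )
}

#' Read / write a pipeline configuration (YAML)
#'
#' The configuration round-trips losslessly through YAML.
#'
#' @param config A configuration list, e.g. [default_config()].
#' @param path File path.
#' @return `write_config`: invisibly, `path`; `read_config`: the list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

# events -> step series for one trial's marker set
trial_steps <- function(markers, config) {
  ev <- detect_gait_events(
    markers$heel_left, markers$toe_left, markers$heel_right,
    markers$toe_right,
    v_thresh = config$events$v_thresh,
    smooth_cutoff = config$events$smooth_cutoff,
    min_window_s = config$events$min_window_s)
  compute_step_times(ev)
}

#' Run the full pipeline for one subject
#'
#' Executes the complete per-subject analysis: gait events and step times
#' from the baseline (BW1) foot markers; the subject-specific metronome
#' track (built from the baseline step statistics unless one is provided);
#' preprocessing of all COM signals; per-trial delay and dimension
#' estimation, averaged across trials; 3-dimensional embedding; reference
#' trajectory and tori from BW1; classification of CW (and BW2); resilience
#' parameters, phase segmentation and occupancy; footfall asynchrony and
#' synchrony recovery from the CW step times. Deterministic given the
#' inputs.
#'
#' @param bw1,cw Lists with elements `markers` (named list of
#'   [marker_trace()], incl. the four foot markers) and `com`
#'   (a [com_signal()]), e.g. from [generate_trial()].
#' @param bw2 Optional second baseline trial, same shape.
#' @param track Optional [build_metronome()] track; built from the BW1 step
#'   statistics if omitted.
#' @param config Pipeline configuration (default [default_config()]).
#' @param subject Subject identifier carried into the result.
#' @return Object of class `subject_result`: nested list with elements
#'   `subject`, `steps` (baseline summary), `track` (base IBI, magnitude,
#'   onset), `embedding` (per-trial and averaged tau/d), `resilience`,
#'   `phases`, `occupancy` (per phase), `synchrony`, plus the
#'   `deviation_series` for CW (`dev_cw`) and BW2 (`dev_bw2`, if present).
#' @export
run_subject <- function(bw1, cw, bw2 = NULL, track = NULL,
                        config = default_config(), subject = "S01") {
  step_fail <- function(stage, e) {
    stopf("subject %s, stage '%s': %s", subject, stage, conditionMessage(e))
  }
  # -- gait events and baseline step statistics
  steps_bw1 <- tryCatch(trial_steps(bw1$markers, config),
                        error = function(e) step_fail("gait_events", e))
  ssum <- step_summary(steps_bw1)
  # -- stimulus schedule
  if (is.null(track)) {
    dur <- max(cw$com$t) - min(cw$com$t)
    track <- build_metronome(ssum$mean_step_time, ssum$sd_step_time,
                             duration = dur,
                             n_perturb = config$stimulus$n_perturb,
                             perturb_onset = config$stimulus$perturb_onset,
                             sd_multiplier = config$stimulus$sd_multiplier,
                             consecutive = config$stimulus$consecutive)
  }
  perturb_onset <- perturbation_onset_time(track)
  # -- preprocessing
  trials <- list(BW1 = bw1$com, CW = cw$com)
  if (!is.null(bw2)) trials$BW2 <- bw2$com
  pp <- lapply(trials, function(s)
    preprocess_com(s, cutoff = config$filter$cutoff,
                   order = config$filter$order, trim = config$filter$trim))
  # -- embedding parameters per trial, averaged across trials
  emb <- config$embedding
  taus <- vapply(pp, function(s) as.integer(estimate_delay(s, emb$max_lag)),
                 integer(1))
  dims <- vapply(pp, function(s)
    as.integer(estimate_dimension(s, taus[[s$trial]], max_dim = emb$max_dim,
                                  r_tol = emb$r_tol, a_tol = emb$a_tol,
                                  fnn_threshold = emb$fnn_threshold,
                                  n_max = emb$n_max)), integer(1))
  avg <- average_embedding_params(taus, dims)
  # -- reduced 3D state space, torus from BW1
  m <- emb$m_torus
  emb_trials <- lapply(pp, embed_delay, tau = avg$tau_samples, m = m)
  ref <- fit_reference(emb_trials$BW1)
  torus <- build_tori(emb_trials$BW1, ref,
                      n_neighbors = config$torus$n_neighbors,
                      k_levels = config$torus$k_levels,
                      sd_about = config$torus$sd_about)
  dev_cw <- classify_trajectory(torus, emb_trials$CW)
  dev_bw2 <- if (!is.null(bw2)) classify_trajectory(torus, emb_trials$BW2)
  # -- resilience and phase occupancy
  res_cfg <- config$resilience
  cycle <- res_cfg$cycle_steps * ssum$mean_step_time
  res <- compute_resilience(dev_cw, perturb_onset, cycle,
                            min_excursion = res_cfg$min_excursion,
                            outlier_max = res_cfg$outlier_max,
                            n_outliers = res_cfg$n_outliers,
                            n_cycles = res_cfg$n_cycles,
                            peak_window = res_cfg$peak_window)
  span <- range(dev_cw$t)
  span[2] <- span[2] + 1 / attr(dev_cw, "fs")  # half-open trial end
  phases <- if (res$deviated) {
    suppressWarnings(segment_phases(span, perturb_onset, res$t_recovery))
  } else {
    list(CW1 = c(span[1], perturb_onset), CW2 = c(perturb_onset, span[2]),
         CW3 = NULL)
  }
  occ <- list(CW = occupancy(dev_cw, span))
  for (ph in names(phases)) {
    w <- phases[[ph]]
    occ[[ph]] <- if (!is.null(w) && diff(w) > 0) occupancy(dev_cw, w)
  }
  if (!is.null(dev_bw2)) {
    sp2 <- range(dev_bw2$t); sp2[2] <- sp2[2] + 1 / attr(dev_bw2, "fs")
    occ$BW2 <- occupancy(dev_bw2, sp2)
  }
  # -- footfall synchrony from the cued trial
  steps_cw <- tryCatch(trial_steps(cw$markers, config),
                       error = function(e) step_fail("gait_events_cw", e))
  asyn <- compute_asynchrony(steps_cw, track$base_ibi)
  perturb_step <- which(asyn$t >= perturb_onset)[1]
  syn_cfg <- config$synchrony
  syn <- if (!is.na(perturb_step)) {
    tryCatch(
      synchrony_recovery(asyn, perturb_step, n_pre = syn_cfg$n_pre,
                         window = syn_cfg$window,
                         n_windows = syn_cfg$n_windows,
                         band_sd = syn_cfg$band_sd, center = syn_cfg$center),
      error = function(e) step_fail("synchrony", e))
  }
  structure(list(
    subject = subject,
    steps = ssum,
    track = list(base_ibi = track$base_ibi,
                 perturb_magnitude = track$perturb_magnitude,
                 perturb_onset = perturb_onset,
                 perturbation_time = perturbation_time(track)),
    embedding = list(tau_per_trial = taus, dim_per_trial = dims,
                     tau_samples = avg$tau_samples, tau_s = avg$tau_samples / bw1$com$fs,
                     dim = avg$dim, m_torus = m),
    resilience = res,
    phases = phases,
    occupancy = occ,
    synchrony = syn,
    asynchrony = asyn,
    dev_cw = dev_cw,
    dev_bw2 = dev_bw2),
    class = "subject_result")
}

#' One summary row per subject result
#'
#' Flattens a [run_subject()] bundle into a single data.frame row of the
#' headline metrics.
#'
#' @param result A `subject_result`.
#' @return One-row data.frame.
#' @export
subject_row <- function(result) {
  r <- result$resilience
  s <- result$synchrony
  occ2 <- function(ph) {
    o <- result$occupancy[[ph]]
    if (is.null(o)) NA_real_ else unname(o["T3"] + o["OUT"])
  }
  data.frame(
    subject = result$subject,
    mean_step_time_s = result$steps$mean_step_time,
    sd_step_time_s = result$steps$sd_step_time,
    perturb_magnitude_s = result$track$perturb_magnitude,
    perturbation_time_s = result$track$perturbation_time,
    tau_s = result$embedding$tau_s,
    dim = result$embedding$dim,
    tau_bw1 = unname(result$embedding$tau_per_trial["BW1"]),
    tau_cw = unname(result$embedding$tau_per_trial["CW"]),
    tau_bw2 = unname(result$embedding$tau_per_trial["BW2"]),
    dim_bw1 = unname(result$embedding$dim_per_trial["BW1"]),
    dim_cw = unname(result$embedding$dim_per_trial["CW"]),
    dim_bw2 = unname(result$embedding$dim_per_trial["BW2"]),
    deviated = r$deviated,
    lag_time_s = r$lag_time,
    peak_time_s = r$peak_time,
    peak_magnitude_mm = r$peak_magnitude,
    com_recovery_time_s = r$com_recovery_time,
    adjusted = if (is.null(s)) NA else s$adjusted,
    synchronized = if (is.null(s)) NA else s$synchronized,
    peak_adjustment_s = if (is.null(s)) NA_real_ else s$peak_adjustment,
    synchrony_recovery_time_s =
      if (is.null(s)) NA_real_ else s$synchrony_recovery_time,
    pre_sd_s = if (is.null(s)) NA_real_ else s$pre_sd,
    out_beyond_t2_cw2_pct = occ2("CW2"),
    stringsAsFactors = FALSE)
}

#' Generate and analyze a full synthetic cohort
#'
#' For each subject of a synthetic cohort, generates BW1, CW and BW2 trials
#' plus the subject-specific metronome track, runs [run_subject()], and
#' collects one row per subject. Reproducible: all randomness derives from
#' the subject seeds.
#'
#' @param cohort List of [subject_model()]s, e.g. [generate_cohort()].
#' @param duration Trial duration (s, default 360).
#' @param config Pipeline configuration.
#' @param keep_results Keep the full per-subject bundles (default FALSE to
#'   save memory).
#' @param progress Print one line per subject (default FALSE).
#' @return List with `table` (one row per subject, including ground-truth
#'   columns `true_peak_mm`, `true_alpha`, `predicted_recovery_steps`) and,
#'   if requested, `results`.
#' @export
run_cohort <- function(cohort, duration = 360, config = default_config(),
                       keep_results = FALSE, progress = FALSE) {
  rows <- vector("list", length(cohort))
  results <- if (keep_results) vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    model <- cohort[[i]]
    id <- names(cohort)[i]
    if (is.null(id) || id == "") id <- sprintf("S%02d", i)
    bw1 <- generate_trial(model, "BW", duration, trial = "BW1",
                          seed = model$seed)
    track <- build_metronome(model$mean_step_time, model$step_sd, duration,
                             n_perturb = config$stimulus$n_perturb,
                             perturb_onset = config$stimulus$perturb_onset,
                             sd_multiplier = config$stimulus$sd_multiplier,
                             consecutive = config$stimulus$consecutive)
    cw <- generate_trial(model, "CW", duration, track = track, trial = "CW",
                         seed = model$seed + 1L)
    bw2 <- generate_trial(model, "BW", duration, trial = "BW2",
                          seed = model$seed + 2L)
    res <- run_subject(bw1, cw, bw2, track = track, config = config,
                       subject = id)
    row <- subject_row(res)
    row$true_peak_mm <- model$transient_peak
    row$true_alpha <- model$alpha
    # analytic geometric-decay prediction of steps from peak to recovery
    peak_clean <- max(abs(cw$truth$asyn_clean))
    row$true_peak_asyn_s <- peak_clean
    row$predicted_recovery_steps <-
      predict_recovery_steps(peak_clean, model$alpha,
                             config$synchrony$band_sd * model$step_sd)
    # measured steps from peak to recovery, for the parameter-recovery check
    s <- res$synchrony
    row$measured_recovery_steps <-
      if (!is.null(s) && s$synchronized) s$recovery_step - s$peak_step
      else NA_integer_
    rows[[i]] <- row
    if (keep_results) results[[i]] <- res
    if (progress) {
      message(sprintf("%s: deviated=%s peak=%.1f mm recovery=%.1f s",
                      id, row$deviated, row$peak_magnitude_mm,
                      row$com_recovery_time_s))
    }
  }
  out <- list(table = do.call(rbind, rows))
  if (keep_results) out$results <- stats::setNames(results, names(cohort))
  out
}

#' Group summary of a cohort table
#'
#' Mean (SD) of the resilience and synchrony metrics over the deviated
#' subjects, phenotype counts, and the paired bootstrap mean difference
#' between COM recovery time and synchrony recovery time.
#'
#' @param table Cohort table from [run_cohort()].
#' @param n_boot Bootstrap resamples (default 5000).
#' @param seed Seed for the bootstrap.
#' @return List with `n`, `n_deviated`, `n_non_adjusting`, `metrics`
#'   (data.frame of mean/SD), and `recovery_difference` (bootstrap result).
#' @export
cohort_summary <- function(table, n_boot = 5000, seed = 1) {
  dv <- table[table$deviated %in% TRUE, , drop = FALSE]
  msd <- function(x) c(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE))
  metrics <- t(vapply(
    c("lag_time_s", "peak_time_s", "peak_magnitude_mm",
      "com_recovery_time_s", "synchrony_recovery_time_s",
      "peak_adjustment_s"),
    function(v) msd(dv[[v]]), numeric(2)))
  diff <- if (sum(is.finite(dv$com_recovery_time_s) &
                  is.finite(dv$synchrony_recovery_time_s)) >= 2) {
    bootstrap_mean_diff(dv$com_recovery_time_s, dv$synchrony_recovery_time_s,
                        n_boot = n_boot, seed = seed)
  }
  list(n = nrow(table),
       n_deviated = sum(table$deviated %in% TRUE),
       n_non_adjusting = sum(table$adjusted %in% FALSE),
       metrics = as.data.frame(metrics),
       recovery_difference = diff)
}

#' Write a subject result bundle to JSON
#'
#' Serializes the headline metrics (not the full per-sample series) of a
#' [run_subject()] bundle.
#'
#' @param result A `subject_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_subject_result <- function(result, path) {
  doc <- list(
    subject = result$subject,
    steps = result$steps,
    track = result$track,
    embedding = result$embedding,
    resilience = unclass(result$resilience),
    occupancy = lapply(result$occupancy, as.list),
    synchrony = if (!is.null(result$synchrony)) unclass(result$synchrony))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}
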