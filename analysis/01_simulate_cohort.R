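#!/usr/bin/env Rscript
# Simulate the synthetic study cohort: 20 walkers with individualized
# baseline rhythm, of whom 5 show no COM deviation after the rhythm
# perturbation and 2 of those do not adjust their step timing at all.
# Writes the cohort parameter table, one example subject's marker data,
# metronome schedule and audio track.

suppressPackageStartupMessages(library(gaitresilience))

seed <- 1
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cohort <- generate_cohort(n_subjects = 20, seed = seed)

params <- do.call(rbind, lapply(names(cohort), function(id) {
  m <- cohort[[id]]
  data.frame(subject = id, mean_step_time_s = m$mean_step_time,
             step_sd_s = m$step_sd, com_amplitude_mm = m$com_amplitude,
             alpha = m$alpha, transient_peak_mm = m$transient_peak,
             transient_rise_s = m$transient_rise,
             transient_decay_s = m$transient_decay, seed = m$seed)
}))
write.csv(params, "results/cohort_parameters.csv", row.names = FALSE)
message("cohort parameters -> results/cohort_parameters.csv")

# example subject: raw marker tables, truth record, stimulus track + audio
m <- cohort[[6]]  # first subject with an injected COM transient
bw1 <- generate_trial(m, "BW", duration = 360, trial = "BW1", seed = m$seed)
track <- build_metronome(m$mean_step_time, m$step_sd, duration = 360)
cw <- generate_trial(m, "CW", duration = 360, track = track, trial = "CW",
                     seed = m$seed + 1L)

write_markers(bw1$markers, "scratch/example_bw1_markers.csv")
write_markers(cw$markers, "scratch/example_cw_markers.csv")
write_truth(cw$truth, "scratch/example_cw_truth.json")
write_track(track, "results/example_track_schedule.csv")
render_wav(track, "scratch/example_track.wav")
message(sprintf(
  "example subject S06: base IBI %.3f s, perturbation %.3f s per interval, %.1f s total",
  track$base_ibi, track$perturb_magnitude, perturbation_time(track)))
message("example data -> scratch/, schedule -> results/example_track_schedule.csv")
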