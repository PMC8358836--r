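# Subject-specific metronome tracks with embedded beat-delay perturbations.
#
# The inter-beat interval (IBI) is matched to the subject's mean baseline
# step time; the perturbation lengthens a small number of IBIs by 20x the
# subject's baseline step-time standard deviation, scaling the challenge to
# each individual's own variability rather than an arbitrary fixed shift.

#' Build a subject-specific metronome track
#'
#' Beats are isochronous at `base_ibi = mean_step_time`, except for
#' `n_perturb` perturbed intervals each lengthened by
#' `perturb_magnitude = 20 * sd_step_time`, starting at the first beat at or
#' after `perturb_onset`.
#'
#' @param mean_step_time Mean baseline step time (s); becomes the nominal IBI.
#' @param sd_step_time Baseline step-time standard deviation (s).
#' @param duration Track duration (s); beats fill it.
#' @param n_perturb Number of perturbed intervals (default 5).
#' @param perturb_onset Approximate time of the perturbation (s, default 180,
#'   i.e. around 3 minutes in).
#' @param sd_multiplier Perturbation scale in units of `sd_step_time`
#'   (default 20).
#' @param consecutive If `TRUE` (default) the perturbed intervals are
#'   consecutive; otherwise they are separated by one unperturbed interval.
#'
#' @return An object of class `metronome_track`: list with `onsets` (s),
#'   `ibis` (s, length `length(onsets) - 1`), `perturbed_idx` (indices into
#'   `ibis`), `base_ibi`, `perturb_magnitude` (s).
#' @export
build_metronome <- function(mean_step_time, sd_step_time, duration,
                            n_perturb = 5, perturb_onset = 180,
                            sd_multiplier = 20, consecutive = TRUE) {
  if (!is_scalar_num(mean_step_time) || mean_step_time <= 0) {
    stopf("mean_step_time must be > 0")
  }
  if (!is_scalar_num(sd_step_time) || sd_step_time < 0) {
    stopf("sd_step_time must be >= 0")
  }
  if (perturb_onset >= duration) stopf("perturb_onset must fall before duration")
  if (sd_step_time == 0) warnf("zero-magnitude perturbation (sd_step_time = 0)")
  base <- mean_step_time
  mag <- sd_multiplier * sd_step_time
  # interval index at which the perturbation begins: the interval following
  # the first beat at or after perturb_onset
  first_beat <- ceiling(perturb_onset / base - 1e-9)
  stride <- if (consecutive) 1L else 2L
  pidx <- first_beat + 1L + stride * (seq_len(n_perturb) - 1L)
  ibis <- numeric(0)
  onset <- 0
  i <- 0L
  repeat {
    i <- i + 1L
    ibi <- base + if (i %in% pidx) mag else 0
    if (onset + ibi > duration + 1e-9) break
    ibis <- c(ibis, ibi)
    onset <- onset + ibi
  }
  if (max(pidx) > length(ibis)) stopf("duration too short for the perturbation")
  structure(
    list(onsets = c(0, cumsum(ibis)), ibis = ibis,
         perturbed_idx = pidx, base_ibi = base, perturb_magnitude = mag),
    class = "metronome_track")
}

#' @export
print.metronome_track <- function(x, ...) {
  cat(sprintf(paste0("<metronome_track: %d beats, IBI %.3f s, %d perturbed ",
                     "intervals (+%.3f s each) from %.2f s>\n"),
              length(x$onsets), x$base_ibi, length(x$perturbed_idx),
              x$perturb_magnitude, perturbation_onset_time(x)))
  invisible(x)
}

#' Onset time of the perturbation
#'
#' Time of the beat that starts the first perturbed inter-beat interval.
#'
#' @param track A `metronome_track`.
#' @return Time in seconds.
#' @export
perturbation_onset_time <- function(track) {
  track$onsets[min(track$perturbed_idx)]
}

#' Total duration of the perturbed intervals
#'
#' The "perturbation time": the summed duration of the perturbed inter-beat
#' intervals.
#'
#' @param track A `metronome_track`.
#' @return Duration in seconds.
#' @export
perturbation_time <- function(track) {
  sum(track$ibis[track$perturbed_idx])
}

#' Render a metronome track to a WAV file
#'
#' Each beat is a 0.1 s sine tone at 440 Hz (musical note A) with short
#' linear fade-in/out ramps to avoid clicks; silence elsewhere. Output is
#' mono 16-bit PCM. The RIFF/WAV container is written directly with
#' `writeBin`.
#'
#' @param track A `metronome_track`.
#' @param path Output `.wav` path.
#' @param sample_rate Audio sampling rate (Hz, default 44100).
#' @param tone_freq Tone frequency (Hz, default 440).
#' @param tone_duration Tone duration (s, default 0.1).
#' @param gain Peak amplitude in (0, 1] (default 0.8).
#' @param fade Linear fade-in/out duration (s, default 0.005).
#' @return Invisibly, the rendered waveform (numeric vector in [-1, 1]).
#' @export
render_wav <- function(track, path, sample_rate = 44100, tone_freq = 440,
                       tone_duration = 0.1, gain = 0.8, fade = 0.005) {
  if (length(track$onsets) == 0L) stopf("track has no beats")
  if (length(track$ibis) && min(track$ibis) < tone_duration) {
    stopf("overlapping tones: an inter-beat interval is shorter than %.3g s",
          tone_duration)
  }
  n_tone <- round(tone_duration * sample_rate)
  tone <- gain * sin(2 * pi * tone_freq * (seq_len(n_tone) - 1) / sample_rate)
  n_fade <- min(round(fade * sample_rate), floor(n_tone / 2))
  if (n_fade > 0) {
    ramp <- seq(0, 1, length.out = n_fade)
    tone[seq_len(n_fade)] <- tone[seq_len(n_fade)] * ramp
    tone[n_tone - n_fade + seq_len(n_fade)] <-
      tone[n_tone - n_fade + seq_len(n_fade)] * rev(ramp)
  }
  total <- round(max(track$onsets) * sample_rate) + n_tone
  wave <- numeric(total)
  for (on in track$onsets) {
    i0 <- round(on * sample_rate)
    wave[i0 + seq_len(n_tone)] <- tone
  }
  write_wav_pcm16(wave, path, sample_rate)
  invisible(wave)
}

# Minimal mono 16-bit PCM RIFF/WAV writer.
write_wav_pcm16 <- function(wave, path, sample_rate) {
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Export / import a track schedule as delimited text
#'
#' Columns `onset_s,ibi_s,perturbed`; the last beat has `ibi_s = NA`. Used to
#' align the stimulus schedule with kinematics.
#'
#' @param track A `metronome_track`.
#' @param path File path.
#' @return `write_track`: invisibly, `path`. `read_track`: a
#'   `metronome_track`.
#' @export
write_track <- function(track, path) {
  n <- length(track$onsets)
  perturbed <- rep(FALSE, n)
  perturbed[track$perturbed_idx] <- TRUE  # interval i starts at beat i
  d <- data.frame(onset_s = track$onsets,
                  ibi_s = c(track$ibis, NA),
                  perturbed = perturbed)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  d <- utils::read.csv(path)
  ibis <- d$ibi_s[-nrow(d)]
  pidx <- which(d$perturbed[-nrow(d)])
  base <- stats::median(ibis)
  mag <- if (length(pidx)) mean(ibis[pidx]) - base else 0
  structure(list(onsets = d$onset_s, ibis = ibis, perturbed_idx = pidx,
                 base_ibi = base, perturb_magnitude = mag),
            class = "metronome_track")
}
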