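#' Marker trajectory container
#'
#' A single motion-capture marker trajectory sampled uniformly in time.
#' Positions are in millimetres, following optical motion-capture convention;
#' column 3 of `pos` is the vertical axis.
#'
#' @param label Marker name, e.g. `"heel_left"` or `"sacrum"`.
#' @param t Sample timestamps in seconds, strictly increasing and uniformly
#'   spaced at `1/fs`.
#' @param pos Numeric matrix with one row per sample and 3 columns (x, y, z)
#'   in mm. A vector is accepted and treated as the vertical (z) coordinate.
#' @param fs Sampling rate in Hz.
#'
#' @return An object of class `marker_trace` with fields `label`, `t`, `pos`
#'   and `fs`.
#' @export
marker_trace <- function(label, t, pos, fs) {
  if (!is_scalar_num(fs) || fs <= 0) stopf("fs must be a positive number")
  t <- as.numeric(t)
  if (is.null(dim(pos))) pos <- cbind(x = 0, y = 0, z = as.numeric(pos))
  pos <- as.matrix(pos)
  if (ncol(pos) != 3L) stopf("pos must have 3 columns (x, y, z)")
  if (nrow(pos) != length(t)) stopf("t and pos lengths differ")
  if (length(t) >= 2L) {
    dt <- diff(t)
    if (any(dt <= 0)) stopf("timestamps must be strictly increasing")
    if (any(abs(dt - 1 / fs) > 1e-9)) {
      stopf("timestamps are not uniform at 1/fs = %g s", 1 / fs)
    }
  }
  if (!all(is.finite(pos))) stopf("marker positions must be finite")
  structure(list(label = label, t = t, pos = pos, fs = fs),
            class = "marker_trace")
}

#' @export
print.marker_trace <- function(x, ...) {
  cat(sprintf("<marker_trace '%s': %d samples @ %g Hz, %.2f-%.2f s>\n",
              x$label, length(x$t), x$fs, x$t[1], x$t[length(x$t)]))
  invisible(x)
}

#' Read marker trajectories from a delimited text file
#'
#' Expects a header `time,<label>_x,<label>_y,<label>_z` (any number of
#' markers), time in seconds and positions in mm.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz; if `NULL`, inferred from the median time
#'   step.
#' @return Named list of [marker_trace()] objects.
#' @export
read_markers <- function(path, fs = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(d)) stopf("marker file must have a 'time' column")
  t <- d$time
  if (is.null(fs)) fs <- 1 / stats::median(diff(t))
  cols <- setdiff(names(d), "time")
  labels <- unique(sub("_[xyz]$", "", cols))
  out <- lapply(labels, function(lab) {
    need <- paste0(lab, "_", c("x", "y", "z"))
    if (!all(need %in% cols)) stopf("marker '%s' is missing x/y/z columns", lab)
    marker_trace(lab, t, as.matrix(d[, need]), fs)
  })
  names(out) <- labels
  out
}

#' Write marker trajectories to a delimited text file
#'
#' Inverse of [read_markers()]: one `time` column plus `<label>_{x,y,z}`
#' columns per marker.
#'
#' @param traces Named list of [marker_trace()] objects on a common time base.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_markers <- function(traces, path) {
  t0 <- traces[[1]]$t
  cols <- list(time = t0)
  for (tr in traces) {
    if (length(tr$t) != length(t0) || max(abs(tr$t - t0)) > 1e-9) {
      stopf("all traces must share one time base")
    }
    cols[[paste0(tr$label, "_x")]] <- tr$pos[, 1]
    cols[[paste0(tr$label, "_y")]] <- tr$pos[, 2]
    cols[[paste0(tr$label, "_z")]] <- tr$pos[, 3]
  }
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE)
  invisible(path)
}

#' Write detected gait events to a delimited text file
#'
#' Long format `time,foot,event` with `event` in `{HS, TO}`.
#'
#' @param events A `gait_events` object from [detect_gait_events()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_events <- function(events, path) {
  d <- rbind(
    data.frame(time = events$heel_strikes_left,  foot = "left",  event = "HS"),
    data.frame(time = events$toe_offs_left,      foot = "left",  event = "TO"),
    data.frame(time = events$heel_strikes_right, foot = "right", event = "HS"),
    data.frame(time = events$toe_offs_right,     foot = "right", event = "TO")
  )
  d <- d[order(d$time), ]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
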