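# COM signal preprocessing and state-space reconstruction.
#
# The vertical sacral displacement stands in for the body centre of mass
# (COM). After trimming start-up effects, zero-phase low-pass filtering and
# demeaning, the scalar series is reconstructed in state space by time-delay
# embedding [x(t), x(t+tau), ..., x(t+(d-1)tau)]. The delay tau comes from
# the first local minimum of average mutual information (AMI), the dimension
# d from the false-nearest-neighbours (FNN) criterion.

#' COM signal container
#'
#' @param t Timestamps (s), uniform at `1/fs`.
#' @param x Vertical sacrum displacement (mm).
#' @param fs Sampling rate (Hz).
#' @param trial Trial label, conventionally one of `"BW1"`, `"CW"`, `"BW2"`.
#' @return Object of class `com_signal`.
#' @export
com_signal <- function(t, x, fs, trial = "BW1") {
  t <- as.numeric(t); x <- as.numeric(x)
  if (length(t) != length(x)) stopf("t and x lengths differ")
  if (!all(is.finite(x))) stopf("signal must be finite")
  if (length(t) >= 2L && any(abs(diff(t) - 1 / fs) > 1e-9)) {
    stopf("timestamps are not uniform at 1/fs")
  }
  structure(list(t = t, x = x, fs = fs, trial = trial), class = "com_signal")
}

#' @export
print.com_signal <- function(x, ...) {
  cat(sprintf("<com_signal %s: %d samples @ %g Hz, sd %.2f mm>\n",
              x$trial, length(x$x), x$fs, stats::sd(x$x)))
  invisible(x)
}

#' Preprocess a COM signal
#'
#' Applies a zero-phase (forward-backward) Butterworth low-pass filter, then
#' drops the first `trim` seconds (walking start-up effects, which also
#' absorb the filter's leading edge transient) and the last `trim_end`
#' seconds (the trailing filter edge), and removes the mean. Zero-phase
#' filtering is used so that event timing in the downstream deviation series
#' is not shifted.
#'
#' @param raw A [com_signal()] covering at least 10 s.
#' @param cutoff Low-pass cutoff frequency (Hz, default 5).
#' @param order Butterworth order (default 4; applied twice by filtfilt).
#' @param trim Seconds removed from the start (default 5).
#' @param trim_end Seconds removed from the end (default 0.5); set to 0 to
#'   keep the full tail.
#' @return A preprocessed [com_signal()] (absolute timestamps retained).
#' @export
preprocess_com <- function(raw, cutoff = 5, order = 4, trim = 5,
                           trim_end = 0.5) {
  fs <- raw$fs
  if (fs <= 2 * cutoff) stopf("sampling rate too low for a %g Hz cutoff", cutoff)
  if (length(raw$x) / fs < 10) stopf("need at least 10 s of data")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # remove the static marker height before filtering: the zero-phase edge
  # transient scales with the DC offset
  x0 <- raw$x - mean(raw$x)
  x <- as.numeric(signal::filtfilt(bf, x0))
  keep <- raw$t >= raw$t[1] + trim &
    raw$t <= raw$t[length(raw$t)] - trim_end
  t <- raw$t[keep]; x <- x[keep]
  x <- x - mean(x)
  com_signal(t, x, fs, raw$trial)
}

# Average mutual information (nats) between x(t) and x(t+lag), using
# equiprobable (rank-based) binning with n_bins bins.
ami_lag <- function(bin_idx, lag, n_bins) {
  n <- length(bin_idx) - lag
  a <- bin_idx[seq_len(n)]
  b <- bin_idx[seq_len(n) + lag]
  joint <- tabulate((a - 1L) * n_bins + b, nbins = n_bins * n_bins) / n
  pa <- tabulate(a, nbins = n_bins) / n
  pb <- tabulate(b, nbins = n_bins) / n
  pp <- outer(pa, pb)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / pp[nz]))
}

#' Estimate the embedding delay by average mutual information
#'
#' tau is the first local minimum of the AMI over lags `1..max_lag` samples,
#' with AMI computed on `ceiling(N^(1/3))` equal-width bins and a valley
#' prominence requirement of 0.1 nats (histogram-estimation ripple is not
#' mistaken for structure). If no qualifying local minimum exists in range,
#' falls back to the first lag at which the autocorrelation drops below
#' `1/e`, with a warning.
#'
#' @param signal A preprocessed [com_signal()], at least 30 s long.
#' @param max_lag Largest lag examined (samples, default 200).
#' @return Integer delay in samples, with attributes `tau_s` (seconds),
#'   `ami` (the AMI curve) and `method` (`"ami"` or `"acf"`).
#' @export
estimate_delay <- function(signal, max_lag = 200) {
  x <- signal$x
  n <- length(x)
  if (n / signal$fs < 30) stopf("need at least 30 s to estimate the delay")
  n_bins <- ceiling(n^(1 / 3))
  # equal-width bins over the signal range; the rank (equiprobable)
  # alternative resonates with the bin grid on strongly periodic signals
  breaks <- seq(min(x) - 1e-12, max(x) + 1e-12, length.out = n_bins + 1)
  bin_idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  max_lag <- min(max_lag, n - 10L)
  ami <- vapply(seq_len(max_lag), function(l) ami_lag(bin_idx, l, n_bins),
                numeric(1))
  # first interior local minimum that is a genuine valley: the curve must
  # rise at least `prominence` nats above the candidate before dropping
  # below it again, so histogram-estimation ripples are not mistaken for
  # structure
  prominence <- 0.1
  tau <- NA_integer_
  for (k in 2:(max_lag - 1)) {
    if (ami[k] < ami[k - 1] && ami[k] <= ami[k + 1]) {
      after <- ami[(k + 1):max_lag]
      below <- which(after < ami[k])
      upto <- if (length(below)) below[1] - 1L else length(after)
      if (upto >= 1L && max(after[seq_len(upto)]) - ami[k] >= prominence) {
        tau <- k
        break
      }
    }
  }
  method <- "ami"
  if (is.na(tau)) {
    warnf("no AMI local minimum within %d lags; falling back to 1/e autocorrelation",
          max_lag)
    ac <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
    tau <- which(ac < exp(-1))[1]
    if (is.na(tau)) tau <- max_lag
    method <- "acf"
  }
  structure(as.integer(tau), tau_s = tau / signal$fs, ami = ami, method = method)
}

# Fraction of false nearest neighbours at dimension d, Kennel-style test:
# a neighbour at dimension d is false if the extra coordinate at d+1 either
# blows up the neighbour distance (ratio > r_tol) or is large relative to
# the attractor size (> a_tol * sd(x)).
fnn_fraction <- function(x, tau, d, r_tol, a_tol, theiler, idx) {
  n_vec <- length(x) - d * tau  # need coordinate d+1 as well
  idx <- idx[idx <= n_vec]
  m <- length(idx)
  emb <- vapply(0:(d - 1), function(k) x[idx + k * tau], numeric(m))
  if (d == 1) emb <- matrix(emb, ncol = 1)
  d2 <- as.matrix(stats::dist(emb))^2
  sep <- abs(outer(idx, idx, "-"))
  d2[sep <= theiler] <- Inf
  nn <- max.col(-d2, ties.method = "first")
  dd <- sqrt(d2[cbind(seq_len(m), nn)])
  xnext <- x[idx + d * tau]
  extra <- abs(xnext - xnext[nn])
  ok <- is.finite(dd)
  # numerically coincident neighbours (projection collisions) are false
  # neighbours exactly when some coincident neighbour separates in the
  # extra coordinate; otherwise the standard distance-ratio and
  # attractor-size criteria apply
  eps <- 1e-6 * stats::sd(x)
  sep <- 1e-3 * stats::sd(x)
  coll_false <- rowSums(d2 <= eps^2 &
                          abs(outer(xnext, xnext, "-")) > sep) > 0
  ratio_false <- (dd[ok] > eps & extra[ok] / pmax(dd[ok], 1e-300) > r_tol) |
    coll_false[ok]
  size_false <- sqrt(dd[ok]^2 + extra[ok]^2) / stats::sd(x) > a_tol
  mean(ratio_false | size_false)
}

#' Estimate the embedding dimension by false nearest neighbours
#'
#' Returns the smallest dimension at which the FNN fraction falls below
#' `fnn_threshold`. The neighbour search runs on a uniform subsample of at
#' most `n_max` embedded vectors with a Theiler exclusion window of `tau`
#' samples.
#'
#' @param signal A preprocessed [com_signal()].
#' @param tau Embedding delay (samples), e.g. from [estimate_delay()].
#' @param max_dim Dimension cap (default 10); if the criterion is never met
#'   the cap is returned with a warning.
#' @param r_tol,a_tol FNN thresholds (defaults 15 and 2).
#' @param fnn_threshold Acceptable FNN fraction (default 0.01).
#' @param n_max Maximum number of vectors used in the neighbour search.
#' @return Integer dimension with attribute `fnn` (fraction per dimension).
#' @export
estimate_dimension <- function(signal, tau, max_dim = 10, r_tol = 15,
                               a_tol = 2, fnn_threshold = 0.01, n_max = 1500) {
  x <- signal$x
  tau <- as.integer(tau)
  if (length(x) <= (max_dim + 1) * tau) stopf("signal too short for FNN up to d = %d", max_dim)
  n_vec <- length(x) - tau
  stride <- max(1L, floor(n_vec / n_max))
  idx <- seq(1L, n_vec, by = stride)
  fracs <- numeric(0)
  for (d in seq_len(max_dim)) {
    f <- fnn_fraction(x, tau, d, r_tol, a_tol, theiler = tau, idx = idx)
    fracs[d] <- f
    if (f < fnn_threshold) {
      return(structure(as.integer(d), fnn = fracs))
    }
  }
  warnf("FNN fraction never fell below %.2g up to d = %d", fnn_threshold, max_dim)
  structure(as.integer(max_dim), fnn = fracs)
}

#' Average embedding parameters across trials
#'
#' Per-trial delays and dimensions are averaged across the walking trials of
#' a subject and rounded half-up to integers, so one common (tau, d) is used
#' for all of that subject's reconstructions.
#'
#' @param taus Integer vector of per-trial delays (samples).
#' @param dims Integer vector of per-trial dimensions.
#' @return List with integer `tau_samples` and `dim`.
#' @export
average_embedding_params <- function(taus, dims) {
  list(tau_samples = as.integer(round_half_up(mean(as.numeric(taus)))),
       dim = as.integer(round_half_up(mean(as.numeric(dims)))))
}

#' Time-delay embedding
#'
#' Builds the delayed-coordinate matrix with vector
#' `i = [x(i), x(i+tau), ..., x(i+(m-1)tau)]`; each vector is stamped with
#' the time of its first coordinate.
#'
#' @param signal A [com_signal()].
#' @param tau Delay in samples (>= 1).
#' @param m Embedding dimension (>= 1).
#' @return Object of class `state_trajectory`: list with `vectors`
#'   (N x m matrix, N = length(x) - (m-1) tau), `t`, `m`, `tau`, `fs`.
#' @export
embed_delay <- function(signal, tau, m) {
  tau <- as.integer(tau); m <- as.integer(m)
  if (tau < 1L || m < 1L) stopf("tau and m must be positive integers")
  n <- length(signal$x) - (m - 1L) * tau
  if (n < 1L) stopf("signal too short to embed at tau = %d, m = %d", tau, m)
  vectors <- vapply(0:(m - 1L), function(k) signal$x[seq_len(n) + k * tau],
                    numeric(n))
  if (n == 1L) vectors <- matrix(vectors, nrow = 1)
  structure(list(vectors = vectors, t = signal$t[seq_len(n)], m = m,
                 tau = tau, fs = signal$fs, trial = signal$trial),
            class = "state_trajectory")
}
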