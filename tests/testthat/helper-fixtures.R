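# Fixtures built in code: small marker traces, COM signals and label
# sequences with known structure.

fs_default <- 100

# foot trace with stance windows starting at known heel-strike times:
# quadratic stance (minimum exactly at the heel strike), sinusoidal swing
make_foot <- function(hs_times, duration, fs = fs_default, stance = 0.7,
                      z0 = 40, h_st = 6, a_sw = 50) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  z <- rep(z0 + h_st, length(t))
  stride <- diff(hs_times)
  hs_ext <- c(hs_times[1] - median(stride), hs_times,
              hs_times[length(hs_times)] + median(stride))
  for (i in seq_len(length(hs_ext) - 1L)) {
    t_to <- hs_ext[i] + stance * (hs_ext[i + 1L] - hs_ext[i])
    st <- t >= hs_ext[i] & t < t_to
    z[st] <- z0 + h_st * ((t[st] - hs_ext[i]) / (t_to - hs_ext[i]))^2
    sw <- t >= t_to & t < hs_ext[i + 1L]
    s <- (t[sw] - t_to) / (hs_ext[i + 1L] - t_to)
    z[sw] <- z0 + h_st * (1 - s) + a_sw * sin(pi * s)
  }
  list(heel = marker_trace("heel", t, cbind(0, -60, z), fs),
       toe = marker_trace("toe", t, cbind(0, 90, z), fs))
}

# pure sine COM signal
make_sine_com <- function(period, duration, fs = fs_default, amp = 10,
                          trial = "BW1") {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  com_signal(t, amp * sin(2 * pi * t / period), fs, trial)
}

# deviation series with an explicit label schedule; D defaults to a smooth
# bump peaking where specified
make_dev_series <- function(duration, fs = fs_default,
                            excursions = list(), d_peak_t = NULL,
                            d_peak = 30) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  label <- rep("T1", length(t))
  for (e in excursions) {
    label[t >= e[1] & t < e[2]] <- "OUT"
  }
  D <- rep(1, length(t))
  if (!is.null(d_peak_t)) {
    D <- 1 + (d_peak - 1) * exp(-((t - d_peak_t) / 0.8)^2)
  }
  out <- data.frame(t = t, D = D,
                    label = factor(label, levels = c("T1", "T2", "T3", "OUT")),
                    theta = rep(0, length(t)))
  attr(out, "fs") <- fs
  class(out) <- c("deviation_series", "data.frame")
  out
}

# independent AMI oracle: equal-width bins via cut() + table() joint
# histogram
ami_oracle <- function(x, max_lag) {
  n <- length(x)
  nb <- ceiling(n^(1 / 3))
  b <- as.integer(cut(x, breaks = seq(min(x) - 1e-12, max(x) + 1e-12,
                                      length.out = nb + 1),
                      include.lowest = TRUE))
  vapply(seq_len(max_lag), function(l) {
    m <- n - l
    jt <- table(factor(b[1:m], levels = 1:nb),
                factor(b[(1 + l):(m + l)], levels = 1:nb)) / m
    pa <- rowSums(jt); pb <- colSums(jt)
    nz <- jt > 0
    sum(jt[nz] * log(jt[nz] / outer(pa, pb)[nz]))
  }, numeric(1))
}

first_local_min <- function(v) {
  for (k in 2:(length(v) - 1)) {
    if (v[k] < v[k - 1] && v[k] <= v[k + 1]) return(k)
  }
  NA_integer_
}
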