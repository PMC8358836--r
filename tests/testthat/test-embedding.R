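# Preprocessing, delay/dimension estimation and delay embedding.

test_that("preprocessing trims, filters and demeans", {
  t <- seq(0, 60 - 0.01, by = 0.01)
  const <- com_signal(t, rep(1000, length(t)), 100)
  pp <- preprocess_com(const)
  expect_true(all(abs(pp$x) < 1e-9))
  # the 5-s start trim leaves 55 s when no end trim is applied
  sig <- com_signal(t, sin(2 * pi * t), 100)
  pp2 <- preprocess_com(sig, trim_end = 0)
  expect_equal(length(pp2$x), 5500L)
  expect_lt(abs(mean(pp2$x)), 1e-9)
  # default also drops the trailing filter edge
  pp3 <- preprocess_com(sig)
  expect_equal(length(pp3$x), 5450L)
  expect_error(preprocess_com(com_signal(t[t < 5], sin(t[t < 5]), 100)),
               "at least 10 s")
})

test_that("a 10 Hz component is attenuated below 0.5% by the 5 Hz filter", {
  t <- seq(0, 60 - 0.01, by = 0.01)
  sig <- com_signal(t, 10 * sin(2 * pi * 10 * t), 100)
  pp <- preprocess_com(sig)
  # squared 4th-order Butterworth magnitude at twice the cutoff
  expect_lt(max(abs(pp$x)) / 10, 0.005)
  # sampling rate too close to the cutoff
  t10 <- seq(0, 59.9, by = 0.1)
  expect_error(preprocess_com(com_signal(t10, sin(t10), 10)), "too low")
})

test_that("AMI delay matches a brute-force oracle on a sine", {
  # a trace of measurement noise regularizes the joint histogram: an exactly
  # grid-periodic noiseless sine visits only 120 distinct states and its
  # binned AMI is degenerate
  set.seed(30)
  t <- seq(0, 60 - 0.01, by = 0.01)
  sig <- com_signal(t, 10 * sin(2 * pi * t / 1.2) + rnorm(length(t), 0, 1),
                    100)
  pp <- preprocess_com(sig)
  tau <- estimate_delay(pp)
  expect_lte(abs(as.integer(tau) - 30), 2)  # quarter period at 100 Hz
  # the AMI curve itself matches an independent implementation
  oracle <- ami_oracle(pp$x, 200)
  expect_equal(as.numeric(attr(tau, "ami")), oracle, tolerance = 1e-3)
})

test_that("white noise falls back to the autocorrelation rule with a warning", {
  set.seed(5)
  t <- seq(0, 40 - 0.01, by = 0.01)
  sig <- com_signal(t, rnorm(length(t)), 100)
  expect_warning(tau <- estimate_delay(sig), "autocorrelation")
  expect_true(as.integer(tau) >= 1)
})

test_that("delay on a quasi-periodic gait oscillation is near a fifth of the period", {
  # canonical minimal gait signal: step-locked sinusoid with step-time
  # variability and measurement noise
  m <- subject_model(waveform_warp = 0, amp_mod = 0, seed = 3)
  tr <- generate_trial(m, "BW", duration = 360)
  pp <- preprocess_com(tr$com)
  tau <- estimate_delay(pp)
  expect_gte(attr(tau, "tau_s"), 0.15)
  expect_lte(attr(tau, "tau_s"), 0.35)
})

test_that("false nearest neighbours finds d = 2 for a sine and caps on noise", {
  # period incommensurate with the sampling grid: generic sampling of the
  # limit cycle, no exact state repeats
  sig <- make_sine_com(period = 1.23456789, duration = 60)
  pp <- preprocess_com(sig)
  d <- estimate_dimension(pp, tau = 30)
  expect_equal(as.integer(d), 2L)
  set.seed(9)
  t <- seq(0, 60 - 0.01, by = 0.01)
  noise <- com_signal(t, rnorm(length(t)), 100)
  expect_warning(dn <- estimate_dimension(noise, tau = 10, max_dim = 6),
                 "never fell below")
  expect_equal(as.integer(dn), 6L)
})

test_that("FNN agrees with a brute-force oracle on a small signal", {
  sig <- make_sine_com(period = 1.23456789, duration = 30)
  pp <- preprocess_com(sig, trim_end = 0)
  x <- pp$x
  tau <- 30L
  n_max <- 200L
  fnn_naive <- function(d) {
    nv <- length(x) - d * tau
    stride <- max(1L, floor((length(x) - tau) / n_max))
    ii <- seq(1L, length(x) - tau, by = stride)
    ii <- ii[ii <= nv]
    emb <- sapply(0:(d - 1), function(k) x[ii + k * tau])
    if (d == 1) emb <- matrix(emb, ncol = 1)
    nfalse <- 0; ntot <- 0
    for (a in seq_along(ii)) {
      best <- Inf; bi <- NA
      for (b in seq_along(ii)) {
        if (abs(ii[a] - ii[b]) <= tau) next
        dd <- sum((emb[a, ] - emb[b, ])^2)
        if (dd < best) { best <- dd; bi <- b }
      }
      if (!is.finite(best)) next
      extra <- abs(x[ii[a] + d * tau] - x[ii[bi] + d * tau])
      ntot <- ntot + 1
      if ((sqrt(best) > 1e-6 * sd(x) && extra / sqrt(best) > 15) ||
          sqrt(best + extra^2) / sd(x) > 2) nfalse <- nfalse + 1
    }
    nfalse / ntot
  }
  d_oracle <- NA
  for (d in 1:5) if (fnn_naive(d) < 0.01) { d_oracle <- d; break }
  d_est <- estimate_dimension(pp, tau = tau, n_max = n_max)
  expect_equal(as.integer(d_est), d_oracle)
  expect_equal(d_oracle, 2L)
})

test_that("delay embedding has the right shape and algebraic properties", {
  t <- seq(0, 10 - 0.01, by = 0.01)
  sig <- com_signal(t, sin(2 * pi * t / 1.2), 100)
  emb <- embed_delay(sig, tau = 20, m = 3)
  expect_equal(nrow(emb$vectors), 1000L - 2L * 20L)
  expect_equal(ncol(emb$vectors), 3L)
  # m = 1 is the identity
  emb1 <- embed_delay(sig, tau = 20, m = 1)
  expect_equal(as.numeric(emb1$vectors), sig$x)
  # linearity in the signal
  sig2 <- com_signal(t, 3.5 * sig$x, 100)
  expect_equal(embed_delay(sig2, 20, 3)$vectors, 3.5 * emb$vectors)
  # sine embedded at quarter period lies on a circle
  embq <- embed_delay(sig, tau = 30, m = 2)
  r <- sqrt(rowSums(embq$vectors^2))
  expect_lt(diff(range(r)) / mean(r), 1e-6)
  expect_error(embed_delay(sig, tau = 600, m = 3), "too short")
})

test_that("embedding parameters average across trials with half-up rounding", {
  avg <- average_embedding_params(c(15L, 16L, 16L), c(4L, 4L, 3L))
  expect_equal(avg$tau_samples, 16L)   # 15.67 -> 16
  expect_equal(avg$dim, 4L)            # 3.67 -> 4
  expect_equal(average_embedding_params(c(15L, 16L), c(3L, 4L))$tau_samples,
               16L)                    # 15.5 rounds half-up
})
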