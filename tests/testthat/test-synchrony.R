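# Footfall-beat asynchrony and synchrony recovery.

make_asyn <- function(asyn, step_time = 0.6) {
  out <- data.frame(step_index = seq_along(asyn),
                    t = cumsum(rep(step_time, length(asyn))),
                    asyn = asyn)
  class(out) <- c("asynchrony_series", "data.frame")
  out
}

test_that("asynchrony is the signed step-time departure from the beat interval", {
  steps <- data.frame(onset = c(0, 0.6, 1.2), step_time = c(0.6, 0.86, 0.6),
                      side = c("left", "right", "left"),
                      gap = c(FALSE, FALSE, FALSE))
  class(steps) <- c("step_series", "data.frame")
  a <- compute_asynchrony(steps, base_ibi = 0.6)
  expect_equal(a$asyn, c(0, 0.26, 0))
  # gap steps are dropped
  steps$gap[1] <- TRUE
  expect_equal(nrow(compute_asynchrony(steps, 0.6)), 2L)
})

test_that("eight 3-step windows tile a 10-step in-band run", {
  # zero asynchrony throughout: the first evaluable window qualifies and
  # the required run spans exactly 10 steps
  set.seed(1)
  a <- make_asyn(rnorm(60, 0, 1e-4))
  s <- synchrony_recovery(a, perturb_step = 20)
  expect_true(s$synchronized)
  # windows advance one step: 8 consecutive 3-step windows cover 10 steps
  expect_equal(8 + 3 - 1, 10)
  expect_equal(s$recovery_step, s$peak_step + 1L)
  # not enough steps after the perturbation
  expect_error(synchrony_recovery(make_asyn(rnorm(25, 0, 1e-4)), 20),
               "too few")
  expect_error(synchrony_recovery(a, perturb_step = 5), "before")
})

test_that("geometric decay recovery matches an exhaustive window scan", {
  set.seed(2)
  pre <- rnorm(15, 0, 0.01)
  post <- 0.16 * 0.5^(0:39)
  a <- make_asyn(c(pre, post))
  s <- synchrony_recovery(a, perturb_step = 16)
  # brute-force oracle over all windows from the peak
  band <- c(mean(pre[6:15]) - 2 * sd(pre[6:15]),
            mean(pre[6:15]) + 2 * sd(pre[6:15]))
  x <- c(pre, post)
  peak <- 15 + which.max(abs(post))
  wins <- vapply(peak:(length(x) - 2), function(i) mean(x[i:(i + 2)]),
                 numeric(1))
  inb <- wins >= band[1] & wins <= band[2]
  first <- NA
  for (i in seq_len(length(inb) - 7)) {
    if (all(inb[i:(i + 7)])) { first <- i; break }
  }
  expect_equal(s$recovery_step, peak + first - 1L + 1L)
  expect_equal(s$peak_step, peak)
  expect_equal(s$peak_adjustment, 0.16, tolerance = 1e-12)
})

test_that("recovery step is invariant to rescaling the asynchronies", {
  set.seed(3)
  pre <- rnorm(15, 0, 0.01)
  post <- 0.2 * 0.6^(0:39) + rnorm(40, 0, 0.005)
  a1 <- make_asyn(c(pre, post))
  a2 <- a1; a2$asyn <- 7 * a1$asyn
  s1 <- synchrony_recovery(a1, 16)
  s2 <- synchrony_recovery(a2, 16)
  expect_equal(s1$recovery_step, s2$recovery_step)
  expect_equal(s2$peak_adjustment, 7 * s1$peak_adjustment)
})

test_that("first-order correction recovers within two steps of the analytic step", {
  set.seed(4)
  for (alpha in c(0.2, 0.35, 0.5, 0.65, 0.8)) {
    peak <- 0.18
    pre <- rnorm(15, 0, 0.008)
    post <- peak * (1 - alpha)^(0:59) + rnorm(60, 0, 0.002)
    a <- make_asyn(c(pre, post))
    s <- synchrony_recovery(a, 16)
    expect_true(s$synchronized)
    # prediction evaluated at the operative band (2 SD of the 10 steps
    # preceding the perturbation)
    band <- 2 * sd(pre[6:15])
    n_pred <- predict_recovery_steps(peak, alpha, band)
    expect_lte(abs((s$recovery_step - s$peak_step) - n_pred), 2)
  }
})

test_that("pure noise shows no measurable adjustment", {
  set.seed(5)
  a <- make_asyn(rnorm(320, 0, 0.013))
  s <- synchrony_recovery(a, perturb_step = 150)
  expect_false(s$adjusted)
  # a genuine adjustment is flagged
  b <- make_asyn(c(rnorm(20, 0, 0.013), 0.2 * 0.6^(0:49),
                   rnorm(30, 0, 0.013)))
  expect_true(synchrony_recovery(b, 21)$adjusted)
})
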