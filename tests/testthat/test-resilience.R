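# Resilience parameters, phase segmentation and occupancy.

test_that("lag, peak and recovery follow a constructed excursion", {
  dev <- make_dev_series(duration = 25, excursions = list(c(10, 12)),
                         d_peak_t = 11)
  r <- compute_resilience(dev, perturb_onset = 9, cycle_duration = 1.2)
  expect_true(r$deviated)
  expect_equal(r$lag_time, 1.0, tolerance = 0.011)
  expect_equal(r$peak_time, 1.0, tolerance = 0.011)
  expect_equal(r$peak_magnitude, 30, tolerance = 0.01)
  expect_equal(r$com_recovery_time, 1.0, tolerance = 0.011)
  # absolute times are ordered
  expect_true(r$t_exit <= r$t_peak && r$t_peak <= r$t_recovery)
})

test_that("up to four one-sample outliers do not delay recovery", {
  dev <- make_dev_series(duration = 25, excursions = list(c(10, 12)),
                         d_peak_t = 11)
  base <- compute_resilience(dev, 9, 1.2)
  # inject four single-sample excursions inside the 5-cycle window after 12 s
  dev2 <- dev
  for (tt in c(13.0, 14.0, 15.0, 16.0)) {
    dev2$label[which.min(abs(dev2$t - tt))] <- "OUT"
  }
  r2 <- compute_resilience(dev2, 9, 1.2)
  expect_equal(r2$t_recovery, base$t_recovery)
  # a fifth outlier pushes the recovery point past it
  dev3 <- dev2
  dev3$label[which.min(abs(dev3$t - 17.0))] <- "OUT"
  r3 <- compute_resilience(dev3, 9, 1.2)
  expect_gt(r3$t_recovery, base$t_recovery)
})

test_that("a trajectory that never leaves the torus is not deviated", {
  dev <- make_dev_series(duration = 25)
  r <- compute_resilience(dev, 9, 1.2)
  expect_false(r$deviated)
  expect_true(is.na(r$lag_time) && is.na(r$peak_magnitude))
  # sub-threshold excursions (shorter than 0.1 s) do not count
  dev2 <- make_dev_series(duration = 25, excursions = list(c(10, 10.05)))
  expect_false(compute_resilience(dev2, 9, 1.2)$deviated)
})

test_that("an unrecovered trial warns and reports a missing recovery", {
  dev <- make_dev_series(duration = 16, excursions = list(c(10, 15.99)),
                         d_peak_t = 11)
  expect_warning(r <- compute_resilience(dev, 9, 1.2), "unrecovered")
  expect_true(r$deviated)
  expect_true(is.na(r$t_recovery) && is.na(r$com_recovery_time))
})

test_that("earlier perturbation onset lengthens the lag by the same amount", {
  dev <- make_dev_series(duration = 30, excursions = list(c(10, 12)),
                         d_peak_t = 11)
  r1 <- compute_resilience(dev, 9, 1.2)
  r2 <- compute_resilience(dev, 7.5, 1.2)
  expect_equal(r2$lag_time - r1$lag_time, 1.5, tolerance = 1e-9)
  # peak magnitude bounds the deviation at exit and recovery
  i_exit <- which.min(abs(dev$t - r1$t_exit))
  i_rec <- which.min(abs(dev$t - r1$t_recovery))
  expect_gte(r1$peak_magnitude, dev$D[i_exit])
  expect_gte(r1$peak_magnitude, dev$D[i_rec])
})

test_that("phases tile the trial exactly", {
  ph <- segment_phases(c(0, 360), 180, 192)
  expect_equal(ph$CW1, c(0, 180))
  expect_equal(ph$CW2, c(180, 192))
  expect_equal(ph$CW3, c(192, 360))
  lens <- vapply(ph, diff, numeric(1))
  expect_equal(sum(lens), 360)
  # degenerate: onset == recovery
  ph2 <- segment_phases(c(0, 360), 180, 180)
  expect_equal(diff(ph2$CW2), 0)
  # missing recovery: CW3 empty with a warning
  expect_warning(ph3 <- segment_phases(c(0, 360), 180, NA), "CW3")
  expect_equal(diff(ph3$CW3), 0)
  expect_error(segment_phases(c(0, 100), 180, NA), "outside")
})

test_that("occupancy percentages are exact and sum to 100", {
  dev <- make_dev_series(duration = 10)
  occ <- occupancy(dev, c(0, 10))
  expect_equal(unname(occ), c(100, 0, 0, 0))
  # equal quarters by construction
  n <- nrow(dev)
  dev$label <- factor(rep(c("T1", "T2", "T3", "OUT"), each = n / 4),
                      levels = levels(dev$label))
  occ2 <- occupancy(dev, c(0, 10))
  expect_equal(unname(occ2), c(25, 25, 25, 25))
  expect_equal(sum(occ2), 100, tolerance = 1e-6)
  expect_error(occupancy(dev, c(20, 30)), "empty window")
})
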