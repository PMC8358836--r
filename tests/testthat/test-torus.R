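# Reference trajectory fitting, torus construction and classification.

# helper: noisy circular loop in dims (1, 2), constant dim 3
make_circle_traj <- function(n = 2000, r = 10, noise = 0, seed = 1,
                             equispaced = FALSE) {
  set.seed(seed)
  th <- if (equispaced) 2 * pi * (seq_len(n) - 1) / n else runif(n, 0, 2 * pi)
  V <- cbind(r * cos(th) + rnorm(n, 0, noise),
             r * sin(th) + rnorm(n, 0, noise),
             5 + rnorm(n, 0, noise))
  structure(list(vectors = V, t = seq_len(n) / 100, m = 3L, tau = 15L,
                 fs = 100, trial = "BW1"),
            class = "state_trajectory")
}

test_that("the Fourier reference reproduces an exact circle", {
  # equispaced angles: the point set is exactly symmetric about the centre
  traj <- make_circle_traj(noise = 0, equispaced = TRUE)
  ref <- fit_reference(traj)
  expect_equal(unname(ref$centroid), c(0, 0, 5), tolerance = 1e-6)
  th <- ref$degrees * pi / 180
  expect_lt(sqrt(mean((ref$M[, 1] - 10 * cos(th))^2)), 1e-6 * 10)
  expect_lt(sqrt(mean((ref$M[, 2] - 10 * sin(th))^2)), 1e-6 * 10)
  expect_lt(sqrt(mean((ref$M[, 3] - 5)^2)), 1e-6 * 10)
})

test_that("Fourier coefficients of a known curve are recovered by least squares", {
  set.seed(2)
  n_terms <- 8
  coefs <- matrix(rnorm(3 * (2 * n_terms + 1), sd = 2), ncol = 3)
  # dominant first harmonic in dims 1-2 so angles sweep the full circle
  coefs[1, ] <- c(0, 0, 3)
  coefs[2, 1] <- 30; coefs[2, 2] <- 0
  coefs[n_terms + 2, 1] <- 0; coefs[n_terms + 2, 2] <- 30
  th <- runif(3000, 0, 2 * pi) * 180 / pi
  V <- eval_reference(coefs, th)
  traj <- structure(list(vectors = V, t = seq_len(3000) / 100, m = 3L,
                         tau = 15L, fs = 100, trial = "BW1"),
                    class = "state_trajectory")
  ref <- fit_reference(traj)
  # independent oracle: normal-equations least squares on the same angles
  theta_data <- atan2(V[, 2] - ref$centroid[2],
                      V[, 1] - ref$centroid[1]) * 180 / pi %% 360
  X <- cbind(1, sapply(1:8, function(k) cos(k * theta_data * pi / 180)),
             sapply(1:8, function(k) sin(k * theta_data * pi / 180)))
  oracle <- solve(crossprod(X), crossprod(X, V))
  expect_equal(unname(ref$coeffs), unname(oracle), tolerance = 1e-6)
})

test_that("a trajectory that does not encircle the centroid is rejected", {
  set.seed(3)
  th <- runif(1000, 0, pi / 2)  # quarter arc only
  V <- cbind(10 * cos(th), 10 * sin(th), 0) + 20
  traj <- structure(list(vectors = V, t = seq_len(1000) / 100, m = 3L,
                         tau = 15L, fs = 100, trial = "BW1"),
                    class = "state_trajectory")
  expect_error(fit_reference(traj), "encircle")
})

test_that("isotropic scatter around a circle gives near-equal ellipse axes", {
  sigma <- 0.8
  traj <- make_circle_traj(n = 40000, r = 20, noise = sigma, seed = 4)
  ref <- fit_reference(traj)
  tor <- build_tori(traj, ref)
  # Monte-Carlo tolerance on a 50-point SD is generous
  expect_lt(max(abs(tor$a - sigma)) / sigma, 0.6)
  expect_gt(mean(tor$a), 0.8 * sigma)
  expect_lt(abs(median(tor$a) - sigma) / sigma, 0.2)
  expect_lt(abs(median(tor$b) - sigma) / sigma, 0.2)
  expect_true(all(tor$a >= tor$b))
  # axes are unit length and orthogonal
  expect_equal(rowSums(tor$u^2), rep(1, 360), tolerance = 1e-9)
  expect_equal(rowSums(tor$w^2), rep(1, 360), tolerance = 1e-9)
  expect_lt(max(abs(rowSums(tor$u * tor$w))), 1e-9)
})

test_that("axis lengths follow the two-largest-SD rule", {
  traj <- make_circle_traj(n = 20000, r = 50, noise = 0.5, seed = 5)
  ref <- fit_reference(traj)
  tor <- build_tori(traj, ref)
  # independent check at a few angles: recompute the neighbourhood SDs
  V <- traj$vectors
  th <- atan2(V[, 2] - ref$centroid[2], V[, 1] - ref$centroid[1]) * 180 / pi
  th <- th %% 360
  for (deg in c(0, 90, 201)) {
    d <- abs(((th - deg + 180) %% 360) - 180)
    sel <- order(d)[1:50]
    sds <- sort(sqrt(colMeans(sweep(V[sel, ], 2, ref$M[deg + 1, ])^2)),
                decreasing = TRUE)
    expect_equal(tor$a[deg + 1], sds[1], tolerance = 1e-9)
    expect_equal(tor$b[deg + 1], sds[2], tolerance = 1e-9)
  }
})

test_that("classification labels match membership algebra and nest", {
  traj <- make_circle_traj(n = 5000, r = 15, noise = 0.5, seed = 6)
  ref <- fit_reference(traj)
  tor <- build_tori(traj, ref)
  # a point exactly on the reference
  pt <- structure(list(vectors = ref$M[91, , drop = FALSE], t = 0, m = 3L,
                       tau = 15L, fs = 100, trial = "CW"),
                  class = "state_trajectory")
  dev <- classify_trajectory(tor, pt)
  expect_equal(as.character(dev$label), "T1")
  expect_lt(dev$D, 0.05)  # curve sampled at one-degree resolution
  # offset 1.5a along u -> inside T2 but not T1
  v2 <- ref$M[91, ] + 1.5 * tor$a[91] * tor$u[91, ]
  pt2 <- structure(list(vectors = matrix(v2, 1), t = 0, m = 3L, tau = 15L,
                        fs = 100, trial = "CW"),
                   class = "state_trajectory")
  expect_equal(as.character(classify_trajectory(tor, pt2)$label), "T2")
  # far away -> OUT
  v3 <- ref$M[91, ] + 10 * tor$a[91] * tor$u[91, ]
  pt3 <- structure(list(vectors = matrix(v3, 1), t = 0, m = 3L, tau = 15L,
                        fs = 100, trial = "CW"),
                   class = "state_trajectory")
  expect_equal(as.character(classify_trajectory(tor, pt3)$label), "OUT")
})

test_that("labels agree with an exhaustive per-point membership oracle", {
  traj <- make_circle_traj(n = 3000, r = 15, noise = 1, seed = 7)
  ref <- fit_reference(traj)
  tor <- build_tori(traj, ref)
  set.seed(8)
  cloud <- traj$vectors[sample(3000, 300), ] +
    matrix(rnorm(900, 0, 1.5), ncol = 3)
  ctraj <- structure(list(vectors = cloud, t = seq_len(300) / 100, m = 3L,
                          tau = 15L, fs = 100, trial = "CW"),
                     class = "state_trajectory")
  dev <- classify_trajectory(tor, ctraj)
  # naive oracle: recompute angle, ellipse coordinates and membership per point
  for (i in seq_len(nrow(cloud))) {
    v <- cloud[i, ]
    ang <- atan2(v[2] - ref$centroid[2], v[1] - ref$centroid[1]) * 180 / pi
    ang <- ang %% 360
    deg <- floor(ang + 0.5) %% 360
    off <- v - ref$M[deg + 1, ]
    p <- sum(off * tor$u[deg + 1, ]); q <- sum(off * tor$w[deg + 1, ])
    lab <- "OUT"
    for (k in 3:1) {
      if ((p / (k * tor$a[deg + 1]))^2 + (q / (k * tor$b[deg + 1]))^2 <= 1) {
        lab <- paste0("T", k)
      }
    }
    expect_equal(as.character(dev$label[i]), lab)
  }
  # nesting: every T1 point passes the T2 and T3 membership tests
  i1 <- which(dev$label == "T1")
  deg <- (floor(dev$theta + 0.5) %% 360) + 1
  off <- cloud - ref$M[deg, , drop = FALSE]
  p <- rowSums(off * tor$u[deg, , drop = FALSE])
  q <- rowSums(off * tor$w[deg, , drop = FALSE])
  for (k in 2:3) {
    expect_true(all((p[i1] / (k * tor$a[deg[i1]]))^2 +
                      (q[i1] / (k * tor$b[deg[i1]]))^2 <= 1))
  }
})

test_that("deviation is invariant under rigid translation of data and model", {
  traj <- make_circle_traj(n = 3000, r = 12, noise = 0.6, seed = 9)
  shift <- c(100, -50, 30)
  traj2 <- traj
  traj2$vectors <- sweep(traj$vectors, 2, -shift)
  ref1 <- fit_reference(traj); tor1 <- build_tori(traj, ref1)
  ref2 <- fit_reference(traj2); tor2 <- build_tori(traj2, ref2)
  d1 <- classify_trajectory(tor1, traj)
  d2 <- classify_trajectory(tor2, traj2)
  expect_equal(d1$D, d2$D, tolerance = 1e-6)
  expect_equal(as.character(d1$label), as.character(d2$label))
})

test_that("baseline walking classifies mostly inside its own 1-sigma torus", {
  m <- subject_model(seed = 12)
  tr <- generate_trial(m, "BW", duration = 240)
  pp <- preprocess_com(tr$com)
  tau <- estimate_delay(pp)
  emb <- embed_delay(pp, tau, 3)
  ref <- fit_reference(emb)
  tor <- build_tori(emb, ref)
  dev <- classify_trajectory(tor, emb)
  occ <- 100 * table(dev$label) / nrow(dev)
  expect_gte(unname(occ["T1"]), 60)
  # nesting of cumulative counts
  expect_true(occ["T1"] <= occ["T1"] + occ["T2"])
})

test_that("torus models serialize losslessly to JSON", {
  traj <- make_circle_traj(n = 2000, r = 15, noise = 0.7, seed = 10)
  ref <- fit_reference(traj)
  tor <- build_tori(traj, ref)
  path <- tempfile(fileext = ".json")
  write_torus(tor, path)
  tor2 <- read_torus(path)
  d1 <- classify_trajectory(tor, traj)
  d2 <- classify_trajectory(tor2, traj)
  expect_equal(d1$D, d2$D, tolerance = 1e-12)
  expect_identical(as.character(d1$label), as.character(d2$label))
  unlink(path)
})
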