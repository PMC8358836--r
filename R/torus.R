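# Steady-state boundary of cyclic COM motion in reduced (3D) state space.
#
# Baseline walking traces a closed loop in the embedded space. The loop is
# summarised by a reference trajectory M(theta): an 8-term Fourier series in
# the angle theta of each state-space vector about the centroid. Around M,
# one ellipse per integer degree captures the local spread of the baseline
# vectors; stacked over 0..359 degrees the ellipses form a torus. Scaling
# the ellipse axes by k = 1, 2, 3 gives the nested boundaries T_1s, T_2s,
# T_3s used to decide whether a later trajectory is still "at steady state".

# angle (degrees, [0, 360)) of each row of `vectors` about `centre`, using
# embedding coordinates 1 and 2 (four-quadrant inverse tangent)
vector_angles <- function(vectors, centre) {
  a <- atan2(vectors[, 2] - centre[2], vectors[, 1] - centre[1]) * 180 / pi
  a %% 360
}

fourier_design <- function(theta_deg, n_terms = 8) {
  th <- theta_deg * pi / 180
  cbind(1, vapply(seq_len(n_terms), function(k) cos(k * th),
                  numeric(length(th))),
        vapply(seq_len(n_terms), function(k) sin(k * th), numeric(length(th))))
}

#' Evaluate a fitted Fourier reference curve
#'
#' @param coeffs Coefficient matrix `(2*n_terms + 1) x 3` from
#'   [fit_reference()].
#' @param theta_deg Angles in degrees.
#' @return Matrix `length(theta_deg) x 3` (mm).
#' @export
eval_reference <- function(coeffs, theta_deg) {
  n_terms <- (nrow(coeffs) - 1L) %/% 2L
  fourier_design(theta_deg, n_terms) %*% coeffs
}

# analytic tangent dM/dtheta of the Fourier curve, rows normalised
reference_tangent <- function(coeffs, theta_deg) {
  n_terms <- (nrow(coeffs) - 1L) %/% 2L
  th <- theta_deg * pi / 180
  dcos <- vapply(seq_len(n_terms), function(k) -k * sin(k * th),
                 numeric(length(th)))
  dsin <- vapply(seq_len(n_terms), function(k) k * cos(k * th),
                 numeric(length(th)))
  d <- cbind(0, dcos, dsin) %*% coeffs
  nrm <- sqrt(rowSums(d^2))
  nrm[nrm == 0] <- 1
  d / nrm
}

#' Fit the reference trajectory of a 3D state-space loop
#'
#' The centroid is the per-dimension mean of the state-space vectors. Each
#' vector's angle about the centroid (four-quadrant inverse tangent on
#' embedding coordinates 1 and 2) parameterises the loop; an 8-term Fourier
#' series in that angle is fit per dimension by least squares, and evaluated
#' at integer degrees 0..359 to give the reference curve M.
#'
#' @param traj A `state_trajectory` with `m = 3` and at least 500 vectors.
#' @param n_terms Number of Fourier harmonics (default 8).
#' @return Object of class `reference_trajectory`: `centroid` (3-vector),
#'   `coeffs` (`(2*n_terms+1) x 3`), `M` (360 x 3, rows = integer degrees),
#'   `degrees` (0:359), `n_terms`.
#' @export
fit_reference <- function(traj, n_terms = 8) {
  if (traj$m != 3L) stopf("reference fitting requires a 3-dimensional embedding")
  V <- traj$vectors
  if (nrow(V) < 500L) stopf("need at least 500 state-space vectors")
  centroid <- colMeans(V)
  theta <- vector_angles(V, centroid)
  if (length(unique(floor(theta))) < 300L) {
    stopf("trajectory does not encircle centroid (angular coverage < 300 degrees)")
  }
  X <- fourier_design(theta, n_terms)
  coeffs <- qr.coef(qr(X), V)
  degrees <- 0:359
  M <- eval_reference(coeffs, degrees)
  structure(list(centroid = centroid, coeffs = coeffs, M = M,
                 degrees = degrees, n_terms = n_terms),
            class = "reference_trajectory")
}

#' Build the nested steady-state tori around a reference trajectory
#'
#' For each integer degree theta, the `n_neighbors` state-space vectors
#' nearest in circular angular distance to theta define a cross-section
#' ellipse: the semi-major axis `a(theta)` is the largest of the three
#' per-coordinate standard deviations of those vectors (about `M(theta)` by
#' default), the semi-minor axis `b(theta)` the second largest. The axis
#' directions are the principal axes of the neighbourhood scatter within
#' the plane normal to the local tangent of M, so each cross-section is
#' transverse to the curve and oriented along the local spread. The k-sigma
#' tori share axes scaled by k.
#'
#' @param traj The `state_trajectory` the reference was fitted from.
#' @param ref The [fit_reference()] result.
#' @param n_neighbors Number of nearest vectors per degree (default 50).
#' @param k_levels Scale multipliers of the nested tori (default `c(1, 2, 3)`).
#' @param sd_about `"reference"` (default) computes neighbourhood SDs about
#'   `M(theta)`; `"neighborhood"` about the neighbourhood mean.
#' @return Object of class `torus_model`: `ref`, `a`, `b` (length-360, mm),
#'   `u`, `w` (360 x 3 unit axis directions), `k_levels`, `n_neighbors`.
#' @export
build_tori <- function(traj, ref, n_neighbors = 50, k_levels = c(1, 2, 3),
                       sd_about = c("reference", "neighborhood")) {
  sd_about <- match.arg(sd_about)
  V <- traj$vectors
  n <- nrow(V)
  if (n < n_neighbors) stopf("need at least %d state-space vectors", n_neighbors)
  theta <- vector_angles(V, ref$centroid)
  ord <- order(theta)
  th_sorted <- theta[ord]
  tang <- reference_tangent(ref$coeffs, ref$degrees)
  a <- b <- numeric(360)
  u <- w <- matrix(0, 360, 3)
  # candidate window in the angle-sorted order: the nearest-by-angle
  # neighbours are contiguous there, take a margin for safety
  half_win <- min(n, max(2L * n_neighbors, 60L))
  for (i in seq_len(360)) {
    deg <- ref$degrees[i]
    p <- findInterval(deg, th_sorted)
    cand <- ((p - half_win):(p + half_win - 1L)) %% n + 1L
    cand <- unique(cand)
    dist <- abs(((th_sorted[cand] - deg + 180) %% 360) - 180)
    sel <- ord[cand[order(dist)[seq_len(n_neighbors)]]]
    centre <- if (sd_about == "reference") ref$M[i, ] else colMeans(V[sel, , drop = FALSE])
    dev <- sweep(V[sel, , drop = FALSE], 2, centre)
    sds <- sqrt(colMeans(dev^2))
    if (any(sds == 0)) stopf("degenerate data: zero neighbourhood SD at %d degrees", deg)
    ordsd <- order(sds, decreasing = TRUE)
    a[i] <- sds[ordsd[1]]
    b[i] <- sds[ordsd[2]]
    # orient the cross-section along the principal axes of the transverse
    # neighbourhood scatter (tangential component projected out)
    tg <- tang[i, ]
    proj <- diag(3) - tcrossprod(tg)
    dt <- dev %*% proj
    ev <- eigen(crossprod(dt) / nrow(dt), symmetric = TRUE)
    u[i, ] <- ev$vectors[, 1]
    w[i, ] <- ev$vectors[, 2]
  }
  structure(list(ref = ref, a = a, b = b, u = u, w = w,
                 k_levels = sort(k_levels), n_neighbors = n_neighbors,
                 sd_about = sd_about),
            class = "torus_model")
}

#' Classify a trajectory against the steady-state tori
#'
#' Each state-space vector gets the angle of the fitting rule, is compared
#' with the cross-section ellipse at its (rounded) degree, and is labelled
#' with the smallest torus `T_k` that encloses it (in-plane ellipse test
#' `(p/(k a))^2 + (q/(k b))^2 <= 1`), or `OUT`. The deviation `D(t)` is the
#' 3D Euclidean distance to the nearest point of the reference curve `M`
#' (evaluated at integer degrees); for points near the curve this coincides
#' with the distance at the vector's own angle, but it remains well-behaved
#' for large excursions past strongly curved sectors of the loop.
#'
#' @param model A [build_tori()] result.
#' @param traj A `state_trajectory` with `m = 3`.
#' @return Object of class `deviation_series`: data.frame with columns `t`
#'   (s), `D` (mm), `label` (factor `T1 < T2 < T3 < OUT`), `theta` (deg).
#'   Attributes `fs`, `trial`.
#' @export
classify_trajectory <- function(model, traj) {
  if (traj$m != 3L) stopf("classification requires a 3-dimensional embedding")
  V <- traj$vectors
  ref <- model$ref
  theta <- vector_angles(V, ref$centroid)
  deg <- as.integer(round_half_up(theta)) %% 360L
  i <- deg + 1L
  offset <- V - ref$M[i, , drop = FALSE]
  # deviation: distance to the nearest point of the reference curve
  d2min <- rep(Inf, nrow(V))
  for (k in seq_len(nrow(ref$M))) {
    d2 <- (V[, 1] - ref$M[k, 1])^2 + (V[, 2] - ref$M[k, 2])^2 +
      (V[, 3] - ref$M[k, 3])^2
    smaller <- d2 < d2min
    d2min[smaller] <- d2[smaller]
  }
  D <- sqrt(d2min)
  p <- rowSums(offset * model$u[i, , drop = FALSE])
  q <- rowSums(offset * model$w[i, , drop = FALSE])
  ks <- model$k_levels
  label <- rep("OUT", nrow(V))
  for (k in rev(seq_along(ks))) {
    inside <- (p / (ks[k] * model$a[i]))^2 + (q / (ks[k] * model$b[i]))^2 <= 1
    label[inside] <- paste0("T", k)
  }
  out <- data.frame(
    t = traj$t, D = D,
    label = factor(label, levels = c(paste0("T", seq_along(ks)), "OUT")),
    theta = theta)
  attr(out, "fs") <- traj$fs
  attr(out, "trial") <- traj$trial
  class(out) <- c("deviation_series", "data.frame")
  out
}

#' Serialize / restore a torus model as JSON
#'
#' Stores the Fourier coefficients, centroid and per-degree ellipse axes in
#' a single structured text document so a model fitted on baseline walking
#' can be reused across trials.
#'
#' @param model A `torus_model`.
#' @param path JSON file path.
#' @return `write_torus`: invisibly, `path`. `read_torus`: a `torus_model`.
#' @export
write_torus <- function(model, path) {
  doc <- list(
    centroid = model$ref$centroid,
    n_terms = model$ref$n_terms,
    coeffs = model$ref$coeffs,
    a = model$a, b = model$b, u = model$u, w = model$w,
    k_levels = model$k_levels, n_neighbors = model$n_neighbors,
    sd_about = model$sd_about)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_torus
#' @export
read_torus <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  coeffs <- matrix(unlist(doc$coeffs), ncol = 3)
  degrees <- 0:359
  ref <- structure(list(centroid = as.numeric(doc$centroid), coeffs = coeffs,
                        M = eval_reference(coeffs, degrees), degrees = degrees,
                        n_terms = doc$n_terms),
                   class = "reference_trajectory")
  structure(list(ref = ref, a = as.numeric(doc$a), b = as.numeric(doc$b),
                 u = matrix(unlist(doc$u), ncol = 3),
                 w = matrix(unlist(doc$w), ncol = 3),
                 k_levels = as.numeric(doc$k_levels),
                 n_neighbors = doc$n_neighbors, sd_about = doc$sd_about),
            class = "torus_model")
}
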