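# Internal helpers shared across modules.

# round half away from zero (MATLAB-style), used when averaging integer
# sample delays across trials
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# draw from a normal truncated at +/- k standard deviations
rtruncnorm4 <- function(n, mean, sd, k = 4) {
  if (sd <= 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- abs(x - mean) > k * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > k * sd
  }
  x
}

# runs of TRUE in a logical vector: data.frame(start, end, length) in samples
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
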