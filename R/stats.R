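# Group-level estimation statistics: BCa bootstrap of a paired mean
# difference, and a one-way repeated-measures ANOVA used to check that the
# embedding parameters do not differ between walking trials.

#' Bootstrap mean difference of paired samples (BCa interval)
#'
#' Computes `mean(a - b)` and a bias-corrected-and-accelerated (BCa) 95%
#' bootstrap interval by resampling subjects, via the `boot` package.
#' Missing pairs are excluded listwise. Fully reproducible under `seed`.
#'
#' @param a,b Paired measurements (s), equal length >= 2.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List with `mean_diff`, `ci_lower`, `ci_upper`, `n`, `n_boot`,
#'   `conf`.
#' @export
bootstrap_mean_diff <- function(a, b, n_boot = 5000, seed = 1, conf = 0.95) {
  ok <- is.finite(a) & is.finite(b)
  d <- (a - b)[ok]
  n <- length(d)
  if (n < 2L) stopf("need at least 2 complete pairs")
  est <- mean(d)
  if (max(d) - min(d) < 1e-12) {
    warnf("all paired differences identical: degenerate interval")
    return(list(mean_diff = est, ci_lower = est, ci_upper = est,
                n = n, n_boot = n_boot, conf = conf))
  }
  set.seed(seed)
  bt <- boot::boot(d, function(x, i) mean(x[i]), R = n_boot)
  ci <- boot::boot.ci(bt, conf = conf, type = "bca")
  list(mean_diff = est, ci_lower = ci$bca[4], ci_upper = ci$bca[5],
       n = n, n_boot = n_boot, conf = conf)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way F test with `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom, fitted via `stats::aov` with an `Error(subject)` stratum.
#' Subjects with any missing condition are dropped (complete cases). No
#' sphericity correction is applied.
#'
#' @param values Numeric matrix, one row per subject, one column per
#'   condition (e.g. the three walking trials).
#' @return List with `F`, `p`, `df1`, `df2`, `n`.
#' @export
rm_anova <- function(values) {
  values <- as.matrix(values)
  values <- values[stats::complete.cases(values), , drop = FALSE]
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2L) stopf("need at least 2 subjects with complete cases")
  if (k < 2L) stopf("need at least 2 conditions")
  d <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(n), times = k)),
    condition = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ condition + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fv <- tab["condition", "F value"]
  pv <- tab["condition", "Pr(>F)"]
  # no condition variation (0/0 in the F ratio): report the null
  ss_cond <- tab["condition", "Sum Sq"]
  if (!is.finite(Fv) || ss_cond <= 1e-10 * max(1, sum(abs(values)))) {
    Fv <- 0; pv <- 1
  }
  list(F = unname(Fv), p = unname(pv),
       df1 = k - 1L, df2 = (k - 1L) * (n - 1L), n = n)
}
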