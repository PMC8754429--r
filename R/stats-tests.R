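# Shared statistical primitives: Mann-Whitney U, bootstrap median CI,
# Bonferroni threshold.

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test of whether two samples come from the same distribution,
#' as used to compare the cold/warm rate-ratio distribution against the
#' same-T_Growth control distribution. The U statistic is computed from rank
#' sums with midranks for ties. For small problems without ties
#' (`n1 * n2 <= exact_threshold`) the p-value is exact, from the complete
#' null distribution of U; otherwise the normal approximation with tie
#' correction and continuity correction is used. The two regimes agree
#' closely where they overlap.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact_threshold use the exact null distribution when
#'   `n1 * n2` is at most this and there are no ties (default 400).
#' @return An object of class `"mw_utest"`: list with `u_statistic` (U for
#'   `x`, in `[0, n1*n2]`), `p_two_sided`, `n1`, `n2`, `method`, `ties`.
#'   Swapping `x` and `y` maps U to `n1*n2 - U` and leaves p unchanged.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))   # exact p = 1/3
#' @export
mann_whitney_u <- function(x, y, exact_threshold = 400) {
  if (length(x) == 0L || length(y) == 0L)
    stopf("both samples must be non-empty")
  stopifnot(is.numeric(x), is.numeric(y), all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L

  if (!ties && n1 * n2 <= exact_threshold) {
    u_low <- min(U, n1 * n2 - U)
    p <- min(1, 2 * stats::pwilcox(u_low, n1, n2))
    method <- "exact"
  } else {
    N <- n1 + n2
    tt <- table(pooled)
    tie_term <- sum(tt^3 - tt)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- U - mu
      z <- (d - sign(d) * 0.5) / sqrt(sigma2)  # continuity correction toward the mean
      if (d == 0) z <- 0
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(list(u_statistic = as.numeric(U), p_two_sided = p,
                 n1 = n1, n2 = n2, method = method, ties = ties),
            class = "mw_utest")
}

#' @export
print.mw_utest <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (two-sided, %s)\nU = %g, n1 = %d, n2 = %d, p = %.4g\n",
              x$method, x$u_statistic, x$n1, x$n2, x$p_two_sided))
  invisible(x)
}

#' Bootstrap percentile confidence interval for a median
#'
#' Draws `reps` resamples of size `n` with replacement, takes the median of
#' each, and returns the percentile interval of the resampled medians. The
#' simple percentile interval is used (and recorded in the output) because
#' it is the minimal reproducible choice. Deterministic given `seed`; the
#' caller's RNG state is left untouched.
#'
#' With `scale = "log"` the median and interval are computed on the natural
#' log of the values and back-transformed. This is the appropriate scale
#' for fold-change and ratio distributions: with an even sample size the
#' median interpolates geometrically rather than arithmetically, so a
#' sample closed under reciprocals (such as the flattened same-T_Growth
#' control) has median exactly 1. With an odd sample size both scales give
#' the ordinary middle value.
#'
#' @param values numeric sample, `n >= 2` (all positive when
#'   `scale = "log"`).
#' @param reps number of bootstrap replications (default 10000).
#' @param seed integer seed governing the resampling.
#' @param conf confidence level (default 0.95).
#' @param scale `"linear"` (midpoint median) or `"log"` (geometric
#'   interpolation, for ratio data).
#' @return An object of class `"median_summary"`: list with `median` (of the
#'   original sample), `ci_low`, `ci_high`, `n`, `bootstrap_reps`, `seed`,
#'   `conf`, `scale`, `interval_type`.
#' @examples
#' bootstrap_median_ci(c(0.8, 1.0, 1.1, 1.4, 2.0), reps = 2000, seed = 7)
#' @export
bootstrap_median_ci <- function(values, reps = 10000, seed, conf = 0.95,
                                scale = c("linear", "log")) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(values), all(is.finite(values)))
  n <- length(values)
  if (n < 2L) stopf("need at least 2 values for a bootstrap CI (got %d)", n)
  if (reps < 1L) stopf("reps must be >= 1")
  if (scale == "log") {
    if (any(values <= 0)) stopf("log-scale median requires positive values")
    v <- log(values)
  } else v <- values
  meds <- with_seed(seed, {
    vapply(seq_len(reps),
           function(i) median_midpoint(sample(v, n, replace = TRUE)),
           numeric(1))
  })
  a <- (1 - conf) / 2
  ci <- stats::quantile(meds, c(a, 1 - a), names = FALSE, type = 7)
  est <- c(median_midpoint(v), ci)
  if (scale == "log") est <- exp(est)
  structure(list(median = est[1],
                 ci_low = est[2], ci_high = est[3],
                 n = n, bootstrap_reps = as.integer(reps),
                 seed = as.integer(seed), conf = conf, scale = scale,
                 interval_type = "percentile"),
            class = "median_summary")
}

#' @export
print.median_summary <- function(x, ...) {
  cat(sprintf("median = %.4g, %d%% CI [%.4g, %.4g] (n = %d, %d bootstrap reps, seed %d)\n",
              x$median, round(100 * x$conf), x$ci_low, x$ci_high,
              x$n, x$bootstrap_reps, x$seed))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise significance level, in (0, 1).
#' @param m number of tests, `>= 1`.
#' @return `alpha / m`. For the per-reaction slope screen over 951 reactions
#'   at alpha = 0.05 this is 5.26e-5.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1)
    stopf("alpha must be in (0, 1)")
  if (!is_scalar_number(m) || m < 1 || m != round(m))
    stopf("m must be a positive integer")
  alpha / m
}
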