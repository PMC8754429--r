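# Per-reaction regression of log10(rate constant) on growth temperature,
# with Bonferroni screening across reactions.

#' Slope of log10(rate) versus growth temperature for one reaction
#'
#' Ordinary least squares of `log10(k)` on `t_growth_C` over a reaction's
#' per-organism measurements. Under rate compensation the slope (`m_rate`)
#' would be negative: colder-adapted variants faster at a common assay
#' temperature. Reactions with fewer than three variants or zero
#' growth-temperature variance are not fittable and yield `NULL`.
#'
#' @param measurements data frame with columns `t_growth_C` and `k` for one
#'   reaction.
#' @return List with `m_rate` (log10 units per degC), `intercept`,
#'   `r_squared`, `p_value` (two-sided t-test of zero slope, n - 2 df), `n`;
#'   or `NULL` when not fittable.
#' @examples
#' fit_reaction_slope(data.frame(t_growth_C = c(10, 20, 30), k = 10^c(1, .8, .6)))
#' @export
fit_reaction_slope <- function(measurements) {
  t <- measurements$t_growth_C
  k <- measurements$k
  n <- length(t)
  if (n < 3L || length(unique(t)) < 2L) return(NULL)
  fit <- stats::lm(log10(k) ~ t)
  # noise-free reactions fit perfectly; summary.lm warns about that, which
  # is expected for simulated data
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  # zero-residual (perfectly collinear) fits give p = 0; keep p in (0, 1]
  p <- if (nrow(co) < 2L || is.nan(co[2, 4])) 1 else max(co[2, 4], .Machine$double.xmin)
  list(m_rate = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = p,
       n = n)
}

#' Slopes for every fittable reaction in a table
#'
#' Applies [fit_reaction_slope()] to each reaction with more than two
#' variants and non-zero temperature spread.
#'
#' @param reactions a `reaction_table`.
#' @return Data frame with `ec_number`, `substrate`, `m_rate`, `intercept`,
#'   `r_squared`, `p_value`, `n`; one row per fittable reaction.
#' @seealso [screen_slopes()]
#' @export
fit_reaction_slopes <- function(reactions) {
  parts <- reaction_split(reactions)
  rows <- lapply(parts, function(m) {
    f <- fit_reaction_slope(m)
    if (is.null(f)) return(NULL)
    data.frame(ec_number = m$ec_number[1], substrate = m$substrate[1],
               m_rate = f$m_rate, intercept = f$intercept,
               r_squared = f$r_squared, p_value = f$p_value, n = f$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(ec_number = character(0), substrate = character(0),
                      m_rate = numeric(0), intercept = numeric(0),
                      r_squared = numeric(0), p_value = numeric(0), n = integer(0))
  rownames(out) <- NULL
  out
}

#' Bonferroni screen over per-reaction slopes
#'
#' Flags reactions whose slope p-value clears the family-wise threshold
#' `alpha / m`, with `m` the number of fitted reactions, and splits the
#' significant ones by slope sign (negative = consistent with rate
#' compensation, positive = opposite).
#'
#' @param slopes data frame from [fit_reaction_slopes()].
#' @param alpha family-wise significance level (default 0.05).
#' @return The input with a logical `significant` column, carrying
#'   attributes `threshold`, `alpha`, `m`, `n_significant_negative`,
#'   `n_significant_positive`.
#' @export
screen_slopes <- function(slopes, alpha = 0.05) {
  m <- nrow(slopes)
  thr <- if (m > 0) bonferroni_threshold(alpha, m) else NA_real_
  slopes$significant <- if (m > 0) slopes$p_value < thr else logical(0)
  structure(slopes,
            threshold = thr, alpha = alpha, m = m,
            n_significant_negative = sum(slopes$significant & slopes$m_rate < 0),
            n_significant_positive = sum(slopes$significant & slopes$m_rate > 0))
}
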