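# The rate-ratio statistic (k_cold / k_warm) and its same-T_Growth control
# null, plus the comparison of the two distributions.

#' Cold/warm rate ratio for one reaction
#'
#' Divides the rate constant of the variant from the organism with minimum
#' growth temperature by that of the variant from the organism with maximum
#' growth temperature. When several variants share the extreme temperature,
#' the median of their rates is used. Under the rate-compensation model the
#' ratio exceeds one; a reaction with zero growth-temperature spread has no
#' cold/warm contrast and yields `NULL` (absence is a value, not an error).
#'
#' @param measurements data frame with one row per variant: columns
#'   `t_growth_C` and `k` (a single reaction's rows of a `reaction_table`).
#' @return List with `k_cold`, `k_warm`, `ratio` (= `k_cold / k_warm`),
#'   `t_cold_C`, `t_warm_C`, `n_variants`, or `NULL` when all variants share
#'   one growth temperature.
#' @examples
#' rate_ratio(data.frame(t_growth_C = c(5, 5, 50), k = c(2, 8, 4)))  # ratio 1.25
#' @export
rate_ratio <- function(measurements) {
  t <- measurements$t_growth_C
  k <- measurements$k
  stopifnot(length(t) >= 2L, all(k > 0))
  t_cold <- min(t); t_warm <- max(t)
  if (t_cold == t_warm) return(NULL)
  k_cold <- median_midpoint(k[t == t_cold])
  k_warm <- median_midpoint(k[t == t_warm])
  list(k_cold = k_cold, k_warm = k_warm, ratio = k_cold / k_warm,
       t_cold_C = t_cold, t_warm_C = t_warm, n_variants = length(k))
}

#' Rate ratios for every reaction in a table
#'
#' @param reactions a `reaction_table` from [build_reactions()].
#' @return Data frame with one row per reaction that has non-zero
#'   growth-temperature spread: `ec_number`, `substrate`, `k_cold`, `k_warm`,
#'   `ratio`, `t_cold_C`, `t_warm_C`, `n_variants`.
#' @seealso [rate_ratio()], [compare_to_control()]
#' @export
rate_ratios <- function(reactions) {
  parts <- reaction_split(reactions)
  rows <- lapply(parts, function(m) {
    rr <- rate_ratio(m)
    if (is.null(rr)) return(NULL)
    data.frame(ec_number = m$ec_number[1], substrate = m$substrate[1],
               k_cold = rr$k_cold, k_warm = rr$k_warm, ratio = rr$ratio,
               t_cold_C = rr$t_cold_C, t_warm_C = rr$t_warm_C,
               n_variants = rr$n_variants, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(ec_number = character(0), substrate = character(0),
                      k_cold = numeric(0), k_warm = numeric(0), ratio = numeric(0),
                      t_cold_C = numeric(0), t_warm_C = numeric(0),
                      n_variants = integer(0))
  rownames(out) <- NULL
  out
}

#' Same-T_Growth control fold changes
#'
#' Rate variation between variants from different organisms with identical
#' growth temperatures is temperature-independent by construction, so it
#' serves as the null distribution for the rate ratio. For each reaction
#' with at least two variants sharing a growth temperature, the fold change
#' `k_max / k_min` within the shared-temperature group and its reciprocal
#' are both recorded; downstream the flattened `{fold_up, fold_down}`
#' multiset is the control sample (closed under reciprocal, hence its median
#' is exactly 1 on the log scale's axis of symmetry).
#'
#' When a reaction has several distinct shared-temperature groups, the group
#' with the most variants is used, ties broken toward the lowest temperature
#' (`groups = "largest"`, the default); `groups = "all"` instead emits one
#' fold-change pair per shared-temperature group.
#'
#' @param reactions a `reaction_table`.
#' @param groups shared-temperature group selection rule.
#' @return Data frame with one row per contributing reaction (or group):
#'   `ec_number`, `substrate`, `t_growth_C`, `n_variants`, `fold_up`
#'   (`>= 1`), `fold_down` (`= 1/fold_up`).
#' @export
control_fold_changes <- function(reactions, groups = c("largest", "all")) {
  groups <- match.arg(groups)
  parts <- reaction_split(reactions)
  rows <- lapply(parts, function(m) {
    cnt <- table(m$t_growth_C)
    shared <- as.numeric(names(cnt)[cnt >= 2L])
    if (!length(shared)) return(NULL)
    if (groups == "largest") {
      sizes <- cnt[as.character(shared)]
      shared <- shared[order(-as.integer(sizes), shared)][1]
    }
    do.call(rbind, lapply(shared, function(tg) {
      k <- m$k[m$t_growth_C == tg]
      fu <- max(k) / min(k)
      data.frame(ec_number = m$ec_number[1], substrate = m$substrate[1],
                 t_growth_C = tg, n_variants = length(k),
                 fold_up = fu, fold_down = 1 / fu, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(ec_number = character(0), substrate = character(0),
                      t_growth_C = numeric(0), n_variants = integer(0),
                      fold_up = numeric(0), fold_down = numeric(0))
  rownames(out) <- NULL
  out
}

#' Compare the rate-ratio distribution to its same-T_Growth control
#'
#' The central test of the rate-compensation model: if cold-adapted variants
#' were systematically faster, the cold/warm rate-ratio distribution would
#' be shifted above the temperature-independent control distribution. The
#' two samples (per-reaction ratios vs the flattened `{fold_up, fold_down}`
#' control multiset) are compared with a two-sided Mann-Whitney U test, and
#' each sample's median gets a bootstrap percentile confidence interval.
#' Both are fold-change distributions, so medians are taken on the log
#' scale (see [bootstrap_median_ci()]); in particular the reciprocal-closed
#' control sample has median exactly 1 up to floating-point rounding. The
#' ratio sample is also partitioned by comparison with 1 (above / below /
#' equal).
#'
#' @param ratios data frame from [rate_ratios()] (non-empty).
#' @param controls data frame from [control_fold_changes()] (non-empty).
#' @param reps bootstrap replications for the median CIs (default 10000).
#' @param seed integer seed; all randomness flows from it via substreams.
#' @param conf confidence level for the median CIs.
#' @return An object of class `"compensation_comparison"`: list with
#'   `data_summary` and `control_summary` (each a `median_summary`), `utest`
#'   (an `mw_utest`), `n_above_one`, `n_below_one`, `n_equal_one`, `seed`.
#' @export
compare_to_control <- function(ratios, controls, reps = 10000, seed, conf = 0.95) {
  if (nrow(ratios) == 0L) stopf("ratio collection is empty")
  if (nrow(controls) == 0L) stopf("control collection is empty")
  data_sample <- ratios$ratio
  control_sample <- c(controls$fold_up, controls$fold_down)
  structure(list(
    data_summary = bootstrap_median_ci(data_sample, reps = reps,
                                       seed = substream_seed(seed, 1), conf = conf,
                                       scale = "log"),
    control_summary = bootstrap_median_ci(control_sample, reps = reps,
                                          seed = substream_seed(seed, 2), conf = conf,
                                          scale = "log"),
    utest = mann_whitney_u(data_sample, control_sample),
    n_above_one = sum(data_sample > 1),
    n_below_one = sum(data_sample < 1),
    n_equal_one = sum(data_sample == 1),
    n_data = length(data_sample),
    n_control = length(control_sample),
    seed = as.integer(seed)
  ), class = "compensation_comparison")
}

#' @export
print.compensation_comparison <- function(x, ...) {
  cat("Rate-compensation test: k_cold/k_warm ratios vs same-T_Growth control\n")
  cat(sprintf("  data    (n = %4d): median %.3f, %d%% CI [%.3f, %.3f]\n",
              x$data_summary$n, x$data_summary$median,
              round(100 * x$data_summary$conf),
              x$data_summary$ci_low, x$data_summary$ci_high))
  cat(sprintf("  control (n = %4d): median %.3f, %d%% CI [%.3f, %.3f]\n",
              x$control_summary$n, x$control_summary$median,
              round(100 * x$control_summary$conf),
              x$control_summary$ci_low, x$control_summary$ci_high))
  cat(sprintf("  Mann-Whitney U = %g, two-sided p = %.3g (%s)\n",
              x$utest$u_statistic, x$utest$p_two_sided, x$utest$method))
  cat(sprintf("  ratios > 1: %d, < 1: %d, = 1: %d\n",
              x$n_above_one, x$n_below_one, x$n_equal_one))
  invisible(x)
}

#' @export
summary.compensation_comparison <- function(object, ...) {
  list(data_median = object$data_summary$median,
       data_ci = c(object$data_summary$ci_low, object$data_summary$ci_high),
       control_median = object$control_summary$median,
       control_ci = c(object$control_summary$ci_low, object$control_summary$ci_high),
       u_statistic = object$utest$u_statistic,
       p_two_sided = object$utest$p_two_sided,
       n_above_one = object$n_above_one,
       n_below_one = object$n_below_one,
       n_equal_one = object$n_equal_one)
}
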