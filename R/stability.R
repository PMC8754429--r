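# Protein-stability mirror of the rate analysis: melting temperature (Tm)
# versus organismal growth temperature across wild-type proteins, and
# per-family cold/warm Tm fold changes.

#' Match stability records to growth temperatures
#'
#' Attaches each wild-type stability record's organismal optimal growth
#' temperature by normalised organism name (same normalisation as the
#' kinetic side). Optionally collapses repeated Tm measurements of the same
#' (protein, organism) pair to their median, consistent with the kinetic
#' aggregation rule.
#'
#' @param records data frame from [read_stability_records()] or
#'   [generate_stability_dataset()].
#' @param table growth-temperature table.
#' @param strip_strains passed to [normalize_organism_name()].
#' @param dedupe collapse repeated (protein, organism) Tm values to their
#'   median (default `TRUE`; switchable because upstream curations differ on
#'   this).
#' @return List with `matched` (records with `t_growth_C` filled),
#'   `n_unmatched`, and `n_deduplicated` (rows removed by collapsing).
#' @export
match_stability_t_growth <- function(records, table, strip_strains = FALSE,
                                     dedupe = TRUE) {
  if (nrow(table) == 0L) stopf("growth-temperature table is empty")
  rec <- records
  rec$t_growth_C <- NULL
  mt <- match_t_growth(rec, table, strip_strains = strip_strains)
  m <- mt$matched
  n_dedup <- 0L
  if (dedupe && nrow(m)) {
    key <- paste(tolower(trimws(m$protein_name)), m$organism_normalized, sep = "\r")
    if (anyDuplicated(key)) {
      tm <- tapply(m$t_m_C, key, median_midpoint)
      first <- !duplicated(key)
      n_dedup <- nrow(m) - sum(first)
      message(sprintf("collapsed %d repeated (protein, organism) Tm measurement(s) to medians",
                      n_dedup))
      m <- m[first, , drop = FALSE]
      m$t_m_C <- as.numeric(tm[key[first]])
      rownames(m) <- NULL
    }
  }
  list(matched = m, n_unmatched = mt$n_unmatched, n_deduplicated = n_dedup)
}

#' Linear fit of melting temperature on growth temperature
#'
#' Ordinary least squares of Tm (degC) on T_Growth (degC), untransformed,
#' across wild-type proteins: the stability analogue of the rate-slope
#' analysis. A positive slope indicates stability compensation (proteins
#' from warmer-growing organisms melt higher).
#'
#' @param matched data frame of matched stability records (the `matched`
#'   element of [match_stability_t_growth()]); at least 3 rows.
#' @return An object of class `"stability_fit"` wrapping the `lm` fit, with
#'   `slope` (degC Tm per degC T_Growth), `intercept`, `r_squared`,
#'   `p_value` (two-sided test of zero slope), `n`. Supports `print()`,
#'   `coef()`, `predict()`, `residuals()`.
#' @examples
#' d <- data.frame(t_growth_C = c(0, 20, 40), t_m_C = c(40, 50, 70))
#' fit_tm_vs_tgrowth(d)   # slope 0.75
#' @export
fit_tm_vs_tgrowth <- function(matched) {
  if (nrow(matched) < 3L)
    stopf("need at least 3 matched stability records (got %d)", nrow(matched))
  fit <- stats::lm(t_m_C ~ t_growth_C, data = matched)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn; expected on clean data
  p <- max(sm$coefficients[2, 4], .Machine$double.xmin)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = p,
                 n = nrow(matched),
                 lm = fit),
            class = "stability_fit")
}

#' @export
print.stability_fit <- function(x, ...) {
  cat(sprintf("Tm ~ T_Growth linear fit (n = %d)\n", x$n))
  cat(sprintf("  slope %.4f degC/degC, intercept %.2f degC, R^2 = %.3f, p = %.3g\n",
              x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' @export
coef.stability_fit <- function(object, ...) stats::coef(object$lm)

#' @export
predict.stability_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$lm, ...)
  else stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
residuals.stability_fit <- function(object, ...) stats::residuals(object$lm)

#' Per-family cold/warm melting-temperature fold changes
#'
#' For each protein family (exact protein-name group after trimming and
#' case-folding) with variants from at least two distinct growth
#' temperatures, divides the Tm of the variant from the coldest-growing
#' organism by that from the warmest (medians when the extreme temperature
#' is shared, as on the kinetic side). A fold change below 1 means the
#' warm-adapted variant is more stable (stability compensation).
#'
#' @param matched data frame of matched stability records.
#' @return Data frame with `family`, `t_m_cold_C`, `t_m_warm_C`,
#'   `fold_change` (= `t_m_cold_C / t_m_warm_C`; requires both Tm > 0 degC),
#'   `t_cold_C`, `t_warm_C`, `n_variants`; attributes `n_warm_more_stable`
#'   (fold change < 1), `n_cold_more_stable` (> 1), `n_families`.
#' @export
family_fold_changes <- function(matched) {
  fam <- tolower(trimws(matched$protein_name))
  parts <- split(matched, fam)
  rows <- lapply(parts, function(g) {
    t <- g$t_growth_C
    if (length(t) < 2L || min(t) == max(t)) return(NULL)
    tm_cold <- median_midpoint(g$t_m_C[t == min(t)])
    tm_warm <- median_midpoint(g$t_m_C[t == max(t)])
    if (tm_cold <= 0 || tm_warm <= 0) return(NULL)  # ratio undefined at/below 0 degC
    data.frame(family = g$protein_name[1], t_m_cold_C = tm_cold,
               t_m_warm_C = tm_warm, fold_change = tm_cold / tm_warm,
               t_cold_C = min(t), t_warm_C = max(t), n_variants = nrow(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(family = character(0), t_m_cold_C = numeric(0),
                      t_m_warm_C = numeric(0), fold_change = numeric(0),
                      t_cold_C = numeric(0), t_warm_C = numeric(0),
                      n_variants = integer(0))
  rownames(out) <- NULL
  structure(out,
            n_families = nrow(out),
            n_warm_more_stable = sum(out$fold_change < 1),
            n_cold_more_stable = sum(out$fold_change > 1))
}
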