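# Curation: raw kinetic entries -> reactions (EC number-substrate pairs with
# per-organism median rate constants matched to growth temperature).

#' Normalise an organism name for matching
#'
#' Deterministic canonical form used on both sides of every organism match:
#' trimmed, internal whitespace collapsed to single spaces, case-folded.
#' With `strip_strains = TRUE` only the first two tokens (genus + species)
#' are retained, so strain designations such as `"KT2440"` do not block a
#' match; the default keeps the full name because matching granularity
#' varies between curations.
#'
#' @param name organism name (species binomial, possibly with strain suffix).
#' @param strip_strains drop tokens after genus and species?
#' @return Normalised name (single character string). Idempotent.
#' @examples
#' normalize_organism_name("Escherichia  coli ")
#' normalize_organism_name("Pseudomonas putida KT2440", strip_strains = TRUE)
#' @export
normalize_organism_name <- function(name, strip_strains = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  x <- tolower(gsub("\\s+", " ", trimws(name)))
  if (is.na(x) || x == "") stopf("organism name is empty")
  if (strip_strains) {
    tok <- strsplit(x, " ", fixed = TRUE)[[1]]
    if (length(tok) > 2L) x <- paste(tok[1:2], collapse = " ")
  }
  x
}

#' Keep only wild-type kinetic entries
#'
#' @param entries data frame of kinetic entries (see [read_kinetic_entries()]).
#' @return The wild-type subset, input order preserved. Idempotent.
#' @export
filter_wild_type <- function(entries) {
  entries[entries$variant_status == "wild_type", , drop = FALSE]
}

#' Match kinetic entries to organismal growth temperatures
#'
#' Attaches each entry's organism optimal growth temperature by normalised
#' organism name. Entries whose organism is absent from the table are
#' excluded and counted.
#'
#' @param entries data frame of kinetic entries.
#' @param table growth-temperature table from [read_growth_temperatures()]
#'   or [generate_kinetic_dataset()].
#' @param strip_strains passed to [normalize_organism_name()] (applied to
#'   both sides).
#' @return List with `matched` (entries plus `t_growth_C` and
#'   `organism_normalized` columns) and `n_unmatched`.
#' @export
match_t_growth <- function(entries, table, strip_strains = FALSE) {
  if (nrow(table) == 0L) stopf("growth-temperature table is empty")
  key_tab <- vapply(table$organism, normalize_organism_name, character(1),
                    strip_strains = strip_strains, USE.NAMES = FALSE)
  agg <- tapply(table$t_growth_C, key_tab, median_midpoint)
  lookup <- stats::setNames(as.numeric(agg), names(agg))
  if (nrow(entries) == 0L) {
    entries$organism_normalized <- character(0)
    entries$t_growth_C <- numeric(0)
    return(list(matched = entries, n_unmatched = 0L))
  }
  key_ent <- vapply(entries$organism, normalize_organism_name, character(1),
                    strip_strains = strip_strains, USE.NAMES = FALSE)
  tgm <- unname(lookup[key_ent])
  hit <- !is.na(tgm)
  matched <- entries[hit, , drop = FALSE]
  matched$organism_normalized <- key_ent[hit]
  matched$t_growth_C <- tgm[hit]
  rownames(matched) <- NULL
  list(matched = matched, n_unmatched = sum(!hit))
}

#' Build reactions from temperature-matched kinetic entries
#'
#' A reaction is an EC number-substrate pair. Within a reaction, repeated
#' measurements of the same enzyme variant (same organism, same substrate)
#' are aggregated to their median; only reactions with measurements from at
#' least two distinct organisms are retained, since a cold/warm comparison
#' needs at least two variants.
#'
#' Substrate names are compared after trimming and case-folding; no chemical
#' synonym resolution is attempted.
#'
#' @param matched data frame of matched entries (the `matched` element of
#'   [match_t_growth()]), all of one value type.
#' @param value_type `"kcat"` or `"kcat_over_km"`; must match the entries.
#' @param report_extra named list merged into the curation report (used by
#'   the pipeline to carry upstream funnel counts).
#' @return An object of class `"reaction_table"`: a data frame with one row
#'   per variant measurement (`ec_number`, `substrate`, `organism`,
#'   `t_growth_C`, `k`, `n_source_entries`) plus attributes `value_type`,
#'   `entries` (the source entries, for re-aggregation under assay-
#'   temperature subsetting) and `curation_report`.
#' @seealso [subset_reactions()], [rate_ratios()], [curation_report()]
#' @export
build_reactions <- function(matched, value_type = c("kcat", "kcat_over_km"),
                            report_extra = list()) {
  value_type <- match.arg(value_type)
  if (nrow(matched) && !all(matched$value_type == value_type))
    stopf("entries contain value types other than '%s'", value_type)
  m <- matched
  m$substrate <- tolower(trimws(m$substrate))
  key_rx <- paste(m$ec_number, m$substrate, sep = "\r")
  key_var <- paste(key_rx, m$organism_normalized, sep = "\r")

  # per-variant median over repeated measurements
  idx <- !duplicated(key_var)
  agg_k <- tapply(m$value, key_var, median_midpoint)
  agg_n <- tapply(m$value, key_var, length)
  vm <- data.frame(ec_number = m$ec_number[idx],
                   substrate = m$substrate[idx],
                   organism = m$organism_normalized[idx],
                   t_growth_C = m$t_growth_C[idx],
                   stringsAsFactors = FALSE)
  kv <- key_var[idx]
  vm$k <- as.numeric(agg_k[kv])
  vm$n_source_entries <- as.integer(agg_n[kv])
  rx_of <- key_rx[idx]

  # keep reactions with >= 2 distinct organisms
  orgs_per_rx <- tapply(vm$organism, rx_of, function(o) length(unique(o)))
  keep_rx <- names(orgs_per_rx)[orgs_per_rx >= 2L]
  keep <- rx_of %in% keep_rx
  out <- vm[keep, , drop = FALSE]
  ord <- order(out$ec_number, out$substrate, out$t_growth_C, out$organism)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL

  report <- c(report_extra, list(
    n_t_growth_matched = nrow(matched),
    n_values_in_reactions = sum(out$n_source_entries),
    n_reactions = length(keep_rx),
    n_organisms = length(unique(out$organism)),
    t_growth_min_C = if (nrow(out)) min(out$t_growth_C) else NA_real_,
    t_growth_max_C = if (nrow(out)) max(out$t_growth_C) else NA_real_
  ))

  structure(out,
            class = c("reaction_table", "data.frame"),
            value_type = value_type,
            entries = matched,
            curation_report = report)
}

#' @export
print.reaction_table <- function(x, ...) {
  rep <- attr(x, "curation_report")
  if (!is.null(rep)) {
    cat(sprintf("Reaction table (%s): %d reactions, %d variant measurements, %d organisms\n",
                attr(x, "value_type") %||% "?", rep$n_reactions, nrow(x), rep$n_organisms))
    if (nrow(x))
      cat(sprintf("T_Growth range: %.1f-%.1f degC\n", rep$t_growth_min_C, rep$t_growth_max_C))
  }
  NextMethod()
}

#' Curation report accessor
#'
#' @param reactions a `reaction_table` from [build_reactions()] or
#'   [curate_entries()].
#' @return Named list of funnel counts (`n_input`, `n_wild_type`,
#'   `n_t_growth_matched`, `n_values_in_reactions`, `n_reactions`,
#'   `n_organisms`) and the retained temperature range.
#' @export
curation_report <- function(reactions) attr(reactions, "curation_report")

#' Curate raw kinetic entries into a reaction table
#'
#' Convenience wrapper running the full curation funnel: filter to wild-type
#' entries of one value type, match organisms to growth temperatures, and
#' build the reaction table. The funnel counts (input, wild type, matched,
#' retained in reactions) are recorded in the curation report.
#'
#' @param entries data frame of kinetic entries.
#' @param t_growth growth-temperature table.
#' @inheritParams build_reactions
#' @inheritParams match_t_growth
#' @return A `reaction_table`; see [build_reactions()].
#' @export
curate_entries <- function(entries, t_growth, value_type = c("kcat", "kcat_over_km"),
                           strip_strains = FALSE) {
  value_type <- match.arg(value_type)
  sel <- entries[entries$value_type == value_type, , drop = FALSE]
  wt <- filter_wild_type(sel)
  mt <- match_t_growth(wt, t_growth, strip_strains = strip_strains)
  build_reactions(mt$matched, value_type,
                  report_extra = list(n_input = nrow(sel),
                                      n_wild_type = nrow(wt),
                                      n_unmatched = mt$n_unmatched))
}

reaction_split <- function(reactions) {
  split(as.data.frame(reactions),
        paste(reactions$ec_number, reactions$substrate, sep = "\r"))
}

#' Restrict a reaction table by assay temperature or T_Growth span
#'
#' Two subsetting axes used for robustness checks: (i) only source entries
#' measured at a given assay temperature (within `assay_tol_C`) contribute,
#' with per-variant medians re-aggregated afterwards; (ii) only reactions
#' whose growth-temperature span exceeds `min_t_growth_span_C` are kept.
#' Every returned reaction still has at least two organisms.
#'
#' @param reactions a `reaction_table`.
#' @param assay_temperature_C optional assay temperature filter (degC).
#' @param min_t_growth_span_C optional minimal span `max(T) - min(T)`
#'   (strictly greater than).
#' @param assay_tol_C tolerance around the assay temperature (default 0.5).
#' @return A `reaction_table` (re-built when the assay filter is active).
#' @export
subset_reactions <- function(reactions, assay_temperature_C = NULL,
                             min_t_growth_span_C = NULL, assay_tol_C = 0.5) {
  out <- reactions
  if (!is.null(assay_temperature_C)) {
    stopifnot(is_scalar_number(assay_temperature_C))
    ent <- attr(reactions, "entries")
    if (is.null(ent)) stopf("reaction table carries no source entries; cannot apply assay filter")
    keep <- !is.na(ent$assay_temperature_C) &
      abs(ent$assay_temperature_C - assay_temperature_C) <= assay_tol_C
    out <- build_reactions(ent[keep, , drop = FALSE], attr(reactions, "value_type"))
  }
  if (!is.null(min_t_growth_span_C)) {
    stopifnot(is_scalar_number(min_t_growth_span_C))
    key <- paste(out$ec_number, out$substrate, sep = "\r")
    span <- tapply(out$t_growth_C, key, function(t) max(t) - min(t))
    keep_rx <- names(span)[span > min_t_growth_span_C]
    sel <- key %in% keep_rx
    rep0 <- attr(out, "curation_report")
    res <- out[sel, , drop = FALSE]
    rownames(res) <- NULL
    rep0$n_reactions <- length(keep_rx)
    rep0$n_organisms <- length(unique(res$organism))
    rep0$n_values_in_reactions <- sum(res$n_source_entries)
    rep0$t_growth_min_C <- if (nrow(res)) min(res$t_growth_C) else NA_real_
    rep0$t_growth_max_C <- if (nrow(res)) max(res$t_growth_C) else NA_real_
    out <- structure(res, class = c("reaction_table", "data.frame"),
                     value_type = attr(out, "value_type"),
                     entries = attr(out, "entries"),
                     curation_report = rep0)
  }
  out
}
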