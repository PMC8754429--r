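# Flat-table readers and writers (TSV/CSV with header row, JSON array of
# flat objects). All validation into domain records happens here; downstream
# code can assume its invariants hold.

VALUE_TYPES <- c("kcat", "kcat_over_km")
WILD_TYPE_TOKENS <- c("wild_type", "wild-type", "wildtype", "wild type", "wt", "wild")
MUTANT_TOKENS <- c("mutant", "mut", "mutation")

# Multiplicative conversion to canonical units: s^-1 for kcat,
# M^-1 s^-1 for kcat/KM. Unknown unit strings cause row rejection.
UNIT_FACTORS <- list(
  kcat = c("s^-1" = 1, "1/s" = 1, "s-1" = 1, "per_s" = 1,
           "min^-1" = 1 / 60, "1/min" = 1 / 60, "min-1" = 1 / 60,
           "h^-1" = 1 / 3600, "1/h" = 1 / 3600, "h-1" = 1 / 3600),
  kcat_over_km = c("M^-1s^-1" = 1, "1/(M*s)" = 1, "M-1s-1" = 1,
                   "mM^-1s^-1" = 1e3, "mM-1s-1" = 1e3,
                   "uM^-1s^-1" = 1e6, "uM-1s-1" = 1e6,
                   "M^-1min^-1" = 1 / 60, "M-1min-1" = 1 / 60)
)

read_flat_table <- function(path) {
  if (!file.exists(path)) stopf("input file does not exist: %s", path)
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    json = {
      x <- jsonlite::fromJSON(path)
      if (!is.data.frame(x)) stopf("JSON input must be an array of flat objects: %s", path)
      x
    },
    csv = utils::read.csv(path, colClasses = "character", check.names = FALSE),
    utils::read.delim(path, colClasses = "character", check.names = FALSE)
  )
  for (j in seq_along(df)) df[[j]] <- as.character(df[[j]])
  df
}

dialect_column <- function(df, dialect, field, required = TRUE) {
  col <- dialect[[field]]
  if (is.null(col) || is.na(col)) {
    if (required)
      stopf("dialect does not map required field '%s'", field)
    return(NULL)
  }
  if (!col %in% names(df)) {
    if (required)
      stopf("required column '%s' (field '%s') missing from input", col, field)
    return(NULL)
  }
  df[[col]]
}

parse_number <- function(x) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Read a table of kinetic-constant entries
#'
#' Reads a flat TSV/CSV/JSON extract of enzyme kinetic constants (one row per
#' measured value of kcat or kcat/KM for one enzyme variant on one substrate)
#' and validates each row into a kinetic entry. Rows failing validation are
#' rejected individually and logged in the attached read report; a missing
#' required column is a configuration error and aborts the read.
#'
#' Validation enforces: a positive numeric value; an EC number of four
#' dot-separated numeric fields; a recognised value type (`"kcat"` or
#' `"kcat_over_km"`); a recognised variant status (wild type or mutant);
#' non-empty organism and substrate. If the dialect maps a units column,
#' values are converted to canonical units (s^-1 for kcat, M^-1 s^-1 for
#' kcat/KM) and rows with unconvertible unit strings are rejected. Value
#' ranges such as `"1.2-3.4"` are rejected as non-numeric rather than
#' guessed at. Assay temperature is optional metadata; unparseable entries
#' become `NA`.
#'
#' @param path path to a `.tsv`/`.txt` (tab-separated), `.csv`, or `.json`
#'   file with a header row.
#' @param dialect column mapping, see [dialect_synthetic()].
#' @param default_value_type value type assumed when the dialect has no
#'   value-type column (single-constant extracts).
#' @return A data frame of accepted entries with columns `entry_id`,
#'   `ec_number`, `substrate`, `organism`, `value`, `value_type`,
#'   `variant_status`, `assay_temperature_C`, carrying a `"read_report"`
#'   attribute (see [read_report()]).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' df <- data.frame(entry_id = "e1", ec_number = "1.1.1.1",
#'                  substrate = "ethanol", organism = "Escherichia coli",
#'                  value = 12.5, value_type = "kcat",
#'                  variant_status = "wild_type", assay_temperature_C = 25)
#' write_table(df, tf, format = "tsv")
#' read_kinetic_entries(tf)
#' @export
read_kinetic_entries <- function(path, dialect = dialect_synthetic(),
                                 default_value_type = "kcat") {
  df <- read_flat_table(path)
  n <- nrow(df)

  ec <- trimws(dialect_column(df, dialect, "ec_number"))
  substrate <- trimws(dialect_column(df, dialect, "substrate"))
  organism <- trimws(dialect_column(df, dialect, "organism"))
  raw_value <- dialect_column(df, dialect, "value")
  vt_raw <- dialect_column(df, dialect, "value_type", required = FALSE)
  vs_raw <- dialect_column(df, dialect, "variant_status")
  at_raw <- dialect_column(df, dialect, "assay_temperature_C", required = FALSE)
  units_raw <- dialect_column(df, dialect, "units", required = FALSE)
  id_raw <- dialect_column(df, dialect, "entry_id", required = FALSE)

  if (is.null(vt_raw)) {
    if (!default_value_type %in% VALUE_TYPES)
      stopf("default_value_type must be one of: %s", paste(VALUE_TYPES, collapse = ", "))
    vt_raw <- rep(default_value_type, n)
  }

  value <- parse_number(raw_value)
  vt <- normalize_value_type(vt_raw)
  vs <- normalize_variant_status(vs_raw)
  assay_t <- if (is.null(at_raw)) rep(NA_real_, n) else parse_number(at_raw)
  entry_id <- if (is.null(id_raw)) sprintf("row%d", seq_len(n)) else trimws(id_raw)

  reason <- rep(NA_character_, n)
  mark <- function(cond, why) reason[is.na(reason) & cond] <<- why
  mark(is.na(value), "non-numeric value")
  mark(!is.na(value) & value <= 0, "non-positive value")
  mark(!grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", ec), "malformed EC number")
  mark(is.na(vt), "unknown value type")
  mark(is.na(vs), "unknown variant status")
  mark(is.na(organism) | organism == "", "missing organism")
  mark(is.na(substrate) | substrate == "", "missing substrate")

  # Unit conversion to canonical scale; blank/absent units assumed canonical.
  if (!is.null(units_raw)) {
    u <- trimws(units_raw)
    for (t in VALUE_TYPES) {
      fac <- UNIT_FACTORS[[t]]
      i <- which(is.na(reason) & vt == t & !is.na(u) & u != "")
      if (!length(i)) next
      known <- u[i] %in% names(fac)
      reason[i[!known]] <- "unconvertible units"
      ik <- i[known]
      value[ik] <- value[ik] * unname(fac[u[ik]])
    }
  }

  keep <- is.na(reason)
  out <- data.frame(entry_id = entry_id[keep],
                    ec_number = ec[keep],
                    substrate = substrate[keep],
                    organism = organism[keep],
                    value = value[keep],
                    value_type = vt[keep],
                    variant_status = vs[keep],
                    assay_temperature_C = assay_t[keep],
                    stringsAsFactors = FALSE)
  attr(out, "read_report") <- make_read_report(n, reason)
  out
}

normalize_value_type <- function(x) {
  x <- tolower(trimws(x))
  x[x %in% c("kcat", "turnover", "turnover_number")] <- "kcat"
  x[x %in% c("kcat_over_km", "kcat/km", "kcat_km", "catalytic_efficiency")] <- "kcat_over_km"
  x[!x %in% VALUE_TYPES] <- NA_character_
  x
}

normalize_variant_status <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  out[x %in% WILD_TYPE_TOKENS] <- "wild_type"
  out[x %in% MUTANT_TOKENS] <- "mutant"
  out
}

make_read_report <- function(n_input, reason) {
  rej <- reason[!is.na(reason)]
  list(n_input = n_input,
       n_accepted = n_input - length(rej),
       n_rejected = length(rej),
       reasons = if (length(rej)) table(rej) else table(character(0)),
       rejected_rows = which(!is.na(reason)))
}

#' Retrieve the read report attached by a reader
#'
#' @param x a data frame returned by [read_kinetic_entries()] or
#'   [read_stability_records()].
#' @return A list with `n_input`, `n_accepted`, `n_rejected`, a `reasons`
#'   table, and the rejected row indices. Accepted plus rejected counts
#'   always equal the input row count.
#' @export
read_report <- function(x) attr(x, "read_report")

#' Read an organism-to-growth-temperature table
#'
#' Reads a two-column mapping from organism name to optimal growth temperature
#' (degrees Celsius), as in curated compilations of median optimal growth
#' temperatures for microbes in culture. Organism names are normalised (see
#' [normalize_organism_name()]) and duplicate names collapse to the median of
#' their temperatures, with a message. Temperatures outside a plausible
#' -5..120 degC range trigger a warning but are retained.
#'
#' @param path input file (TSV/CSV/JSON).
#' @param organism_col,temperature_col column names in the file.
#' @param strip_strains passed to [normalize_organism_name()].
#' @return Data frame with columns `organism` (normalised key), `t_growth_C`
#'   and `n_source` (rows collapsed into each record).
#' @export
read_growth_temperatures <- function(path, organism_col = "organism",
                                     temperature_col = "t_growth_C",
                                     strip_strains = FALSE) {
  df <- read_flat_table(path)
  if (nrow(df) == 0L) stopf("growth-temperature table is empty: %s", path)
  for (col in c(organism_col, temperature_col))
    if (!col %in% names(df)) stopf("required column '%s' missing from input", col)
  tg <- parse_number(df[[temperature_col]])
  if (anyNA(tg))
    stopf("temperature column '%s' contains non-numeric values", temperature_col)
  org <- vapply(df[[organism_col]], normalize_organism_name,
                character(1), strip_strains = strip_strains, USE.NAMES = FALSE)
  agg <- tapply(tg, org, median_midpoint)
  cnt <- tapply(tg, org, length)
  n_dup <- sum(cnt > 1L)
  if (n_dup > 0L)
    message(sprintf("collapsed %d duplicated organism name(s) to their median temperature", n_dup))
  out <- data.frame(organism = names(agg),
                    t_growth_C = as.numeric(agg),
                    n_source = as.integer(cnt),
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  bad <- out$t_growth_C < -5 | out$t_growth_C > 120
  if (any(bad))
    warnf("%d growth temperature(s) outside plausible range -5..120 degC", sum(bad))
  out
}

#' Read wild-type protein stability records
#'
#' Reads a protein thermostability export (one row per melting-temperature
#' measurement) and retains only wild-type rows with a finite melting
#' temperature. Mutant rows and rows without a parseable Tm are dropped and
#' counted in the attached read report.
#'
#' @param path input file (TSV/CSV/JSON).
#' @param dialect column mapping, see [dialect_prothermdb()].
#' @return Data frame with columns `protein_name`, `organism`, `t_m_C`,
#'   `t_growth_C` (all `NA` until matched), and any mapped metadata columns
#'   (`pH`, `method`, `state`, `reversibility`); `"read_report"` attribute
#'   attached.
#' @export
read_stability_records <- function(path, dialect = dialect_prothermdb()) {
  df <- read_flat_table(path)
  n <- nrow(df)
  protein <- trimws(dialect_column(df, dialect, "protein_name"))
  organism <- trimws(dialect_column(df, dialect, "organism"))
  mutation <- trimws(dialect_column(df, dialect, "mutation"))
  tm <- parse_number(dialect_column(df, dialect, "t_m_C"))

  is_wt <- tolower(mutation) %in% WILD_TYPE_TOKENS
  reason <- rep(NA_character_, n)
  reason[!is_wt] <- "not wild type"
  reason[is.na(reason) & is.na(tm)] <- "missing or non-numeric Tm"
  reason[is.na(reason) & (is.na(protein) | protein == "")] <- "missing protein name"
  reason[is.na(reason) & (is.na(organism) | organism == "")] <- "missing organism"

  keep <- is.na(reason)
  out <- data.frame(protein_name = protein[keep],
                    organism = organism[keep],
                    t_m_C = tm[keep],
                    t_growth_C = NA_real_,
                    stringsAsFactors = FALSE)
  for (f in c("pH", "method", "state", "reversibility")) {
    col <- dialect_column(df, dialect, f, required = FALSE)
    if (!is.null(col)) out[[f]] <- trimws(col)[keep]
  }
  attr(out, "read_report") <- make_read_report(n, reason)
  out
}

#' Write a result table to TSV, CSV or JSON
#'
#' Writes any homogeneous collection of records (a data frame) so that
#' re-reading yields value-identical records; numeric fields are written to
#' full double precision. An empty collection produces a header-only file.
#'
#' @param records data frame to write.
#' @param path output path.
#' @param format one of `"tsv"`, `"csv"`, `"json"`.
#' @export
write_table <- function(records, path, format = c("tsv", "csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(records))
    records <- as.data.frame(records, stringsAsFactors = FALSE)
  out <- records
  # full precision: as.character on doubles keeps 15 significant digits;
  # force 17 so write/read is the identity on doubles
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  ok <- tryCatch({
    switch(format,
      tsv = utils::write.table(out, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = ""),
      csv = utils::write.csv(out, path, quote = FALSE, row.names = FALSE, na = ""),
      json = jsonlite::write_json(records, path, dataframe = "rows",
                                  digits = NA, na = "null")
    )
    TRUE
  }, error = function(e) stopf("cannot write table to '%s': %s", path, conditionMessage(e)))
  invisible(ok)
}
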