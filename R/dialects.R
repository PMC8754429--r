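#' Column-mapping dialects for flat-table readers
#'
#' A dialect is a named character vector mapping the package's canonical field
#' names to the column headers of a particular export format. Database exports
#' do not share a header convention, so the readers are decoupled from any
#' specific one; a dialect entry set to `NA` marks an optional field absent
#' from that format.
#'
#' `dialect_synthetic()` matches the tables written by the synthetic-data
#' generator and by [write_table()]. `dialect_brenda()` matches a flat
#' kinetic-constant extract in the style of a BRENDA SOAP download;
#' `dialect_prothermdb()` matches a ProThermDB stability export.
#'
#' @param ... named overrides, e.g. `value = "turnoverNumber"`.
#' @return Named character vector usable as the `dialect` argument of the
#'   readers.
#' @seealso [read_kinetic_entries()], [read_stability_records()]
#' @examples
#' dialect_synthetic(value = "kcat_value")
#' @export
dialect_synthetic <- function(...) {
  d <- c(entry_id = "entry_id",
         ec_number = "ec_number",
         substrate = "substrate",
         organism = "organism",
         value = "value",
         value_type = "value_type",
         variant_status = "variant_status",
         assay_temperature_C = "assay_temperature_C",
         units = NA_character_)
  modify_dialect(d, ...)
}

#' @rdname dialect_synthetic
#' @export
dialect_brenda <- function(...) {
  d <- c(entry_id = "entryId",
         ec_number = "ecNumber",
         substrate = "substrate",
         organism = "organism",
         value = "value",
         value_type = "valueType",
         variant_status = "variant",
         assay_temperature_C = "assayTemperature",
         units = "unit")
  modify_dialect(d, ...)
}

#' @rdname dialect_synthetic
#' @export
dialect_prothermdb <- function(...) {
  d <- c(protein_name = "PROTEIN",
         organism = "SOURCE",
         mutation = "MUTATION",
         t_m_C = "Tm_C",
         pH = "pH",
         method = "METHOD",
         state = "STATE",
         reversibility = "REVERSIBILITY")
  modify_dialect(d, ...)
}

#' @rdname dialect_synthetic
#' @export
dialect_stability_synthetic <- function(...) {
  d <- c(protein_name = "protein_name",
         organism = "organism",
         mutation = "mutation",
         t_m_C = "t_m_C",
         pH = NA_character_,
         method = NA_character_,
         state = NA_character_,
         reversibility = NA_character_)
  modify_dialect(d, ...)
}

modify_dialect <- function(d, ...) {
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(d))
    if (length(bad))
      stopf("unknown dialect field(s): %s", paste(bad, collapse = ", "))
    d[names(over)] <- over
  }
  d
}
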