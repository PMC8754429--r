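test_that("valid rows are accepted and the report conserves row counts", {
  rows <- rbind(kinetic_row(entry_id = "e1"),
                kinetic_row(entry_id = "e2", value = "3.5"),
                kinetic_row(entry_id = "e3", value = "0.02"))
  path <- write_kinetic_fixture(rows)
  ent <- read_kinetic_entries(path)
  rep <- read_report(ent)
  expect_equal(nrow(ent), 3L)
  expect_equal(rep$n_rejected, 0L)
  expect_equal(rep$n_accepted + rep$n_rejected, rep$n_input)
  expect_equal(ent$value, c(10, 3.5, 0.02))
})

test_that("invalid rows are rejected individually with reasons, never fatally", {
  rows <- rbind(kinetic_row(entry_id = "ok"),
                kinetic_row(entry_id = "dash", value = "-"),
                kinetic_row(entry_id = "zero", value = "0"),
                kinetic_row(entry_id = "range", value = "1.2-3.4"),
                kinetic_row(entry_id = "badec", ec_number = "1.1.1"),
                kinetic_row(entry_id = "badvs", variant_status = "chimera"))
  ent <- read_kinetic_entries(write_kinetic_fixture(rows))
  rep <- read_report(ent)
  expect_equal(nrow(ent), 1L)
  expect_equal(rep$n_rejected, 5L)
  expect_equal(rep$n_accepted + rep$n_rejected, rep$n_input)
  reasons <- as.list(rep$reasons)
  expect_equal(reasons[["non-numeric value"]], 2L)  # "-" and the range "1.2-3.4"
  expect_equal(reasons[["non-positive value"]], 1L)
  expect_equal(reasons[["malformed EC number"]], 1L)
  expect_equal(reasons[["unknown variant status"]], 1L)
})

test_that("units are converted to canonical scale and unknown units rejected", {
  rows <- rbind(kinetic_row(entry_id = "a", value = "60"),
                kinetic_row(entry_id = "b", value = "60"),
                kinetic_row(entry_id = "c", value = "60"))
  rows$unit <- c("s^-1", "min^-1", "furlongs")
  d <- dialect_synthetic(units = "unit")
  ent <- read_kinetic_entries(write_kinetic_fixture(rows), dialect = d)
  expect_equal(nrow(ent), 2L)
  expect_equal(ent$value, c(60, 1))
  expect_equal(as.list(read_report(ent)$reasons)[["unconvertible units"]], 1L)
})

test_that("a missing required column is a configuration error", {
  rows <- kinetic_row()
  rows$value <- NULL
  expect_error(read_kinetic_entries(write_kinetic_fixture(rows)),
               "required column")
  expect_error(read_kinetic_entries(tempfile()), "does not exist")
})

test_that("growth-temperature reader collapses duplicates to the median", {
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(organism = "Escherichia coli", t_growth_C = 37),
                     tf, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_growth_temperatures(tf)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$t_growth_C, 37)

  utils::write.table(data.frame(organism = c("Xa yb", "Xa yb"),
                                t_growth_C = c(30, 40)),
                     tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(tab2 <- read_growth_temperatures(tf), "duplicated")
  expect_equal(tab2$t_growth_C, 35)  # midpoint median of {30, 40}
  expect_equal(tab2$n_source, 2L)
})

test_that("growth-temperature reader errors on non-numeric temperatures and empty tables", {
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(organism = "Xa yb", t_growth_C = "warm"),
                     tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_growth_temperatures(tf), "t_growth_C")
  utils::write.table(data.frame(organism = character(0), t_growth_C = numeric(0)),
                     tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_growth_temperatures(tf), "empty")
  utils::write.table(data.frame(organism = "Pyrolobus fumarii", t_growth_C = 150),
                     tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(read_growth_temperatures(tf), "plausible range")
})

test_that("stability reader keeps only wild-type rows with a parseable Tm", {
  df <- data.frame(protein_name = c("lysozyme", "lysozyme", "barnase", "nuclease"),
                   organism = c("Gallus gallus", "Gallus gallus",
                                "Bacillus amyloliquefaciens", "Staphylococcus aureus"),
                   mutation = c("wild_type", "A23G", "wild-type", "wild_type"),
                   t_m_C = c("74.5", "70.1", "52.3", ""),
                   stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_stability_records(tf, dialect = dialect_stability_synthetic(
    mutation = "mutation"))
  rep <- read_report(rec)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$t_m_C, c(74.5, 52.3))
  expect_equal(rep$n_rejected, 2L)
  expect_equal(rep$n_accepted + rep$n_rejected, rep$n_input)
})

test_that("write/read round-trip is the identity at full numeric precision", {
  slope_fit <- data.frame(ec_number = "1.1.1.1", substrate = "x",
                          m_rate = -0.0213456789012345,
                          p_value = 5.23456789012345e-7,
                          r_squared = 0.912345678901234, n = 7L,
                          stringsAsFactors = FALSE)
  for (fmt in c("tsv", "csv", "json")) {
    tf <- tempfile(fileext = paste0(".", fmt))
    write_table(slope_fit, tf, format = fmt)
    back <- coldcomp:::read_flat_table(tf)
    expect_equal(as.numeric(back$p_value), slope_fit$p_value, tolerance = 1e-13)
    expect_equal(as.numeric(back$m_rate), slope_fit$m_rate, tolerance = 1e-13)
  }
})

test_that("writing an empty collection yields a header-only file", {
  tf <- tempfile(fileext = ".tsv")
  write_table(data.frame(a = numeric(0), b = character(0)), tf, "tsv")
  lines <- readLines(tf)
  expect_equal(length(lines), 1L)
  expect_equal(lines, "a\tb")
  rows <- rate_ratios(make_reactions(data.frame(
    ec_number = rep("1.1.1.1", 2), substrate = "s",
    organism = c("a b", "c d"), t_growth_C = c(10, 40), value = c(2, 4))))
  write_table(rows, tf, "tsv")
  expect_equal(length(readLines(tf)), nrow(rows) + 1L)
})
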