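test_that("organism names normalise deterministically and idempotently", {
  expect_equal(normalize_organism_name("Escherichia  coli "), "escherichia coli")
  expect_equal(normalize_organism_name("Escherichia coli"), "escherichia coli")
  expect_equal(normalize_organism_name(normalize_organism_name("A  B")),
               normalize_organism_name("A  B"))
  expect_equal(normalize_organism_name("Pseudomonas putida KT2440",
                                       strip_strains = TRUE),
               "pseudomonas putida")
  expect_equal(normalize_organism_name("Pseudomonas putida KT2440"),
               "pseudomonas putida kt2440")
  expect_error(normalize_organism_name("  "), "empty")
})

test_that("wild-type filtering preserves order and is idempotent", {
  ent <- rbind(kinetic_row(entry_id = "w1"),
               kinetic_row(entry_id = "m1", variant_status = "mutant"),
               kinetic_row(entry_id = "w2"))
  ent <- read_kinetic_entries(write_kinetic_fixture(ent))
  wt <- filter_wild_type(ent)
  expect_equal(wt$entry_id, c("w1", "w2"))
  expect_equal(filter_wild_type(wt), wt)
  allmut <- ent[ent$variant_status == "mutant", ]
  expect_equal(nrow(filter_wild_type(allmut)), 0L)
})

test_that("temperature matching counts unmatched entries and ignores case/whitespace", {
  ent <- rbind(kinetic_row(entry_id = "a", organism = "Escherichia  COLI"),
               kinetic_row(entry_id = "b", organism = "Bacillus subtilis"),
               kinetic_row(entry_id = "c", organism = "Ignotus organismus"))
  ent <- read_kinetic_entries(write_kinetic_fixture(ent))
  tab <- data.frame(organism = c("escherichia coli", "BACILLUS SUBTILIS"),
                    t_growth_C = c(37, 30))
  res <- match_t_growth(ent, tab)
  expect_equal(nrow(res$matched), 2L)
  expect_equal(res$n_unmatched, 1L)
  expect_equal(res$matched$t_growth_C, c(37, 30))
  empty <- match_t_growth(ent[0, ], tab)
  expect_equal(nrow(empty$matched), 0L)
  expect_equal(empty$n_unmatched, 0L)
})

test_that("reactions aggregate repeated measurements by median and need two organisms", {
  df <- data.frame(
    ec_number = rep("1.1.1.1", 5),
    substrate = rep("s", 5),
    organism = c("a b", "a b", "a b", "c d", "e f"),
    t_growth_C = c(10, 10, 10, 40, 25),
    value = c(1, 2, 9, 4, 7))
  # e f belongs to a different reaction key -> single organism, dropped
  df$substrate[5] <- "other"
  rx <- make_reactions(df)
  expect_equal(nrow(rx), 2L)
  expect_equal(sort(rx$k), c(2, 4))  # median{1,2,9} = 2, single value 4
  rep <- curation_report(rx)
  expect_equal(rep$n_reactions, 1L)
  expect_equal(rep$n_organisms, 2L)
  expect_equal(rep$n_values_in_reactions, 4L)
  expect_true(rep$n_t_growth_matched >= rep$n_values_in_reactions)
})

test_that("curation output is invariant to input row permutation", {
  d <- generate_kinetic_dataset(kinetic_sim_config(n_reactions = 30, seed = 5))
  rx1 <- curate_entries(d$entries, d$t_growth)
  perm <- d$entries[rev(seq_len(nrow(d$entries))), ]
  rx2 <- curate_entries(perm, d$t_growth)
  # provenance attributes may carry rows in input order; the measurements
  # table itself must be identical
  expect_equal(as.data.frame(rx1), as.data.frame(rx2), ignore_attr = TRUE)
  expect_equal(curation_report(rx1), curation_report(rx2))
})

test_that("the curation funnel is monotone and matches generator ground truth", {
  d <- generate_kinetic_dataset(kinetic_sim_config(n_reactions = 80, seed = 11))
  rx <- curate_entries(d$entries, d$t_growth)
  rep <- curation_report(rx)
  expect_true(rep$n_input >= rep$n_wild_type)
  expect_true(rep$n_wild_type >= rep$n_t_growth_matched)
  expect_true(rep$n_t_growth_matched >= rep$n_values_in_reactions)
  # every variant has a distinct organism and >= 2 per reaction, so all
  # generated reactions survive curation
  expect_equal(rep$n_reactions, 80L)
  expect_equal(rep$n_organisms,
               length(unique(tolower(d$truth$variants$organism))))
  # funnel conservation: input = wild type + mutant; wild type = matched + unmatched
  expect_equal(rep$n_input,
               rep$n_wild_type + sum(d$entries$variant_status == "mutant"))
  expect_equal(rep$n_wild_type, rep$n_t_growth_matched + rep$n_unmatched)
})

test_that("span subsetting keeps only reactions exceeding the threshold", {
  df <- data.frame(
    ec_number = c("1.1.1.1", "1.1.1.1", "2.2.2.2", "2.2.2.2"),
    substrate = "s",
    organism = c("a b", "c d", "e f", "g h"),
    t_growth_C = c(10, 25, 10, 35),
    value = c(1, 2, 3, 4))
  rx <- make_reactions(df)
  narrow <- subset_reactions(rx, min_t_growth_span_C = 20)
  expect_equal(unique(narrow$ec_number), "2.2.2.2")  # 25 degC span retained
  expect_equal(curation_report(narrow)$n_reactions, 1L)
  none <- subset_reactions(rx, min_t_growth_span_C = 30)
  expect_equal(nrow(none), 0L)
})

test_that("assay-temperature subsetting re-aggregates and can drop reactions", {
  ent <- rbind(
    kinetic_row(entry_id = "a", organism = "Aa bb", assay_temperature_C = "25"),
    kinetic_row(entry_id = "b", organism = "Cc dd", assay_temperature_C = "37"),
    kinetic_row(entry_id = "c", ec_number = "2.2.2.2", organism = "Aa bb",
                assay_temperature_C = "25"),
    kinetic_row(entry_id = "d", ec_number = "2.2.2.2", organism = "Cc dd",
                value = "40", assay_temperature_C = "25.3"))
  ent <- read_kinetic_entries(write_kinetic_fixture(ent))
  tab <- data.frame(organism = c("aa bb", "cc dd"), t_growth_C = c(20, 45))
  rx <- curate_entries(ent, tab)
  expect_equal(curation_report(rx)$n_reactions, 2L)
  at25 <- subset_reactions(rx, assay_temperature_C = 25)
  # reaction 1.1.1.1 loses its only warm variant (assayed at 37) -> dropped;
  # 2.2.2.2 keeps both (25.3 within +/-0.5 tolerance)
  expect_equal(unique(at25$ec_number), "2.2.2.2")
  expect_equal(nrow(at25), 2L)
})
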