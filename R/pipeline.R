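# End-to-end orchestration: curate -> ratios/control/compare -> slopes ->
# stability, with machine-readable reports and a reproducibility manifest.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full rate- and stability-compensation analysis
#'
#' Orchestrates every stage over flat input tables (real or simulated):
#' curation of kinetic entries into reactions, cold/warm rate ratios, the
#' same-T_Growth control, the data-vs-control comparison, the per-reaction
#' slope screen with Bonferroni correction and, when a stability table is
#' configured, the Tm-vs-T_Growth fit and family fold changes. All stage
#' outputs are written as TSV/JSON into `out_dir` together with a manifest
#' (config snapshot, input digests, seed, package version, per-stage row
#' counts); re-running with the same config and inputs reproduces identical
#' outputs apart from the manifest timestamp.
#'
#' @param config named list (or path to a JSON file holding one) with
#'   elements: `kinetic_entries` and `t_growth` (paths, required),
#'   `stability` (path, optional), `kinetic_dialect` / `stability_dialect`
#'   (dialect preset names `"synthetic"`, `"brenda"`, `"prothermdb"`,
#'   `"stability_synthetic"`; defaults `"synthetic"`), `value_type`
#'   (default `"kcat"`), `assay_temperature_C` / `min_t_growth_span_C`
#'   (optional subset filters), `strip_strains` (default `FALSE`), `reps`
#'   (bootstrap replications, default 10000), `alpha` (slope screen
#'   family-wise level, default 0.05), `seed` (required).
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with every stage result (`reactions`,
#'   `ratios`, `controls`, `comparison`, `slopes`, `stability_fit`,
#'   `families`, `manifest`).
#' @export
run_full_analysis <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  for (field in c("kinetic_entries", "t_growth", "seed"))
    if (is.null(config[[field]]))
      stopf("config is missing required input '%s'", field)
  for (field in c("kinetic_entries", "t_growth", "stability"))
    if (!is.null(config[[field]]) && !file.exists(config[[field]]))
      stopf("config input '%s' does not exist: %s", field, config[[field]])

  value_type <- config$value_type %||% "kcat"
  reps <- config$reps %||% 10000
  alpha <- config$alpha %||% 0.05
  strip_strains <- isTRUE(config$strip_strains)
  seed <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  kin_dialect <- pick_dialect(config$kinetic_dialect %||% "synthetic")
  entries <- run_stage("read_kinetic_entries",
    read_kinetic_entries(config$kinetic_entries, dialect = kin_dialect))
  t_growth <- run_stage("read_growth_temperatures",
    read_growth_temperatures(config$t_growth, strip_strains = strip_strains))

  reactions <- run_stage("curation",
    curate_entries(entries, t_growth, value_type = value_type,
                   strip_strains = strip_strains))
  if (!is.null(config$assay_temperature_C) || !is.null(config$min_t_growth_span_C))
    reactions <- run_stage("subset_reactions",
      subset_reactions(reactions,
                       assay_temperature_C = config$assay_temperature_C,
                       min_t_growth_span_C = config$min_t_growth_span_C))

  ratios <- run_stage("rate_ratios", rate_ratios(reactions))
  controls <- run_stage("control_fold_changes", control_fold_changes(reactions))
  comparison <- run_stage("compare_to_control",
    compare_to_control(ratios, controls, reps = reps, seed = seed))

  slopes <- run_stage("slopes", screen_slopes(fit_reaction_slopes(reactions), alpha = alpha))

  stab_fit <- NULL; families <- NULL
  if (!is.null(config$stability)) {
    stab_dialect <- pick_stability_dialect(config$stability_dialect %||% "stability_synthetic")
    stab <- run_stage("read_stability_records",
      read_stability_records(config$stability, dialect = stab_dialect))
    stab_m <- run_stage("match_stability_t_growth",
      match_stability_t_growth(stab, t_growth, strip_strains = strip_strains))
    stab_fit <- run_stage("fit_tm_vs_tgrowth", fit_tm_vs_tgrowth(stab_m$matched))
    families <- run_stage("family_fold_changes", family_fold_changes(stab_m$matched))
  }

  # ---- write stage outputs ----
  write_table(as.data.frame(reactions), file.path(out_dir, "reactions.tsv"), "tsv")
  write_json_report(curation_report(reactions), file.path(out_dir, "curation_report.json"))
  write_table(ratios, file.path(out_dir, "ratios.tsv"), "tsv")
  write_table(controls, file.path(out_dir, "control.tsv"), "tsv")
  write_table(slopes, file.path(out_dir, "slopes.tsv"), "tsv")

  sig_neg <- slopes[slopes$significant & slopes$m_rate < 0, c("ec_number", "substrate")]
  sig_pos <- slopes[slopes$significant & slopes$m_rate > 0, c("ec_number", "substrate")]
  comp_json <- c(summary(comparison),
                 list(seed = seed, bootstrap_reps = reps,
                      bonferroni_alpha = alpha,
                      bonferroni_m = attr(slopes, "m"),
                      bonferroni_threshold = attr(slopes, "threshold"),
                      significant_negative_slopes = sig_neg,
                      significant_positive_slopes = sig_pos,
                      schema_version = "1.0"))
  write_json_report(comp_json, file.path(out_dir, "comparison.json"))

  if (!is.null(stab_fit)) {
    write_json_report(list(slope = stab_fit$slope, intercept = stab_fit$intercept,
                           r_squared = stab_fit$r_squared, p_value = stab_fit$p_value,
                           n = stab_fit$n, temperature_scale = "celsius"),
                      file.path(out_dir, "stability_fit.json"))
    write_table(families, file.path(out_dir, "family_fold_changes.tsv"), "tsv")
  }

  manifest <- list(
    config = config,
    inputs = input_digests(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("coldcomp")),
    row_counts = list(entries = nrow(entries),
                      reactions = curation_report(reactions)$n_reactions,
                      variant_measurements = nrow(reactions),
                      ratios = nrow(ratios),
                      controls = nrow(controls),
                      slopes = nrow(slopes),
                      stability_records = if (is.null(stab_fit)) NULL else stab_fit$n,
                      families = if (is.null(families)) NULL else nrow(families)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  write_json_report(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(reactions = reactions, ratios = ratios, controls = controls,
                 comparison = comparison, slopes = slopes,
                 stability_fit = stab_fit, families = families,
                 manifest = manifest))
}

pick_dialect <- function(x) {
  if (is.character(x) && length(x) == 1L)
    switch(x,
           synthetic = dialect_synthetic(),
           brenda = dialect_brenda(),
           stopf("unknown kinetic dialect preset '%s'", x))
  else x
}

pick_stability_dialect <- function(x) {
  if (is.character(x) && length(x) == 1L)
    switch(x,
           prothermdb = dialect_prothermdb(),
           stability_synthetic = dialect_stability_synthetic(),
           stopf("unknown stability dialect preset '%s'", x))
  else x
}

input_digests <- function(config) {
  paths <- Filter(Negate(is.null),
                  config[c("kinetic_entries", "t_growth", "stability")])
  lapply(paths, function(p) unname(tools::md5sum(p)))
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, dataframe = "rows")
}
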