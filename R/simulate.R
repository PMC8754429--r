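# Synthetic-data generators: database-style kinetic tables, growth-temperature
# tables, stability tables and initial-rate series with known ground truth.
# These define the study conditions every pipeline stage is validated under.

#' Configuration for the synthetic kinetic dataset
#'
#' The generator emulates the statistical structure of a curated kinetic-
#' constant extract: reactions keyed by EC number-substrate pair, each with
#' two to many enzyme variants from different organisms, growth temperatures
#' spanning roughly 1-83 degC, log-scale rate variation with a tunable
#' temperature slope, repeated measurements per variant, and configurable
#' contamination (mutant rows, organisms absent from the temperature table).
#'
#' The hierarchical model is: per reaction a baseline
#' `mu_r ~ Normal(0, sigma_reaction)`; per variant at growth temperature
#' `T_v`, `log10(k_v) = mu_r + beta * T_v + Normal(0, sigma_noise)` drawn
#' independently per measurement. `beta` is the ground-truth slope of
#' log10(rate) on T_Growth; `beta = 0` is the temperature-independent null.
#'
#' Defaults mirror a real curation funnel: about 35% of rows are mutant,
#' about two thirds of wild-type rows belong to organisms without a curated
#' growth temperature, variants-per-reaction is a truncated geometric
#' distribution dominated by 2-variant reactions, and growth temperatures
#' lie on a 1 degC grid (curated optimal growth temperatures are coarse, so
#' distinct organisms can share a value, which is what feeds the
#' same-temperature control).
#'
#' @param n_reactions number of reactions.
#' @param variants_per_reaction distribution spec: either
#'   `list(type = "geometric", p, min, max)` (P(min) = p, geometric tail,
#'   truncated at max) or `list(type = "categorical", sizes, probs)`.
#' @param t_growth_range_C growth-temperature interval, degC.
#' @param t_resolution_C grid spacing for organism growth temperatures.
#' @param beta ground-truth slope of log10(k) on T_Growth (log10 per degC).
#' @param sigma_reaction between-reaction spread of baseline log10(k).
#' @param sigma_noise within-reaction residual spread of log10(k).
#' @param replicate_rate probability a variant receives repeated
#'   measurements.
#' @param mutant_rate fraction of kinetic rows flagged mutant.
#' @param unmatched_rate fraction of wild-type rows from organisms absent
#'   from the growth-temperature table.
#' @param n_organisms organism pool size; organisms are reused across
#'   reactions so matching code paths are exercised.
#' @param value_type `"kcat"` or `"kcat_over_km"`.
#' @param seed integer seed; all draws flow from it via substreams.
#' @return A validated config list of class `"kinetic_sim_config"`.
#' @export
kinetic_sim_config <- function(n_reactions = 500,
                               variants_per_reaction = list(type = "geometric",
                                                            p = 0.57, min = 2, max = 12),
                               t_growth_range_C = c(1, 83),
                               t_resolution_C = 1,
                               beta = 0,
                               sigma_reaction = 1.5,
                               sigma_noise = 0.5,
                               replicate_rate = 0.3,
                               mutant_rate = 0.35,
                               unmatched_rate = 0.66,
                               n_organisms = NULL,
                               value_type = c("kcat", "kcat_over_km"),
                               seed = 1L) {
  value_type <- match.arg(value_type)
  stopifnot(is_scalar_number(n_reactions), n_reactions >= 1,
            is.numeric(t_growth_range_C), length(t_growth_range_C) == 2L,
            t_growth_range_C[1] < t_growth_range_C[2],
            is_scalar_number(t_resolution_C), t_resolution_C > 0,
            is_scalar_number(beta),
            is_scalar_number(sigma_reaction), sigma_reaction >= 0,
            is_scalar_number(sigma_noise), sigma_noise >= 0,
            is_scalar_number(replicate_rate), replicate_rate >= 0, replicate_rate <= 1,
            is_scalar_number(mutant_rate), mutant_rate >= 0, mutant_rate < 1,
            is_scalar_number(unmatched_rate), unmatched_rate >= 0, unmatched_rate < 1,
            is_scalar_number(seed))
  vmax <- max_variants(variants_per_reaction)
  if (is.null(n_organisms))
    n_organisms <- max(vmax + 1, ceiling(n_reactions * 0.4))
  if (n_organisms < vmax)
    stopf("n_organisms (%d) must be at least the maximum variants per reaction (%d)",
          n_organisms, vmax)
  structure(list(n_reactions = as.integer(n_reactions),
                 variants_per_reaction = variants_per_reaction,
                 t_growth_range_C = t_growth_range_C,
                 t_resolution_C = t_resolution_C,
                 beta = beta, sigma_reaction = sigma_reaction,
                 sigma_noise = sigma_noise,
                 replicate_rate = replicate_rate,
                 mutant_rate = mutant_rate,
                 unmatched_rate = unmatched_rate,
                 n_organisms = as.integer(n_organisms),
                 value_type = value_type,
                 seed = as.integer(seed)),
            class = "kinetic_sim_config")
}

max_variants <- function(spec) {
  switch(spec$type,
         geometric = spec$max,
         categorical = max(spec$sizes),
         stopf("unknown variants_per_reaction type '%s'", spec$type))
}

draw_variant_counts <- function(n, spec) {
  switch(spec$type,
    geometric = {
      support <- spec$min:spec$max
      probs <- spec$p * (1 - spec$p)^(support - spec$min)
      sample(support, n, replace = TRUE, prob = probs / sum(probs))
    },
    categorical = sample(spec$sizes, n, replace = TRUE, prob = spec$probs)
  )
}

draw_t_growth <- function(n, range, resolution) {
  t <- stats::runif(n, range[1], range[2])
  pmin(pmax(round(t / resolution) * resolution, range[1]), range[2])
}

#' Generate a synthetic kinetic dataset with ground truth
#'
#' Draws a kinetic-entry table, its companion growth-temperature table and a
#' full ground-truth record under the hierarchical log-linear model of
#' [kinetic_sim_config()]. Byte-identical given the same config (including
#' seed).
#'
#' @param config a [kinetic_sim_config()].
#' @return List with `entries` (kinetic-entry data frame in the
#'   [dialect_synthetic()] layout), `t_growth` (organism table covering the
#'   matched organisms only), and `truth` (config echo plus per-reaction
#'   baselines and per-variant true values, sufficient to recompute every
#'   generated value).
#' @examples
#' d <- generate_kinetic_dataset(kinetic_sim_config(n_reactions = 20, seed = 42))
#' head(d$entries)
#' @export
generate_kinetic_dataset <- function(config) {
  stopifnot(inherits(config, "kinetic_sim_config"))
  cfg <- config

  organisms <- sprintf("Syntheticus organismus%04d", seq_len(cfg$n_organisms))
  t_org <- with_seed(substream_seed(cfg$seed, 1),
                     draw_t_growth(cfg$n_organisms, cfg$t_growth_range_C,
                                   cfg$t_resolution_C))

  nv <- with_seed(substream_seed(cfg$seed, 2),
                  draw_variant_counts(cfg$n_reactions, cfg$variants_per_reaction))
  mu <- with_seed(substream_seed(cfg$seed, 3),
                  stats::rnorm(cfg$n_reactions, 0, cfg$sigma_reaction))
  ec <- sprintf("%d.%d.%d.%d",
                (seq_len(cfg$n_reactions) - 1L) %% 6L + 1L,
                (seq_len(cfg$n_reactions) - 1L) %/% 6L %% 20L + 1L,
                (seq_len(cfg$n_reactions) - 1L) %/% 120L %% 20L + 1L,
                seq_len(cfg$n_reactions))
  substrate <- sprintf("substrate%04d", seq_len(cfg$n_reactions))

  org_idx <- with_seed(substream_seed(cfg$seed, 4),
                       unlist(lapply(nv, function(k) sample.int(cfg$n_organisms, k))))
  rx_of_variant <- rep(seq_len(cfg$n_reactions), nv)
  t_var <- t_org[org_idx]
  log10k_expected <- mu[rx_of_variant] + cfg$beta * t_var

  n_variants <- length(org_idx)
  n_meas <- with_seed(substream_seed(cfg$seed, 5), {
    extra <- ifelse(stats::runif(n_variants) < cfg$replicate_rate,
                    sample(1:2, n_variants, replace = TRUE), 0L)
    1L + extra
  })
  var_of_meas <- rep(seq_len(n_variants), n_meas)
  eps <- with_seed(substream_seed(cfg$seed, 6),
                   stats::rnorm(length(var_of_meas), 0, cfg$sigma_noise))
  value <- 10^(log10k_expected[var_of_meas] + eps)
  rx_of_meas <- rx_of_variant[var_of_meas]

  wt <- data.frame(ec_number = ec[rx_of_meas],
                   substrate = substrate[rx_of_meas],
                   organism = organisms[org_idx[var_of_meas]],
                   value = value,
                   variant_status = "wild_type",
                   stringsAsFactors = FALSE)

  # contamination: wild-type rows from organisms without a curated T_Growth
  n_wt <- nrow(wt)
  n_un <- round(n_wt * cfg$unmatched_rate / (1 - cfg$unmatched_rate))
  if (n_un > 0) {
    un <- with_seed(substream_seed(cfg$seed, 7), {
      rx <- sample.int(cfg$n_reactions, n_un, replace = TRUE)
      data.frame(ec_number = ec[rx], substrate = substrate[rx],
                 organism = sprintf("Incognita absentis%04d",
                                    sample.int(max(n_un, 50L), n_un, replace = TRUE)),
                 value = 10^(mu[rx] + stats::rnorm(n_un, 0, cfg$sigma_reaction)),
                 variant_status = "wild_type", stringsAsFactors = FALSE)
    })
    wt <- rbind(wt, un)
  }

  # mutant rows (filtered out by curation)
  n_mut <- round(nrow(wt) * cfg$mutant_rate / (1 - cfg$mutant_rate))
  ent <- wt
  if (n_mut > 0) {
    mut <- with_seed(substream_seed(cfg$seed, 8), {
      src <- sample.int(nrow(wt), n_mut, replace = TRUE)
      m <- wt[src, , drop = FALSE]
      m$value <- m$value * 10^stats::rnorm(n_mut, 0, 0.5)
      m$variant_status <- "mutant"
      m
    })
    ent <- rbind(ent, mut)
  }

  ent$assay_temperature_C <- with_seed(substream_seed(cfg$seed, 9),
    sample(c(25, 37, NA_real_), nrow(ent), replace = TRUE, prob = c(0.3, 0.4, 0.3)))
  ent$entry_id <- sprintf("syn%06d", seq_len(nrow(ent)))
  ent$value_type <- cfg$value_type
  ent <- ent[, c("entry_id", "ec_number", "substrate", "organism", "value",
                 "value_type", "variant_status", "assay_temperature_C")]
  rownames(ent) <- NULL

  t_growth <- data.frame(organism = organisms, t_growth_C = t_org,
                         stringsAsFactors = FALSE)
  truth <- list(config = cfg,
                reactions = data.frame(ec_number = ec, substrate = substrate,
                                       mu = mu, beta = cfg$beta, n_variants = nv,
                                       stringsAsFactors = FALSE),
                variants = data.frame(ec_number = ec[rx_of_variant],
                                      substrate = substrate[rx_of_variant],
                                      organism = organisms[org_idx],
                                      t_growth_C = t_var,
                                      log10_k_expected = log10k_expected,
                                      n_measurements = n_meas,
                                      stringsAsFactors = FALSE))
  list(entries = ent, t_growth = t_growth, truth = truth)
}

#' Generate reactions whose variants share one growth temperature
#'
#' Exercises the same-T_Growth control path in isolation: every generated
#' reaction has all variants at a single growth temperature, with rates
#' spanning exactly the factor `k_spread` (so a two-variant reaction yields
#' the control pair `(k_spread, 1/k_spread)`), and therefore contributes
#' nothing to the cold/warm ratio analysis.
#'
#' @param config a [kinetic_sim_config()] (n_reactions, pool and seed are
#'   used; slope and noise parameters are irrelevant here).
#' @param k_spread ratio of the largest to smallest rate within each
#'   reaction, `>= 1`.
#' @param variants_per_reaction number of variants per reaction (default 2).
#' @return List with `entries` and `t_growth` as in
#'   [generate_kinetic_dataset()].
#' @export
generate_same_temperature_variants <- function(config, k_spread,
                                               variants_per_reaction = 2L) {
  stopifnot(inherits(config, "kinetic_sim_config"),
            is_scalar_number(k_spread), k_spread >= 1,
            variants_per_reaction >= 2L)
  cfg <- config
  nv <- as.integer(variants_per_reaction)
  # organisms are unique per reaction here: each must carry exactly its
  # reaction's shared temperature in the companion table
  res <- with_seed(substream_seed(cfg$seed, 21), {
    t_rx <- draw_t_growth(cfg$n_reactions, cfg$t_growth_range_C, cfg$t_resolution_C)
    rows <- lapply(seq_len(cfg$n_reactions), function(r) {
      base <- 10^stats::rnorm(1, 0, cfg$sigma_reaction)
      # rates span exactly k_spread: endpoints fixed, interior log-uniform
      lk <- if (nv == 2L) c(0, log10(k_spread))
            else c(0, log10(k_spread),
                   stats::runif(nv - 2L, 0, log10(k_spread)))
      data.frame(ec_number = sprintf("9.9.9.%d", r),
                 substrate = sprintf("ctrlsub%04d", r),
                 organism = sprintf("Aequitherma ctrl%04dv%d", r, seq_len(nv)),
                 value = base * 10^lk,
                 t_rx = t_rx[r],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  ent <- data.frame(entry_id = sprintf("ctl%06d", seq_len(nrow(res))),
                    ec_number = res$ec_number, substrate = res$substrate,
                    organism = res$organism, value = res$value,
                    value_type = cfg$value_type, variant_status = "wild_type",
                    assay_temperature_C = NA_real_, stringsAsFactors = FALSE)
  t_growth <- data.frame(organism = res$organism, t_growth_C = res$t_rx,
                         stringsAsFactors = FALSE)
  list(entries = ent, t_growth = t_growth)
}

#' Configuration for the synthetic stability dataset
#'
#' Emulates a wild-type protein-stability survey: melting temperatures
#' follow `T_m = a + b * T_Growth + Normal(0, sigma)` across proteins, with
#' a designated number of protein families carrying both a cold- and a
#' warm-adapted member. The default slope, intercept and noise are chosen
#' so that the variance explained by growth temperature is comparable to
#' published wild-type Tm surveys (about 40%).
#'
#' @param n_proteins total number of stability records.
#' @param families_with_pairs number of families given a cold and a warm
#'   member (each family contributes two of the `n_proteins` records).
#' @param slope_b true slope, degC Tm per degC T_Growth.
#' @param intercept_a true intercept, degC.
#' @param sigma residual standard deviation of Tm, degC.
#' @param t_growth_range_C growth-temperature interval.
#' @param t_resolution_C temperature grid spacing.
#' @param seed integer seed.
#' @return A validated config list of class `"stability_sim_config"`.
#' @export
stability_sim_config <- function(n_proteins = 433, families_with_pairs = 43,
                                 slope_b = 0.4, intercept_a = 45, sigma = 11,
                                 t_growth_range_C = c(1, 83),
                                 t_resolution_C = 1, seed = 1L) {
  stopifnot(is_scalar_number(n_proteins), n_proteins >= 3,
            is_scalar_number(families_with_pairs), families_with_pairs >= 0,
            2 * families_with_pairs <= n_proteins,
            is_scalar_number(slope_b), is_scalar_number(intercept_a),
            is_scalar_number(sigma), sigma >= 0,
            is.numeric(t_growth_range_C), length(t_growth_range_C) == 2L,
            t_growth_range_C[1] < t_growth_range_C[2],
            is_scalar_number(seed))
  structure(list(n_proteins = as.integer(n_proteins),
                 families_with_pairs = as.integer(families_with_pairs),
                 slope_b = slope_b, intercept_a = intercept_a, sigma = sigma,
                 t_growth_range_C = t_growth_range_C,
                 t_resolution_C = t_resolution_C,
                 seed = as.integer(seed)),
            class = "stability_sim_config")
}

#' Generate a synthetic protein-stability dataset with ground truth
#'
#' @param config a [stability_sim_config()].
#' @return List with `records` (wild-type stability rows: `protein_name`,
#'   `organism`, `mutation`, `t_m_C`), `t_growth` (organism table), and
#'   `truth` (config echo plus each record's true expected Tm).
#' @export
generate_stability_dataset <- function(config) {
  stopifnot(inherits(config, "stability_sim_config"))
  cfg <- config
  n_fam_members <- 2L * cfg$families_with_pairs
  n_single <- cfg$n_proteins - n_fam_members

  out <- with_seed(substream_seed(cfg$seed, 31), {
    organisms <- sprintf("Stabilis organismus%04d", seq_len(cfg$n_proteins))
    mid <- mean(cfg$t_growth_range_C)
    # family pairs: cold member from the lower half, warm from the upper,
    # so every family has a genuine cold/warm contrast
    t_cold <- draw_t_growth(cfg$families_with_pairs,
                            c(cfg$t_growth_range_C[1], mid), cfg$t_resolution_C)
    t_warm <- draw_t_growth(cfg$families_with_pairs,
                            c(mid + cfg$t_resolution_C, cfg$t_growth_range_C[2]),
                            cfg$t_resolution_C)
    t_single <- draw_t_growth(n_single, cfg$t_growth_range_C, cfg$t_resolution_C)
    tg <- c(rbind(t_cold, t_warm), t_single)
    protein <- c(rep(sprintf("family%03d protein", seq_len(cfg$families_with_pairs)),
                     each = 2L),
                 sprintf("singleton%04d protein", seq_len(n_single)))
    tm_expected <- cfg$intercept_a + cfg$slope_b * tg
    tm <- tm_expected + stats::rnorm(cfg$n_proteins, 0, cfg$sigma)
    list(records = data.frame(protein_name = protein, organism = organisms,
                              mutation = "wild_type", t_m_C = tm,
                              stringsAsFactors = FALSE),
         t_growth = data.frame(organism = organisms, t_growth_C = tg,
                               stringsAsFactors = FALSE),
         tm_expected = tm_expected)
  })
  truth <- list(config = cfg, tm_expected = out$tm_expected,
                t_growth_C = out$t_growth$t_growth_C)
  list(records = out$records, t_growth = out$t_growth, truth = truth)
}

#' Generate a synthetic Michaelis-Menten initial-rate series
#'
#' `v_i = k_cat * E * S_i / (K_M + S_i) * (1 + Normal(0, noise_cv))`,
#' truncated just above zero so velocities stay positive.
#'
#' @param k_cat true turnover number, 1/s.
#' @param K_M true Michaelis constant, uM.
#' @param enzyme_conc enzyme concentration, M.
#' @param substrate_concs substrate concentrations, uM (default the
#'   9-600 uM span typical of such assays).
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed integer seed.
#' @return An [initial_rate_series()].
#' @export
generate_mm_series <- function(k_cat, K_M, enzyme_conc,
                               substrate_concs = c(9, 25, 50, 100, 300, 600),
                               noise_cv = 0, seed = 1L) {
  stopifnot(is_scalar_number(k_cat), k_cat > 0,
            is_scalar_number(K_M), K_M > 0,
            is_scalar_number(enzyme_conc), enzyme_conc > 0,
            is.numeric(substrate_concs), all(substrate_concs > 0),
            is_scalar_number(noise_cv), noise_cv >= 0)
  v0 <- k_cat * enzyme_conc * substrate_concs / (K_M + substrate_concs)
  v <- with_seed(substream_seed(seed, 41),
                 v0 * pmax(1 + stats::rnorm(length(v0), 0, noise_cv), 1e-6))
  initial_rate_series(substrate_concs, v, enzyme_conc)
}
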