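# Independent oracles used to validate the package's statistical routines.
# Each is a deliberately naive, brute-force computation that shares no code
# with the implementation it checks.

# Closed-form two-parameter OLS: slope, intercept, R^2 and the two-sided
# t-test p-value for zero slope, from the textbook sums.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- syy - slope * sxy
  r2 <- if (syy == 0) NA_real_ else 1 - ss_res / syy
  se <- sqrt(ss_res / (n - 2) / sxx)
  p <- if (se == 0) 0 else 2 * stats::pt(-abs(slope / se), df = n - 2)
  list(slope = slope, intercept = intercept, r_squared = r2, p_value = p)
}

# Exhaustive Mann-Whitney oracle: enumerate every assignment of the pooled
# ranks to the first sample (no ties assumed), build the full null
# distribution of U, and compute the two-sided p as 2 * P(U <= min(u, n1n2-u))
# capped at 1. Feasible for n1 + n2 <= ~12.
mw_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_u <- apply(utils::combn(n1 + n2, n1), 2,
                 function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  u_low <- min(u_obs, n1 * n2 - u_obs)
  p <- min(1, 2 * mean(all_u <= u_low))
  list(u = u_obs, p = p)
}

# Exhaustive bootstrap oracle for n = 3: all 27 equally likely resamples.
bootstrap_enum_oracle_n3 <- function(values, conf = 0.95) {
  stopifnot(length(values) == 3L)
  grid <- expand.grid(i = 1:3, j = 1:3, k = 1:3)
  meds <- apply(grid, 1, function(r) stats::median(values[as.integer(r)]))
  a <- (1 - conf) / 2
  # exact quantiles of the enumerated median distribution (inverse ECDF)
  c(stats::quantile(meds, a, type = 1, names = FALSE),
    stats::quantile(meds, 1 - a, type = 1, names = FALSE))
}

# Dense grid search + bisection refinement for the Michaelis-Menten fit,
# independent of any derivative-based optimiser.
mm_grid_oracle <- function(S, v, E, kcat_range, km_range, n_grid = 120, refine = 25) {
  sse <- function(kcat, km) sum((v - kcat * E * S / (km + S))^2)
  kc <- exp(seq(log(kcat_range[1]), log(kcat_range[2]), length.out = n_grid))
  km <- exp(seq(log(km_range[1]), log(km_range[2]), length.out = n_grid))
  errs <- outer(kc, km, Vectorize(sse))
  best <- arrayInd(which.min(errs), dim(errs))
  b_kc <- kc[best[1]]; b_km <- km[best[2]]
  # coordinate-wise interval bisection around the grid optimum
  w_kc <- diff(log(kcat_range)) / n_grid
  w_km <- diff(log(km_range)) / n_grid
  for (it in seq_len(refine)) {
    for (d in c(1, -1)) {
      cand <- b_kc * exp(d * w_kc)
      if (sse(cand, b_km) < sse(b_kc, b_km)) b_kc <- cand
      cand <- b_km * exp(d * w_km)
      if (sse(b_kc, cand) < sse(b_kc, b_km)) b_km <- cand
    }
    w_kc <- w_kc / 2; w_km <- w_km / 2
  }
  list(k_cat = b_kc, K_M = b_km, rmse = sqrt(sse(b_kc, b_km) / length(S)))
}

# Small fixture writers used across the io tests.
write_kinetic_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

kinetic_row <- function(entry_id = "e1", ec_number = "1.1.1.1",
                        substrate = "ethanol", organism = "Escherichia coli",
                        value = "10", value_type = "kcat",
                        variant_status = "wild_type",
                        assay_temperature_C = "25") {
  data.frame(entry_id = entry_id, ec_number = ec_number, substrate = substrate,
             organism = organism, value = value, value_type = value_type,
             variant_status = variant_status,
             assay_temperature_C = assay_temperature_C,
             stringsAsFactors = FALSE)
}

# Minimal reaction table (bypassing file IO) for statistics tests.
make_reactions <- function(df, value_type = "kcat") {
  df$organism_normalized <- df$organism
  df$value_type <- value_type
  df$assay_temperature_C <- df$assay_temperature_C %||% NA_real_
  coldcomp::build_reactions(df, value_type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
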