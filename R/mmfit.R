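# Michaelis-Menten fitting of initial-rate series, as used to determine
# per-variant kcat and KM from spectrophotometric assays at a common
# temperature.

#' Construct an initial-rate series
#'
#' One enzyme variant's initial velocities across substrate concentrations
#' at fixed enzyme concentration. At least four distinct substrate
#' concentrations are required for the two-parameter fit to be meaningfully
#' constrained (assays typically span six to seven).
#'
#' @param substrate_conc substrate concentrations, uM, all positive.
#' @param velocity initial velocities, M/s, all positive.
#' @param enzyme_conc enzyme concentration, M, positive scalar.
#' @param variant_label,organism,t_growth_C optional metadata carried along
#'   so fitted constants can feed the slope analysis directly.
#' @return An object of class `"initial_rate_series"`.
#' @export
initial_rate_series <- function(substrate_conc, velocity, enzyme_conc,
                                variant_label = "", organism = "",
                                t_growth_C = NA_real_) {
  stopifnot(is.numeric(substrate_conc), is.numeric(velocity),
            length(substrate_conc) == length(velocity),
            all(substrate_conc > 0), all(velocity > 0),
            is_scalar_number(enzyme_conc), enzyme_conc > 0)
  if (length(unique(substrate_conc)) < 4L)
    stopf("need at least 4 distinct substrate concentrations (got %d)",
          length(unique(substrate_conc)))
  structure(list(substrate_conc = as.numeric(substrate_conc),
                 velocity = as.numeric(velocity),
                 enzyme_conc = enzyme_conc,
                 variant_label = variant_label, organism = organism,
                 t_growth_C = t_growth_C),
            class = "initial_rate_series")
}

#' Fit the Michaelis-Menten equation to an initial-rate series
#'
#' Nonlinear least squares of `v = kcat * [E] * [S] / (KM + [S])` with both
#' parameters log-parameterised (hence constrained positive). Starting
#' values are `kcat0 = max(v)/[E]` and `KM0` the substrate concentration
#' nearest half-maximal velocity. Non-convergence or an unidentifiable fit
#' (KM driven far outside the assayed concentration range, as when all
#' velocities are saturated) is reported through `converged = FALSE`, never
#' raised and never returned as a silently plausible KM.
#'
#' @param series an [initial_rate_series()].
#' @return An object of class `"mm_fit"`: `k_cat` (1/s), `K_M` (uM),
#'   `k_cat_over_km` (1/M/s, i.e. `k_cat / (K_M * 1e-6)`), `fit_rmse`,
#'   `converged`, `n_points`, plus the series and fitted values. Supports
#'   `print()`, `coef()`, `predict()`, `residuals()`.
#' @examples
#' S <- c(9, 25, 50, 100, 300, 600)
#' v <- 10 * 1e-8 * S / (100 + S)
#' fit_michaelis_menten(initial_rate_series(S, v, 1e-8))
#' @export
fit_michaelis_menten <- function(series) {
  stopifnot(inherits(series, "initial_rate_series"))
  S <- series$substrate_conc
  v <- series$velocity
  E <- series$enzyme_conc

  kcat0 <- max(v) / E
  km0 <- S[which.min(abs(v - max(v) / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ exp(lkcat) * E * S / (exp(lkm) + S),
                      start = list(lkcat = log(kcat0), lkm = log(km0)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(structure(list(k_cat = NA_real_, K_M = NA_real_,
                          k_cat_over_km = NA_real_, fit_rmse = NA_real_,
                          converged = FALSE, n_points = length(S),
                          series = series, fitted = rep(NA_real_, length(S))),
                     class = "mm_fit"))
  }
  est <- exp(stats::coef(fit))
  k_cat <- unname(est["lkcat"])
  K_M <- unname(est["lkm"])
  fitted_v <- as.numeric(stats::fitted(fit))
  rmse <- sqrt(mean((v - fitted_v)^2))
  # identifiability guard: KM pushed far outside the assayed range means the
  # data do not constrain it (e.g. fully saturated series)
  identifiable <- K_M > min(S) * 1e-3 && K_M < max(S) * 1e3
  structure(list(k_cat = k_cat, K_M = K_M,
                 k_cat_over_km = k_cat / (K_M * 1e-6),
                 fit_rmse = rmse,
                 converged = isTRUE(fit$convInfo$isConv) && identifiable,
                 n_points = length(S),
                 series = series, fitted = fitted_v),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!x$converged) cat("Michaelis-Menten fit: NOT converged/identifiable\n")
  cat(sprintf("kcat = %.4g 1/s, KM = %.4g uM, kcat/KM = %.4g 1/M/s (RMSE %.3g, n = %d)\n",
              x$k_cat, x$K_M, x$k_cat_over_km, x$fit_rmse, x$n_points))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(k_cat = object$k_cat, K_M = object$K_M)
}

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$series$substrate_conc
       else if (is.data.frame(newdata)) newdata$substrate_conc
       else as.numeric(newdata)
  object$k_cat * object$series$enzyme_conc * S / (object$K_M + S)
}

#' @export
residuals.mm_fit <- function(object, ...) {
  object$series$velocity - object$fitted
}

#' Aggregate replicate Michaelis-Menten fits
#'
#' Reported kinetic constants are conventionally the mean over independent
#' experiments with the sample standard deviation (n - 1 denominator) as the
#' error. Non-converged fits are excluded.
#'
#' @param fits list of `mm_fit` objects (at least one converged).
#' @return List with `k_cat_mean`, `k_cat_sd`, `K_M_mean`, `K_M_sd`, `n`;
#'   with a single replicate the standard deviations are reported as 0 and
#'   `n = 1` flags it.
#' @export
aggregate_replicates <- function(fits) {
  if (inherits(fits, "mm_fit")) fits <- list(fits)
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(fits)) stopf("no converged fits to aggregate")
  kc <- vapply(fits, `[[`, numeric(1), "k_cat")
  km <- vapply(fits, `[[`, numeric(1), "K_M")
  n <- length(fits)
  list(k_cat_mean = mean(kc),
       k_cat_sd = if (n > 1L) stats::sd(kc) else 0,
       K_M_mean = mean(km),
       K_M_sd = if (n > 1L) stats::sd(km) else 0,
       n = n)
}
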