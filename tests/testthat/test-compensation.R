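test_that("rate ratio uses extreme-temperature medians and needs spread", {
  expect_equal(rate_ratio(data.frame(t_growth_C = c(10, 40), k = c(5, 5)))$ratio, 1)
  rr <- rate_ratio(data.frame(t_growth_C = c(5, 5, 50), k = c(2, 8, 4)))
  expect_equal(rr$k_cold, 5)  # median of the two cold variants
  expect_equal(rr$k_warm, 4)
  expect_equal(rr$ratio, 1.25)
  expect_equal(rr$t_cold_C, 5)
  expect_equal(rr$t_warm_C, 50)
  expect_null(rate_ratio(data.frame(t_growth_C = rep(30, 3), k = c(1, 2, 3))))
})

test_that("reflecting the temperature axis reciprocates the rate ratio", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    m <- data.frame(t_growth_C = sample(seq(0, 80, 5), n), k = rlnorm(n))
    if (min(m$t_growth_C) == max(m$t_growth_C)) next
    fwd <- rate_ratio(m)
    rev <- rate_ratio(transform(m, t_growth_C = -t_growth_C))
    expect_equal(fwd$ratio, 1 / rev$ratio)
  }
})

test_that("control fold changes come from shared-temperature groups only", {
  df <- data.frame(
    ec_number = c(rep("1.1.1.1", 3), rep("2.2.2.2", 2), rep("3.3.3.3", 2)),
    substrate = "s",
    organism = c("a b", "c d", "e f", "g h", "i j", "k l", "m n"),
    t_growth_C = c(20, 20, 50, 10, 40, 30, 30),
    value = c(2, 8, 5, 1, 2, 3, 3))
  cc <- control_fold_changes(make_reactions(df))
  cc <- cc[order(cc$ec_number), ]
  expect_equal(nrow(cc), 2L)  # 2.2.2.2 has no shared temperature
  expect_equal(cc$fold_up, c(4, 1))
  expect_equal(cc$fold_down, c(0.25, 1))
  expect_equal(cc$t_growth_C, c(20, 30))
})

test_that("largest shared-temperature group wins, ties to the coldest", {
  df <- data.frame(
    ec_number = "1.1.1.1", substrate = "s",
    organism = c("a b", "c d", "e f", "g h", "i j"),
    t_growth_C = c(10, 10, 40, 40, 40),
    value = c(1, 2, 1, 4, 16))
  cc <- control_fold_changes(make_reactions(df))
  expect_equal(cc$t_growth_C, 40)  # 3 variants beat 2
  expect_equal(cc$fold_up, 16)
  df$t_growth_C <- c(10, 10, 40, 40, 25)
  cc2 <- control_fold_changes(make_reactions(df))
  expect_equal(cc2$t_growth_C, 10)  # tie on size -> lowest temperature
  all_groups <- control_fold_changes(make_reactions(df), groups = "all")
  expect_equal(nrow(all_groups), 2L)
})

test_that("the flattened control multiset has median 1", {
  for (seed in 1:5) {
    d <- generate_kinetic_dataset(kinetic_sim_config(n_reactions = 150, seed = seed))
    rx <- curate_entries(d$entries, d$t_growth)
    cc <- control_fold_changes(rx)
    if (nrow(cc) < 2) next
    flat <- c(cc$fold_up, cc$fold_down)
    expect_equal(exp(median(log(flat))), 1, tolerance = 1e-12)
    expect_true(all(cc$fold_up >= 1))
    expect_equal(cc$fold_down, 1 / cc$fold_up)
  }
})

test_that("compare_to_control partitions ratios and handles the degenerate case", {
  ratios <- data.frame(ratio = rep(1, 6))
  controls <- data.frame(fold_up = rep(1, 4), fold_down = rep(1, 4))
  cmp <- compare_to_control(ratios, controls, reps = 200, seed = 1)
  expect_equal(cmp$data_summary$median, 1)
  expect_equal(cmp$control_summary$median, 1)
  expect_equal(cmp$utest$u_statistic, 6 * 8 / 2)
  expect_equal(cmp$n_equal_one, 6)
  expect_error(compare_to_control(ratios[0, , drop = FALSE], controls,
                                  reps = 10, seed = 1), "empty")

  d <- generate_kinetic_dataset(kinetic_sim_config(n_reactions = 120, seed = 8))
  rx <- curate_entries(d$entries, d$t_growth)
  cmp2 <- compare_to_control(rate_ratios(rx), control_fold_changes(rx),
                             reps = 300, seed = 4)
  expect_equal(cmp2$n_above_one + cmp2$n_below_one + cmp2$n_equal_one,
               cmp2$n_data)
  expect_equal(cmp2$control_summary$median, 1, tolerance = 1e-12)
  s <- summary(cmp2)
  expect_equal(s$p_two_sided, cmp2$utest$p_two_sided)
})

test_that("reaction slopes match the hand-derived OLS examples", {
  exact <- fit_reaction_slope(data.frame(t_growth_C = c(10, 20, 30),
                                         k = 10^c(1.0, 0.8, 0.6)))
  expect_equal(exact$m_rate, -0.02, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-9)

  noisy <- fit_reaction_slope(data.frame(t_growth_C = c(10, 20, 30),
                                         k = 10^c(1.0, 0.9, 0.6)))
  expect_equal(noisy$m_rate, -0.02, tolerance = 1e-12)  # Sxy/Sxx = -4/200
  expect_equal(noisy$r_squared, 12 / 13, tolerance = 1e-12)

  expect_null(fit_reaction_slope(data.frame(t_growth_C = c(10, 40), k = c(1, 2))))
  expect_null(fit_reaction_slope(data.frame(t_growth_C = rep(25, 4), k = 1:4)))
})

test_that("slope fits agree with the closed-form OLS solution", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    t <- runif(n, 0, 80)
    k <- 10^(rnorm(1) - 0.01 * t + rnorm(n, 0, 0.4))
    got <- fit_reaction_slope(data.frame(t_growth_C = t, k = k))
    want <- ols_oracle(t, log10(k))
    expect_equal(got$m_rate, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  }
})

test_that("slope screening applies the Bonferroni threshold and splits by sign", {
  slopes <- data.frame(ec_number = letters[1:4], substrate = "s",
                       m_rate = c(-0.03, 0.04, -0.001, 0.002),
                       intercept = 0, r_squared = 0.5,
                       p_value = c(1e-8, 1e-7, 0.2, 0.9), n = 5L)
  sc <- screen_slopes(slopes, alpha = 0.05)
  expect_equal(attr(sc, "threshold"), 0.05 / 4)
  expect_equal(sc$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(attr(sc, "n_significant_negative"), 1L)
  expect_equal(attr(sc, "n_significant_positive"), 1L)
})
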