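mk_table <- function(values_by_group, cycles = c(60, 120, 180)) {
  rows <- do.call(rbind, lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    expand.grid(specimen = seq_along(v), pin_group = g, cycle = cycles,
                stringsAsFactors = FALSE)
  }))
  rows$response <- unlist(lapply(names(values_by_group), function(g)
    rep(values_by_group[[g]], times = length(cycles))))
  measurement_table(rows)
}

test_that("group summaries use sample SD and reject degenerate groups", {
  tb <- mk_table(list(three = c(1, 2, 3), two = c(4, 5, 6)), cycles = 60)
  s <- summarize_groups(tb)
  expect_equal(s$mean[s$pin_group == "three"], 2)
  expect_equal(s$sd[s$pin_group == "three"], 1)

  one_obs <- measurement_table(data.frame(specimen = 1, pin_group = "one",
                                          cycle = 60, response = 2))
  expect_error(summarize_groups(one_obs), class = "torsionrig_data_error")

  # specimen-level aggregation averages cycles first
  tb2 <- measurement_table(data.frame(
    specimen = rep(1:2, each = 2), pin_group = "two",
    cycle = rep(c(60, 120), 2), response = c(1, 3, 5, 7)))
  s2 <- summarize_groups(tb2, by_specimen = TRUE)
  expect_equal(s2$n, 2L)
  expect_equal(s2$mean, 4)   # specimen means 2 and 6
  expect_equal(s2$sd, sd(c(2, 6)))

  expect_error(measurement_table(data.frame(specimen = 1, pin_group = "four",
                                            cycle = 60, response = 1)),
               class = "torsionrig_data_error")
})

test_that("mixed model reduces to OLS with no grouping variance and recovers effects", {
  # responses determined by fixed effects only: lmer (singular) == lm
  tb <- simulate_measurements(group_effects = c(three = 0, two = 1, one = 2),
                              specimen_sd = 0, sigma = 0.3, seed = 21)
  m <- fit_mixed_model(tb)
  ols <- lm(response ~ pin_group + cycle,
            data = transform(tb,
                             pin_group = factor(pin_group,
                                                c("three", "two", "one")),
                             cycle = factor(cycle, c("60", "120", "180"))))
  expect_equal(unname(m$fixed$estimate), unname(coef(ols)), tolerance = 1e-6)
  expect_true(m$singular)
  expect_named(m$p_fixed, c("pin_group", "cycle"))

  # strong effect is detected; absent cycle effect is not
  expect_lt(m$p_fixed[["pin_group"]], 1e-6)
  expect_gt(m$p_fixed[["cycle"]], 0.05)

  expect_error(fit_mixed_model(mk_table(list(three = 1:5), cycles = 60)),
               class = "torsionrig_data_error")
})

test_that("mixed-model estimates are invariant to specimen relabeling", {
  tb <- simulate_measurements(group_effects = c(three = 0, two = 0.5, one = 2),
                              specimen_sd = 1, sigma = 0.4, seed = 31)
  m1 <- fit_mixed_model(tb)
  tb2 <- tb
  perm <- sample(seq_len(12))
  tb2$specimen <- paste0("bone_", perm[tb$specimen])
  m2 <- fit_mixed_model(tb2)
  expect_equal(m1$fixed$estimate, m2$fixed$estimate, tolerance = 1e-6)
  expect_equal(m1$p_fixed, m2$p_fixed, tolerance = 1e-6)
})

test_that("marker random intercept is included for motion tables", {
  tb <- simulate_measurements(group_effects = c(three = 0, two = 0, one = 2),
                              n_markers = 4, marker_sd = 0.8, seed = 41)
  m <- fit_mixed_model(tb)
  expect_true(all(c("specimen", "marker") %in% names(m$ranef_variances)))
  expect_named(m$p_random, c("specimen", "marker"))
})

test_that("pairwise comparisons are gated, paired and optionally adjusted", {
  tb <- simulate_measurements(group_effects = c(three = 0, two = 1.5, one = 3),
                              specimen_sd = 1, sigma = 0.3, seed = 51)
  res <- pairwise_group_tests(tb)
  expect_equal(nrow(res), 3L)
  expect_lt(res$p_value[res$group_a == "three" & res$group_b == "one"], 0.001)
  expect_true(is.finite(attr(res, "overall_p")))

  # groups separated by 5 SD are overwhelmingly significant
  tb5 <- simulate_measurements(group_effects = c(three = 0, two = 0, one = 5),
                               specimen_sd = 0.5, sigma = 1, seed = 52)
  res5 <- pairwise_group_tests(tb5, force = TRUE)
  expect_lt(res5$p_value[res5$group_b == "one" & res5$group_a == "three"], 1e-3)

  # identical groups: the gate rejects (null p-value above alpha)
  tb0 <- simulate_measurements(seed = 53)
  expect_error(pairwise_group_tests(tb0), class = "torsionrig_estimation_error")

  # null simulation: unadjusted pairwise p > 0.05 in most replicates
  null_sig <- vapply(1:40, function(i) {
    t0 <- simulate_measurements(seed = 600 + i)
    any(pairwise_group_tests(t0, force = TRUE)$p_value < 0.05)
  }, logical(1))
  expect_gte(mean(!null_sig), 0.75)

  # holm adjustment never decreases p-values
  r_none <- pairwise_group_tests(tb, force = TRUE, p_adjust = "none")
  r_holm <- pairwise_group_tests(tb, force = TRUE, p_adjust = "holm")
  expect_true(all(r_holm$p_value >= r_none$p_value - 1e-12))

  solo <- measurement_table(data.frame(
    specimen = 1, pin_group = rep(c("three", "two", "one"), each = 3),
    cycle = rep(c(60, 120, 180), 3), response = rnorm(9)))
  expect_error(pairwise_group_tests(solo, force = TRUE),
               class = "torsionrig_data_error")

  # unmatched specimens are rejected in paired mode
  tb_un <- tb[!(tb$specimen == 1 & tb$pin_group == "one"), ]
  expect_error(pairwise_group_tests(measurement_table(tb_un), force = TRUE),
               class = "torsionrig_data_error")
})

test_that("system comparison returns the Welch p-value and pooled-mean ratio", {
  same <- c(1, 2, 3, 4)
  expect_equal(compare_systems(same, same)$ratio, 1.0)
  cs <- compare_systems(c(6.64, 7.81, 9.74), c(2.34, 2.75, 4.22))
  expect_equal(round(cs$ratio, 2), 2.60)
  expect_error(compare_systems(rep(1, 3), rep(2, 3)),
               class = "torsionrig_degenerate_error")
  expect_error(compare_systems(1, c(1, 2)), class = "torsionrig_data_error")
})

test_that("ratio and percentage arithmetic matches the printed conventions", {
  expect_equal(round(ratio_and_percent(4.22, 2.75, "ratio"), 2), 1.53)
  expect_equal(ratio_and_percent(3.3, 3.3, "ratio"), 1.0)
  expect_equal(round(ratio_and_percent(2.75, 2.34, "percent_decrease_of_larger"), 2),
               14.91)
  # symmetric in argument order
  expect_equal(ratio_and_percent(2.34, 2.75, "percent_decrease_of_larger"),
               ratio_and_percent(2.75, 2.34, "percent_decrease_of_larger"))
  expect_error(ratio_and_percent(1, 0, "ratio"), class = "torsionrig_config_error")
})

test_that("implant area fraction is exact and scale-invariant", {
  a <- implant_area_fraction(3, 3.0, 30)
  expect_equal(round(a$combined_area), 21)
  expect_equal(a$fraction, 3.0)
  z <- implant_area_fraction(0, 3.0, 30)
  expect_equal(z$combined_area, 0)
  expect_equal(z$fraction, 0)
  expect_equal(implant_area_fraction(1, 3.0, 30)$fraction, 1.0)
  # rescaling both diameters leaves the fraction unchanged
  expect_equal(implant_area_fraction(2, 3.0, 30)$fraction,
               implant_area_fraction(2, 6.0, 60)$fraction)
  expect_warning(implant_area_fraction(1, 30, 30), "physis")
})
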