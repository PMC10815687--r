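ctrl_aj <- control_frequencies(1259, 4912)

test_that("Hardy-Weinberg genotype expectations are exact", {
  g <- hwe_genotype_freqs(1259 / 4912)
  expect_equal(unname(g["noncarrier"]), (1 - 1259 / 4912)^2)
  expect_equal(sum(g), 1)
  expect_equal(round(hwe_carrier_freq(1259 / 4912), 4), 0.4469)
  expect_equal(round(100 * hwe_carrier_freq(1259 / 4912), 1), 44.7)

  expect_identical(unname(hwe_genotype_freqs(0)), c(1, 0, 0))
  expect_equal(unname(hwe_genotype_freqs(0.5)), c(0.25, 0.5, 0.25))
  expect_error(hwe_genotype_freqs(1.3), "\\[0, 1\\]")
})

test_that("the Woolf odds-ratio test reproduces the published allele contrast", {
  res <- odds_ratio_test(assoc_2x2(515, 1885, 1259, 3653))
  expect_equal(round(res$odds_ratio, 3), 0.793)
  expect_equal(round(res$ci_low, 3), 0.705)
  expect_equal(round(res$ci_high, 3), 0.891)
  expect_lt(res$p_value, 0.001)

  eq <- odds_ratio_test(assoc_2x2(10, 90, 10, 90))
  expect_equal(eq$odds_ratio, 1)
  expect_lt(eq$ci_low, 1); expect_gt(eq$ci_high, 1)
})

test_that("odds-ratio arithmetic matches a direct hand computation", {
  res <- odds_ratio_test(assoc_2x2(2, 8, 5, 5))
  or <- (2 / 8) / (5 / 5)
  se <- sqrt(1 / 2 + 1 / 8 + 1 / 5 + 1 / 5)
  expect_equal(res$odds_ratio, or)
  expect_equal(res$ci_low, or * exp(-qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(res$ci_high, or * exp(qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pnorm(log(or) / se), tolerance = 1e-12)

  expect_error(odds_ratio_test(assoc_2x2(0, 8, 5, 5)), "case_exposed")
  h <- odds_ratio_test(assoc_2x2(0, 8, 5, 5), haldane = TRUE)
  expect_true(is.finite(h$odds_ratio))
})

test_that("swapping rows inverts the odds ratio and scaling shifts only the CI", {
  a <- odds_ratio_test(assoc_2x2(12, 34, 56, 78))
  b <- odds_ratio_test(assoc_2x2(56, 78, 12, 34))
  expect_equal(a$odds_ratio, 1 / b$odds_ratio, tolerance = 1e-12)
  expect_equal(a$ci_low, 1 / b$ci_high, tolerance = 1e-12)
  expect_equal(a$ci_high, 1 / b$ci_low, tolerance = 1e-12)

  big <- odds_ratio_test(assoc_2x2(120, 340, 560, 780))
  expect_equal(big$odds_ratio, a$odds_ratio, tolerance = 1e-12)
  expect_lt(big$ci_high - big$ci_low, a$ci_high - a$ci_low)
  small <- odds_ratio_test(assoc_2x2(1.2, 3.4, 5.6, 7.8))
  expect_gt(small$ci_high - small$ci_low, a$ci_high - a$ci_low)
})

test_that("genetic-model tables are assembled per contract", {
  # allelic: 515 alt of 2400 case alleles vs 1259/4912 control alleles
  tab <- model_tables(c(725, 435, 40), ctrl_aj, "allelic")
  expect_equal(unlist(tab[, -1]),
               c(case_exposed = 515, case_unexposed = 1885,
                 control_exposed = 1259, control_unexposed = 3653))

  # recessive closed form: p = 0.5, 100 control individuals
  ctrl_half <- control_frequencies(100, 200)
  rec <- model_tables(c(30, 50, 20), ctrl_half, "recessive")
  expect_equal(rec$control_exposed, 25)
  expect_equal(rec$control_unexposed, 75)

  dom0 <- model_tables(c(10, 5, 5), control_frequencies(0, 100), "dominant")
  expect_equal(dom0$control_exposed, 0)
  expect_error(odds_ratio_test(dom0 |> dplyr::select(-model)),
               "control_exposed")

  expect_error(model_tables(c(1, 1, 1), ctrl_aj, "additive"), "unknown model")
})

test_that("stratified analysis reproduces the printed subgroup contrasts", {
  # case allele counts per stratum, as (n0, n1, n2) summing to the printed
  # alternate-allele totals
  strata_counts <- list(
    all = c(725, 435, 40),     # 515 / 2400
    GBA1 = c(140, 91, 4),      # 99 / 470
    LRRK2 = c(91, 52, 2),      # 56 / 290
    NC = c(470, 289, 28)       # 345 / 1574
  )
  expected_or <- c(all = 0.793, GBA1 = 0.774, LRRK2 = 0.694, NC = 0.815)
  for (s in names(strata_counts)) {
    res <- odds_ratio_test(
      model_tables(strata_counts[[s]], ctrl_aj, "allelic") |>
        dplyr::select(-model))
    expect_equal(round(res$odds_ratio, 3), unname(expected_or[s]))
  }
})

test_that("stratified_association validates subgroups and respects exclusivity", {
  meta <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:8),
    subgroup = c("GBA1", "GBA1", "LRRK2", "dual", "SMPD1", "NC", "NC", "NC"),
    h2_dosage = c(0L, 1L, 1L, 2L, 0L, 0L, 1L, 2L)
  )
  res <- stratified_association(meta, ctrl_aj, models = "allelic")
  expect_identical(res$n_cases[res$stratum == "all"], 8L)
  expect_identical(res$n_cases[res$stratum == "GBA1"], 2L)  # dual excluded
  expect_identical(res$n_cases[res$stratum == "LRRK2"], 1L)

  bad <- meta; bad$subgroup[1] <- "GBA1+LRRK2"
  expect_error(stratified_association(bad, ctrl_aj), "invalid subgroup")
})

test_that("null cohorts give subgroup CIs covering 1 most of the time", {
  covered <- 0L; total <- 0L
  for (i in 1:50) {
    cfg <- clean_config(n_samples = 800, h2_protective_or = 1, seed = 3000 + i,
                        n_divergent_snvs = 6, n_background_snvs = 0,
                        n_indels = 0)
    ch <- simulate_cohort(cfg)
    res <- stratified_association(ch$meta, ctrl_aj, models = "allelic",
                                  strata = c("all", "GBA1", "LRRK2", "NC"))
    ok <- !is.na(res$ci_low)
    covered <- covered + sum(res$ci_low[ok] <= 1 & res$ci_high[ok] >= 1)
    total <- total + sum(ok)
  }
  expect_gte(covered / total, 0.90)
})

test_that("dual-carrier simulation is seeded, bounded and degenerate-safe", {
  s1 <- simulate_dual_carriers(10000, 0.1, 0.447, seed = 4)
  s2 <- simulate_dual_carriers(10000, 0.1, 0.447, seed = 4)
  expect_identical(s1, s2)

  all_mut <- simulate_dual_carriers(500, 1, 0.5, seed = 1)
  expect_identical(all_mut$n_mutation_carriers, 500L)

  big <- simulate_dual_carriers(1e6, 0.1, 0.447, seed = 11)
  dual_frac <- big$n_dual_carriers / big$n_sim
  bound <- 3 * sqrt(0.1 * 0.447 * (1 - 0.1 * 0.447) / 1e6)
  expect_lt(abs(dual_frac - 0.0447), bound)

  expect_error(simulate_dual_carriers(0, 0.1, 0.4), "positive")
  expect_error(simulate_dual_carriers(10, 1.1, 0.4), "\\[0, 1\\]")
})

test_that("dual-carrier test reproduces the published co-occurrence deficits", {
  f <- hwe_carrier_freq(1259 / 4912)
  gba <- dual_carrier_test(86, 235, expected_h2_carrier_freq = f)
  expect_equal(round(gba$odds_ratio, 3), 0.714)
  expect_equal(round(100 * gba$observed_rate, 1), 36.6)

  lrrk <- dual_carrier_test(52, 145, expected_h2_carrier_freq = f)
  expect_equal(round(lrrk$odds_ratio, 3), 0.692)
  expect_equal(round(100 * lrrk$observed_rate, 1), 35.9)

  # observed rate exactly at expectation -> OR 1
  null <- dual_carrier_test(47, 100, expected_h2_carrier_freq = 0.47)
  expect_equal(null$odds_ratio, 1)

  expect_error(dual_carrier_test(0, 10, expected_h2_carrier_freq = 0.4),
               "haldane")
  expect_error(dual_carrier_test(5, 10), "exactly one")
})

test_that("the Monte-Carlo dual-carrier path converges to the closed form", {
  f <- hwe_carrier_freq(1259 / 4912)
  closed <- dual_carrier_test(86, 235, expected_h2_carrier_freq = f)
  sim <- simulate_dual_carriers(100000, 0.065, f, seed = 7)
  mc <- dual_carrier_test(86, 235, simulated = sim)
  se_mc <- sqrt(1 / sim$n_dual_carriers +
                1 / (sim$n_mutation_carriers - sim$n_dual_carriers))
  expect_lt(abs(log(mc$odds_ratio) - log(closed$odds_ratio)), 3 * se_mc)
})
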