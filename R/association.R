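#' Hardy-Weinberg genotype expectations from an allele frequency
#'
#' Returns the expected non-carrier, heterozygote and homozygote fractions
#' ((1-p)^2, 2p(1-p), p^2) at alternate allele frequency `p`; the carrier
#' fraction is their complement of the first, `1 - (1-p)^2`.
#'
#' @param alt_freq Alternate allele frequency in [0, 1].
#' @return Named numeric vector `noncarrier`, `het`, `hom`.
#' @examples
#' hwe_genotype_freqs(1259 / 4912)  # carrier fraction ~0.447
#' @export
hwe_genotype_freqs <- function(alt_freq) {
  if (length(alt_freq) != 1 || is.na(alt_freq) || alt_freq < 0 || alt_freq > 1) {
    abort("alt_freq must be a single value in [0, 1]")
  }
  p <- alt_freq
  c(noncarrier = (1 - p)^2, het = 2 * p * (1 - p), hom = p^2)
}

#' Expected carrier fraction under Hardy-Weinberg equilibrium
#' @inheritParams hwe_genotype_freqs
#' @return `1 - (1 - p)^2`.
#' @export
hwe_carrier_freq <- function(alt_freq) {
  unname(1 - hwe_genotype_freqs(alt_freq)["noncarrier"])
}

#' External control allele counts
#'
#' Scalar allele counts from an external reference panel (e.g. a gnomAD
#' population subset) used as the control arm of all association contrasts.
#'
#' @param alt_alleles,total_alleles Non-negative counts with
#'   `alt_alleles <= total_alleles`.
#' @return One-row tibble with `alt_alleles`, `total_alleles`, `alt_freq`.
#' @examples
#' control_frequencies(1259, 4912)
#' @export
control_frequencies <- function(alt_alleles, total_alleles) {
  if (alt_alleles < 0 || total_alleles <= 0 || alt_alleles > total_alleles) {
    abort("require 0 <= alt_alleles <= total_alleles and total_alleles > 0")
  }
  tibble(alt_alleles = alt_alleles, total_alleles = total_alleles,
         alt_freq = alt_alleles / total_alleles)
}

#' Build a 2x2 association table
#'
#' Cells may be fractional: control genotype cells derived from allele
#' frequencies under Hardy-Weinberg equilibrium are expected counts.
#'
#' @param case_exposed,case_unexposed,control_exposed,control_unexposed
#'   Non-negative cell values.
#' @return One-row tibble with the four cells.
#' @export
assoc_2x2 <- function(case_exposed, case_unexposed,
                      control_exposed, control_unexposed) {
  cells <- c(case_exposed, case_unexposed, control_exposed, control_unexposed)
  if (any(is.na(cells)) || any(cells < 0)) {
    abort("all 2x2 cells must be non-negative")
  }
  tibble(case_exposed = case_exposed, case_unexposed = case_unexposed,
         control_exposed = control_exposed,
         control_unexposed = control_unexposed)
}

#' Odds ratio with Woolf confidence interval and z-test
#'
#' OR = (case_exposed/case_unexposed) / (control_exposed/control_unexposed);
#' the confidence interval is exp(ln OR +/- z * SE) with
#' SE = sqrt(sum of reciprocal cells), and the two-sided p-value comes from
#' z = ln(OR)/SE against the standard normal.
#'
#' @param table A 2x2 tibble from [assoc_2x2()] (extra columns such as
#'   `model` or `stratum` are carried through to the result).
#' @param ci_level Confidence level (default 0.95).
#' @param haldane Add 0.5 to every cell (Haldane-Anscombe correction);
#'   without it a zero cell is an error naming the offending cell.
#' @return One-row tibble: any metadata columns, then `odds_ratio`,
#'   `ci_low`, `ci_high`, `z`, `p_value`.
#' @examples
#' odds_ratio_test(assoc_2x2(515, 1885, 1259, 3653))
#' @export
odds_ratio_test <- function(table, ci_level = 0.95, haldane = FALSE) {
  cells <- c("case_exposed", "case_unexposed",
             "control_exposed", "control_unexposed")
  stopifnot(all(cells %in% names(table)), nrow(table) == 1)
  x <- unlist(table[1, cells])
  if (haldane) x <- x + 0.5
  zero <- cells[x == 0]
  if (length(zero) > 0) {
    abort(paste0("zero cell(s): ", paste(zero, collapse = ", "),
                 "; odds ratio undefined (set haldane = TRUE to correct)"))
  }
  or <- (x[1] / x[2]) / (x[3] / x[4])
  se <- sqrt(sum(1 / x))
  zq <- qnorm(1 - (1 - ci_level) / 2)
  z <- log(or) / se
  meta <- table[1, setdiff(names(table), cells), drop = FALSE]
  dplyr::bind_cols(meta, tibble(
    odds_ratio = unname(or),
    ci_low = unname(or * exp(-zq * se)),
    ci_high = unname(or * exp(zq * se)),
    z = unname(z),
    p_value = unname(2 * pnorm(-abs(z)))
  ))
}

#' Case genotype counts vs external allele counts under a genetic model
#'
#' Converts case genotype counts and control allele counts into the 2x2
#' table of a named genetic model:
#' * `allelic` — case alternate vs reference alleles against the control
#'   allele counts directly;
#' * `dominant` — case carriers (het + hom) vs non-carriers against
#'   Hardy-Weinberg expected carrier/non-carrier counts among
#'   `total_alleles / 2` control individuals;
#' * `recessive` — case homozygotes vs the rest against the expected
#'   p^2 / (1 - p^2) split.
#'
#' Control genotype cells are expectations and may be fractional.
#'
#' @param case_genotype_counts Numeric length-3 vector `(n0, n1, n2)`:
#'   cases with 0, 1, 2 alternate alleles.
#' @param controls A [control_frequencies()] row.
#' @param model `"allelic"`, `"dominant"` or `"recessive"`.
#' @return One-row tibble: `model` plus the four 2x2 cells.
#' @examples
#' ctrl <- control_frequencies(1259, 4912)
#' model_tables(c(725, 435, 40), ctrl, "dominant")
#' @export
model_tables <- function(case_genotype_counts, controls, model) {
  stopifnot(length(case_genotype_counts) == 3)
  if (any(case_genotype_counts < 0)) abort("genotype counts must be non-negative")
  n0 <- case_genotype_counts[1]; n1 <- case_genotype_counts[2]
  n2 <- case_genotype_counts[3]
  p <- controls$alt_freq
  n_ctrl <- controls$total_alleles / 2
  tab <- switch(model,
    allelic = assoc_2x2(n1 + 2 * n2, 2 * n0 + n1,
                        controls$alt_alleles,
                        controls$total_alleles - controls$alt_alleles),
    dominant = assoc_2x2(n1 + n2, n0,
                         n_ctrl * (1 - (1 - p)^2), n_ctrl * (1 - p)^2),
    recessive = assoc_2x2(n2, n0 + n1,
                          n_ctrl * p^2, n_ctrl * (1 - p^2)),
    abort(sprintf("unknown model '%s' (use allelic, dominant or recessive)",
                  model))
  )
  dplyr::bind_cols(tibble(model = model), tab)
}

#' Stratified case-versus-external-control association
#'
#' Runs each genetic model in each founder-mutation stratum against the same
#' external control frequencies. Strata follow the exclusivity convention of
#' stratified founder-mutation analyses: `GBA1` and `LRRK2` strata exclude
#' dual-mutation carriers, `NC` contains carriers of no genotyped mutation,
#' and `all` is the full cohort (dual and SMPD1 carriers included).
#'
#' @param meta Per-sample tibble with `subgroup` (one of `GBA1`, `LRRK2`,
#'   `dual`, `SMPD1`, `NC`; exactly one per sample) and `h2_dosage`
#'   (0/1/2, `NA` dropped per stratum).
#' @param controls A [control_frequencies()] row.
#' @param models Genetic models to fit.
#' @param strata Strata to report.
#' @return A tibble of class `h2_assoc`, one row per stratum x model:
#'   `stratum`, `model`, `n_cases`, `case_alt_alleles`, `case_af`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `z`, `p_value`. A model whose 2x2
#'   table has a zero cell (e.g. no homozygotes in a small stratum) keeps
#'   its row with `NA` statistics.
#' @examples
#' ch <- simulate_cohort(cohort_config(n_samples = 400, seed = 5))
#' stratified_association(ch$meta, control_frequencies(1259, 4912))
#' @export
stratified_association <- function(meta, controls,
                                   models = c("allelic", "dominant",
                                              "recessive"),
                                   strata = c("all", "GBA1", "LRRK2", "NC")) {
  if (!all(c("subgroup", "h2_dosage") %in% names(meta))) {
    abort("meta must have `subgroup` and `h2_dosage` columns")
  }
  allowed <- c("GBA1", "LRRK2", "dual", "SMPD1", "NC")
  bad <- setdiff(unique(meta$subgroup), allowed)
  if (length(bad) > 0 || anyNA(meta$subgroup)) {
    abort(paste0("invalid subgroup assignment: every sample needs exactly one of ",
                 paste(allowed, collapse = ", ")))
  }
  res <- purrr::map(strata, function(s) {
    sub <- if (s == "all") meta else meta |> filter(.data$subgroup == s)
    d <- sub$h2_dosage[!is.na(sub$h2_dosage)]
    counts <- as.numeric(table(factor(d, levels = 0:2)))
    purrr::map(models, function(m) {
      tab <- model_tables(counts, controls, m)
      out <- tryCatch(
        odds_ratio_test(tab |> select(-"model")),
        error = function(e) tibble(odds_ratio = NA_real_, ci_low = NA_real_,
                                   ci_high = NA_real_, z = NA_real_,
                                   p_value = NA_real_))
      dplyr::bind_cols(
        tibble(stratum = s, model = m, n_cases = length(d),
               case_alt_alleles = counts[2] + 2 * counts[3],
               case_af = (counts[2] + 2 * counts[3]) / (2 * length(d))),
        out
      )
    }) |> bind_rows()
  }) |> bind_rows()
  class(res) <- c("h2_assoc", class(res))
  res
}

#' Monte-Carlo draw of founder-mutation / H2 dual carriers
#'
#' Simulates `n_sim` individuals with independent Bernoulli carrier states
#' for a founder mutation and the H2 haplotype, returning the number of
#' mutation carriers and of H2 carriers among them — the independence null
#' for the dual-carrier rate.
#'
#' @param n_sim Number of simulated individuals (> 0).
#' @param mutation_carrier_freq,h2_carrier_freq Carrier probabilities in
#'   [0, 1].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return One-row tibble: `n_sim`, `n_mutation_carriers`, `n_dual_carriers`.
#' @examples
#' simulate_dual_carriers(100000, 0.065, 0.447, seed = 1)
#' @export
simulate_dual_carriers <- function(n_sim, mutation_carrier_freq,
                                   h2_carrier_freq, seed = NULL) {
  if (n_sim <= 0) abort("n_sim must be positive")
  freqs <- c(mutation_carrier_freq, h2_carrier_freq)
  if (any(freqs < 0 | freqs > 1)) abort("carrier frequencies must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n_mut <- rbinom(1, n_sim, mutation_carrier_freq)
  n_dual <- rbinom(1, n_mut, h2_carrier_freq)
  tibble(n_sim = n_sim, n_mutation_carriers = n_mut, n_dual_carriers = n_dual)
}

#' Test an observed dual-carrier rate against its independence expectation
#'
#' Compares the observed odds of H2 carriage among founder-mutation carriers
#' (`k` of `n`) with the expected odds under independence, via the same
#' log-OR machinery as [odds_ratio_test()]. The expectation comes either
#' from a closed-form carrier frequency (`expected_h2_carrier_freq`,
#' optionally with a finite reference carrier count `n_reference_carriers`
#' governing CI width; infinite-reference limit when `NULL`) or from a
#' Monte-Carlo draw ([simulate_dual_carriers()]).
#'
#' @param observed_carriers Observed H2 carriers `k` among the mutation
#'   carriers.
#' @param group_size Number of mutation carriers `n` (> 0).
#' @param expected_h2_carrier_freq Closed-form expected H2 carrier fraction
#'   (e.g. [hwe_carrier_freq()] of the control allele frequency).
#' @param n_reference_carriers Size of the reference mutation-carrier pool
#'   the expectation is counted in; controls the expectation-side variance
#'   contribution. `NULL` = treat the expectation as exact.
#' @param simulated A row from [simulate_dual_carriers()]; used instead of
#'   the closed form when supplied.
#' @param ci_level Confidence level.
#' @param haldane Apply the 0.5 correction when `k` is 0 or `n` (otherwise
#'   an error).
#' @return One-row tibble: `observed_carriers`, `group_size`,
#'   `observed_rate`, `expected_carrier_freq`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `z`, `p_value`, `n_simulated`.
#' @examples
#' dual_carrier_test(86, 235, expected_h2_carrier_freq = hwe_carrier_freq(1259 / 4912))
#' @export
dual_carrier_test <- function(observed_carriers, group_size,
                              expected_h2_carrier_freq = NULL,
                              n_reference_carriers = NULL,
                              simulated = NULL,
                              ci_level = 0.95, haldane = FALSE) {
  k <- observed_carriers; n <- group_size
  if (n <= 0 || k < 0 || k > n) abort("require 0 <= observed_carriers <= group_size, group_size > 0")
  if (is.null(expected_h2_carrier_freq) == is.null(simulated)) {
    abort("supply exactly one of expected_h2_carrier_freq or simulated")
  }
  if ((k == 0 || k == n) && !haldane) {
    abort("all or no observed carriers: odds undefined (set haldane = TRUE)")
  }
  if (!is.null(simulated)) {
    S <- simulated$n_mutation_carriers
    E <- simulated$n_dual_carriers
    n_simulated <- simulated$n_sim
    exp_freq <- E / S
  } else {
    exp_freq <- expected_h2_carrier_freq
    if (exp_freq <= 0 || exp_freq >= 1) {
      abort("expected_h2_carrier_freq must lie strictly within (0, 1)")
    }
    S <- if (is.null(n_reference_carriers)) Inf else n_reference_carriers
    E <- exp_freq * S
    n_simulated <- NA_integer_
  }
  kk <- k; nn <- n
  if (haldane) { kk <- k + 0.5; nn <- n + 1 }
  or <- (kk / (nn - kk)) / (exp_freq / (1 - exp_freq))
  se2 <- 1 / kk + 1 / (nn - kk)
  if (is.finite(S)) se2 <- se2 + 1 / E + 1 / (S - E)
  se <- sqrt(se2)
  zq <- qnorm(1 - (1 - ci_level) / 2)
  z <- log(or) / se
  tibble(
    observed_carriers = k, group_size = n, observed_rate = k / n,
    expected_carrier_freq = exp_freq,
    odds_ratio = or, ci_low = or * exp(-zq * se), ci_high = or * exp(zq * se),
    z = z, p_value = 2 * pnorm(-abs(z)), n_simulated = n_simulated
  )
}
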