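#' Configuration for the synthetic inversion-haplotype cohort
#'
#' Bundles every generative parameter of the synthetic Ashkenazi-like PD
#' cohort: the genomic region, the divergent (inversion-style) SNV block with
#' its tag variant, background variation, founder-mutation subgroup
#' frequencies, the protective effect injected for the H2 haplotype, the
#' age-at-onset model, and per-call depth/quality noise.
#'
#' Defaults mirror the cohort structure the analysis assumes: 1200 cases;
#' subgroup frequencies GBA1 0.196, LRRK2 0.121, dual 0.021, SMPD1 0.007
#' (remainder non-carriers); H2 allele frequency 0.256 (the external control
#' allele frequency); onset mean 60.5 y, SD 11.2 y; 39.6% female.
#'
#' Variant positions are deterministic given the configuration: divergent
#' SNVs are evenly spaced across `divergent_span`, background SNVs and indels
#' across `region`, so the variant panel does not depend on the seed. The tag
#' SNV is the divergent site closest to the centre of the block.
#'
#' @param n_samples Number of cases to emit (0 allowed; yields empty output).
#' @param region Overall locus, a [genomic_interval()] (default the ~1.4 Mb
#'   chr17 MAPT locus span).
#' @param divergent_span Interval holding the perfect-LD divergent block
#'   (default the region shrunk by 100 kb on each side).
#' @param n_divergent_snvs,n_background_snvs,n_indels Panel composition.
#' @param h2_allele_freq Population frequency of the H2 (inversion) haplotype.
#' @param recombinant_rate Per-haplotype probability of carrying a planted
#'   recombination breakpoint.
#' @param recombinant_breakpoints Positions at which recombinant haplotypes
#'   switch class. Default: two breakpoints placed between the 2nd/3rd
#'   divergent sites from each end of the block, so recombinants narrow the
#'   recoverable LD interval deterministically.
#' @param carrier_freqs Named probabilities for subgroups `GBA1`, `LRRK2`,
#'   `dual`, `SMPD1`; the remainder are non-carriers (`NC`). Must sum to <= 1.
#' @param h2_protective_or Target carrier-vs-expected odds ratio for H2 among
#'   cases (dominant mechanism, injected by rejection sampling); 1 = null.
#' @param amso_mean,amso_sd Age at motor symptom onset mean/SD in years.
#' @param beta_sex Sex effect (years, female vs male) in the onset model.
#' @param female_frac Fraction of female cases.
#' @param dp_mean,dp_size Negative-binomial read-depth model (mean, size).
#' @param gq_mean,gq_sd Genotype-quality model: Gaussian clipped to [0, 99].
#' @param missing_rate Per-call probability of a missing genotype.
#' @param bg_maf_range Range of minor-allele frequencies assigned (evenly
#'   spaced) to background SNVs and indels.
#' @param seed Integer seed; a fixed seed makes all outputs bit-identical.
#' @return An object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_samples = 50, seed = 7)
#' cfg$tag_id
#' @export
cohort_config <- function(n_samples = 1200,
                          region = genomic_interval("chr17", 45394449, 46808970),
                          divergent_span = NULL,
                          n_divergent_snvs = 60,
                          n_background_snvs = 40,
                          n_indels = 10,
                          h2_allele_freq = 0.256,
                          recombinant_rate = 0.01,
                          recombinant_breakpoints = NULL,
                          carrier_freqs = c(GBA1 = 0.196, LRRK2 = 0.121,
                                            dual = 0.021, SMPD1 = 0.007),
                          h2_protective_or = 0.75,
                          amso_mean = 60.5,
                          amso_sd = 11.2,
                          beta_sex = -1.0,
                          female_frac = 0.396,
                          dp_mean = 40,
                          dp_size = 6,
                          gq_mean = 85,
                          gq_sd = 20,
                          missing_rate = 0.002,
                          bg_maf_range = c(0.05, 0.5),
                          seed = 1L) {
  if (is.null(divergent_span)) {
    divergent_span <- genomic_interval(region$chrom,
                                       region$start + 1e5,
                                       region$end - 1e5)
  }
  probs <- c(h2_allele_freq, recombinant_rate, female_frac, missing_rate,
             carrier_freqs)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  if (n_samples < 0) abort("n_samples must be non-negative")
  if (sum(carrier_freqs) > 1) {
    abort("carrier_freqs sum to more than 1: no probability left for non-carriers")
  }
  required <- c("GBA1", "LRRK2", "dual", "SMPD1")
  if (!all(required %in% names(carrier_freqs))) {
    abort("carrier_freqs must name GBA1, LRRK2, dual and SMPD1")
  }
  if (n_divergent_snvs < 1) {
    abort("at least one divergent SNV is required: the tag SNV is undefined otherwise")
  }
  n_var <- n_divergent_snvs + n_background_snvs + n_indels
  if (interval_width(region) < n_var) {
    abort("region is too short for the requested number of variants")
  }
  if (amso_sd < 0 || dp_mean <= 0 || dp_size <= 0 || gq_sd < 0) {
    abort("noise parameters must be non-negative (dp_mean, dp_size positive)")
  }
  if (h2_protective_or <= 0) abort("h2_protective_or must be positive")

  cfg <- list(
    n_samples = as.integer(n_samples), region = region,
    divergent_span = divergent_span,
    n_divergent_snvs = as.integer(n_divergent_snvs),
    n_background_snvs = as.integer(n_background_snvs),
    n_indels = as.integer(n_indels),
    h2_allele_freq = h2_allele_freq,
    recombinant_rate = recombinant_rate,
    recombinant_breakpoints = recombinant_breakpoints,
    carrier_freqs = carrier_freqs[required],
    h2_protective_or = h2_protective_or,
    amso_mean = amso_mean, amso_sd = amso_sd, beta_sex = beta_sex,
    female_frac = female_frac,
    dp_mean = dp_mean, dp_size = dp_size,
    gq_mean = gq_mean, gq_sd = gq_sd,
    missing_rate = missing_rate,
    bg_maf_range = bg_maf_range,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  variants <- cohort_variants(cfg)
  cfg$tag_id <- variants$variant_id[variants$is_tag]
  if (is.null(cfg$recombinant_breakpoints)) {
    cfg$recombinant_breakpoints <- default_breakpoints(variants)
  }
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  n_samples: %d   seed: %d\n", x$n_samples, x$seed))
  cat(sprintf("  region: %s:%s-%s\n", x$region$chrom,
              format(x$region$start, big.mark = ","),
              format(x$region$end, big.mark = ",")))
  cat(sprintf("  variants: %d divergent + %d background + %d indels (tag: %s)\n",
              x$n_divergent_snvs, x$n_background_snvs, x$n_indels, x$tag_id))
  cat(sprintf("  H2 freq: %.3f  protective OR: %.2f  recombinant rate: %.3f\n",
              x$h2_allele_freq, x$h2_protective_or, x$recombinant_rate))
  invisible(x)
}

# Deterministic variant panel for a configuration. Divergent sites evenly
# cover the divergent span; background SNVs and indels evenly cover the full
# region, shifted off any divergent position.
cohort_variants <- function(config) {
  dv_pos <- round(seq(config$divergent_span$start, config$divergent_span$end,
                      length.out = config$n_divergent_snvs))
  n_bg <- config$n_background_snvs + config$n_indels
  bg_pos <- integer(0)
  if (n_bg > 0) {
    bg_pos <- round(seq(config$region$start + 50, config$region$end - 50,
                        length.out = n_bg)) + 1L
    while (any(bg_pos %in% dv_pos) || anyDuplicated(bg_pos)) {
      bg_pos[bg_pos %in% dv_pos | duplicated(bg_pos)] <-
        bg_pos[bg_pos %in% dv_pos | duplicated(bg_pos)] + 1L
    }
  }
  tag_idx <- which.min(abs(dv_pos - (config$divergent_span$start +
                                       config$divergent_span$end) / 2))
  div <- tibble(
    variant_id = sprintf("hd%04d", seq_along(dv_pos)),
    pos = as.numeric(dv_pos),
    ref = "A", alt = "G", is_indel = FALSE, role = "divergent",
    maf = config$h2_allele_freq
  )
  div$variant_id[tag_idx] <- "tagSNV"
  div$is_tag <- seq_along(dv_pos) == tag_idx
  bg <- tibble(variant_id = character(0), pos = numeric(0), ref = character(0),
               alt = character(0), is_indel = logical(0), role = character(0),
               maf = numeric(0), is_tag = logical(0))
  if (n_bg > 0) {
    mafs <- seq(config$bg_maf_range[1], config$bg_maf_range[2],
                length.out = n_bg)
    is_ind <- seq_len(n_bg) > config$n_background_snvs
    bg <- tibble(
      variant_id = ifelse(is_ind,
                          sprintf("ind%04d", cumsum(is_ind)),
                          sprintf("bg%04d", seq_len(n_bg))),
      pos = as.numeric(bg_pos),
      ref = ifelse(is_ind, "AT", "C"),
      alt = ifelse(is_ind, "A", "T"),
      is_indel = is_ind, role = ifelse(is_ind, "indel", "background"),
      maf = mafs, is_tag = FALSE
    )
  }
  out <- bind_rows(div, bg)
  out$chrom <- config$region$chrom
  out |>
    select("variant_id", "chrom", "pos", "ref", "alt", "is_indel",
           "role", "maf", "is_tag") |>
    arrange(.data$pos)
}

# Default planted breakpoints: between the 2nd and 3rd divergent sites from
# each end, so that recombinant haplotypes trim two sites off either flank.
default_breakpoints <- function(variants) {
  dv <- variants$pos[variants$role == "divergent"]
  dv <- sort(dv)
  k <- length(dv)
  if (k < 6) return(numeric(0))
  c(floor((dv[2] + dv[3]) / 2), ceiling((dv[k - 2] + dv[k - 1]) / 2))
}
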