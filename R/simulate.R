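#' Simulate phased haplotypes for the inversion-style block
#'
#' Draws `2 * n_samples` haplotypes. Each haplotype receives an H1/H2 label
#' (H2 with probability `h2_allele_freq`); divergent SNVs carry the allele
#' matching the label everywhere except past a planted breakpoint on
#' recombinant haplotypes, which switch class at the breakpoint. Background
#' SNVs and indels are drawn independently of the label at their configured
#' allele frequencies.
#'
#' @param config A [cohort_config()].
#' @return A list of class `h2_haplotypes` with elements `haplotypes`
#'   (integer matrix, haplotypes x variants, 1 = alternate allele),
#'   `variants` (tibble) and `truth` (per-haplotype tibble: `hap_id`,
#'   `sample_id`, `label`, `recombinant`, `breakpoint`).
#' @examples
#' hp <- simulate_haplotypes(cohort_config(n_samples = 20, seed = 1))
#' table(hp$truth$label)
#' @export
simulate_haplotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_hap <- 2L * config$n_samples
  labels <- rbinom(n_hap, 1L, config$h2_allele_freq)
  emit_haplotypes(labels, config)
}

# Emit allele matrix + truth for a fixed vector of H1/H2 labels (1 = H2).
# Consumes the RNG stream in a fixed order: recombinant flags, breakpoint
# choices, background alleles.
emit_haplotypes <- function(labels, config) {
  variants <- cohort_variants(config)
  n_hap <- length(labels)
  bp_avail <- config$recombinant_breakpoints
  recomb <- if (length(bp_avail) > 0 && config$recombinant_rate > 0) {
    rbinom(n_hap, 1L, config$recombinant_rate) == 1L
  } else rep(FALSE, n_hap)
  breakpoint <- rep(NA_real_, n_hap)
  if (any(recomb)) {
    breakpoint[recomb] <- bp_avail[sample.int(length(bp_avail),
                                              sum(recomb), replace = TRUE)]
  }
  tag_pos <- variants$pos[variants$is_tag]
  mat <- matrix(0L, nrow = n_hap, ncol = nrow(variants),
                dimnames = list(NULL, variants$variant_id))
  is_div <- variants$role == "divergent"
  if (n_hap > 0) {
    mat[, is_div] <- matrix(rep(labels, sum(is_div)), nrow = n_hap)
    for (i in which(recomb)) {
      b <- breakpoint[i]
      flipped <- if (b < tag_pos) is_div & variants$pos < b
                 else is_div & variants$pos > b
      mat[i, flipped] <- 1L - labels[i]
    }
    other <- which(!is_div)
    for (j in other) {
      mat[, j] <- rbinom(n_hap, 1L, variants$maf[j])
    }
  }
  truth <- tibble(
    hap_id = seq_len(n_hap),
    sample_id = sprintf("S%05d", rep(seq_len(max(1, n_hap %/% 2)),
                                     each = 2)[seq_len(n_hap)]),
    label = ifelse(labels == 1L, "H2", "H1"),
    recombinant = recomb,
    breakpoint = breakpoint
  )
  structure(list(haplotypes = mat, variants = variants, truth = truth),
            class = "h2_haplotypes")
}

# Rejection sampler for case H1/H2 label pairs under a dominant protective
# (or risk) odds ratio. Accepting carriers with probability `or` (or <= 1)
# scales the realised carrier odds among accepted cases by exactly `or`
# relative to the Hardy-Weinberg expectation.
sample_case_labels <- function(n, config) {
  or <- config$h2_protective_or
  out1 <- integer(0); out2 <- integer(0)
  while (length(out1) < n) {
    m <- max(1000L, 2L * (n - length(out1)))
    l1 <- rbinom(m, 1L, config$h2_allele_freq)
    l2 <- rbinom(m, 1L, config$h2_allele_freq)
    carrier <- (l1 + l2) > 0L
    u <- runif(m)
    keep <- if (or <= 1) !carrier | u < or else carrier | u < 1 / or
    out1 <- c(out1, l1[keep]); out2 <- c(out2, l2[keep])
  }
  list(l1 = out1[seq_len(n)], l2 = out2[seq_len(n)])
}

#' Simulate a diploid case cohort with metadata
#'
#' Pairs haplotypes into diploid genotypes, assigns founder-mutation
#' subgroups, injects the configured H2 protective effect by rejection
#' sampling of cases against carrier status (dominant mechanism), and adds
#' per-call read depth (negative binomial), genotype quality (clipped
#' Gaussian) and random missingness. Age at motor symptom onset is drawn via
#' [simulate_amso()].
#'
#' @param config A [cohort_config()].
#' @return A list of class `h2_cohort`:
#'   * `calls` — long tibble, one row per (sample, variant) call:
#'     `sample_id`, `variant_id`, `chrom`, `pos`, `ref`, `alt`, `is_indel`,
#'     `dosage` (0/1/2 or `NA`), `dp`, `gq`;
#'   * `meta` — per-sample tibble: `sample_id`, `sex`, `subgroup`,
#'     `gba1_class`, `compound_het`, `n370s_hom`, `h2_dosage`, `h2_carrier`,
#'     `amso`;
#'   * `variants`, `truth`, `config`.
#' @examples
#' ch <- simulate_cohort(cohort_config(n_samples = 30, seed = 2))
#' dplyr::count(ch$meta, subgroup)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  variants <- cohort_variants(config)
  if (n == 0L) {
    empty_calls <- tibble(sample_id = character(0), variant_id = character(0),
                          chrom = character(0), pos = numeric(0),
                          ref = character(0), alt = character(0),
                          is_indel = logical(0), dosage = integer(0),
                          dp = integer(0), gq = integer(0))
    empty_meta <- tibble(sample_id = character(0), sex = character(0),
                         subgroup = character(0), gba1_class = character(0),
                         compound_het = logical(0), n370s_hom = logical(0),
                         h2_dosage = integer(0), h2_carrier = logical(0),
                         amso = numeric(0))
    return(structure(list(calls = empty_calls, meta = empty_meta,
                          variants = variants,
                          truth = list(haplotypes = tibble(),
                                       samples = empty_meta[0, ]),
                          config = config),
                     class = "h2_cohort"))
  }

  if (config$h2_protective_or == 1) {
    labels <- rbinom(2L * n, 1L, config$h2_allele_freq)
  } else {
    lp <- sample_case_labels(n, config)
    labels <- as.integer(rbind(lp$l1, lp$l2))
  }
  hp <- emit_haplotypes(labels, config)
  h1 <- hp$haplotypes[seq(1, 2 * n, by = 2), , drop = FALSE]
  h2 <- hp$haplotypes[seq(2, 2 * n, by = 2), , drop = FALSE]
  dose <- h1 + h2
  sample_id <- sprintf("S%05d", seq_len(n))
  rownames(dose) <- sample_id

  cf <- config$carrier_freqs
  subgroup <- sample(c(names(cf), "NC"), n, replace = TRUE,
                     prob = c(cf, 1 - sum(cf)))
  sex <- ifelse(rbinom(n, 1, config$female_frac) == 1, "female", "male")
  has_gba1 <- subgroup %in% c("GBA1", "dual")
  gba1_class <- rep("none", n)
  gba1_class[has_gba1] <- sample(c("severe", "mild", "risk"), sum(has_gba1),
                                 replace = TRUE, prob = c(0.25, 0.45, 0.30))
  compound_het <- has_gba1 & rbinom(n, 1, 0.03) == 1
  n370s_hom <- has_gba1 & rbinom(n, 1, 0.02) == 1
  gba1_class[n370s_hom] <- "mild"

  l1 <- labels[seq(1, 2 * n, by = 2)]
  l2 <- labels[seq(2, 2 * n, by = 2)]
  h2_dosage <- as.integer(l1 + l2)

  meta <- tibble(
    sample_id = sample_id, sex = sex, subgroup = subgroup,
    gba1_class = gba1_class, compound_het = compound_het,
    n370s_hom = n370s_hom, h2_dosage = h2_dosage,
    h2_carrier = h2_dosage >= 1L
  )
  meta <- simulate_amso(meta, beta_h2 = 0, beta_sex = config$beta_sex,
                        sigma = config$amso_sd, amso_mean = config$amso_mean)

  n_var <- nrow(variants)
  n_call <- n * n_var
  dp <- rnbinom(n_call, mu = config$dp_mean, size = config$dp_size)
  gq <- as.integer(round(pmin(99, pmax(0, rnorm(n_call, config$gq_mean,
                                                config$gq_sd)))))
  dosage <- as.integer(dose)  # column-major: variant blocks of n samples
  if (config$missing_rate > 0) {
    dosage[runif(n_call) < config$missing_rate] <- NA_integer_
  }
  calls <- tibble(
    sample_id = rep(sample_id, times = n_var),
    variant_id = rep(variants$variant_id, each = n),
    chrom = rep(variants$chrom, each = n),
    pos = rep(variants$pos, each = n),
    ref = rep(variants$ref, each = n),
    alt = rep(variants$alt, each = n),
    is_indel = rep(variants$is_indel, each = n),
    dosage = dosage,
    dp = as.integer(dp),
    gq = gq
  ) |> arrange(.data$pos, .data$sample_id)

  hp$truth$sample_id <- rep(sample_id, each = 2)
  structure(list(calls = calls, meta = meta, variants = variants,
                 truth = list(haplotypes = hp$truth,
                              samples = meta |>
                                select("sample_id", "subgroup",
                                       "h2_dosage", "h2_carrier")),
                 config = config),
            class = "h2_cohort")
}

#' @export
print.h2_cohort <- function(x, ...) {
  cat("<h2_cohort>\n")
  cat(sprintf("  %d samples x %d variants (%d calls)\n",
              nrow(x$meta), nrow(x$variants), nrow(x$calls)))
  if (nrow(x$meta) > 0) {
    tb <- table(x$meta$subgroup)
    cat("  subgroups:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Draw age at motor symptom onset from a linear model
#'
#' AMSO = intercept + `beta_h2` x \[H2 carrier\] + `beta_sex` x \[female\] +
#' Gaussian(0, `sigma`). When `intercept` is `NULL` it is derived so the
#' expected cohort mean equals `amso_mean` given the realised carrier and
#' female fractions.
#'
#' @param meta Metadata tibble with columns `sex` and `h2_carrier` (or
#'   `h2_dosage`, from which carrier status is derived).
#' @param beta_h2 Carrier effect in years.
#' @param beta_sex Female-vs-male effect in years.
#' @param sigma Residual SD in years (must be >= 0).
#' @param intercept Intercept in years, or `NULL` to derive from `amso_mean`.
#' @param amso_mean Target cohort mean used when `intercept` is `NULL`.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return `meta` with an `amso` column (years).
#' @examples
#' meta <- tibble::tibble(sex = c("female", "male"), h2_carrier = c(TRUE, FALSE))
#' simulate_amso(meta, beta_h2 = -2, beta_sex = -1, sigma = 0, intercept = 60)
#' @export
simulate_amso <- function(meta, beta_h2 = 0, beta_sex = -1, sigma = 11.2,
                          intercept = NULL, amso_mean = 60.5, seed = NULL) {
  if (sigma < 0) abort("sigma must be non-negative")
  if (!"sex" %in% names(meta)) abort("meta must have a `sex` column")
  if (!"h2_carrier" %in% names(meta)) {
    if (!"h2_dosage" %in% names(meta)) {
      abort("meta must have `h2_carrier` or `h2_dosage`")
    }
    meta$h2_carrier <- meta$h2_dosage >= 1L
  }
  if (!is.null(seed)) set.seed(seed)
  carrier <- as.numeric(meta$h2_carrier)
  female <- as.numeric(meta$sex == "female")
  if (is.null(intercept)) {
    intercept <- if (nrow(meta) == 0) amso_mean else {
      amso_mean - beta_h2 * mean(carrier) - beta_sex * mean(female)
    }
  }
  noise <- if (nrow(meta) > 0) rnorm(nrow(meta), 0, sigma) else numeric(0)
  meta$amso <- intercept + beta_h2 * carrier + beta_sex * female + noise
  meta
}
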