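#' The 13 GTEx brain tissues used for cross-tissue QTL consistency
#' @format Character vector of tissue names.
#' @export
gtex_brain_tissues <- c(
  "amygdala", "anterior_cingulate_cortex", "caudate",
  "cerebellar_hemisphere", "cerebellum", "cortex", "frontal_cortex",
  "hippocampus", "hypothalamus", "nucleus_accumbens", "putamen",
  "spinal_cord_cervical_c1", "substantia_nigra"
)

#' Filter annotation records by CADD Phred score
#'
#' Keeps records with `cadd_phred >= phred_min` (inclusive, matching the
#' "score of X or higher" convention), sorted by descending score. A CADD
#' Phred of 20 corresponds roughly to the top 1% most deleterious possible
#' substitutions genome-wide.
#'
#' @param records Annotation tibble with at least `cadd_phred`.
#' @param phred_min Non-negative score threshold.
#' @return The filtered tibble, sorted by descending `cadd_phred`.
#' @export
filter_cadd <- function(records, phred_min) {
  if (phred_min < 0) abort("phred_min must be non-negative")
  if (!"cadd_phred" %in% names(records)) {
    abort("records must have a `cadd_phred` column")
  }
  if (any(records$cadd_phred < 0, na.rm = TRUE)) {
    abort("cadd_phred scores must be non-negative")
  }
  records |>
    filter(!is.na(.data$cadd_phred), .data$cadd_phred >= phred_min) |>
    arrange(dplyr::desc(.data$cadd_phred))
}

#' Candidate-variant annotation report
#'
#' Formats filtered annotation records as a human-readable candidate table:
#' one row per variant with gene, consequence, amino-acid change,
#' constrained-region and regulatory-element columns, with missing values
#' rendered as `"N.A"` and logical flags as `"Yes"`/`"N.A"`.
#'
#' @param records Annotation tibble (typically from [filter_cadd()]) with
#'   any of: `variant_id`, `chrom`, `pos`, `ref`, `alt`, `cadd_phred`,
#'   `gene`, `consequence`, `amino_acid_change`, `in_ecr`, `ccre_class`,
#'   `ccre_accession`.
#' @return A character tibble; zero rows in, header-only report out.
#' @export
candidate_table <- function(records) {
  cols <- c("variant_id", "chrom", "pos", "ref", "alt", "cadd_phred",
            "gene", "consequence", "amino_acid_change", "in_ecr",
            "ccre_class", "ccre_accession")
  present <- intersect(cols, names(records))
  out <- records[, present, drop = FALSE]
  out <- out |>
    mutate(across(dplyr::everything(), function(x) {
      if (is.logical(x)) {
        dplyr::case_when(x %in% TRUE ~ "Yes", .default = "N.A")
      } else {
        y <- as.character(x)
        ifelse(is.na(y) | y == "" | y == "none", "N.A", y)
      }
    }))
  as_tibble(out)
}

#' Filter expression QTL records
#'
#' Keeps eQTL records meeting both the posterior and p-value criteria:
#' `m_value >= m_min` (inclusive) and `p_value < p_max` (strict).
#'
#' @param records QTL tibble with `qtl_type = "expression"`, `m_value`,
#'   `p_value`. Splicing records are an error — use [filter_sqtl()].
#' @param m_min Minimum posterior probability that the effect is present in
#'   the tissue (default 0.9).
#' @param p_max Strict p-value bound (default 5e-4).
#' @return The filtered tibble.
#' @export
filter_eqtl <- function(records, m_min = 0.9, p_max = 0.0005) {
  check_qtl(records, "expression")
  records |>
    filter(!is.na(.data$m_value), .data$m_value >= m_min,
           .data$p_value < p_max)
}

#' Filter splicing QTL records
#'
#' Keeps sQTL records with `p_value < p_max` (strict).
#'
#' @param records QTL tibble with `qtl_type = "splicing"` and `p_value`.
#'   Expression records are an error — use [filter_eqtl()].
#' @param p_max Strict p-value bound (default 1e-4).
#' @return The filtered tibble.
#' @export
filter_sqtl <- function(records, p_max = 0.0001) {
  check_qtl(records, "splicing")
  records |> filter(.data$p_value < p_max)
}

check_qtl <- function(records, type) {
  needed <- c("variant_id", "gene", "tissue", "qtl_type", "p_value")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("QTL records missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  wrong <- setdiff(unique(records$qtl_type), type)
  if (length(wrong) > 0) {
    abort(sprintf("records of qtl_type '%s' passed to the %s filter",
                  paste(wrong, collapse = "/"), type))
  }
  if (any(records$p_value <= 0 | records$p_value > 1, na.rm = TRUE)) {
    abort("p_value must lie in (0, 1]")
  }
  invisible(records)
}

#' Cross-tissue consistency of significant QTL effects
#'
#' Summarises significance-filtered QTL records per gene and QTL type:
#' number of tissues with a significant effect, whether all effect signs
#' agree, and an all-tissues-consistent flag raised only when the gene is
#' significant with a single direction in every one of `required_tissues`
#' tissues. When several haplotype-proxy variants represent the same
#' haplotype, records are collapsed per (gene, tissue, type) to the best
#' (smallest) p-value before summarising.
#'
#' @param records Filtered QTL tibble with `variant_id`, `gene`, `tissue`,
#'   `qtl_type`, `effect_sign` (`"+"` or `"-"`), `p_value`. Duplicate
#'   (gene, tissue, variant, type) rows are an error.
#' @param required_tissues Number of tissues required for the universal
#'   flag (default `length(gtex_brain_tissues)`, i.e. 13).
#' @param collapse_proxies Collapse proxy variants by best p per
#'   (gene, tissue, type) (default `TRUE`).
#' @return Tibble: `gene`, `qtl_type`, `n_tissues`, `direction_consistent`,
#'   `all_tissues_consistent`.
#' @export
cross_tissue_consistency <- function(records,
                                     required_tissues = length(gtex_brain_tissues),
                                     collapse_proxies = TRUE) {
  needed <- c("variant_id", "gene", "tissue", "qtl_type", "effect_sign",
              "p_value")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("QTL records missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  dup <- records |>
    count(.data$gene, .data$tissue, .data$variant_id, .data$qtl_type) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate (gene, tissue, variant, type) rows, e.g. %s/%s/%s",
                  dup$gene[1], dup$tissue[1], dup$variant_id[1]))
  }
  if (collapse_proxies) {
    records <- records |>
      group_by(.data$gene, .data$tissue, .data$qtl_type) |>
      dplyr::slice_min(.data$p_value, n = 1, with_ties = FALSE) |>
      ungroup()
  }
  records |>
    group_by(.data$gene, .data$qtl_type) |>
    summarise(
      n_tissues = dplyr::n_distinct(.data$tissue),
      direction_consistent = dplyr::n_distinct(.data$effect_sign) == 1,
      .groups = "drop"
    ) |>
    mutate(all_tissues_consistent = .data$n_tissues == required_tissues &
             .data$direction_consistent)
}
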