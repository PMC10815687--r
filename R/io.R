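#' Write a simulated cohort as VCF v4.2
#'
#' Emits an uncompressed VCF with FORMAT `GT:DP:GQ`, a contig header line
#' for the configured chromosome and 1-based positions. Genotypes are
#' written unphased from dosage (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param cohort An `h2_cohort` from [simulate_cohort()], or any long call
#'   tibble with the standard columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  calls <- if (inherits(cohort, "h2_cohort")) cohort$calls else cohort
  check_calls(calls)
  samples <- sort(unique(calls$sample_id))
  vars <- calls |>
    distinct(.data$variant_id, .data$chrom, .data$pos, .data$ref, .data$alt) |>
    arrange(.data$chrom, .data$pos)
  gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  calls <- calls |>
    mutate(gt = ifelse(is.na(.data$dosage), "./.",
                       gt_of[as.character(.data$dosage)]),
           field = paste(.data$gt, .data$dp, .data$gq, sep = ":"))
  wide <- calls |>
    select("sample_id", "variant_id", "field") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "field")
  wide <- wide[match(vars$variant_id, wide$variant_id), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=h2scan",
    sprintf("##contig=<ID=%s>", unique(vars$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body_mat <- as.matrix(wide[, samples, drop = FALSE])
  body <- apply(cbind(vars$chrom,
                      format(vars$pos, scientific = FALSE, trim = TRUE),
                      vars$variant_id, vars$ref, vars$alt, ".", "PASS", ".",
                      "GT:DP:GQ", body_mat),
                1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into the long call tibble
#'
#' Parses a VCF (via vcfR) into the sample x variant call representation
#' used by all downstream filters. Multi-allelic records are split into one
#' bi-allelic record per alternate allele, with the dosage counting that
#' alternate only; split record ids get an `_altN` suffix.
#'
#' @param path VCF path (plain or bgzipped).
#' @return Long call tibble: `sample_id`, `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `is_indel`, `dosage`, `dp`, `gq`.
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)  # single-record VCF drops to vector
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  as_mat <- function(x) if (is.null(dim(x))) t(x) else x
  gt <- as_mat(vcfR::extract.gt(v, element = "GT"))
  dp <- as_mat(suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)))
  gq <- as_mat(suppressWarnings(
    vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)))
  samples <- colnames(gt)
  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    id_base <- if (is.na(fix$ID[i]) || fix$ID[i] == ".") {
      paste0(fix$CHROM[i], ":", fix$POS[i])
    } else fix$ID[i]
    alleles <- strsplit(gsub("\\|", "/", gt[i, ]), "/", fixed = FALSE)
    purrr::map(seq_along(alts), function(a) {
      dosage <- purrr::map_int(alleles, function(al) {
        if (length(al) == 0 || anyNA(al) || any(al == ".")) {
          NA_integer_
        } else {
          sum(al == as.character(a))
        }
      })
      tibble(
        sample_id = samples,
        variant_id = if (length(alts) == 1) id_base
                     else paste0(id_base, "_alt", a),
        chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a],
        is_indel = nchar(fix$REF[i]) != nchar(alts[a]),
        dosage = unname(dosage),
        dp = unname(as.integer(dp[i, ])), gq = unname(as.integer(gq[i, ]))
      )
    }) |> bind_rows()
  }) |> bind_rows()
  rows |> arrange(.data$chrom, .data$pos, .data$variant_id, .data$sample_id)
}

#' Write per-sample metadata as TSV
#' @param meta Metadata tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata_tsv <- function(meta, path) {
  readr::write_tsv(meta, path)
  invisible(path)
}

#' Read per-sample metadata from TSV
#' @param path TSV path.
#' @return Metadata tibble.
#' @export
read_metadata_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
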