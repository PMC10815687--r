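#' Default pipeline configuration
#'
#' Nested configuration for [run_pipeline()]: the synthetic-cohort
#' parameters, stage toggles and every stage's thresholds. Any subset can be
#' overridden by the `overrides` list (recursively merged) or supplied as a
#' YAML file to [run_pipeline()].
#'
#' @param overrides Named list merged over the defaults.
#' @return A nested configuration list.
#' @export
pipeline_config <- function(overrides = list()) {
  base <- list(
    seed = 1L,
    # WGS-cohort scale: the LD/QC stages model the sequenced subset, not the
    # full genotyped cohort, and the call-rate-1.0 filter is steep in n.
    cohort = list(n_samples = 202),
    stages = list(qc = TRUE, ld = TRUE, assoc = TRUE, amso = TRUE,
                  annotation = FALSE, qtl = FALSE),
    qc = list(min_depth = 10, min_quality = 30, min_call_rate = 1.0,
              exclude_indels = TRUE, low_coverage_min_span = 1000),
    ld = list(window_kb = 1200, r2_min = 0.99),
    assoc = list(
      controls = list(alt_alleles = 1259, total_alleles = 4912),
      models = c("allelic", "dominant", "recessive"),
      strata = c("all", "GBA1", "LRRK2", "NC"),
      dual = list(n_sim = 100000,
                  mutation_carrier_freqs = list(GBA1 = 0.065, LRRK2 = 0.018))
    ),
    amso = list(strata = c("all", "GBA1", "LRRK2", "NC")),
    annotation = list(path = NULL, cadd_min = 20),
    qtl = list(path = NULL, required_tissues = 13)
  )
  merge_config(base, overrides)
}

merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the canonical stage order — simulate, QC (region extraction,
#' call filters, variant filters, low-coverage scan), LD fine-mapping,
#' stratified association with the dual-carrier null, onset regression, and
#' optional annotation/QTL filtering from user tables — writing TSV/BED/VCF
#' outputs and a JSON manifest (seed, parameters, stage attrition counts,
#' output checksums) to `out_dir`. With a fixed seed two runs produce
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()] list, a partial override list, or a
#'   path to a YAML file with the same structure.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- pipeline_config(yaml::read_yaml(config))
  } else if (!identical(names(config),
                        names(pipeline_config()))) {
    config <- pipeline_config(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(out_dir, f)
  manifest <- list(package = "h2scan",
                   version = as.character(utils::packageVersion("h2scan")),
                   seed = config$seed, config = config, counts = list())
  note <- function(...) message(sprintf(...))

  # --- simulate ---------------------------------------------------------
  cohort_args <- config$cohort
  cohort_args$seed <- config$seed
  for (nm in c("region", "divergent_span")) {
    if (is.list(cohort_args[[nm]]) && !is.data.frame(cohort_args[[nm]])) {
      cohort_args[[nm]] <- genomic_interval(cohort_args[[nm]]$chrom,
                                            cohort_args[[nm]]$start,
                                            cohort_args[[nm]]$end)
    }
  }
  cfg <- do.call(cohort_config, cohort_args)
  cohort <- simulate_cohort(cfg)
  write_cohort_vcf(cohort, out("cohort.vcf"))
  write_metadata_tsv(cohort$meta, out("metadata.tsv"))
  manifest$counts$n_samples <- nrow(cohort$meta)
  manifest$counts$n_variants_simulated <- nrow(cohort$variants)
  note("simulate: %d samples, %d variants", nrow(cohort$meta),
       nrow(cohort$variants))

  calls <- cohort$calls
  # --- qc ---------------------------------------------------------------
  if (isTRUE(config$stages$qc)) {
    calls <- extract_region(calls, cfg$region)
    n_raw <- dplyr::n_distinct(calls$variant_id)
    calls <- apply_call_filters(calls, config$qc$min_depth,
                                config$qc$min_quality)
    calls <- filter_variants_for_ld(calls, config$qc$min_call_rate,
                                    config$qc$exclude_indels)
    n_kept <- dplyr::n_distinct(calls$variant_id)
    manifest$counts$n_variants_extracted <- n_raw
    manifest$counts$n_variants_post_filters <- n_kept
    note("qc: %d variants extracted, %d pass call-rate/indel filters",
         n_raw, n_kept)
    lowcov <- scan_low_coverage(depth_track(cohort$calls),
                                min_span = config$qc$low_coverage_min_span)
    write_bed(lowcov, out("low_coverage.bed"))
    manifest$counts$n_low_coverage_intervals <- nrow(lowcov)
  }

  # --- ld ---------------------------------------------------------------
  if (isTRUE(config$stages$ld) && !cfg$tag_id %in% calls$variant_id) {
    note("ld: tag variant %s removed by QC; stage skipped", cfg$tag_id)
    config$stages$ld <- FALSE
  }
  if (isTRUE(config$stages$ld)) {
    scan <- r2_scan(calls, cfg$tag_id, config$ld$window_kb)
    readr::write_tsv(as_tibble(scan), out("ld_stats.tsv"))
    divergent <- call_divergent_snvs(scan, config$ld$r2_min)
    readr::write_tsv(tibble(variant_id = divergent), out("divergent_snvs.tsv"))
    manifest$counts$n_divergent_snvs <- length(divergent)
    note("ld: %d haplotype-divergent SNVs (r2 >= %.2f)",
         length(divergent), config$ld$r2_min)
    hom <- find_tag_homozygotes(calls, cfg$tag_id)
    manifest$counts$n_tag_homozygotes <- length(hom)
    if (length(hom) > 0 && length(divergent) > 1) {
      segs <- detect_recombinant_segments(calls, hom, divergent, cfg$tag_id)
      readr::write_tsv(segs, out("recombinant_segments.tsv"))
      if (nrow(segs) > 0) {
        interval <- minimal_ld_interval(segs)
        write_bed(interval, out("minimal_ld_interval.bed"))
        manifest$counts$minimal_interval <-
          list(chrom = interval$chrom, start = interval$start,
               end = interval$end)
        note("ld: minimal LD interval %s:%d-%d (%.2f Mb)", interval$chrom,
             interval$start, interval$end, interval_width(interval) / 1e6)
      }
    } else {
      note("ld: no tag homozygotes; minimal interval skipped")
    }
  }

  # --- assoc ------------------------------------------------------------
  if (isTRUE(config$stages$assoc)) {
    ctrl <- control_frequencies(config$assoc$controls$alt_alleles,
                                config$assoc$controls$total_alleles)
    assoc <- stratified_association(cohort$meta, ctrl,
                                    models = config$assoc$models,
                                    strata = config$assoc$strata)
    readr::write_tsv(as_tibble(assoc), out("association.tsv"))
    manifest$counts$n_association_rows <- nrow(assoc)

    exp_freq <- hwe_carrier_freq(ctrl$alt_freq)
    dual_rows <- purrr::imap(
      config$assoc$dual$mutation_carrier_freqs,
      function(mut_freq, grp) {
        sub <- cohort$meta |> filter(.data$subgroup == grp)
        k <- sum(sub$h2_carrier); n <- nrow(sub)
        if (n == 0) return(NULL)
        sim <- simulate_dual_carriers(config$assoc$dual$n_sim, mut_freq,
                                      exp_freq, seed = config$seed)
        closed <- dual_carrier_test(k, n,
                                    expected_h2_carrier_freq = exp_freq,
                                    haldane = k == 0 || k == n)
        mc <- dual_carrier_test(k, n, simulated = sim,
                                haldane = k == 0 || k == n)
        bind_rows(closed |> mutate(path = "closed_form", group = grp),
                  mc |> mutate(path = "monte_carlo", group = grp))
      }) |> bind_rows()
    if (ncol(dual_rows) > 0) {
      readr::write_tsv(dual_rows, out("dual_carrier.tsv"))
    }
  }

  # --- amso -------------------------------------------------------------
  if (isTRUE(config$stages$amso)) {
    excl <- amso_exclusion_filter(cohort$meta)
    readr::write_tsv(excl$report, out("amso_exclusions.tsv"))
    fits <- purrr::map(config$amso$strata, function(s) {
      tryCatch(tidy(fit_amso_regression(excl$meta, s)),
               error = function(e) {
                 note("amso: stratum '%s' skipped (%s)", s, conditionMessage(e))
                 NULL
               })
    }) |> bind_rows()
    if (ncol(fits) > 0) readr::write_tsv(fits, out("amso_regression.tsv"))
    manifest$counts$n_amso_excluded <-
      excl$report$n[excl$report$reason == "total_excluded"]
  }

  # --- annotation / qtl -------------------------------------------------
  if (isTRUE(config$stages$annotation)) {
    path <- config$annotation$path
    if (is.null(path) || !file.exists(path)) {
      abort(sprintf("annotation stage: input table not found: %s",
                    path %||% "<unset>"))
    }
    ann <- readr::read_tsv(path, show_col_types = FALSE)
    kept <- filter_cadd(ann, config$annotation$cadd_min)
    readr::write_tsv(candidate_table(kept), out("candidate_variants.tsv"))
    manifest$counts$n_cadd_survivors <- nrow(kept)
  }
  if (isTRUE(config$stages$qtl)) {
    path <- config$qtl$path
    if (is.null(path) || !file.exists(path)) {
      abort(sprintf("qtl stage: input table not found: %s",
                    path %||% "<unset>"))
    }
    qtl <- readr::read_tsv(path, show_col_types = FALSE)
    eqtl <- qtl |> filter(.data$qtl_type == "expression") |> filter_eqtl()
    sqtl <- qtl |> filter(.data$qtl_type == "splicing") |> filter_sqtl()
    cons <- bind_rows(eqtl, sqtl) |>
      cross_tissue_consistency(required_tissues = config$qtl$required_tissues)
    readr::write_tsv(cons, out("qtl_consistency.tsv"))
    manifest$counts$n_qtl_significant <- nrow(eqtl) + nrow(sqtl)
  }

  files <- setdiff(list.files(out_dir), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest$outputs <- as.list(setNames(unname(sums), files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
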