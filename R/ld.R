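# Wide dosage matrix (samples x variants) from the long call tibble.
dosage_matrix <- function(calls) {
  samples <- sort(unique(calls$sample_id))
  vars <- calls |> distinct(.data$variant_id, .data$pos) |> arrange(.data$pos)
  mat <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(vars),
                dimnames = list(samples, vars$variant_id))
  mat[cbind(match(calls$sample_id, samples),
            match(calls$variant_id, vars$variant_id))] <- calls$dosage
  mat
}

#' Tag-SNV linkage disequilibrium scan
#'
#' Computes composite (genotypic) r-squared — the squared Pearson correlation
#' of dosage vectors — between a tag SNV and every other SNV within
#' `window_kb` of it, over samples non-missing at both sites. Indels are
#' skipped; partners monomorphic among the usable samples are reported with
#' `r_squared = NA` and `excluded = TRUE`.
#'
#' @param calls Long call tibble (post QC filters; see
#'   [apply_call_filters()] and [filter_variants_for_ld()]).
#' @param tag_id Variant identifier of the tag SNV; must be present and
#'   polymorphic.
#' @param window_kb Scan window half-width in kb around the tag (default
#'   1200).
#' @return A tibble of class `h2_ld_scan`: `variant_id`, `chrom`, `pos`,
#'   `r_squared`, `n_used`, `excluded`, sorted by position. The tag row has
#'   `r_squared = 1`.
#' @examples
#' ch <- simulate_cohort(cohort_config(n_samples = 60, missing_rate = 0, seed = 3))
#' scan <- r2_scan(ch$calls, tag_id = "tagSNV")
#' head(scan)
#' @export
r2_scan <- function(calls, tag_id, window_kb = 1200) {
  check_calls(calls)
  if (!tag_id %in% calls$variant_id) {
    abort(sprintf("tag variant '%s' not present in calls", tag_id))
  }
  if (!"is_indel" %in% names(calls)) {
    calls$is_indel <- nchar(calls$ref) != nchar(calls$alt)
  }
  snvs <- calls |> filter(!.data$is_indel)
  mat <- dosage_matrix(snvs)
  vars <- snvs |> distinct(.data$variant_id, .data$chrom, .data$pos) |>
    arrange(.data$pos)
  tag <- mat[, tag_id]
  if (length(unique(tag[!is.na(tag)])) < 2) {
    abort("tag variant is monomorphic: r-squared is undefined")
  }
  tag_pos <- vars$pos[vars$variant_id == tag_id]
  in_win <- abs(vars$pos - tag_pos) <= window_kb * 1000
  vars <- vars[in_win, ]
  stats <- purrr::map(vars$variant_id, function(v) {
    y <- mat[, v]
    ok <- !is.na(tag) & !is.na(y)
    n <- sum(ok)
    if (n < 2 || stats::var(tag[ok]) == 0 || stats::var(y[ok]) == 0) {
      return(tibble(r_squared = NA_real_, n_used = n, excluded = TRUE))
    }
    tibble(r_squared = cor(tag[ok], y[ok])^2, n_used = n, excluded = FALSE)
  }) |> bind_rows()
  out <- dplyr::bind_cols(vars, stats)
  attr(out, "tag_id") <- tag_id
  attr(out, "tag_pos") <- tag_pos
  class(out) <- c("h2_ld_scan", class(out))
  out
}

#' Call haplotype-divergent SNVs from an LD scan
#'
#' Variants in (near-)perfect LD with the tag — r-squared at or above
#' `r2_min` — are called haplotype-divergent: fixed for different alleles on
#' the two haplotype classes. The tag itself is always included.
#'
#' @param stats An LD scan tibble from [r2_scan()].
#' @param r2_min Divergence threshold (default 0.99, operationalising
#'   "r-squared approximately 1" while tolerating finite-sample rounding).
#' @return Character vector of variant identifiers, ordered by position.
#' @export
call_divergent_snvs <- function(stats, r2_min = 0.99) {
  keep <- stats |>
    filter(!.data$excluded, .data$r_squared >= r2_min) |>
    arrange(.data$pos)
  ids <- keep$variant_id
  tag <- attr(stats, "tag_id")
  if (!is.null(tag) && !tag %in% ids) {
    ids <- stats |>
      filter(.data$variant_id %in% c(ids, tag)) |>
      arrange(.data$pos) |> pull("variant_id")
  }
  ids
}

#' Identify tag-SNV homozygotes
#'
#' Samples carrying two copies of the tag's alternate (haplotype-tagging)
#' allele; on the H2-tagged coding these are the H2/H2 individuals whose
#' recombinant alleles narrow the LD interval.
#'
#' @inheritParams r2_scan
#' @return Character vector of sample identifiers.
#' @export
find_tag_homozygotes <- function(calls, tag_id) {
  check_calls(calls)
  if (!tag_id %in% calls$variant_id) {
    abort(sprintf("tag variant '%s' not present in calls", tag_id))
  }
  calls |>
    filter(.data$variant_id == tag_id, !is.na(.data$dosage),
           .data$dosage == 2L) |>
    pull("sample_id") |> sort()
}

#' Detect recombinant segments in tag homozygotes
#'
#' For each tag homozygote, finds the maximal contiguous run of divergent
#' sites at dosage 2, extended outward from the tag. A site below dosage 2
#' beyond the run marks a recombination breakpoint; the affected side is
#' labelled `proximal` (lower coordinates), `distal`, `both`, or `none` for
#' a fully consistent haplotype pair.
#'
#' Samples with a missing call at any divergent site are dropped with a
#' warning (the call-rate filter normally guarantees completeness).
#'
#' @inheritParams r2_scan
#' @param homozygotes Sample identifiers from [find_tag_homozygotes()].
#' @param divergent Variant identifiers of the divergent set (order is
#'   re-derived from positions internally).
#' @return Tibble with one row per homozygote: `sample_id`, `chrom`,
#'   `start`, `end` (the consistent interval, always containing the tag) and
#'   `breakpoint_side`.
#' @export
detect_recombinant_segments <- function(calls, homozygotes, divergent,
                                        tag_id) {
  check_calls(calls)
  if (length(homozygotes) == 0) abort("no tag homozygotes supplied")
  if (!tag_id %in% divergent) divergent <- c(divergent, tag_id)
  dv <- calls |>
    filter(.data$variant_id %in% divergent) |>
    distinct(.data$variant_id, .data$chrom, .data$pos) |>
    arrange(.data$pos)
  sub <- calls |>
    filter(.data$variant_id %in% divergent,
           .data$sample_id %in% homozygotes)
  mat <- dosage_matrix(sub)
  mat <- mat[, dv$variant_id, drop = FALSE]
  i_tag <- match(tag_id, dv$variant_id)
  k <- nrow(dv)
  rows <- purrr::map(homozygotes, function(s) {
    d <- mat[s, ]
    if (anyNA(d)) {
      warn(sprintf("sample %s has missing calls at divergent sites; skipped", s))
      return(NULL)
    }
    if (d[i_tag] != 2L) {
      abort(sprintf("sample %s is not homozygous at the tag: inconsistent input", s))
    }
    lo <- i_tag
    while (lo > 1 && d[lo - 1] == 2L) lo <- lo - 1
    hi <- i_tag
    while (hi < k && d[hi + 1] == 2L) hi <- hi + 1
    side <- if (lo > 1 && hi < k) "both"
            else if (lo > 1) "proximal"
            else if (hi < k) "distal"
            else "none"
    tibble(sample_id = s, chrom = dv$chrom[1],
           start = dv$pos[lo], end = dv$pos[hi], breakpoint_side = side)
  })
  bind_rows(rows)
}

#' Minimal LD interval across tag homozygotes
#'
#' Intersects the consistent intervals of all homozygotes: the endpoints are
#' the outermost divergent SNV positions consistent in every individual.
#' Recombinant alleles therefore shrink the interval; adding a segment can
#' never widen it.
#'
#' @param segments Segment tibble from [detect_recombinant_segments()].
#' @return A one-row [genomic_interval()].
#' @export
minimal_ld_interval <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0) {
    abort("no segments supplied: minimal interval is undefined")
  }
  start <- max(segments$start)
  end <- min(segments$end)
  if (start > end) {
    abort("consistent intervals have empty intersection: check tag variant and data")
  }
  genomic_interval(segments$chrom[1], start, end)
}

#' @export
print.h2_ld_scan <- function(x, ...) {
  cat(sprintf("<h2_ld_scan> tag %s @ %s; %d variants (%d excluded)\n",
              attr(x, "tag_id"), format(attr(x, "tag_pos"), big.mark = ","),
              nrow(x), sum(x$excluded)))
  NextMethod()
}
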