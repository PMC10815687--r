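#' Mask genotype calls failing depth/quality thresholds
#'
#' Sets the dosage of any call with read depth below `min_depth` or genotype
#' quality below `min_quality` to missing. Both comparisons are strict
#' ("lower than"), so a call at exactly DP 10 / GQ 30 passes the defaults.
#' Dimensions are unchanged: no rows are dropped, only dosages masked.
#'
#' @param calls Long call tibble (`sample_id`, `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `is_indel`, `dosage`, `dp`, `gq`), e.g.
#'   `simulate_cohort()$calls` or [read_genotype_vcf()].
#' @param min_depth,min_quality Non-negative thresholds (defaults 10 and 30).
#' @return The call tibble with failing dosages set to `NA`.
#' @examples
#' calls <- simulate_cohort(cohort_config(n_samples = 10, seed = 1))$calls
#' filtered <- apply_call_filters(calls)
#' @export
apply_call_filters <- function(calls, min_depth = 10, min_quality = 30) {
  if (min_depth < 0 || min_quality < 0) {
    abort("filter thresholds must be non-negative")
  }
  check_calls(calls)
  fail <- (!is.na(calls$dp) & calls$dp < min_depth) |
    (!is.na(calls$gq) & calls$gq < min_quality)
  calls$dosage[fail] <- NA_integer_
  calls
}

#' Drop variants unsuitable for LD analysis
#'
#' Removes variants whose non-missing call fraction is below `min_call_rate`
#' and, by default, all indels. Intended to run after [apply_call_filters()]
#' so that quality-masked calls count as missing. The sample set is
#' unchanged.
#'
#' @inheritParams apply_call_filters
#' @param min_call_rate Minimum fraction of non-missing calls (default 1.0:
#'   any missingness drops the variant).
#' @param exclude_indels Drop variants whose ref/alt lengths differ.
#' @return The call tibble restricted to passing variants.
#' @export
filter_variants_for_ld <- function(calls, min_call_rate = 1.0,
                                   exclude_indels = TRUE) {
  check_calls(calls)
  if (!"is_indel" %in% names(calls)) {
    calls$is_indel <- nchar(calls$ref) != nchar(calls$alt)
  }
  if (nrow(calls) == 0) return(calls)
  keep <- calls |>
    group_by(.data$variant_id) |>
    summarise(call_rate = mean(!is.na(.data$dosage)),
              is_indel = .data$is_indel[1], .groups = "drop") |>
    filter(.data$call_rate >= min_call_rate,
           !(.env$exclude_indels & .data$is_indel)) |>
    pull("variant_id")
  calls |> filter(.data$variant_id %in% keep)
}

#' Restrict calls to a genomic interval
#'
#' Keeps variants with `start <= pos <= end`; both endpoints are inclusive,
#' matching the printed-coordinate convention used throughout.
#'
#' @inheritParams apply_call_filters
#' @param region A [genomic_interval()].
#' @return The call tibble restricted to the region. If the region's
#'   chromosome matches no call, an empty tibble is returned with a warning.
#' @export
extract_region <- function(calls, region) {
  check_calls(calls)
  stopifnot(nrow(region) == 1)
  out <- calls |>
    filter(.data$chrom == region$chrom,
           .data$pos >= region$start, .data$pos <= region$end)
  if (nrow(calls) > 0 && !any(calls$chrom == region$chrom)) {
    warn(sprintf("no calls on chromosome '%s'; returning empty result",
                 region$chrom))
  }
  out
}

#' Cohort-mean depth per position
#'
#' Collapses a call tibble to one mean read depth per variant position, the
#' input expected by [scan_low_coverage()].
#'
#' @inheritParams apply_call_filters
#' @return Tibble with `chrom`, `pos`, `depth` sorted by position.
#' @export
depth_track <- function(calls) {
  check_calls(calls)
  calls |>
    group_by(.data$chrom, .data$pos) |>
    summarise(depth = mean(.data$dp, na.rm = TRUE), .groups = "drop") |>
    arrange(.data$pos)
}

#' Scan a depth track for low-coverage intervals
#'
#' Finds maximal runs of consecutive track positions whose depth is strictly
#' below `threshold` and whose genomic span is at least `min_span` bp,
#' returned as 1-based inclusive intervals. Runs separated by even a single
#' position at or above the threshold are never merged. The track may be a
#' dense per-base profile or a sparse per-variant one; runs are over
#' consecutive track entries and the span is genomic.
#'
#' @param track Tibble with columns `pos` (ascending, unique) and `depth`;
#'   an optional `chrom` column is carried through.
#' @param threshold Depth below which a position counts as low coverage.
#'   Default: 25% of the track's median depth.
#' @param min_span Minimum run length in bp (default 1000).
#' @return Tibble of intervals (`chrom`, `start`, `end`), disjoint and
#'   sorted; empty for an empty track.
#' @examples
#' track <- tibble::tibble(pos = 1:5000,
#'                         depth = ifelse(dplyr::between(1:5000, 1001, 2500), 3, 30))
#' scan_low_coverage(track, threshold = 10, min_span = 1000)
#' @export
scan_low_coverage <- function(track, threshold = NULL, min_span = 1000) {
  empty <- genomic_interval(character(0), numeric(0), numeric(0))
  if (is.null(track) || nrow(track) == 0) return(empty)
  stopifnot(all(c("pos", "depth") %in% names(track)))
  track <- track[order(track$pos), ]
  if (anyDuplicated(track$pos)) {
    abort("depth track positions must be unique")
  }
  if (is.null(threshold)) threshold <- 0.25 * stats::median(track$depth)
  chrom <- if ("chrom" %in% names(track)) track$chrom[1] else "."
  r <- rle(track$depth < threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  span <- track$pos[ends] - track$pos[starts] + 1
  low <- which(r$values & span >= min_span)
  if (length(low) == 0) return(empty)
  genomic_interval(rep(chrom, length(low)),
                   track$pos[starts[low]], track$pos[ends[low]])
}

check_calls <- function(calls) {
  needed <- c("sample_id", "variant_id", "chrom", "pos", "dosage", "dp", "gq")
  missing <- setdiff(needed, names(calls))
  if (length(missing) > 0) {
    abort(paste0("call tibble is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(calls)
}
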