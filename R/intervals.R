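#' Construct a 1-based inclusive genomic interval
#'
#' Intervals in h2scan follow the coordinate style of printed genome-browser
#' spans: 1-based, with both endpoints included. They are represented as
#' one-row tibbles so that lists of intervals stack with `bind_rows()`.
#'
#' @param chrom Contig name, e.g. `"chr17"`.
#' @param start,end 1-based inclusive endpoints; `start <= end`.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @examples
#' genomic_interval("chr17", 45394449, 46808970)
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == length(start),
            length(start) == length(end))
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 1) || any(end < start)) {
    abort("interval requires 1 <= start <= end")
  }
  tibble(chrom = chrom, start = start, end = end)
}

#' Interval width in base pairs (inclusive)
#' @param interval A tibble as returned by [genomic_interval()].
#' @return Numeric vector of widths.
#' @export
interval_width <- function(interval) {
  interval$end - interval$start + 1
}

#' Write intervals as BED
#'
#' Internally all coordinates are 1-based inclusive; conversion to BED's
#' 0-based half-open convention happens only here, at the writer.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  bed <- tibble(
    chrom = intervals$chrom,
    start = format(intervals$start - 1, scientific = FALSE, trim = TRUE),
    end = format(intervals$end, scientific = FALSE, trim = TRUE)
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
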