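# Genomic intervals are plain data frames with columns chrom/start/end,
# 1-based and inclusive at both ends. BED and bedGraph files are converted at
# the I/O boundary (see io.R); everything inside the package uses this one
# convention, which matches how region coordinates are printed in genome
# papers (e.g. an SDR span written "Chr14: 39979216-52678755").

#' Construct a genomic interval table
#'
#' @param chrom chromosome names (character)
#' @param start 1-based inclusive start positions
#' @param end 1-based inclusive end positions (`end >= start`)
#' @param ... further equal-length columns to carry along
#' @return a `data.frame` with columns `chrom`, `start`, `end` (and any extras)
#' @export
gi <- function(chrom, start, end, ...) {
  out <- data.frame(chrom = as.character(chrom),
                    start = as.numeric(start),
                    end = as.numeric(end),
                    ...,
                    stringsAsFactors = FALSE)
  validate_gi(out)
  out
}

#' @noRd
validate_gi <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 1)) stop("interval start must be >= 1")
  if (any(x$end < x$start)) stop("interval end must be >= start")
  invisible(x)
}

#' Interval length in base pairs (inclusive convention)
#'
#' @param x interval table from [gi()]
#' @return numeric vector `end - start + 1`
#' @export
gi_length_bp <- function(x) {
  validate_gi(x)
  x$end - x$start + 1
}

#' Convert an interval table to a GRanges
#' @noRd
gi_to_gr <- function(x) {
  validate_gi(x)
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
}

#' Convert a GRanges back to an interval table
#' @noRd
gr_to_gi <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Merge overlapping or bookended intervals
#' @param x interval table
#' @return interval table with overlaps collapsed
#' @export
gi_reduce <- function(x) {
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  gr_to_gi(GenomicRanges::reduce(gi_to_gr(x)))
}

#' Report interval spans the way genome papers print them
#'
#' Span lengths are reported in Mb as `(end - start) / 1e6`, rounded half-up
#' to two decimals. The subtraction convention (no `+ 1`) is deliberate:
#' printed spans such as 39979216-52678755 "(12.70 Mb)" correspond to
#' `end - start` (12 699 539 bp), and the same table reproduces 3.38, 11.77
#' and 2.51 Mb for the other published sex-chromosome spans.
#'
#' @param x interval table from [gi()]
#' @return `x` with added columns `span_bp` (`end - start`), `length_bp`
#'   (inclusive length) and `length_mb` (2-decimal span in Mb)
#' @export
interval_report <- function(x) {
  validate_gi(x)
  x$span_bp <- x$end - x$start
  x$length_bp <- x$end - x$start + 1
  x$length_mb <- round_half_up(x$span_bp / 1e6, 2)
  x
}
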