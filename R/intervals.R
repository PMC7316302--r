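# Genomic intervals are plain data frames with columns chrom/start/end in
# 0-based half-open (BED) coordinates. GRanges (1-based closed) is used for
# overlap machinery; conversion happens only at these two helpers.

#' Validate a genomic interval table
#'
#' Checks for chrom/start/end columns, numeric coordinates, and strictly
#' positive widths (`start < end`, 0-based half-open). Input row order is
#' preserved.
#'
#' @param x data frame with at least `chrom`, `start`, `end`.
#' @param context label used in error messages.
#' @return `x`, with coordinates coerced to numeric.
#' @export
validate_intervals <- function(x, context = "interval table") {
  if (!is.data.frame(x)) stop(context, " must be a data frame", call. = FALSE)
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop(context, " lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  if (anyNA(x$start) || anyNA(x$end)) {
    stop(context, ": non-numeric start/end", call. = FALSE)
  }
  if (any(x$start < 0)) stop(context, ": negative start", call. = FALSE)
  bad <- which(x$start >= x$end)
  if (length(bad)) {
    stop(sprintf("%s: zero- or negative-length interval at row %d (%s:%g-%g)",
                 context, bad[1], x$chrom[bad[1]], x$start[bad[1]],
                 x$end[bad[1]]), call. = FALSE)
  }
  x
}

intervals_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

gr_to_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

interval_sort_order <- function(x) order(x$chrom, x$start, x$end)
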