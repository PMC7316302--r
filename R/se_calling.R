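# Per-sample ROSE-style superenhancer calling: stitch peaks within 12.5 kb,
# score stitched regions by depth-adjusted, input-subtracted signal, rank,
# and classify everything beyond the rank-curve inflection as an SE.

#' Stitch enhancer peaks into candidate regions
#'
#' Adjacent peaks are merged into one stitched region when the gap between
#' them (`next start - previous end`) is at most `stitch_distance`; the
#' comparison is inclusive, matching ROSE's "within 12.5 kb" semantics.
#' With `tss_exclusion > 0`, peaks falling entirely inside a TSS interval
#' extended by `tss_exclusion` on both sides are removed before stitching;
#' the default 0 performs no exclusion.
#'
#' @param peaks interval data frame of peak calls.
#' @param stitch_distance bp; inclusive maximum gap.
#' @param tss optional interval data frame of TSS positions.
#' @param tss_exclusion bp; TSS window half-width (0 disables).
#' @return data frame of stitched regions (`chrom`, `start`, `end`,
#'   `n_constituents`) with a `constituents` list column holding each
#'   region's source peak intervals. Regions are in genomic order.
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500, tss = NULL,
                         tss_exclusion = 0) {
  if (stitch_distance < 0) stop("stitch_distance must be non-negative",
                                call. = FALSE)
  peaks <- validate_intervals(peaks, "peaks")
  if (tss_exclusion > 0 && !is.null(tss) && nrow(tss)) {
    tss <- validate_intervals(
      data.frame(chrom = tss$chrom,
                 start = pmax(0, tss$start - tss_exclusion),
                 end = tss$end + tss_exclusion), "TSS windows")
    inside <- GenomicRanges::countOverlaps(
      intervals_to_gr(peaks), intervals_to_gr(tss), type = "within") > 0
    peaks <- peaks[!inside, , drop = FALSE]
  }
  if (!nrow(peaks)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_constituents = integer())
    out$constituents <- list()
    return(out)
  }
  peaks <- peaks[interval_sort_order(peaks), , drop = FALSE]
  rownames(peaks) <- NULL
  n <- nrow(peaks)
  # sweep: a sorted peak joins the open region iff its gap to the running
  # maximum end is <= stitch_distance (transitive closure of the gap
  # relation, since components are contiguous in start order)
  region_id <- integer(n)
  region_id[1] <- 1L
  cur_end <- peaks$end[1]
  cur_chrom <- peaks$chrom[1]
  for (i in seq_len(n)[-1]) {
    if (peaks$chrom[i] == cur_chrom &&
        peaks$start[i] - cur_end <= stitch_distance) {
      region_id[i] <- region_id[i - 1]
      cur_end <- max(cur_end, peaks$end[i])
    } else {
      region_id[i] <- region_id[i - 1] + 1L
      cur_end <- peaks$end[i]
      cur_chrom <- peaks$chrom[i]
    }
  }
  idx <- split(seq_len(n), region_id)
  out <- data.frame(
    chrom = vapply(idx, function(i) peaks$chrom[i[1]], ""),
    start = vapply(idx, function(i) min(peaks$start[i]), 0),
    end = vapply(idx, function(i) max(peaks$end[i]), 0),
    n_constituents = lengths(idx),
    stringsAsFactors = FALSE
  )
  out$constituents <- lapply(idx, function(i) {
    peaks[i, c("chrom", "start", "end"), drop = FALSE]
  })
  rownames(out) <- NULL
  out
}

#' Score stitched regions by input-subtracted, depth-adjusted signal
#'
#' `signal = max(0, chip/(chip_lib/1e6) - input/(input_lib/1e6))`: both
#' counts are scaled to reads per million before the paired input is
#' subtracted, and negative values are floored at zero (background in
#' excess of ChIP is not meaningful enhancer signal).
#'
#' @param regions stitched region data frame.
#' @param chip_counts,input_counts per-region read counts, aligned to
#'   `regions` rows.
#' @param chip_lib,input_lib total mapped reads per track.
#' @return `regions` with a `signal` column appended.
#' @export
score_regions <- function(regions, chip_counts, input_counts,
                          chip_lib, input_lib) {
  if (length(chip_counts) != nrow(regions) ||
      length(input_counts) != nrow(regions)) {
    stop("counts must align with regions (length mismatch)", call. = FALSE)
  }
  if (chip_lib <= 0 || input_lib <= 0) {
    stop("library sizes must be positive", call. = FALSE)
  }
  regions$signal <- pmax(0, chip_counts / (chip_lib / 1e6) -
                            input_counts / (input_lib / 1e6))
  regions
}

#' Classify superenhancers at the rank-curve inflection
#'
#' Regions are ranked ascending by signal (ties broken by genomic order),
#' ranks and signals are min-max scaled to the unit square, and the cutoff
#' rank is the point maximizing `x - y` -- the discrete equivalent of
#' ROSE's slope-1 tangent to the ranked signal curve. Every region ranked
#' above the cutoff is a superenhancer.
#'
#' @param regions scored region data frame (needs a `signal` column).
#' @return A `rose_table`: `regions` in rank order with `signal`, `rank`
#'   and `is_SE` columns, plus attribute `cutoff_rank`. If all signals are
#'   equal the curve is degenerate: no SEs, with a warning.
#' @export
classify_superenhancers <- function(regions) {
  if (is.null(regions$signal)) stop("regions must carry a signal column",
                                    call. = FALSE)
  n <- nrow(regions)
  if (n < 2) stop("need at least 2 scored regions", call. = FALSE)
  ord <- order(regions$signal, regions$chrom, regions$start)
  tab <- regions[ord, , drop = FALSE]
  tab$rank <- seq_len(n)
  rownames(tab) <- NULL
  s <- tab$signal
  if (max(s) == min(s)) {
    warning("all region signals are equal; degenerate rank curve, no SEs",
            call. = FALSE)
    tab$is_SE <- FALSE
    return(structure(tab, cutoff_rank = n, class = c("rose_table",
                                                     class(tab))))
  }
  x <- (tab$rank - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  cutoff <- which.max(x - y)
  tab$is_SE <- tab$rank > cutoff
  structure(tab, cutoff_rank = cutoff, class = c("rose_table", class(tab)))
}

#' Call superenhancers for one sample from peaks and coverage
#'
#' Convenience wrapper running [stitch_peaks()], coverage counting,
#' [score_regions()] and [classify_superenhancers()].
#'
#' @param peaks peak interval data frame.
#' @param chip_coverage,input_coverage bedGraph data frames.
#' @param chip_lib,input_lib library sizes (total mapped reads).
#' @param config an [se_config()].
#' @param tss optional TSS intervals for exclusion.
#' @return a `rose_table`.
#' @export
call_superenhancers <- function(peaks, chip_coverage, input_coverage,
                                chip_lib, input_lib, config = se_config(),
                                tss = NULL) {
  regions <- stitch_peaks(peaks, config$stitch_distance, tss,
                          config$tss_exclusion)
  chip <- interval_coverage(chip_coverage, regions)
  inp <- interval_coverage(input_coverage, regions)
  classify_superenhancers(
    score_regions(regions, chip, inp, chip_lib, input_lib))
}

#' @export
print.rose_table <- function(x, ...) {
  cat(sprintf("<rose_table> %d stitched regions, %d superenhancers\n",
              nrow(x), sum(x$is_SE)))
  cutoff <- attr(x, "cutoff_rank")
  cat(sprintf("  inflection at rank %d (signal %.3g)\n",
              cutoff, x$signal[cutoff]))
  invisible(x)
}

#' Plot the ranked enhancer signal curve
#'
#' The classic hockey-stick: regions ordered by signal, with the
#' inflection cutoff marked and superenhancers highlighted.
#'
#' @param x a `rose_table`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rose_table <- function(x, ...) {
  graphics::plot(x$rank, x$signal, type = "l",
                 xlab = "enhancer rank", ylab = "input-subtracted signal",
                 ...)
  graphics::points(x$rank[x$is_SE], x$signal[x$is_SE], col = "firebrick",
                   pch = 16, cex = 0.6)
  graphics::abline(v = attr(x, "cutoff_rank"), lty = 2, col = "grey40")
  invisible(x)
}
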