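# Score every sample against the consensus map: input-subtracted RPKM per
# bin, element-level scores (length-weighted mean of bin RPKMs = the
# whole-element RPKM), SE presence calls at log2(RPKM+1) >= 6, and the
# signal-mass "SE size" used wherever the analysis speaks of size.

#' Reads per kilobase per million mapped reads
#'
#' `count / ((length/1000) * (library/1e6))`. Invariant under uniform
#' duplication of all reads (count and library scale together).
#'
#' @param count reads (or fractional coverage sum) in the interval.
#' @param length interval length in bp (> 0).
#' @param library total mapped reads (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(count, length, library) {
  if (any(length <= 0)) stop("interval length must be positive",
                             call. = FALSE)
  if (any(library <= 0)) stop("library size must be positive",
                              call. = FALSE)
  count / ((length / 1000) * (library / 1e6))
}

#' Score samples against consensus intervals
#'
#' For every interval and sample computes
#' `max(0, RPKM_chip - RPKM_input)` using each sample's paired ChIP and
#' input counts and library sizes, and the log2(value+1) transform used
#' for presence calls and clustering.
#'
#' @param intervals consensus bins (or elements) with `chrom`, `start`,
#'   `end`; an `element_id` column is carried along for aggregation, and
#'   `bin_id`/`element_id` provide rownames.
#' @param chip_counts,input_counts numeric matrices (intervals x samples),
#'   columns named by sample.
#' @param metadata sample metadata (see [read_sample_metadata()]); every
#'   scored sample needs paired chip and input library sizes.
#' @return An `se_score_matrix`: list with `values` and `log2` matrices,
#'   the scored `intervals`, and `samples`.
#' @export
score_samples <- function(intervals, chip_counts, input_counts, metadata) {
  metadata <- validate_sample_metadata(metadata)
  intervals <- validate_intervals(intervals, "consensus intervals")
  samples <- colnames(chip_counts)
  if (is.null(samples)) stop("chip_counts needs sample column names",
                             call. = FALSE)
  if (!identical(samples, colnames(input_counts))) {
    missing_input <- setdiff(samples, colnames(input_counts))
    stop("sample(s) missing paired input counts: ",
         paste(missing_input, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(samples, metadata$sample_id)
  if (length(absent)) {
    stop("sample(s) missing from metadata: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  md <- metadata[match(samples, metadata$sample_id), ]
  len <- intervals$end - intervals$start
  vals <- matrix(0, nrow(intervals), length(samples),
                 dimnames = list(interval_ids(intervals), samples))
  for (j in seq_along(samples)) {
    vals[, j] <- pmax(0, rpkm(chip_counts[, j], len, md$chip_library_size[j]) -
                         rpkm(input_counts[, j], len,
                              md$input_library_size[j]))
  }
  structure(list(values = vals, log2 = log2(vals + 1),
                 intervals = intervals, samples = samples),
            class = "se_score_matrix")
}

interval_ids <- function(intervals) {
  if (!is.null(intervals$bin_id)) return(intervals$bin_id)
  if (!is.null(intervals$element_id)) return(intervals$element_id)
  sprintf("%s:%g-%g", intervals$chrom, intervals$start, intervals$end)
}

#' Aggregate bin-level scores to consensus elements
#'
#' `statistic = "rpkm"` returns the length-weighted mean of bin RPKMs,
#' which equals the RPKM of the whole element (counts are additive over
#' the bin partition); this is the scale the SE presence cutoff lives on.
#' `statistic = "size"` returns the plain sum of bin values -- the
#' signal-mass surrogate used wherever the analysis refers to "SE size"
#' (genomic width is fixed per consensus element, so signal is the only
#' sample-varying size).
#'
#' @param scores a bin-level `se_score_matrix` whose intervals carry
#'   `element_id`.
#' @param statistic `"rpkm"` or `"size"`.
#' @return An element-level `se_score_matrix`.
#' @export
element_scores <- function(scores, statistic = c("rpkm", "size")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(scores, "se_score_matrix"))
  bins <- scores$intervals
  if (is.null(bins$element_id)) {
    stop("scores are not bin-level (no element_id)", call. = FALSE)
  }
  len <- bins$end - bins$start
  ids <- unique(bins$element_id)
  if (statistic == "rpkm") {
    num <- rowsum(scores$values * len, bins$element_id, reorder = FALSE)
    vals <- num / as.vector(rowsum(len, bins$element_id, reorder = FALSE))
  } else {
    vals <- rowsum(scores$values, bins$element_id, reorder = FALSE)
  }
  vals <- vals[ids, , drop = FALSE]
  spans <- do.call(rbind, lapply(split(seq_len(nrow(bins)),
                                       bins$element_id)[ids],
                                 function(i) {
    data.frame(element_id = bins$element_id[i[1]], chrom = bins$chrom[i[1]],
               start = min(bins$start[i]), end = max(bins$end[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(spans) <- NULL
  structure(list(values = vals, log2 = log2(vals + 1), intervals = spans,
                 samples = scores$samples),
            class = "se_score_matrix")
}

#' Call SE presence per element and sample
#'
#' An element is present as a superenhancer in a sample iff
#' `log2(score + 1) >= se_log_cutoff` (inclusive threshold).
#'
#' @param scores an `se_score_matrix` (typically element-level RPKM) or a
#'   plain matrix of non-negative score values.
#' @param se_log_cutoff log2(RPKM+1) cutoff (default 6).
#' @return logical matrix, same dimensions as the score values.
#' @export
call_presence <- function(scores, se_log_cutoff = 6) {
  lv <- if (inherits(scores, "se_score_matrix")) scores$log2
        else log2(scores + 1)
  lv >= se_log_cutoff
}

#' Per-sample SE size of one element
#'
#' Sum of the element's bin values in each sample (signal mass).
#'
#' @param scores bin-level `se_score_matrix`.
#' @param element element id.
#' @return named numeric vector over samples (all zero if the element has
#'   no signal).
#' @export
se_size <- function(scores, element) {
  stopifnot(inherits(scores, "se_score_matrix"))
  rows <- scores$intervals$element_id == element
  if (!any(rows)) stop("unknown element: ", element, call. = FALSE)
  colSums(scores$values[rows, , drop = FALSE])
}

#' @export
print.se_score_matrix <- function(x, ...) {
  lvl <- if (!is.null(x$intervals$bin_id)) "bins" else "elements"
  cat(sprintf("<se_score_matrix> %d %s x %d samples\n",
              nrow(x$values), lvl, ncol(x$values)))
  cat(sprintf("  score range %.3g-%.3g RPKM\n", min(x$values),
              max(x$values)))
  invisible(x)
}
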