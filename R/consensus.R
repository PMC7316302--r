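# Cross-sample consensus maps: merge per-sample elements that share at
# least a minimum number of bases (5000 bp for SEs, 10 bp for enhancers),
# drop TSS-overlapping enhancers, and split elements into fixed-width bins.

#' Consolidate per-sample elements into a consensus map
#'
#' Two elements merge iff their intervals share at least `min_overlap`
#' bases; merging is transitive, the merged interval is the span of the
#' merged set, and contributing samples are unioned. This is the
#' required-overlap reading of bedtools `merge` with a negative distance.
#'
#' @param elements interval data frame; an optional `sample` column
#'   records the contributing sample of each row.
#' @param min_overlap bp; inclusive minimum shared bases (> 0).
#' @param prefix id prefix for consensus element names.
#' @return data frame `element_id`, `chrom`, `start`, `end`, `n_samples`
#'   with a `samples` list column, in genomic order.
#' @export
consolidate_elements <- function(elements, min_overlap, prefix = "EL") {
  if (min_overlap <= 0) stop("min_overlap must be positive", call. = FALSE)
  elements <- validate_intervals(elements, "elements")
  if (is.null(elements$sample)) elements$sample <- NA_character_
  n <- nrow(elements)
  if (!n) {
    out <- data.frame(element_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_samples = integer())
    out$samples <- list()
    return(out)
  }
  ord <- interval_sort_order(elements)
  elements <- elements[ord, , drop = FALSE]
  # union-find over all pairs sharing >= min_overlap bases; with starts
  # sorted, a partner of i must start at or before end_i - min_overlap
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  starts <- elements$start
  ends <- elements$end
  chroms <- elements$chrom
  for (i in seq_len(n - 1)) {
    j <- i + 1L
    while (j <= n && chroms[j] == chroms[i] &&
           starts[j] <= ends[i] - min_overlap) {
      if (min(ends[i], ends[j]) - starts[j] >= min_overlap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
      j <- j + 1L
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  idx <- split(seq_len(n), comp)
  out <- data.frame(
    chrom = vapply(idx, function(i) chroms[i[1]], ""),
    start = vapply(idx, function(i) min(starts[i]), 0),
    end = vapply(idx, function(i) max(ends[i]), 0),
    n_samples = vapply(idx, function(i) {
      length(unique(stats::na.omit(elements$sample[i])))
    }, 1L),
    stringsAsFactors = FALSE
  )
  out$samples <- lapply(idx, function(i) {
    sort(unique(stats::na.omit(elements$sample[i])))
  })
  out <- out[interval_sort_order(out), , drop = FALSE]
  out <- cbind(element_id = sprintf("%s_%04d", prefix, seq_len(nrow(out))),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Remove TSS-overlapping elements
#'
#' Any element sharing at least one base with a TSS interval is removed
#' entirely (no trimming). Applied to the enhancer-class consensus only;
#' SEs retain their TSS overlap.
#'
#' @param elements consensus element data frame.
#' @param tss TSS interval data frame (may be empty).
#' @return filtered `elements`.
#' @export
subtract_tss <- function(elements, tss) {
  if (is.null(tss) || !nrow(tss)) return(elements)
  tss <- validate_intervals(tss, "TSS")
  if (!nrow(elements)) return(elements)
  hit <- GenomicRanges::countOverlaps(intervals_to_gr(elements),
                                      intervals_to_gr(tss)) > 0
  elements[!hit, , drop = FALSE]
}

#' Split consensus elements into fixed-width bins
#'
#' Element `[s, e)` yields bins `[s, s+w), [s+w, s+2w), ...` with the
#' final bin truncated at `e`; elements shorter than `w` yield a single
#' bin. Binning conserves bases exactly.
#'
#' @param elements consensus element data frame with `element_id`.
#' @param bin_width bp (> 0).
#' @return data frame `bin_id`, `element_id`, `chrom`, `start`, `end`.
#' @export
bin_elements <- function(elements, bin_width = 20000) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  if (!nrow(elements)) {
    return(data.frame(bin_id = character(), element_id = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  ids <- if (is.null(elements$element_id)) {
    sprintf("EL_%04d", seq_len(nrow(elements)))
  } else {
    elements$element_id
  }
  pieces <- lapply(seq_len(nrow(elements)), function(i) {
    s <- elements$start[i]
    e <- elements$end[i]
    starts <- seq(s, e - 1, by = bin_width)
    data.frame(
      element_id = ids[i],
      chrom = elements$chrom[i],
      start = starts,
      end = pmin(starts + bin_width, e),
      stringsAsFactors = FALSE
    )
  })
  bins <- do.call(rbind, pieces)
  bins <- cbind(bin_id = paste0(bins$element_id, "_b",
                                stats::ave(seq_len(nrow(bins)),
                                           bins$element_id,
                                           FUN = seq_along)),
                bins, stringsAsFactors = FALSE)
  rownames(bins) <- NULL
  bins
}
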