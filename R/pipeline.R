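# End-to-end driver: per-sample SE calling, consensus maps, scoring,
# clustering, gene association and tumor-specific calls on an in-memory
# synthetic landscape. Mirrors the file-based flow step for step.

#' Run the full landscape pipeline on a synthetic study
#'
#' Per sample: stitch the owned peaks (plus false-positive peaks), count
#' analytic coverage, score and classify superenhancers. Across samples:
#' consolidate SE and enhancer consensus maps, remove TSS-overlapping
#' enhancers, bin SEs, score every sample against the bins, call
#' presence, cluster the tumor cell lines on the top-variance SEs,
#' assign cluster-defining SEs, map SEs to genes (when an expression
#' matrix is supplied) and call tumor-specific SEs.
#'
#' @param landscape an `se_landscape`.
#' @param expression optional genes x samples RPKM matrix (e.g. from
#'   [simulate_expression()]).
#' @param k clusters to cut; defaults to the number of planted cell-line
#'   clusters when the landscape records them, else `config$cluster_k`.
#' @param config an [se_config()] (default: the landscape's).
#' @return list with per-sample `rose` tables, `consensus_se`,
#'   `consensus_enh`, `bins`, bin/element score matrices, `sizes`,
#'   `presence`, `selection`, `clustering`, `group_specific`,
#'   `associations`, `tumor_specific`, `ts_genes`.
#' @export
run_landscape_pipeline <- function(landscape, expression = NULL, k = NULL,
                                   config = landscape$config) {
  md <- landscape$samples
  ids <- md$sample_id
  tss <- data.frame(chrom = landscape$genes$chrom,
                    start = landscape$genes$start,
                    end = landscape$genes$start + 1)

  rose <- lapply(ids, function(s) {
    h <- sample_peak_heights(landscape, s)
    owned <- landscape$peaks[h > 0, c("chrom", "start", "end")]
    fp <- landscape$false_peaks[landscape$false_peaks$sample == s,
                                c("chrom", "start", "end")]
    peaks <- rbind(owned, fp)
    if (nrow(peaks) < 2) return(NULL)
    regions <- stitch_peaks(peaks, config$stitch_distance, tss,
                            config$tss_exclusion)
    if (nrow(regions) < 2) return(NULL)
    chip <- coverage_counts(landscape, s, regions, "chip")
    inp <- coverage_counts(landscape, s, regions, "input")
    i <- match(s, md$sample_id)
    suppressWarnings(classify_superenhancers(
      score_regions(regions, chip, inp, md$chip_library_size[i],
                    md$input_library_size[i])))
  })
  names(rose) <- ids

  collect <- function(se_only) {
    do.call(rbind, lapply(ids, function(s) {
      tab <- rose[[s]]
      if (is.null(tab)) return(NULL)
      if (se_only) tab <- tab[tab$is_SE, , drop = FALSE]
      if (!nrow(tab)) return(NULL)
      data.frame(chrom = tab$chrom, start = tab$start, end = tab$end,
                 sample = s, stringsAsFactors = FALSE)
    }))
  }
  se_calls <- collect(TRUE)
  all_calls <- collect(FALSE)
  if (is.null(se_calls) || !nrow(se_calls)) {
    return(list(rose = rose, consensus_se = NULL,
                message = "no superenhancers called in any sample"))
  }
  consensus_se <- consolidate_elements(se_calls, config$se_merge_overlap,
                                       prefix = "SE")
  consensus_enh <- subtract_tss(
    consolidate_elements(all_calls, config$enh_merge_overlap,
                         prefix = "ENH"), tss)

  bins <- bin_elements(consensus_se, config$bin_width)
  chip <- vapply(ids, function(s) coverage_counts(landscape, s, bins,
                                                  "chip"),
                 numeric(nrow(bins)))
  inp <- vapply(ids, function(s) coverage_counts(landscape, s, bins,
                                                 "input"),
                numeric(nrow(bins)))
  scores_bins <- score_samples(bins, chip, inp, md)
  scores_el <- element_scores(scores_bins, "rpkm")
  sizes <- element_scores(scores_bins, "size")$values
  presence <- call_presence(scores_el, config$se_log_cutoff)

  # clustering operates on the element-level RPKM score matrix: variance
  # on the RPKM scale keeps element length (fixed per consensus element)
  # out of the across-element ranking, and correlation uses its log2 values
  lines <- ids[md$category == "tumor_cell_line"]
  selection <- top_variable(scores_el$values, config$variance_top_fraction,
                            samples = lines)
  corr <- correlate_samples(scores_el$log2[, lines, drop = FALSE],
                            elements = selection)
  if (is.null(k)) {
    k <- if (!is.null(landscape$truth$line_clusters)) {
      length(unique(landscape$truth$line_clusters))
    } else {
      config$cluster_k
    }
  }
  clustering <- cluster_samples(corr, k = min(k, length(lines)),
                                min_cluster_size = config$min_cluster_size)
  group_specific <- tryCatch(
    group_specific_ses(scores_el$log2[selection, lines, drop = FALSE],
                       clustering$labels),
    error = function(e) NULL)

  associations <- NULL
  ts_genes <- NULL
  if (!is.null(expression)) {
    associations <- map_se_genes(consensus_se, sizes, expression,
                                 landscape$genes, config,
                                 samples = lines)
  }
  tumor_specific <- call_tumor_specific(presence, sizes, md, config)
  if (!is.null(associations)) {
    ts_genes <- suppressWarnings(
      tumor_specific_genes(tumor_specific, associations))
  }
  list(rose = rose, consensus_se = consensus_se,
       consensus_enh = consensus_enh, bins = bins,
       scores_bins = scores_bins, scores_elements = scores_el,
       sizes = sizes, presence = presence, selection = selection,
       corr = corr, clustering = clustering,
       group_specific = group_specific, associations = associations,
       tumor_specific = tumor_specific, ts_genes = ts_genes,
       metadata = md, config = config)
}

#' Match consensus elements to planted landscape elements
#'
#' Planted elements are placed farther apart than the stitch distance, so
#' each maps to at most one consensus element; matching is by interval
#' overlap.
#'
#' @param consensus consensus element data frame (`element_id` + interval).
#' @param landscape the generating `se_landscape`.
#' @return data frame `element_id`, `element_idx`, `class` (NA where a
#'   consensus element matches no planted element).
#' @export
match_planted <- function(consensus, landscape) {
  hits <- GenomicRanges::findOverlaps(
    intervals_to_gr(consensus),
    intervals_to_gr(landscape$elements))
  idx <- rep(NA_integer_, nrow(consensus))
  idx[S4Vectors::queryHits(hits)] <-
    landscape$elements$element_idx[S4Vectors::subjectHits(hits)]
  data.frame(element_id = consensus$element_id, element_idx = idx,
             class = ifelse(is.na(idx), NA_character_,
                            landscape$elements$class[idx]),
             stringsAsFactors = FALSE)
}
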