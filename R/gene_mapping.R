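# SE-to-gene association: candidate genes within a 10 Mb cis window,
# Pearson correlation of log2 SE size vs log2 expression across tumor cell
# lines, a 0.6 association threshold, and a mandatory minimum of two
# highest-correlation genes per SE.

#' Candidate genes within a cis window of an element
#'
#' Returns genes on the element's chromosome whose span overlaps the
#' element extended by `window` on both sides (inclusive boundary: a gene
#' edge exactly `window` bp away is a candidate). Distance is 0 for
#' overlapping genes, otherwise the nearest-edge gap in bp. The gene span,
#' not the TSS, is used: the conservative superset of "genes within the
#' window of the enhancer coordinates".
#'
#' @param element single-row interval data frame (or list with `chrom`,
#'   `start`, `end`).
#' @param genes gene annotation data frame (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param window bp.
#' @return `genes` rows within the window, with a `distance_bp` column.
#' @export
genes_in_window <- function(element, genes, window = 1e7) {
  genes <- validate_intervals(genes, "gene annotation")
  el_gr <- GenomicRanges::GRanges(element$chrom,
                                  IRanges::IRanges(element$start + 1,
                                                   element$end))
  hits <- GenomicRanges::findOverlaps(intervals_to_gr(genes), el_gr,
                                      maxgap = window)
  cand <- genes[S4Vectors::queryHits(hits), , drop = FALSE]
  if (!nrow(cand)) {
    cand$distance_bp <- numeric(0)
    return(cand)
  }
  cand$distance_bp <- pmax(0, pmax(cand$start - element$end,
                                   element$start - cand$end))
  rownames(cand) <- NULL
  cand
}

#' Associate candidate genes with a superenhancer
#'
#' Pearson correlation of `log2(SE size + 1)` vs `log2(RPKM + 1)` across
#' the shared samples. The association set is the union of (i) all
#' candidates with `r >= corr_threshold` and (ii) the `min_genes`
#' highest-correlation candidates regardless of r (mandatory
#' assignments). Zero-variance expression vectors get r = 0: excluded
#' from the threshold set but still eligible for mandatory slots. Results
#' are sorted by r descending, ties by distance then gene id. If fewer
#' than `min_genes` candidates exist all are returned and flagged.
#'
#' @param element_id id recorded in the output.
#' @param sizes named numeric vector of per-sample SE sizes (raw scale).
#' @param expression RPKM matrix, genes x samples.
#' @param candidates candidate gene data frame from [genes_in_window()].
#' @param corr_threshold Pearson r cutoff (inclusive).
#' @param min_genes mandatory minimum assignments per SE.
#' @param samples samples to correlate across (default: all samples shared
#'   by `sizes` and `expression`); the pipeline passes tumor cell lines.
#' @return data frame `element_id`, `gene_id`, `pearson_r`, `distance_bp`,
#'   `mandatory`; attribute `flagged` is TRUE when the window held fewer
#'   than `min_genes` candidates.
#' @export
associate_genes <- function(element_id, sizes, expression, candidates,
                            corr_threshold = 0.6, min_genes = 2,
                            samples = NULL) {
  if (is.null(samples)) {
    samples <- intersect(names(sizes), colnames(expression))
  }
  if (length(samples) < 3) {
    stop("need >= 3 shared samples for correlation", call. = FALSE)
  }
  x <- log2(sizes[samples] + 1)
  empty <- data.frame(element_id = character(), gene_id = character(),
                      pearson_r = numeric(), distance_bp = numeric(),
                      mandatory = logical(), stringsAsFactors = FALSE)
  if (!nrow(candidates)) {
    attr(empty, "flagged") <- TRUE
    return(empty)
  }
  r <- vapply(candidates$gene_id, function(g) {
    safe_cor(x, log2(expression[g, samples] + 1))
  }, 0)
  ord <- order(-r, candidates$distance_bp, candidates$gene_id)
  r <- r[ord]
  cand <- candidates[ord, , drop = FALSE]
  rank <- seq_along(r)
  # the inclusive threshold tolerates machine epsilon so correlations
  # that are exactly at the cutoff up to fp rounding are not dropped
  keep <- r >= corr_threshold - 1e-9 | rank <= min_genes
  out <- data.frame(element_id = element_id,
                    gene_id = cand$gene_id[keep],
                    pearson_r = unname(r[keep]),
                    distance_bp = cand$distance_bp[keep],
                    mandatory = (rank <= min_genes &
                                   r < corr_threshold - 1e-9)[keep],
                    stringsAsFactors = FALSE)
  attr(out, "flagged") <- nrow(candidates) < min_genes
  out
}

#' Map all consensus SEs to putative target genes
#'
#' @param elements consensus SE element data frame.
#' @param sizes SE size matrix (elements x samples).
#' @param expression RPKM matrix (genes x samples).
#' @param genes gene annotation data frame.
#' @param config an [se_config()].
#' @param samples samples to correlate across (the published analysis uses
#'   tumor cell lines).
#' @return combined association data frame.
#' @export
map_se_genes <- function(elements, sizes, expression, genes,
                         config = se_config(), samples = NULL) {
  out <- lapply(seq_len(nrow(elements)), function(i) {
    el <- elements[i, ]
    cand <- genes_in_window(el, genes, config$gene_window)
    associate_genes(el$element_id, sizes[el$element_id, ], expression,
                    cand, config$corr_threshold, config$min_genes_per_se,
                    samples = samples)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Distribution of SE-gene association distances
#'
#' @param associations association data frame.
#' @param probs quantiles to report.
#' @return list with the per-association `distances` table and a
#'   `summary` of quantiles.
#' @export
distance_report <- function(associations,
                            probs = c(0, 0.25, 0.5, 0.75, 0.9, 1)) {
  d <- associations[, c("element_id", "gene_id", "distance_bp")]
  list(distances = d,
       summary = stats::quantile(d$distance_bp, probs = probs))
}
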