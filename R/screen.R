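# CRISPR dropout screen scoring: per-guide log2 fold-changes between the
# reference and late timepoints, gene-level LFC from the most depleted
# guides, control-anchored normalization (essential genes -> -1, NTCs ->
# 0), hit calling, dependency classification from CERES-like scores, and
# dependency-correlated SE signatures.

#' Per-guide log2 fold-change between timepoints
#'
#' Counts are scaled to counts-per-million before a pseudocount is added:
#' `LFC = log2((cpm_late + p) / (cpm_t0 + p))`. Guides with a missing
#' count at either timepoint are excluded with a warning.
#'
#' @param counts_t0,counts_late named count vectors aligned on guide ids.
#' @param t0_lib,late_lib library sizes (default: column totals).
#' @param pseudocount added on the CPM scale (default 0.5).
#' @return named numeric vector of guide LFCs.
#' @export
guide_lfc <- function(counts_t0, counts_late,
                      t0_lib = sum(counts_t0, na.rm = TRUE),
                      late_lib = sum(counts_late, na.rm = TRUE),
                      pseudocount = 0.5) {
  if (!is.null(names(counts_t0)) && !is.null(names(counts_late))) {
    shared <- intersect(names(counts_t0), names(counts_late))
    dropped <- union(setdiff(names(counts_t0), shared),
                     setdiff(names(counts_late), shared))
    counts_t0 <- counts_t0[shared]
    counts_late <- counts_late[shared]
  } else {
    stopifnot(length(counts_t0) == length(counts_late))
    dropped <- character()
  }
  na <- is.na(counts_t0) | is.na(counts_late)
  if (any(na)) dropped <- c(dropped, names(counts_t0)[na])
  if (length(dropped)) {
    warning("guide(s) missing at a timepoint, excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  counts_t0 <- counts_t0[!na]
  counts_late <- counts_late[!na]
  log2((counts_late / (late_lib / 1e6) + pseudocount) /
       (counts_t0 / (t0_lib / 1e6) + pseudocount))
}

#' Gene-level LFC from the most depleted guides
#'
#' Mean of the `top_guides` most negative guide LFCs (the standard
#' dropout-screen reading of "top" guides); genes with fewer guides use
#' all of them.
#'
#' @param guide_lfcs numeric guide LFCs for one gene.
#' @param top_guides number averaged (default 3).
#' @param selection `"depleted"` (most negative) or `"abs"` (largest
#'   magnitude).
#' @return gene-level raw LFC.
#' @export
gene_lfc <- function(guide_lfcs, top_guides = 3,
                     selection = c("depleted", "abs")) {
  selection <- match.arg(selection)
  if (!length(guide_lfcs)) stop("no guide LFCs", call. = FALSE)
  k <- min(top_guides, length(guide_lfcs))
  ord <- if (selection == "depleted") order(guide_lfcs)
         else order(-abs(guide_lfcs))
  mean(guide_lfcs[ord[seq_len(k)]])
}

#' Control-anchored normalization of gene LFCs
#'
#' Affine map placing the positive-control (essential gene) mean at -1.0
#' and the NTC mean at 0.0:
#' `norm(x) = -(x - m_NTC) / (m_pos - m_NTC)`. Invariant under any affine
#' transform of all raw LFCs, since both anchors move with the data.
#'
#' @param raw_lfcs named numeric vector of raw gene LFCs.
#' @param positive_controls gene ids of essential positive controls.
#' @param ntc_genes gene ids of non-targeting control genes.
#' @return named numeric vector of normalized LFCs.
#' @export
normalize_lfc <- function(raw_lfcs, positive_controls, ntc_genes) {
  pos <- intersect(positive_controls, names(raw_lfcs))
  ntc <- intersect(ntc_genes, names(raw_lfcs))
  if (!length(pos) || !length(ntc)) {
    stop("both control sets must be present in the LFC table",
         call. = FALSE)
  }
  m_pos <- mean(raw_lfcs[pos])
  m_ntc <- mean(raw_lfcs[ntc])
  if (m_pos == m_ntc) {
    stop("positive-control and NTC means coincide; screen failed QC",
         call. = FALSE)
  }
  -(raw_lfcs - m_ntc) / (m_pos - m_ntc)
}

#' Call screen hits
#'
#' A gene is a putative hit iff its normalized LFC is at or below
#' `hit_cutoff` (inclusive).
#'
#' @param norm_lfcs normalized gene LFCs.
#' @param hit_cutoff default -0.5.
#' @return logical vector.
#' @export
call_hits <- function(norm_lfcs, hit_cutoff = -0.5) {
  norm_lfcs <= hit_cutoff
}

#' Score a dropout screen count table for one cell line
#'
#' Runs [guide_lfc()], per-gene [gene_lfc()], [normalize_lfc()] and
#' [call_hits()].
#'
#' @param counts data frame with `guide`, `gene`, `count_t0`,
#'   `count_late` and optionally `role` (`target` / `positive_control` /
#'   `NTC`).
#' @param positive_controls,ntc_genes control gene ids (taken from the
#'   `role` column when omitted).
#' @param config an [se_config()].
#' @param pseudocount CPM pseudocount for [guide_lfc()].
#' @return An `se_screen_result` data frame: `gene`, `role`, `n_guides`,
#'   `raw_lfc`, `norm_lfc`, `is_hit`; anchors stored as attributes.
#' @export
analyze_screen <- function(counts, positive_controls = NULL,
                           ntc_genes = NULL, config = se_config(),
                           pseudocount = 0.5) {
  stopifnot(all(c("guide", "gene", "count_t0", "count_late") %in%
                names(counts)))
  if (is.null(positive_controls) || is.null(ntc_genes)) {
    if (is.null(counts$role)) {
      stop("control genes undefined: supply positive_controls/ntc_genes ",
           "or a role column", call. = FALSE)
    }
    positive_controls <- unique(counts$gene[counts$role ==
                                            "positive_control"])
    ntc_genes <- unique(counts$gene[counts$role == "NTC"])
  }
  if (!length(positive_controls) || !length(ntc_genes)) {
    stop("no control genes defined; normalization impossible",
         call. = FALSE)
  }
  glfc <- guide_lfc(stats::setNames(counts$count_t0, counts$guide),
                    stats::setNames(counts$count_late, counts$guide),
                    pseudocount = pseudocount)
  gene_of <- stats::setNames(counts$gene, counts$guide)[names(glfc)]
  raw <- vapply(split(glfc, gene_of), gene_lfc,
                top_guides = config$top_guides, 0)
  norm <- normalize_lfc(raw, positive_controls, ntc_genes)
  genes <- names(raw)
  role <- ifelse(genes %in% positive_controls, "positive_control",
                 ifelse(genes %in% ntc_genes, "NTC", "target"))
  out <- data.frame(gene = genes, role = role,
                    n_guides = as.integer(table(gene_of)[genes]),
                    raw_lfc = unname(raw), norm_lfc = unname(norm),
                    is_hit = unname(call_hits(norm, config$hit_cutoff)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, m_pos = mean(raw[intersect(positive_controls, genes)]),
            m_ntc = mean(raw[intersect(ntc_genes, genes)]),
            class = c("se_screen_result", class(out)))
}

#' @export
print.se_screen_result <- function(x, ...) {
  cat(sprintf("<se_screen_result> %d genes (%d targets), %d hits\n",
              nrow(x), sum(x$role == "target"),
              sum(x$is_hit & x$role == "target")))
  cat(sprintf("  anchors: positive-control mean %.3f, NTC mean %.3f (raw LFC)\n",
              attr(x, "m_pos"), attr(x, "m_ntc")))
  invisible(x)
}

#' Classify cell-line dependency from CERES-like scores
#'
#' A line is sensitive to knockout iff its dependency score is at or
#' below `ceres_cutoff`; missing scores leave the line unlabeled (NA).
#'
#' @param ceres_scores named numeric vector, one score per cell line.
#' @param ceres_cutoff default -0.5.
#' @return named character vector: `"sensitive"` / `"insensitive"` / NA.
#' @export
classify_dependent <- function(ceres_scores, ceres_cutoff = -0.5) {
  if (!length(ceres_scores)) {
    return(stats::setNames(character(), character()))
  }
  out <- ifelse(is.na(ceres_scores), NA_character_,
                ifelse(ceres_scores <= ceres_cutoff, "sensitive",
                       "insensitive"))
  stats::setNames(out, names(ceres_scores))
}

#' Dependency-correlated SE signature
#'
#' Correlates each element's log2 score across cell lines with the
#' dependency indicator (point-biserial Pearson; constant elements get
#' r = 0), then takes the `signature_size` most positively and most
#' negatively correlated elements. The separation p-value compares
#' per-line summed signature scores (positive arm minus negative arm)
#' between sensitive and insensitive lines.
#'
#' @param log_scores elements x cell-line matrix (log2 scale).
#' @param dependent named logical (or `"sensitive"`-coded) vector over
#'   the same lines.
#' @param signature_size elements per arm (default 600; truncated to the
#'   available elements).
#' @param test separation test, `"mannwhitney"` (default) or `"t"`.
#' @return A `dependency_signature`: list with `positive`, `negative`
#'   (data frames of element ids and correlations), `line_score`,
#'   `separation_p`, `test`.
#' @export
dependency_signature <- function(log_scores, dependent,
                                 signature_size = 600,
                                 test = c("mannwhitney", "t")) {
  test <- match.arg(test)
  if (is.character(dependent)) dependent <- dependent == "sensitive"
  dependent <- dependent[colnames(log_scores)]
  if (sum(dependent, na.rm = TRUE) < 2 ||
      sum(!dependent, na.rm = TRUE) < 2) {
    stop("need >= 2 lines per dependency class", call. = FALSE)
  }
  ind <- as.numeric(dependent)
  r <- apply(log_scores, 1, function(v) safe_cor(v, ind))
  ord <- order(-r, rownames(log_scores))
  k <- min(signature_size, floor(length(r) / 2))
  pos_idx <- ord[seq_len(k)]
  neg_idx <- rev(ord)[seq_len(k)]
  pos <- data.frame(element_id = rownames(log_scores)[pos_idx],
                    r = unname(r[pos_idx]), stringsAsFactors = FALSE)
  neg <- data.frame(element_id = rownames(log_scores)[neg_idx],
                    r = unname(r[neg_idx]), stringsAsFactors = FALSE)
  line_score <- colSums(log_scores[pos_idx, , drop = FALSE]) -
    colSums(log_scores[neg_idx, , drop = FALSE])
  sep <- compare_groups(line_score[dependent], line_score[!dependent],
                        test = if (test == "t") "t" else "mannwhitney")
  structure(list(positive = pos, negative = neg, line_score = line_score,
                 separation_p = sep$p_value, test = sep$method,
                 signature_size = k),
            class = "dependency_signature")
}

#' @export
print.dependency_signature <- function(x, ...) {
  cat(sprintf("<dependency_signature> %d elements per arm; separation p = %.3g (%s)\n",
              x$signature_size, x$separation_p, x$test))
  invisible(x)
}

#' Sweep dependency-signature sizes
#'
#' Evaluates the class-separation p-value over candidate signature sizes
#' (the published signature size was chosen this way).
#'
#' @inheritParams dependency_signature
#' @param sizes candidate sizes.
#' @return data frame `size`, `separation_p`.
#' @export
signature_size_sweep <- function(log_scores, dependent, sizes,
                                 test = c("mannwhitney", "t")) {
  test <- match.arg(test)
  p <- vapply(sizes, function(s) {
    dependency_signature(log_scores, dependent, s, test)$separation_p
  }, 0)
  data.frame(size = sizes, separation_p = p)
}
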