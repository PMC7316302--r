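# Tumor-specific superenhancers: elements present in enough tumor cell
# lines and primaries while absent from every normal (acquired), or
# present in normals but carrying at least enlarged_fold times the normal
# signal in tumors (enlarged).

#' Call tumor-specific superenhancers
#'
#' Acquired mode: present (SE presence call) in at least
#' `min_tumor_lines` tumor cell lines and `min_primaries` primary tumors,
#' and absent from every normal sample. Enlarged mode additionally admits
#' elements present in normals whose mean tumor signal is at least
#' `enlarged_fold` times the mean normal signal (inclusive), under the
#' same tumor/primary presence requirements. Signal means use the
#' input-subtracted score (depth-comparable), not raw read totals. An
#' element qualifying both ways is reported once, as acquired.
#'
#' @param presence logical element x sample presence matrix.
#' @param scores numeric element x sample score matrix (SE sizes) used
#'   for the fold comparison.
#' @param metadata sample metadata with categories.
#' @param config an [se_config()].
#' @return data frame `element_id`, `mode`, presence counts per category,
#'   `tumor_mean_signal`, `normal_mean_signal`, `fold`.
#' @export
call_tumor_specific <- function(presence, scores, metadata,
                                config = se_config()) {
  metadata <- validate_sample_metadata(metadata)
  samples <- colnames(presence)
  md <- metadata[match(samples, metadata$sample_id), ]
  if (anyNA(md$sample_id)) {
    stop("presence matrix contains samples absent from metadata",
         call. = FALSE)
  }
  lines <- samples[md$category == "tumor_cell_line"]
  prims <- samples[md$category == "primary_tumor"]
  norms <- samples[md$category == "normal"]
  if (!length(norms)) {
    stop("no normal samples in metadata; tumor-specific criterion undefined",
         call. = FALSE)
  }
  tumors <- c(lines, prims)
  n_t <- rowSums(presence[, lines, drop = FALSE])
  n_p <- rowSums(presence[, prims, drop = FALSE])
  n_n <- rowSums(presence[, norms, drop = FALSE])
  tumor_mean <- rowMeans(scores[, tumors, drop = FALSE])
  normal_mean <- rowMeans(scores[, norms, drop = FALSE])
  fold <- ifelse(normal_mean > 0, tumor_mean / normal_mean, Inf)
  eligible <- n_t >= config$min_tumor_lines & n_p >= config$min_primaries
  acquired <- eligible & n_n == 0
  enlarged <- eligible & !acquired & n_n > 0 & fold >= config$enlarged_fold
  keep <- which(acquired | enlarged)
  out <- data.frame(
    element_id = rownames(presence)[keep],
    mode = ifelse(acquired[keep], "acquired", "enlarged"),
    n_tumor_lines_present = n_t[keep],
    n_primaries_present = n_p[keep],
    n_normals_present = n_n[keep],
    tumor_mean_signal = tumor_mean[keep],
    normal_mean_signal = normal_mean[keep],
    fold = fold[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Genes fed to the dropout screen by tumor-specific SEs
#'
#' Deduplicated, sorted union of the genes associated with any
#' tumor-specific element. Called elements with no association contribute
#' nothing, with a warning.
#'
#' @param calls output of [call_tumor_specific()].
#' @param associations SE-gene association data frame.
#' @return sorted character vector of gene ids.
#' @export
tumor_specific_genes <- function(calls, associations) {
  if (!nrow(calls)) return(character())
  hit <- associations[associations$element_id %in% calls$element_id, ]
  orphan <- setdiff(calls$element_id, hit$element_id)
  if (length(orphan)) {
    warning("tumor-specific element(s) with no gene association: ",
            paste(orphan, collapse = ", "), call. = FALSE)
  }
  sort(unique(hit$gene_id))
}
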