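#' Pipeline configuration
#'
#' Collects every numeric parameter of the landscape pipeline in one
#' validated object. Defaults reproduce the published analysis settings:
#' 12.5 kb ROSE stitching with no TSS exclusion, 5000 bp / 10 bp consensus
#' merge overlaps for SEs / enhancers, 20 kb bins, a superenhancer presence
#' cutoff of log2(RPKM+1) >= 6, top 10% most-variable SEs for clustering,
#' a 10 Mb cis window with a Pearson 0.6 association threshold and a
#' mandatory minimum of two genes per SE, tumor-specific presence in >= 4
#' tumor cell lines and >= 1 primary with no normals (or >= 2-fold
#' enlargement), 8 guides per gene with the top 3 averaged, screen hits at
#' normalized LFC <= -0.5, dependency at CERES <= -0.5, and 600-element
#' dependency signatures.
#'
#' @param stitch_distance bp; maximum gap between peaks merged into one
#'   stitched region.
#' @param tss_exclusion bp; half-width of the TSS window whose fully
#'   contained peaks are dropped before stitching (0 disables).
#' @param se_merge_overlap bp; minimum shared bases for cross-sample SE
#'   consolidation.
#' @param enh_merge_overlap bp; minimum shared bases for cross-sample
#'   enhancer consolidation.
#' @param bin_width bp; width of consensus SE bins.
#' @param se_log_cutoff log2(RPKM+1) units; inclusive SE presence cutoff.
#' @param variance_top_fraction fraction of elements kept by variance.
#' @param cluster_k number of clusters cut from the sample dendrogram.
#' @param min_cluster_size clusters smaller than this dissolve to unassigned.
#' @param gene_window bp; cis window for SE-to-gene candidates.
#' @param corr_threshold Pearson r for SE-gene association.
#' @param min_genes_per_se genes always assigned per SE regardless of r.
#' @param min_tumor_lines minimum tumor cell lines carrying a
#'   tumor-specific SE.
#' @param min_primaries minimum primary tumors carrying a tumor-specific SE.
#' @param enlarged_fold tumor/normal signal ratio for the enlarged mode.
#' @param guides_per_gene library design: sgRNAs per gene.
#' @param top_guides most-depleted guides averaged into the gene LFC.
#' @param hit_cutoff normalized LFC at or below which a gene is a hit.
#' @param ceres_cutoff dependency score at or below which a line is
#'   sensitive.
#' @param signature_size SEs per arm of a dependency signature.
#' @param rng_seed integer seed recorded with the configuration.
#' @return A list of class `se_config`.
#' @seealso [load_config()]
#' @export
#' @examples
#' cfg <- se_config(bin_width = 10000)
#' cfg$stitch_distance
se_config <- function(stitch_distance = 12500,
                      tss_exclusion = 0,
                      se_merge_overlap = 5000,
                      enh_merge_overlap = 10,
                      bin_width = 20000,
                      se_log_cutoff = 6,
                      variance_top_fraction = 0.10,
                      cluster_k = 10,
                      min_cluster_size = 3,
                      gene_window = 1e7,
                      corr_threshold = 0.6,
                      min_genes_per_se = 2,
                      min_tumor_lines = 4,
                      min_primaries = 1,
                      enlarged_fold = 2,
                      guides_per_gene = 8,
                      top_guides = 3,
                      hit_cutoff = -0.5,
                      ceres_cutoff = -0.5,
                      signature_size = 600,
                      rng_seed = 1L) {
  cfg <- list(
    stitch_distance = stitch_distance,
    tss_exclusion = tss_exclusion,
    se_merge_overlap = se_merge_overlap,
    enh_merge_overlap = enh_merge_overlap,
    bin_width = bin_width,
    se_log_cutoff = se_log_cutoff,
    variance_top_fraction = variance_top_fraction,
    cluster_k = cluster_k,
    min_cluster_size = min_cluster_size,
    gene_window = gene_window,
    corr_threshold = corr_threshold,
    min_genes_per_se = min_genes_per_se,
    min_tumor_lines = min_tumor_lines,
    min_primaries = min_primaries,
    enlarged_fold = enlarged_fold,
    guides_per_gene = guides_per_gene,
    top_guides = top_guides,
    hit_cutoff = hit_cutoff,
    ceres_cutoff = ceres_cutoff,
    signature_size = signature_size,
    rng_seed = as.integer(rng_seed)
  )
  validate_se_config(cfg)
  structure(cfg, class = "se_config")
}

validate_se_config <- function(cfg) {
  num1 <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop(sprintf("config key '%s' must be a single number", key),
           call. = FALSE)
    }
    v
  }
  nonneg <- c("stitch_distance", "tss_exclusion", "se_merge_overlap",
              "enh_merge_overlap", "bin_width", "gene_window",
              "min_genes_per_se", "min_tumor_lines", "min_primaries",
              "enlarged_fold", "guides_per_gene", "top_guides",
              "cluster_k", "min_cluster_size", "signature_size")
  for (key in nonneg) {
    if (num1(key) < 0) {
      stop(sprintf("config key '%s' must be non-negative", key),
           call. = FALSE)
    }
  }
  for (key in setdiff(names(cfg), c(nonneg, "rng_seed"))) num1(key)
  f <- cfg$variance_top_fraction
  if (f <= 0 || f > 1) {
    stop("variance_top_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$top_guides > cfg$guides_per_gene) {
    stop("top_guides must not exceed guides_per_gene", call. = FALSE)
  }
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys absent from the file take the [se_config()] defaults; unknown keys
#' are an error so that typos do not silently fall back to defaults.
#'
#' @param path YAML file of `key: value` pairs (may be empty).
#' @return An `se_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file must contain key: value pairs",
                           call. = FALSE)
  known <- names(formals(se_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(se_config, vals)
}

#' @export
print.se_config <- function(x, ...) {
  cat("<se_config>\n")
  for (key in names(x)) cat(sprintf("  %-22s %s\n", key, format(x[[key]])))
  invisible(x)
}
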