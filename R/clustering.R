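# Sample clustering on the most variable superenhancers: Pearson
# correlation across samples, 1 - r distance, average-linkage (UPGMA)
# hierarchical clustering, cluster-number diagnostics, cluster-defining SE
# assignment, and the group comparison tests.

#' Select the most variable elements
#'
#' Elements are ranked by the variance of their values across the
#' restricted sample set and the top `ceiling(fraction * n)` are returned
#' (ceiling guarantees a non-empty selection); ties break by element id.
#'
#' @param values numeric matrix, elements x samples (typically SE sizes).
#' @param fraction fraction in (0, 1].
#' @param samples optional character vector restricting the variance
#'   computation (e.g. tumor cell lines only).
#' @return character vector of selected element ids.
#' @export
top_variable <- function(values, fraction = 0.10, samples = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]",
                                          call. = FALSE)
  if (!is.null(samples)) values <- values[, samples, drop = FALSE]
  if (ncol(values) < 2) stop("need >= 2 samples to compute variance",
                             call. = FALSE)
  v <- apply(values, 1, stats::var)
  ord <- order(-v, rownames(values))
  k <- ceiling(fraction * nrow(values))
  rownames(values)[ord[seq_len(k)]]
}

#' Sample-sample Pearson correlation on selected elements
#'
#' Computed on log2(value+1) scores. Samples with zero variance across the
#' selected elements have undefined correlations; they are flagged (NA
#' rows/columns, recorded in attribute `flagged`) and later excluded from
#' clustering with a warning.
#'
#' @param log_values numeric matrix, elements x samples, log2 scale.
#' @param elements optional element ids to subset rows.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlate_samples <- function(log_values, elements = NULL) {
  if (!is.null(elements)) log_values <- log_values[elements, , drop = FALSE]
  if (nrow(log_values) < 2) stop("need >= 2 elements for correlation",
                                 call. = FALSE)
  sds <- apply(log_values, 2, stats::sd)
  flagged <- colnames(log_values)[sds == 0]
  if (length(flagged)) {
    warning("zero-variance sample(s) flagged: ",
            paste(flagged, collapse = ", "), call. = FALSE)
  }
  cm <- suppressWarnings(stats::cor(log_values))
  diag(cm) <- 1
  attr(cm, "flagged") <- flagged
  cm
}

#' Hierarchically cluster samples from a correlation matrix
#'
#' Distance is `1 - Pearson r`; linkage is average (UPGMA). The tree is
#' cut at `k`; clusters smaller than `min_cluster_size` are dissolved and
#' their members left unassigned (NA), mirroring samples whose SE profile
#' resembles no other sample.
#'
#' @param corr correlation matrix from [correlate_samples()].
#' @param k number of clusters to cut.
#' @param min_cluster_size minimum assigned cluster size.
#' @return An `se_clustering`: list with `labels` (named integer vector,
#'   NA = unassigned), `tree` (hclust), `k`, and `corr`.
#' @export
cluster_samples <- function(corr, k, min_cluster_size = 3) {
  flagged <- attr(corr, "flagged")
  if (length(flagged)) {
    warning("excluding zero-variance sample(s) from clustering: ",
            paste(flagged, collapse = ", "), call. = FALSE)
    keep <- setdiff(colnames(corr), flagged)
    corr <- corr[keep, keep, drop = FALSE]
  }
  n <- ncol(corr)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  tree <- stats::hclust(stats::as.dist(1 - corr), method = "average")
  labels <- stats::cutree(tree, k = k)
  sizes <- table(labels)
  small <- as.integer(names(sizes)[sizes < min_cluster_size])
  labels[labels %in% small] <- NA_integer_
  if (length(flagged)) {
    labels <- c(labels, stats::setNames(rep(NA_integer_, length(flagged)),
                                        flagged))
  }
  structure(list(labels = labels, tree = tree, k = k, corr = corr),
            class = "se_clustering")
}

#' @export
print.se_clustering <- function(x, ...) {
  assigned <- x$labels[!is.na(x$labels)]
  cat(sprintf("<se_clustering> %d samples, k = %d: %d assigned in %d cluster(s), %d unassigned\n",
              length(x$labels), x$k, length(assigned),
              length(unique(assigned)), sum(is.na(x$labels))))
  invisible(x)
}

#' @export
plot.se_clustering <- function(x, ...) {
  graphics::plot(x$tree, xlab = "", sub = "",
                 main = "Sample dendrogram (1 - Pearson, UPGMA)", ...)
  invisible(x)
}

#' Cluster-number diagnostics
#'
#' For each candidate `k` reports the elbow curve (total within-cluster
#' mean dissimilarity), the mean silhouette width, and a gap statistic.
#' All three use the `1 - Pearson` distance; the gap reference is built by
#' permuting each element's values across samples (destroying the sample
#' correlation structure while keeping marginal score distributions).
#' Diagnostics inform but never override the configured `k`.
#'
#' @param log_values elements x samples matrix (log2 scale), already
#'   restricted to the selected high-variance elements.
#' @param k_range candidate cluster numbers.
#' @param B permutation references for the gap statistic.
#' @param seed RNG seed for the permutations.
#' @return data frame `k`, `within_disp`, `silhouette`, `gap`, `gap_se`.
#' @export
cluster_diagnostics <- function(log_values, k_range = 2:10, B = 20,
                                seed = 1L) {
  sds <- apply(log_values, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance sample(s) from diagnostics: ",
            paste(colnames(log_values)[sds == 0], collapse = ", "),
            call. = FALSE)
    log_values <- log_values[, sds > 0, drop = FALSE]
  }
  # undefined correlations (constant columns, e.g. in permutation
  # references) are treated as uncorrelated: distance 1
  cor_dist <- function(m) {
    d <- 1 - suppressWarnings(stats::cor(m))
    d[is.na(d)] <- 1
    diag(d) <- 0
    d
  }
  dmat <- cor_dist(log_values)
  within_disp <- function(d, labels) {
    sum(vapply(split(names(labels), labels), function(members) {
      if (length(members) < 2) return(0)
      sum(d[members, members]) / (2 * length(members))
    }, 0))
  }
  cut_k <- function(d, k) {
    stats::cutree(stats::hclust(stats::as.dist(d), method = "average"),
                  k = k)
  }
  k_range <- k_range[k_range >= 2 & k_range <= ncol(log_values) - 1]
  if (!length(k_range)) stop("too few samples for diagnostics",
                             call. = FALSE)
  obs <- vapply(k_range, function(k) within_disp(dmat, cut_k(dmat, k)), 0)
  sil <- vapply(seq_along(k_range), function(i) {
    labels <- cut_k(dmat, k_range[i])
    mean(cluster::silhouette(labels, stats::as.dist(dmat))[, "sil_width"])
  }, 0)
  ref <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      perm <- t(apply(log_values, 1, sample))
      colnames(perm) <- colnames(log_values)
      dperm <- cor_dist(perm)
      vapply(k_range, function(k) within_disp(dperm, cut_k(dperm, k)), 0)
    }, numeric(length(k_range)))
  })
  log_ref <- log(pmax(ref, .Machine$double.eps))
  gap <- rowMeans(log_ref) - log(pmax(obs, .Machine$double.eps))
  gap_se <- apply(log_ref, 1, stats::sd) * sqrt(1 + 1 / B)
  data.frame(k = k_range, within_disp = obs, silhouette = sil,
             gap = gap, gap_se = gap_se)
}

#' Identify cluster-defining (group-specific) superenhancers
#'
#' For each element, clusters are ordered by their mean score and the
#' smallest leading set `S` is sought such that every member cluster's
#' `mean - sd` exceeds the mean of every cluster outside `S` (the
#' "mean minus one standard deviation does not overlap the other group
#' means" criterion). `|S| = 1` marks an element specific to one cluster;
#' `|S| > 1` marks it shared among those clusters (as for the elements
#' shared between the two epithelial-like groups); no valid proper subset
#' means the element is not group-specific. SDs are sample SDs (n-1);
#' clusters with a single member are skipped with a warning.
#'
#' @param log_values elements x samples matrix (log2 SE sizes).
#' @param labels named cluster labels (NA = unassigned).
#' @param strict use strict `>` (default) or `>=` comparison.
#' @return data frame `element_id`, `groups` (comma-separated cluster
#'   labels), `n_groups`, `specific` plus per-group summary columns.
#' @export
group_specific_ses <- function(log_values, labels, strict = TRUE) {
  labels <- labels[!is.na(labels)]
  sizes <- table(labels)
  single <- names(sizes)[sizes < 2]
  if (length(single)) {
    warning("cluster(s) with a single member skipped (SD undefined): ",
            paste(single, collapse = ", "), call. = FALSE)
    labels <- labels[!(labels %in% as.integer(single))]
  }
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need >= 2 clusters with >= 2 members",
                               call. = FALSE)
  members <- split(names(labels), labels)
  cmp <- if (strict) `>` else `>=`
  rows <- lapply(rownames(log_values), function(el) {
    v <- log_values[el, ]
    mu <- vapply(members, function(m) mean(v[m]), 0)
    sd_g <- vapply(members, function(m) stats::sd(v[m]), 0)
    ord <- order(-mu)
    for (m in seq_len(length(groups) - 1)) {
      sel <- ord[seq_len(m)]
      rest <- ord[-seq_len(m)]
      if (all(outer(mu[sel] - sd_g[sel], mu[rest], cmp))) {
        grp <- names(mu)[sel]
        return(data.frame(element_id = el,
                          groups = paste(sort(grp), collapse = ","),
                          n_groups = m, specific = m == 1L,
                          top_mean = max(mu),
                          margin = min(outer(mu[sel] - sd_g[sel], mu[rest],
                                             `-`)),
                          stringsAsFactors = FALSE))
      }
    }
    NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(element_id = character(), groups = character(),
                      n_groups = integer(), specific = logical(),
                      top_mean = numeric(), margin = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Compare SE scores between two groups of samples
#'
#' Two-sided unpaired tests: the classic pooled-variance t-test (the
#' default for group comparisons of superenhancer signal) or the
#' Mann-Whitney U test.
#'
#' @param x,y numeric score vectors for the two groups.
#' @param test `"t"` or `"mannwhitney"`.
#' @return list with `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(x, y, test = c("t", "mannwhitney")) {
  test <- match.arg(test)
  if (test == "t") {
    if (length(x) < 2 || length(y) < 2) {
      stop("t-test needs >= 2 values per group", call. = FALSE)
    }
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      stop("zero variance in both groups; t statistic undefined",
           call. = FALSE)
    }
    ht <- stats::t.test(x, y, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "two-sided unpaired t (pooled variance)")
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "two-sided Mann-Whitney U")
  }
}
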