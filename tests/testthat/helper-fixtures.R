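# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately brute-force and share no code with the implementation.

# Small planted study: 2 line clusters of 3, 2 primaries, 2 normals;
# a handful of elements per class. Runs in well under a second.
tiny_landscape <- function(seed = 11L, ...) {
  simulate_landscape(
    config = se_config(min_cluster_size = 2, variance_top_fraction = 0.3),
    n_tumor_lines = 6, n_primaries = 2, n_normals = 2,
    n_line_clusters = 2, n_primary_clusters = 1,
    n_shared = 8, n_cluster_specific = 3, n_primary_specific = 1,
    n_tumor_specific = 2, n_enlarged = 1, n_normal_only = 2,
    n_typical = 30, n_false_peaks = 2,
    genome = data.frame(chrom = c("chr1", "chr2"),
                        length = c(4e6, 4e6)),
    seed = seed, ...)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             max_pos = 1e5, max_len = 5000) {
  start <- floor(runif(n, 0, max_pos))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + ceiling(runif(n, 1, max_len)),
             stringsAsFactors = FALSE)
}

# Pairwise relation matrices for the brute-force closure oracle:
# "gap" relates i,j when max(starts) - min(ends) <= value, "overlap" when
# min(ends) - max(starts) >= value. Components come from igraph,
# independent of the package's union-find sweep.
interval_adjacency <- function(x, type = c("gap", "overlap"), value) {
  type <- match.arg(type)
  same <- outer(x$chrom, x$chrom, "==")
  minend <- outer(x$end, x$end, pmin)
  maxstart <- outer(x$start, x$start, pmax)
  adj <- if (type == "gap") same & (maxstart - minend <= value)
         else same & (minend - maxstart >= value)
  diag(adj) <- FALSE
  adj
}

closure_components <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  igraph::components(g)$membership
}

# Merged spans from component labels, sorted genomically.
closure_spans <- function(x, membership) {
  out <- do.call(rbind, lapply(split(seq_len(nrow(x)), membership),
                               function(i) {
    data.frame(chrom = x$chrom[i[1]], start = min(x$start[i]),
               end = max(x$end[i]), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start, out$end), ]
  rownames(out) <- NULL
  out
}

# Per-base summation oracle for coverage counting (instances <= 10 kb).
per_base_coverage_sum <- function(coverage, interval) {
  bases <- seq(interval$start, interval$end - 1)
  depth <- numeric(length(bases))
  for (k in seq_len(nrow(coverage))) {
    if (coverage$chrom[k] != interval$chrom) next
    hit <- bases >= coverage$start[k] & bases < coverage$end[k]
    depth[hit] <- depth[hit] + coverage$value[k]
  }
  sum(depth)
}

# Exhaustive Mann-Whitney U by pair counting.
brute_u_statistic <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# Vector with exact Pearson correlation r to x (orthogonal-component
# construction, no noise).
vector_with_cor <- function(x, r, seed_vec = NULL) {
  z1 <- (x - mean(x)) / sd(x)
  if (is.null(seed_vec)) seed_vec <- rnorm(length(x))
  resid <- stats::residuals(stats::lm(seed_vec ~ z1))
  z2 <- resid / sd(resid)
  r * z1 + sqrt(1 - r^2) * z2
}

expected_cluster_ari <- function(result, landscape) {
  lab <- result$clustering$labels
  truth <- landscape$truth$line_clusters[names(lab)]
  mclust::adjustedRandIndex(lab, truth)
}
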