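# Synthetic miniature study with planted ground truth: a small genome
# carrying shared, cluster-specific, tumor-specific, enlarged, normal-only
# superenhancers and typical enhancers; per-sample ChIP/input coverage as
# uniform background plus boxcar enrichment over owned peaks; expression
# correlated with realized SE sizes; and a dropout screen with essential
# controls, NTCs and planted tumor-line dependencies. Every generator is
# deterministic under its seed.

#' Simulate a planted enhancer landscape
#'
#' Places disjoint elements along a small genome with inter-element gaps
#' exceeding the stitch distance, so each planted element maps to exactly
#' one consensus element. Superenhancer-class elements are clusters of
#' 3-10 constituent peaks separated by less than the stitch distance;
#' typical enhancers are single peaks. Element classes and their owners:
#'
#' * `shared_SE` - all samples, amplitude 200-600 RPKM.
#' * `cluster_specific_SE` - the members of one sample cluster (tumor
#'   cell-line clusters and primary-tumor clusters), amplitude 700-880,
#'   so the cell-line cluster-defining set is exactly the top-variance
#'   stratum.
#' * `tumor_specific_SE` - a subset of tumor lines (at least
#'   `min_tumor_lines`) plus primaries (at least `min_primaries`), no
#'   normals; amplitude 200-350.
#' * `enlarged_SE` - all samples, but normals carry `1/(1.5 x
#'   enlarged_fold)` of the tumor amplitude, exercising the 2x rule.
#' * `normal_only_SE` - normal samples only.
#' * `typical_enhancer` - all samples at 5-50 RPKM, below the SE scale.
#'
#' Per-sample, per-element amplitudes get multiplicative lognormal jitter;
#' background is a uniform per-base rate identical in ChIP and input, with
#' equal library sizes, so input subtraction cancels background exactly.
#'
#' @param config an [se_config()]; thresholds, bin width and ownership
#'   minima are taken from here.
#' @param n_tumor_lines,n_primaries,n_normals sample counts (defaults
#'   16 / 8 / 6, a desk-scale version of the published panel).
#' @param n_line_clusters,n_primary_clusters planted cluster counts.
#' @param n_shared,n_cluster_specific,n_primary_specific,n_tumor_specific,n_enlarged,n_normal_only,n_typical
#'   element counts (`n_cluster_specific` and `n_primary_specific` are per
#'   cluster).
#' @param n_false_peaks background-only peaks added per sample in a
#'   reserved region (false positives with no enrichment).
#' @param genome data frame `chrom`, `length`.
#' @param bg_rate uniform background coverage per base.
#' @param jitter_sd lognormal sdlog of per-sample amplitude jitter.
#' @param library_size ChIP and input library size for every sample.
#' @param signal_scale global multiplier on all enrichment amplitudes
#'   (0 gives a null landscape with no signal anywhere).
#' @param seed RNG seed (default from `config$rng_seed`).
#' @return An `se_landscape` with samples, elements, peaks, per-sample
#'   amplitudes, false peaks, gene annotation, and a `truth` list
#'   (cluster labels, tumor-specific elements with modes, planted genes).
#' @export
simulate_landscape <- function(config = se_config(),
                               n_tumor_lines = 16, n_primaries = 8,
                               n_normals = 6,
                               n_line_clusters = 4, n_primary_clusters = 2,
                               n_shared = 186, n_cluster_specific = 6,
                               n_primary_specific = 5,
                               n_tumor_specific = 8, n_enlarged = 4,
                               n_normal_only = 8, n_typical = 300,
                               n_false_peaks = 5,
                               genome = data.frame(
                                 chrom = c("chr1", "chr2"),
                                 length = c(16e6, 16e6)),
                               bg_rate = 0.05, jitter_sd = 0.05,
                               library_size = 2e7, signal_scale = 1,
                               seed = config$rng_seed) {
  stopifnot(n_tumor_lines >= n_line_clusters,
            n_primaries >= n_primary_clusters, n_normals >= 1)
  with_seed(seed, {
    ## --- samples and planted cluster labels -------------------------------
    line_ids <- sprintf("TL%02d", seq_len(n_tumor_lines))
    prim_ids <- sprintf("PT%02d", seq_len(n_primaries))
    norm_ids <- sprintf("NM%02d", seq_len(n_normals))
    line_cl <- sort(rep(seq_len(n_line_clusters),
                        length.out = n_tumor_lines))
    prim_cl <- sort(rep(n_line_clusters + seq_len(n_primary_clusters),
                        length.out = n_primaries))
    norm_cl <- rep(n_line_clusters + n_primary_clusters + 1L, n_normals)
    samples <- data.frame(
      sample_id = c(line_ids, prim_ids, norm_ids),
      category = rep(c("tumor_cell_line", "primary_tumor", "normal"),
                     c(n_tumor_lines, n_primaries, n_normals)),
      subtype = rep(c("TNBC", "TNBC", "HMEC"),
                    c(n_tumor_lines, n_primaries, n_normals)),
      chip_library_size = library_size,
      input_library_size = library_size,
      truth_cluster = c(line_cl, prim_cl, norm_cl),
      stringsAsFactors = FALSE
    )
    all_ids <- samples$sample_id

    ## --- element catalog: class, owners, amplitude ------------------------
    owner_lines <- max(config$min_tumor_lines,
                       min(n_tumor_lines, round(0.4 * n_tumor_lines)))
    owner_prims <- max(config$min_primaries, min(n_primaries, 3))
    if (owner_lines > n_tumor_lines || owner_prims > n_primaries) {
      stop("too few tumor samples to satisfy tumor-specific ownership",
           call. = FALSE)
    }
    cat_rows <- list()
    add <- function(class, owners, amplitude, normal_amplitude = NA) {
      cat_rows[[length(cat_rows) + 1L]] <<- list(
        class = class, owners = owners, amplitude = amplitude,
        normal_amplitude = normal_amplitude)
    }
    for (i in seq_len(n_shared)) {
      add("shared_SE", all_ids, stats::runif(1, 200, 600))
    }
    for (cl in seq_len(n_line_clusters)) {
      for (i in seq_len(n_cluster_specific)) {
        add("cluster_specific_SE", line_ids[line_cl == cl],
            stats::runif(1, 700, 880))
      }
    }
    for (cl in seq_len(n_primary_clusters)) {
      for (i in seq_len(n_primary_specific)) {
        add("cluster_specific_SE",
            prim_ids[prim_cl == n_line_clusters + cl],
            stats::runif(1, 700, 880))
      }
    }
    for (i in seq_len(n_tumor_specific)) {
      add("tumor_specific_SE",
          c(sample(line_ids, owner_lines), sample(prim_ids, owner_prims)),
          stats::runif(1, 200, 350))
    }
    for (i in seq_len(n_enlarged)) {
      amp <- stats::runif(1, 280, 380)
      add("enlarged_SE", all_ids, amp,
          normal_amplitude = amp / (1.5 * config$enlarged_fold))
    }
    for (i in seq_len(n_normal_only)) {
      add("normal_only_SE", norm_ids, stats::runif(1, 200, 600))
    }
    for (i in seq_len(n_typical)) {
      add("typical_enhancer", all_ids, stats::runif(1, 5, 50))
    }
    cat_rows <- cat_rows[sample(length(cat_rows))]
    n_el <- length(cat_rows)

    ## --- placement along the genome ---------------------------------------
    tail_reserve <- 250000
    chrom_i <- 1L
    cursor <- 0
    el_list <- vector("list", n_el)
    peak_list <- vector("list", n_el)
    for (e in seq_len(n_el)) {
      cls <- cat_rows[[e]]$class
      gap <- stats::runif(1, 15000, 25000)
      if (cls == "typical_enhancer") {
        widths <- stats::runif(1, 800, 2000)
        intra <- numeric(0)
      } else {
        np <- sample(3:10, 1)
        widths <- stats::runif(np, 1000, 2500)
        intra <- stats::runif(np - 1, 2000, 8000)
      }
      span <- sum(widths) + sum(intra)
      repeat {
        start <- cursor + gap
        if (start + span <= genome$length[chrom_i] - tail_reserve) break
        chrom_i <- chrom_i + 1L
        cursor <- 0
        if (chrom_i > nrow(genome)) {
          stop("planted elements do not fit; enlarge the synthetic genome",
               call. = FALSE)
        }
      }
      p_start <- start + cumsum(c(0, widths[-length(widths)] + intra))
      peak_list[[e]] <- data.frame(
        element_idx = e, chrom = genome$chrom[chrom_i],
        start = round(p_start), end = round(p_start + widths),
        stringsAsFactors = FALSE)
      el_list[[e]] <- data.frame(
        element_idx = e, class = cls, chrom = genome$chrom[chrom_i],
        start = round(p_start[1]),
        end = round(p_start[length(widths)] + widths[length(widths)]),
        amplitude = cat_rows[[e]]$amplitude,
        normal_amplitude = cat_rows[[e]]$normal_amplitude,
        stringsAsFactors = FALSE)
      cursor <- start + span
    }
    elements <- do.call(rbind, el_list)
    peaks <- do.call(rbind, peak_list)
    elements$peak_bases <- as.vector(
      rowsum(peaks$end - peaks$start, peaks$element_idx))
    owners <- lapply(cat_rows, `[[`, "owners")

    ## --- per-sample amplitudes (jittered, scaled) -------------------------
    jitter <- matrix(exp(stats::rnorm(n_el * nrow(samples), 0, jitter_sd)),
                     n_el, nrow(samples), dimnames = list(NULL, all_ids))
    amp <- matrix(0, n_el, nrow(samples), dimnames = list(NULL, all_ids))
    for (e in seq_len(n_el)) {
      own <- owners[[e]]
      base <- rep(elements$amplitude[e], length(own))
      if (elements$class[e] == "enlarged_SE") {
        is_norm <- own %in% norm_ids
        base[is_norm] <- elements$normal_amplitude[e]
      }
      amp[e, own] <- base * jitter[e, own]
    }
    amp <- amp * signal_scale

    ## --- false-positive peaks in the reserved tail ------------------------
    fp_list <- lapply(all_ids, function(s) {
      if (n_false_peaks == 0) return(NULL)
      ci <- sample(nrow(genome), n_false_peaks, replace = TRUE)
      w <- stats::runif(n_false_peaks, 800, 2000)
      st <- round(stats::runif(n_false_peaks,
                               genome$length[ci] - tail_reserve + 13000,
                               genome$length[ci] - 3000))
      data.frame(sample = s, chrom = genome$chrom[ci], start = st,
                 end = round(st + w), stringsAsFactors = FALSE)
    })
    false_peaks <- do.call(rbind, fp_list)

    ## --- gene annotation and planted association targets ------------------
    focal <- which(elements$class %in% c("tumor_specific_SE",
                                         "enlarged_SE"))
    gene_rows <- list()
    assoc_rows <- list()
    gid <- 0L
    for (e in focal) {
      chrom_len <- genome$length[genome$chrom == elements$chrom[e]]
      offs <- c(stats::runif(1, 3e4, 2e5), stats::runif(1, 5e5, 4e6))
      for (o in offs) {
        gid <- gid + 1L
        glen <- stats::runif(1, 2000, 10000)
        gstart <- if (elements$end[e] + o + glen < chrom_len) {
          elements$end[e] + o
        } else {
          max(0, elements$start[e] - o - glen)
        }
        gene_id <- sprintf("GENE%03d", gid)
        gene_rows[[gid]] <- data.frame(
          gene_id = gene_id, chrom = elements$chrom[e],
          start = round(gstart), end = round(gstart + glen),
          stringsAsFactors = FALSE)
        assoc_rows[[length(assoc_rows) + 1L]] <- data.frame(
          element_idx = e, gene_id = gene_id, stringsAsFactors = FALSE)
      }
    }
    n_background_genes <- 96
    for (i in seq_len(n_background_genes)) {
      gid <- gid + 1L
      ci <- sample(nrow(genome), 1)
      glen <- stats::runif(1, 2000, 10000)
      gstart <- round(stats::runif(1, 0, genome$length[ci] - glen - 1))
      gene_rows[[gid]] <- data.frame(
        gene_id = sprintf("GENE%03d", gid), chrom = genome$chrom[ci],
        start = gstart, end = round(gstart + glen),
        stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, gene_rows)
    planted_assoc <- do.call(rbind, assoc_rows)

    truth <- list(
      cluster_labels = stats::setNames(samples$truth_cluster,
                                       samples$sample_id),
      line_clusters = stats::setNames(line_cl, line_ids),
      tumor_specific = data.frame(
        element_idx = focal,
        mode = ifelse(elements$class[focal] == "enlarged_SE",
                      "enlarged", "acquired"),
        chrom = elements$chrom[focal], start = elements$start[focal],
        end = elements$end[focal], stringsAsFactors = FALSE),
      planted_genes = planted_assoc
    )
    structure(list(config = config, seed = seed, genome = genome,
                   samples = samples, elements = elements, peaks = peaks,
                   owners = owners, amplitude = amp, jitter = jitter,
                   false_peaks = false_peaks, genes = genes,
                   bg_rate = bg_rate, truth = truth),
              class = "se_landscape")
  })
}

#' @export
print.se_landscape <- function(x, ...) {
  cat(sprintf("<se_landscape> %d samples, %d planted elements on %d chromosome(s)\n",
              nrow(x$samples), nrow(x$elements), nrow(x$genome)))
  print(table(x$elements$class))
  invisible(x)
}

# Per-peak enrichment height for one sample: chosen so the element-level
# input-subtracted RPKM equals the planted amplitude (background cancels
# because ChIP and input share the rate and the library size).
sample_peak_heights <- function(landscape, sample) {
  el <- landscape$elements
  lib <- landscape$samples$chip_library_size[
    match(sample, landscape$samples$sample_id)]
  span <- el$end - el$start
  h_el <- landscape$amplitude[, sample] * (lib / 1e6) * (span / 1000) /
    el$peak_bases
  h_el[landscape$peaks$element_idx]
}

#' Analytic coverage counts for a landscape sample
#'
#' Returns, per query interval, the exact sum of per-base coverage under
#' the generator's model: uniform background everywhere plus boxcar
#' enrichment over owned peaks (ChIP track only). Identical to summing
#' the emitted bedGraph.
#'
#' @param landscape an `se_landscape`.
#' @param sample sample id.
#' @param intervals query interval data frame.
#' @param track `"chip"` or `"input"`.
#' @return numeric vector of counts.
#' @export
coverage_counts <- function(landscape, sample, intervals,
                            track = c("chip", "input")) {
  track <- match.arg(track)
  intervals <- validate_intervals(intervals, "query intervals")
  counts <- landscape$bg_rate * (intervals$end - intervals$start)
  if (track == "input") return(counts)
  h <- sample_peak_heights(landscape, sample)
  active <- which(h > 0)
  if (!length(active)) return(counts)
  pk <- landscape$peaks[active, , drop = FALSE]
  hits <- GenomicRanges::findOverlaps(intervals_to_gr(intervals),
                                      intervals_to_gr(pk))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- pmin(intervals$end[qh], pk$end[sh]) -
      pmax(intervals$start[qh], pk$start[sh])
    agg <- rowsum(ov * h[active][sh], group = qh)
    counts[as.integer(rownames(agg))] <-
      counts[as.integer(rownames(agg))] + agg[, 1]
  }
  counts
}

#' Write a landscape as a self-contained study directory
#'
#' Emits, per sample, a peak BED (owned peaks plus the sample's
#' false-positive peaks), a ChIP bedGraph (background + boxcar
#' enrichment) and an input bedGraph (background only); plus
#' `metadata.tsv`, `genes.bed`, `tss.bed` and a `truth.json` ground-truth
#' file. Everything parses back through the package readers.
#'
#' @param landscape an `se_landscape`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
emit_sample_files <- function(landscape, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop("cannot write to directory: ", out_dir, call. = FALSE)
  }
  gen <- landscape$genome
  for (s in landscape$samples$sample_id) {
    h <- sample_peak_heights(landscape, s)
    owned <- landscape$peaks[h > 0, c("chrom", "start", "end")]
    fp <- landscape$false_peaks[landscape$false_peaks$sample == s,
                                c("chrom", "start", "end")]
    bed <- rbind(owned, fp)
    bed <- bed[order(bed$chrom, bed$start), ]
    write_bed(bed, file.path(out_dir, paste0(s, ".peaks.bed")))

    rows <- list()
    for (ci in seq_len(nrow(gen))) {
      on_chrom <- which(h > 0 & landscape$peaks$chrom == gen$chrom[ci])
      on_chrom <- on_chrom[order(landscape$peaks$start[on_chrom])]
      pos <- 0
      for (p in on_chrom) {
        ps <- landscape$peaks$start[p]
        pe <- landscape$peaks$end[p]
        if (ps > pos) {
          rows[[length(rows) + 1L]] <- c(gen$chrom[ci], pos, ps,
                                         landscape$bg_rate)
        }
        rows[[length(rows) + 1L]] <- c(gen$chrom[ci], ps, pe,
                                       landscape$bg_rate + h[p])
        pos <- pe
      }
      rows[[length(rows) + 1L]] <- c(gen$chrom[ci], pos, gen$length[ci],
                                     landscape$bg_rate)
    }
    bg <- data.frame(chrom = vapply(rows, `[[`, "", 1L),
                     start = as.numeric(vapply(rows, `[[`, "", 2L)),
                     end = as.numeric(vapply(rows, `[[`, "", 3L)),
                     value = as.numeric(vapply(rows, `[[`, "", 4L)),
                     stringsAsFactors = FALSE)
    utils::write.table(
      bg, file.path(out_dir, paste0(s, ".chip.bedGraph")), sep = "\t",
      quote = FALSE, row.names = FALSE, col.names = FALSE)
    inp <- data.frame(chrom = gen$chrom, start = 0, end = gen$length,
                      value = landscape$bg_rate)
    utils::write.table(
      inp, file.path(out_dir, paste0(s, ".input.bedGraph")), sep = "\t",
      quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(
    landscape$samples[, c("sample_id", "category", "subtype",
                          "chip_library_size", "input_library_size")],
    file.path(out_dir, "metadata.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  genes <- landscape$genes
  write_bed(data.frame(chrom = genes$chrom, start = genes$start,
                       end = genes$end, name = genes$gene_id),
            file.path(out_dir, "genes.bed"))
  write_bed(data.frame(chrom = genes$chrom, start = genes$start,
                       end = genes$start + 1, name = genes$gene_id),
            file.path(out_dir, "tss.bed"))
  truth <- landscape$truth
  truth$elements <- landscape$elements[, c("element_idx", "class", "chrom",
                                           "start", "end")]
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

# SE sizes of the planted SE-class elements, computed with the pipeline's
# own binning and scoring on the analytic coverage (elements x samples).
landscape_se_sizes <- function(landscape, element_idx = NULL) {
  el <- landscape$elements
  if (is.null(element_idx)) {
    element_idx <- which(el$class != "typical_enhancer")
  }
  sub <- el[element_idx, , drop = FALSE]
  sub$element_id <- sprintf("P%04d", sub$element_idx)
  bins <- bin_elements(sub, landscape$config$bin_width)
  ids <- landscape$samples$sample_id
  chip <- vapply(ids, function(s) coverage_counts(landscape, s, bins,
                                                  "chip"),
                 numeric(nrow(bins)))
  inp <- vapply(ids, function(s) coverage_counts(landscape, s, bins,
                                                 "input"),
                numeric(nrow(bins)))
  sm <- score_samples(bins, chip, inp, landscape$samples)
  sizes <- element_scores(sm, "size")$values
  rownames(sizes) <- as.character(sub$element_idx[
    match(rownames(sizes), sub$element_id)])
  sizes
}

#' Simulate gene expression correlated with planted SE sizes
#'
#' For each planted (SE, gene) pair the log2 expression is a linear
#' function of the pipeline-realized log2 SE size plus Gaussian noise
#' scaled so the expected Pearson correlation across tumor cell lines
#' equals `target_r` (`target_r = 1` or `noise_sd = 0` is exactly
#' noiseless, giving r = 1). Unassociated genes are independent noise.
#'
#' @param landscape an `se_landscape` (needs >= 6 samples).
#' @param target_r target correlation in (0, 1].
#' @param noise_sd overrides the derived noise SD when given.
#' @param slope,intercept linear map from log2 size to log2 RPKM.
#' @param seed RNG seed.
#' @return list with `expression` (genes x samples RPKM matrix),
#'   `associations` (element_idx, gene_id, target_r), `noise_sd`.
#' @export
simulate_expression <- function(landscape, target_r = 0.9,
                                noise_sd = NULL, slope = 0.8,
                                intercept = 1,
                                seed = landscape$seed + 1L) {
  if (nrow(landscape$samples) < 6) {
    stop("need >= 6 samples for meaningful correlations", call. = FALSE)
  }
  if (target_r <= 0 || target_r > 1) {
    stop("target_r must lie in (0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    ids <- landscape$samples$sample_id
    lines <- ids[landscape$samples$category == "tumor_cell_line"]
    assoc <- landscape$truth$planted_genes
    sizes <- landscape_se_sizes(landscape,
                                unique(assoc$element_idx))
    expr <- matrix(0, nrow(landscape$genes), length(ids),
                   dimnames = list(landscape$genes$gene_id, ids))
    planted <- character()
    for (i in seq_len(nrow(assoc))) {
      x <- log2(sizes[as.character(assoc$element_idx[i]), ] + 1)
      sd_x <- stats::sd(x[lines])
      eps_sd <- if (!is.null(noise_sd)) noise_sd
                else slope * sd_x * sqrt(1 / target_r^2 - 1)
      lg <- intercept + slope * x + stats::rnorm(length(x), 0, eps_sd)
      expr[assoc$gene_id[i], ] <- pmax(2^lg - 1, 0)
      planted <- c(planted, assoc$gene_id[i])
    }
    for (g in setdiff(rownames(expr), planted)) {
      mu <- stats::runif(1, 2, 6)
      expr[g, ] <- pmax(2^stats::rnorm(length(ids), mu, 1) - 1, 0)
    }
    assoc$target_r <- if (!is.null(noise_sd) && noise_sd == 0) 1
                      else target_r
    list(expression = expr, associations = assoc,
         noise_sd = if (is.null(noise_sd)) NA_real_ else noise_sd)
  })
}

#' Simulate a pooled CRISPR dropout screen
#'
#' Negative-binomial guide counts at a reference and a late timepoint for
#' target genes, essential positive controls and non-targeting controls.
#' Essential genes are depleted in every line; planted dependency genes
#' are depleted only in tumor cell lines. Per-guide efficacy varies (half
#' the guides carry near-full effect), making top-guide selection
#' meaningful.
#'
#' @param landscape optional `se_landscape`; supplies default targets
#'   (the planted SE-associated genes), dependency genes (the first gene
#'   of each tumor-specific element) and screened lines (three tumor
#'   lines and one normal).
#' @param targets,dependent_genes,lines overrides; `lines` is a data
#'   frame `line`, `category`.
#' @param n_essential,n_ntc control gene counts (must both be > 0).
#' @param guides_per_gene library design (default from `config`).
#' @param effect_essential,effect_dependency log2 depletion at full
#'   efficacy.
#' @param mean_count mean t0 guide abundance.
#' @param nb_size negative-binomial size (inverse dispersion).
#' @param config an [se_config()].
#' @param seed RNG seed.
#' @return list with `counts` (per-line data frames: guide, gene, role,
#'   count_t0, count_late), `guide_map`, `lines`, and `truth`
#'   (`dependent_genes`, `essential_genes`).
#' @export
simulate_screen <- function(landscape = NULL, targets = NULL,
                            dependent_genes = NULL, lines = NULL,
                            n_essential = 20, n_ntc = 25,
                            guides_per_gene = NULL,
                            effect_essential = -3,
                            effect_dependency = -3,
                            mean_count = 400, nb_size = 100,
                            config = if (!is.null(landscape))
                              landscape$config else se_config(),
                            seed = if (!is.null(landscape))
                              landscape$seed + 2L else 1L) {
  if (n_essential < 1 || n_ntc < 1) {
    stop("both control sets must be non-empty (normalization impossible)",
         call. = FALSE)
  }
  if (is.null(guides_per_gene)) guides_per_gene <- config$guides_per_gene
  if (is.null(targets)) {
    if (is.null(landscape)) stop("supply targets or a landscape",
                                 call. = FALSE)
    targets <- sort(unique(landscape$truth$planted_genes$gene_id))
  }
  if (is.null(dependent_genes)) {
    if (!is.null(landscape)) {
      pg <- landscape$truth$planted_genes
      dependent_genes <- vapply(split(pg$gene_id, pg$element_idx),
                                `[[`, "", 1L)
      dependent_genes <- unname(dependent_genes)
    } else {
      dependent_genes <- character()
    }
  }
  if (is.null(lines)) {
    if (!is.null(landscape)) {
      md <- landscape$samples
      lines <- data.frame(
        line = c(utils::head(md$sample_id[md$category ==
                                          "tumor_cell_line"], 3),
                 utils::head(md$sample_id[md$category == "normal"], 1)),
        stringsAsFactors = FALSE)
      lines$category <- md$category[match(lines$line, md$sample_id)]
    } else {
      lines <- data.frame(line = c("T1", "T2", "T3", "N1"),
                          category = c(rep("tumor_cell_line", 3),
                                       "normal"),
                          stringsAsFactors = FALSE)
    }
  }
  with_seed(seed, {
    ess <- sprintf("ESS%02d", seq_len(n_essential))
    ntc <- sprintf("NTC%02d", seq_len(n_ntc))
    genes <- c(targets, ess, ntc)
    role <- rep(c("target", "positive_control", "NTC"),
                c(length(targets), n_essential, n_ntc))
    guide_map <- data.frame(
      guide = paste0(rep(genes, each = guides_per_gene), "_g",
                     seq_len(guides_per_gene)),
      gene = rep(genes, each = guides_per_gene),
      role = rep(role, each = guides_per_gene),
      stringsAsFactors = FALSE)
    n_hi <- ceiling(guides_per_gene / 2)
    efficacy <- unlist(lapply(genes, function(g) {
      e <- c(stats::runif(n_hi, 0.85, 1),
             stats::runif(guides_per_gene - n_hi, 0.05, 0.4))
      sample(e)
    }))
    rel <- exp(stats::rnorm(nrow(guide_map), 0, 0.15))
    rate0 <- mean_count * rel
    counts <- lapply(seq_len(nrow(lines)), function(li) {
      eff_gene <- ifelse(
        guide_map$role == "positive_control", effect_essential,
        ifelse(guide_map$gene %in% dependent_genes &
                 lines$category[li] == "tumor_cell_line",
               effect_dependency, 0))
      t0 <- stats::rnbinom(nrow(guide_map), mu = rate0, size = nb_size)
      late <- stats::rnbinom(nrow(guide_map),
                             mu = rate0 * 2^(eff_gene * efficacy),
                             size = nb_size)
      data.frame(guide = guide_map$guide, gene = guide_map$gene,
                 role = guide_map$role, count_t0 = t0, count_late = late,
                 stringsAsFactors = FALSE)
    })
    names(counts) <- lines$line
    list(counts = counts, guide_map = guide_map, lines = lines,
         truth = list(dependent_genes = dependent_genes,
                      essential_genes = ess))
  })
}

#' Simulate a CERES-like dependency score table
#'
#' For a focal planted tumor-specific SE, its owner tumor cell lines are
#' made dependent (scores near -1) and all other lines independent
#' (scores near 0) on the focal gene.
#'
#' @param landscape an `se_landscape`.
#' @param focal_element element index (default: first tumor-specific).
#' @param noise_sd Gaussian noise on the scores.
#' @param seed RNG seed.
#' @return list with `scores` (named vector over tumor cell lines),
#'   `focal_element`, `dependent_lines`.
#' @export
simulate_dependency <- function(landscape, focal_element = NULL,
                                noise_sd = 0.1,
                                seed = landscape$seed + 3L) {
  if (is.null(focal_element)) {
    focal_element <- which(landscape$elements$class ==
                             "tumor_specific_SE")[1]
  }
  lines <- landscape$samples$sample_id[
    landscape$samples$category == "tumor_cell_line"]
  dep <- intersect(landscape$owners[[focal_element]], lines)
  with_seed(seed, {
    mu <- ifelse(lines %in% dep, -1, 0)
    scores <- stats::setNames(stats::rnorm(length(lines), mu, noise_sd),
                              lines)
    list(scores = scores, focal_element = focal_element,
         dependent_lines = dep)
  })
}
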