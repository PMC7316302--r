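test_that("landscape generation is deterministic under a fixed seed", {
  a <- tiny_landscape(seed = 3L)
  b <- tiny_landscape(seed = 3L)
  expect_equal(a$elements, b$elements)
  expect_equal(a$amplitude, b$amplitude)
  expect_equal(a$false_peaks, b$false_peaks)
  c <- tiny_landscape(seed = 4L)
  expect_false(identical(a$amplitude, c$amplitude))
})

test_that("planted ownership invariants hold by construction", {
  ls0 <- tiny_landscape()
  cfg <- ls0$config
  md <- ls0$samples
  ts <- which(ls0$elements$class == "tumor_specific_SE")
  expect_length(ts, 2)
  for (e in ts) {
    own <- ls0$owners[[e]]
    cats <- md$category[match(own, md$sample_id)]
    expect_gte(sum(cats == "tumor_cell_line"), cfg$min_tumor_lines)
    expect_gte(sum(cats == "primary_tumor"), cfg$min_primaries)
    expect_equal(sum(cats == "normal"), 0)
  }
  # elements are placed disjoint with gaps beyond the stitch distance
  el <- ls0$elements[order(ls0$elements$chrom, ls0$elements$start), ]
  same <- el$chrom[-1] == el$chrom[-nrow(el)]
  gaps <- el$start[-1] - el$end[-nrow(el)]
  expect_true(all(gaps[same] > cfg$stitch_distance))
})

test_that("owner coverage is enriched over input; non-owners sit at input", {
  ls0 <- tiny_landscape()
  e <- which(ls0$elements$class == "cluster_specific_SE")[1]
  own <- ls0$owners[[e]]
  non <- setdiff(ls0$samples$sample_id, own)[1]
  peak1 <- ls0$peaks[ls0$peaks$element_idx == e, ][1, c("chrom", "start",
                                                        "end")]
  chip_own <- coverage_counts(ls0, own[1], peak1, "chip")
  chip_non <- coverage_counts(ls0, non, peak1, "chip")
  inp <- coverage_counts(ls0, own[1], peak1, "input")
  expect_gt(chip_own, inp)
  expect_equal(chip_non, inp)  # uniform background model: exact equality
})

test_that("emitted study files parse back and match analytic coverage", {
  ls0 <- tiny_landscape()
  dir <- withr::local_tempdir()
  emit_sample_files(ls0, dir)
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(md$sample_id, ls0$samples$sample_id)
  s <- ls0$samples$sample_id[1]
  peaks <- read_bed(file.path(dir, paste0(s, ".peaks.bed")))
  expect_gt(nrow(peaks), 0)
  chip <- read_bedgraph(file.path(dir, paste0(s, ".chip.bedGraph")))
  q <- ls0$elements[1:5, c("chrom", "start", "end")]
  expect_equal(interval_coverage(chip, q),
               coverage_counts(ls0, s, q, "chip"), tolerance = 1e-9)
  genes <- read_bed(file.path(dir, "genes.bed"))
  expect_equal(nrow(genes), nrow(ls0$genes))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(sort(unlist(truth$tumor_specific$element_idx)),
               sort(ls0$truth$tumor_specific$element_idx))
})

test_that("noiseless planted associations are exactly linear (r = 1)", {
  ls0 <- tiny_landscape()
  ex <- simulate_expression(ls0, noise_sd = 0)
  sizes <- selandscape:::landscape_se_sizes(
    ls0, unique(ex$associations$element_idx))
  for (i in seq_len(nrow(ex$associations))) {
    x <- log2(sizes[as.character(ex$associations$element_idx[i]), ] + 1)
    y <- log2(ex$expression[ex$associations$gene_id[i], ] + 1)
    expect_equal(cor(x, y), 1, tolerance = 1e-12)
  }
  expect_error(simulate_expression(ls0, target_r = 1.5), "target_r")
})

test_that("generator calibration: target r = 0.9 is realized across seeds", {
  ls0 <- tiny_landscape()
  sizes <- selandscape:::landscape_se_sizes(
    ls0, unique(ls0$truth$planted_genes$element_idx))
  lines <- ls0$samples$sample_id[ls0$samples$category == "tumor_cell_line"]
  gene1 <- ls0$truth$planted_genes$gene_id[1]
  el1 <- as.character(ls0$truth$planted_genes$element_idx[1])
  x <- log2(sizes[el1, lines] + 1)
  r_real <- vapply(1:200, function(s) {
    ex <- simulate_expression(ls0, target_r = 0.9, seed = 1000L + s)
    cor(x, log2(ex$expression[gene1, lines] + 1))
  }, 0)
  expect_gte(mean(r_real >= 0.7 & r_real <= 0.999), 0.95)
})

test_that("unassociated genes rarely clear the association threshold", {
  withr::local_seed(70)
  # null distribution of Pearson r at n = 20: |r| < 0.6 almost always
  r_null <- replicate(400, cor(rnorm(20), rnorm(20)))
  expect_gte(mean(abs(r_null) < 0.6), 0.95)
})

test_that("screen counts book-keep the library design and null center", {
  scr <- simulate_screen(targets = paste0("T", 1:6),
                         dependent_genes = character(),
                         n_essential = 4, n_ntc = 5, seed = 9L)
  counts <- scr$counts[[1]]
  expect_equal(nrow(counts), (6 + 4 + 5) * 8)
  res <- analyze_screen(counts)
  # unaffected target genes share the NTC null: normalized LFCs center
  # on the 0 anchor and none approach the hit cutoff
  expect_lt(abs(mean(res$norm_lfc[res$role == "target"])), 0.2)
  expect_false(any(res$is_hit[res$role %in% c("target", "NTC")]))
  expect_error(simulate_screen(targets = "T1", n_ntc = 0),
               "control sets")
})

test_that("planted essential genes drop out below the NTC band", {
  ok <- vapply(1:50, function(s) {
    scr <- simulate_screen(targets = paste0("T", 1:3),
                           dependent_genes = character(),
                           n_essential = 5, n_ntc = 5, seed = 500L + s)
    res <- analyze_screen(scr$counts[[1]])
    all(res$raw_lfc[res$role == "positive_control"] <
          mean(res$raw_lfc[res$role == "NTC"]))
  }, TRUE)
  expect_gte(mean(ok), 0.99)
})

test_that("a zero-signal landscape yields no superenhancers end to end", {
  ls0 <- tiny_landscape(signal_scale = 0)
  res <- suppressWarnings(run_landscape_pipeline(ls0))
  expect_true(is.null(res$consensus_se) || nrow(res$consensus_se) == 0)
})
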