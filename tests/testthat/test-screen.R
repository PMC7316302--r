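test_that("guide LFC is zero at equal abundance and -1 when halved", {
  t0 <- setNames(c(100, 200), c("g1", "g2"))
  late_same <- setNames(c(100, 200), c("g1", "g2"))
  expect_equal(unname(guide_lfc(t0, late_same, pseudocount = 0)),
               c(0, 0))
  # halved relative abundance at matched library size
  late_half <- setNames(c(50, 100), c("g1", "g2"))
  lfc <- guide_lfc(t0, late_half, t0_lib = 300, late_lib = 300,
                   pseudocount = 0)
  expect_equal(unname(lfc), c(-1, -1))
  # depth-invariance: doubling all late counts and the late library
  withr::local_seed(7)
  a0 <- setNames(rpois(20, 300), paste0("g", 1:20))
  a1 <- setNames(rpois(20, 250), paste0("g", 1:20))
  expect_equal(guide_lfc(a0, a1), guide_lfc(a0, 2 * a1))
  # missing guide excluded with a warning
  expect_warning(out <- guide_lfc(setNames(c(10, 20), c("a", "b")),
                                  setNames(30, "a")), "excluded")
  expect_equal(names(out), "a")
})

test_that("gene LFC averages the top depleted guides", {
  g <- c(-3, -2, -1, 0, 0, 0, 0, 1)
  expect_equal(gene_lfc(g, top_guides = 3), -2)
  expect_equal(gene_lfc(rep(0, 8), 3), 0)
  expect_equal(gene_lfc(c(-4, -2), 3), -3)  # fewer guides: use all
  # permutation invariance over guide order
  withr::local_seed(13)
  v <- rnorm(8)
  expect_equal(gene_lfc(v, 3), gene_lfc(sample(v), 3))
  # |LFC|-based selection option
  expect_equal(gene_lfc(c(5, -1, 0.5, 0), 2, selection = "abs"), 2)
})

test_that("control-anchored normalization places -1 and 0 anchors", {
  raw <- setNames(c(-2, 0, -1, -3), c("ESS1", "NTC1", "mid", "deep"))
  norm <- normalize_lfc(raw, "ESS1", "NTC1")
  expect_equal(unname(norm["ESS1"]), -1)
  expect_equal(unname(norm["NTC1"]), 0)
  expect_equal(unname(norm["mid"]), -0.5)
  expect_equal(unname(norm["deep"]), -1.5)
  expect_error(normalize_lfc(raw, "absent", "NTC1"), "control sets")
  expect_error(normalize_lfc(setNames(c(1, 1), c("E", "N")), "E", "N"),
               "QC")
  # affine invariance: anchors move with the data
  withr::local_seed(29)
  raw2 <- setNames(rnorm(30), paste0("G", 1:30))
  pos <- paste0("G", 1:5); ntc <- paste0("G", 6:10)
  expect_equal(normalize_lfc(raw2, pos, ntc),
               normalize_lfc(1.7 * raw2 - 3.2, pos, ntc))
})

test_that("hit calling is inclusive at the -0.5 cutoff", {
  expect_true(call_hits(-0.5))
  expect_false(call_hits(-0.499))
  expect_equal(call_hits(c(-1, -0.5, -0.4, 0)), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("dependency classification is inclusive at -0.5", {
  s <- setNames(c(-0.5, 0.1, NA), c("l1", "l2", "l3"))
  got <- classify_dependent(s)
  expect_equal(unname(got), c("sensitive", "insensitive", NA))
  expect_equal(classify_dependent(setNames(numeric(), character())),
               setNames(character(), character()))
})

test_that("analyze_screen wires guides to genes with role bookkeeping", {
  withr::local_seed(41)
  scr <- simulate_screen(targets = paste0("T", 1:5),
                         dependent_genes = paste0("T", 1:2),
                         n_essential = 5, n_ntc = 5, seed = 41L)
  counts <- scr$counts[["T1"]]
  expect_equal(names(scr$counts), c("T1", "T2", "T3", "N1"))
  res <- analyze_screen(counts)
  expect_equal(nrow(res), 15)
  expect_equal(sort(unique(res$n_guides)), 8L)
  expect_equal(mean(res$norm_lfc[res$role == "positive_control"]), -1)
  expect_equal(mean(res$norm_lfc[res$role == "NTC"]), 0, tolerance = 1e-12)
  expect_error(analyze_screen(counts[, setdiff(names(counts), "role")]),
               "control genes")
})

test_that("dependency signatures rank co-owned elements and are disjoint", {
  withr::local_seed(83)
  lines <- paste0("L", 1:10)
  dep <- setNames(rep(c(TRUE, FALSE), each = 5), lines)
  m <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(sprintf("E%02d", 1:40), lines))
  m["E01", ] <- ifelse(dep, 8, 0) + rnorm(10, 0, 0.1)
  m["E02", ] <- ifelse(dep, 0, 8) + rnorm(10, 0, 0.1)
  sig <- dependency_signature(m, dep, signature_size = 5)
  expect_true("E01" %in% sig$positive$element_id)
  expect_true("E02" %in% sig$negative$element_id)
  expect_length(intersect(sig$positive$element_id,
                          sig$negative$element_id), 0)
  expect_lt(sig$separation_p, 0.05)
  # constant elements get r = 0
  m0 <- m; m0["E03", ] <- 4
  sig0 <- dependency_signature(m0, dep, signature_size = 20)
  both <- rbind(sig0$positive, sig0$negative)
  expect_equal(both$r[both$element_id == "E03"], 0)
  expect_error(dependency_signature(m, setNames(rep(TRUE, 10), lines),
                                    5), "per dependency class")
  sweep <- signature_size_sweep(m, dep, sizes = c(2, 5, 10))
  expect_equal(sweep$size, c(2, 5, 10))
  expect_true(all(sweep$separation_p > 0 & sweep$separation_p <= 1))
})

test_that("signature separation is calibrated against label permutations", {
  # The signature is selected to separate the labels it is given, so its
  # own separation p is descriptive, not inferential: on pure-noise data
  # re-selection drives it to the minimum attainable exact-U value for
  # every label shuffle. Calibration therefore fixes the signature once
  # and permutes labels: the permuted separation p behaves like a
  # (discrete, conservative) null p, and the true-label separation on
  # structured data beats essentially all permutations.
  withr::local_seed(59)
  lines <- paste0("L", 1:12)
  dep <- setNames(rep(c(TRUE, FALSE), each = 6), lines)
  m <- matrix(rnorm(60 * 12), 60, 12,
              dimnames = list(sprintf("E%02d", 1:60), lines))
  for (i in 1:8) m[i, ] <- ifelse(dep, 6, 0) + rnorm(12, 0, 0.5)
  sig <- dependency_signature(m, dep, signature_size = 10)
  expect_lt(sig$separation_p, 0.01)
  perm_p <- replicate(200, {
    shuffled <- setNames(sample(dep), lines)
    compare_groups(sig$line_score[shuffled], sig$line_score[!shuffled],
                   "mannwhitney")$p_value
  })
  expect_lte(mean(perm_p <= 0.05), 0.10)
  expect_lte(sig$separation_p, quantile(perm_p, 0.05))

  # re-selection on pure noise pins the p at its attainable minimum,
  # the circularity the fixed-signature calibration exists to avoid
  noise <- matrix(rnorm(60 * 12), 60, 12, dimnames = dimnames(m))
  p_null <- replicate(20, {
    shuffled <- setNames(sample(dep), lines)
    dependency_signature(noise, shuffled, signature_size = 10)$separation_p
  })
  expect_true(all(p_null < 0.05))
})
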