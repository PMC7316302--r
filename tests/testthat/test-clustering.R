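test_that("top_variable uses the ceiling rule and matches a variance sort", {
  withr::local_seed(14)
  m <- matrix(rnorm(100), 10, 10,
              dimnames = list(sprintf("el%02d", 1:10), paste0("s", 1:10)))
  sel <- top_variable(m, 0.10)
  expect_length(sel, 1)
  expect_equal(sel, names(which.max(apply(m, 1, var))))

  m2 <- rbind(m, const = rep(5, 10))
  expect_false("const" %in% top_variable(m2, 0.5))

  sel6 <- top_variable(m, 0.55)  # ceiling(5.5) = 6
  want <- names(sort(apply(m, 1, var), decreasing = TRUE))[1:6]
  expect_setequal(sel6, want)
  expect_error(top_variable(m, 0), "fraction")
})

test_that("sample correlation has unit diagonal and matches cor()", {
  withr::local_seed(25)
  m <- matrix(rnorm(25), 5, 5,
              dimnames = list(paste0("e", 1:5), paste0("s", 1:5)))
  cm <- correlate_samples(m)
  expect_equal(diag(cm), setNames(rep(1, 5), paste0("s", 1:5)))
  expect_equal(cm["s1", "s2"],
               sum((m[, 1] - mean(m[, 1])) * (m[, 2] - mean(m[, 2]))) /
                 ((5 - 1) * sd(m[, 1]) * sd(m[, 2])))
  # self vs exact negation
  m2 <- cbind(a = m[, 1], b = -m[, 1])
  cm2 <- correlate_samples(m2)
  expect_equal(cm2["a", "b"], -1)
  # zero-variance sample flagged and excluded from clustering
  m3 <- cbind(m, flat = rep(2, 5))
  expect_warning(cm3 <- correlate_samples(m3), "flat")
  expect_equal(attr(cm3, "flagged"), "flat")
  expect_warning(cl <- cluster_samples(cm3, k = 2, min_cluster_size = 1),
                 "excluding")
  expect_true(is.na(cl$labels["flat"]))
})

test_that("planted correlation blocks are recovered at ARI 1", {
  withr::local_seed(33)
  base1 <- rnorm(40); base2 <- rnorm(40)
  m <- cbind(sapply(1:4, function(i) base1 + rnorm(40, 0, 0.1)),
             sapply(1:4, function(i) base2 + rnorm(40, 0, 0.1)))
  colnames(m) <- paste0("s", 1:8)
  cl <- cluster_samples(correlate_samples(m), k = 2, min_cluster_size = 3)
  truth <- rep(1:2, each = 4)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
  # UPGMA merge heights are non-decreasing
  expect_true(all(diff(cl$tree$height) >= -1e-12))
  # order invariance up to labeling
  perm <- sample(8)
  cl2 <- cluster_samples(correlate_samples(m[, perm]), k = 2,
                         min_cluster_size = 3)
  expect_equal(mclust::adjustedRandIndex(
    cl$labels[colnames(m)], cl2$labels[colnames(m)]), 1)
})

test_that("k = n dissolves all singleton clusters to unassigned", {
  withr::local_seed(71)
  m <- matrix(rnorm(30), 5, 6, dimnames = list(NULL, paste0("s", 1:6)))
  cl <- cluster_samples(correlate_samples(m), k = 6, min_cluster_size = 3)
  expect_true(all(is.na(cl$labels)))
  expect_error(cluster_samples(correlate_samples(m), k = 7), "exceeds")
})

test_that("cluster diagnostics cover the k range with finite values", {
  withr::local_seed(97)
  base1 <- rnorm(30); base2 <- rnorm(30); base3 <- rnorm(30)
  m <- cbind(sapply(1:3, function(i) base1 + rnorm(30, 0, 0.2)),
             sapply(1:3, function(i) base2 + rnorm(30, 0, 0.2)),
             sapply(1:3, function(i) base3 + rnorm(30, 0, 0.2)))
  colnames(m) <- paste0("s", 1:9)
  d <- cluster_diagnostics(m, k_range = 2:5, B = 10, seed = 4)
  expect_equal(d$k, 2:5)
  expect_true(all(is.finite(d$within_disp)))
  expect_true(all(is.finite(d$silhouette)))
  expect_true(all(is.finite(d$gap)))
  # the planted k = 3 maximizes the mean silhouette width
  expect_equal(d$k[which.max(d$silhouette)], 3)
})

test_that("group-specific assignment follows the mean-minus-SD criterion", {
  m <- rbind(
    clean  = c(8, 8, 8, 0, 0, 0),
    sharedAB = c(8, 8, 8, 7.5, 8, 8.5),
    flat   = rep(3, 6)
  )
  colnames(m) <- paste0("s", 1:6)
  labels <- setNames(rep(1:2, each = 3), colnames(m))
  g <- group_specific_ses(m, labels)
  expect_equal(g$element_id, "clean")  # 8 - 0 > 0; A specific
  expect_true(g$specific)
  expect_equal(g$groups, "1")

  # three groups: A and B overlap each other but both clear C
  m3 <- rbind(x = c(8, 8, 8, 7.5, 8, 8.5, 0, 0, 0))
  colnames(m3) <- paste0("s", 1:9)
  lab3 <- setNames(rep(1:3, each = 3), colnames(m3))
  g3 <- group_specific_ses(m3, lab3)
  expect_equal(g3$groups, "1,2")
  expect_false(g3$specific)
  expect_equal(g3$n_groups, 2L)

  # all groups equal -> nothing is group-specific
  m4 <- rbind(x = rep(5, 9))
  colnames(m4) <- paste0("s", 1:9)
  expect_equal(nrow(group_specific_ses(m4, lab3)), 0)

  # singleton cluster skipped with a warning
  lab_s <- setNames(c(1, 1, 1, 2, 2, 2, 3), paste0("s", 1:7))
  m5 <- rbind(x = c(8, 8, 8, 0, 0, 0, 4))
  colnames(m5) <- paste0("s", 1:7)
  expect_warning(g5 <- group_specific_ses(m5, lab_s), "single member")
  expect_equal(g5$groups, "1")
})

test_that("group comparisons match closed forms and pair counting", {
  r <- compare_groups(c(1, 2, 3), c(101, 102, 103), test = "t")
  expect_equal(r$statistic, -100 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(r$statistic, 2), -122.47)
  expect_lt(r$p_value, 0.01)
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3) + 1e-12,
                              test = "t")$statistic, 0, tolerance = 1e-3)
  expect_error(compare_groups(c(1, 1), c(1, 1), test = "t"),
               "zero variance")

  withr::local_seed(55)
  for (rep in 1:5) {
    x <- sample(1:50, sample(3:8, 1))
    y <- sample(1:50, sample(3:8, 1))
    got <- compare_groups(x, y, test = "mannwhitney")
    expect_equal(got$statistic, brute_u_statistic(x, y))
  }
  ident <- compare_groups(c(5, 6, 7, 8), c(7, 5, 8, 6),
                          test = "mannwhitney")
  expect_equal(ident$p_value, 1)
})
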