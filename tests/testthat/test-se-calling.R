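test_that("stitching merges at the inclusive 12.5 kb boundary", {
  p1 <- data.frame(chrom = "chr1", start = c(0, 12600), end = c(100, 12700))
  r1 <- stitch_peaks(p1, 12500)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$start, 0)
  expect_equal(r1$end, 12700)
  expect_equal(r1$n_constituents, 2L)

  p2 <- data.frame(chrom = "chr1", start = c(0, 12602), end = c(100, 12700))
  r2 <- stitch_peaks(p2, 12500)
  expect_equal(nrow(r2), 2)
  expect_error(stitch_peaks(p1, -5), "non-negative")
})

test_that("stitching equals the transitive closure of the gap relation", {
  withr::local_seed(31)
  for (rep in 1:4) {
    peaks <- random_intervals(100, max_pos = 3e5, max_len = 4000)
    d <- 10000
    got <- stitch_peaks(peaks, d)
    want <- closure_spans(peaks, closure_components(
      interval_adjacency(peaks, "gap", d)))
    expect_equal(got[, c("chrom", "start", "end")], want)
  }
})

test_that("stitching is order-invariant, idempotent, and conserves bases", {
  withr::local_seed(8)
  peaks <- random_intervals(60, max_pos = 2e5)
  a <- stitch_peaks(peaks, 12500)
  b <- stitch_peaks(peaks[sample(nrow(peaks)), ], 12500)
  expect_equal(a[, c("chrom", "start", "end")],
               b[, c("chrom", "start", "end")])
  again <- stitch_peaks(a[, c("chrom", "start", "end")], 12500)
  expect_equal(again[, c("chrom", "start", "end")],
               a[, c("chrom", "start", "end")])
  # no bases lost or invented: union of constituents == union of inputs
  cons <- do.call(rbind, a$constituents)
  gr_in <- GenomicRanges::reduce(GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end)))
  gr_out <- GenomicRanges::reduce(GenomicRanges::GRanges(
    cons$chrom, IRanges::IRanges(cons$start + 1, cons$end)))
  expect_equal(sum(GenomicRanges::width(gr_in)),
               sum(GenomicRanges::width(gr_out)))
})

test_that("TSS exclusion removes only fully contained peaks, default off", {
  peaks <- data.frame(chrom = "chr1",
                      start = c(1000, 5000, 50000),
                      end = c(1400, 5400, 50400))
  tss <- data.frame(chrom = "chr1", start = 1200, end = 1201)
  with_excl <- stitch_peaks(peaks, 100, tss = tss, tss_exclusion = 2000)
  expect_equal(nrow(with_excl), 2)  # peak at 1000 dropped (inside window)
  no_excl <- stitch_peaks(peaks, 100, tss = tss, tss_exclusion = 0)
  expect_equal(nrow(no_excl), 3)
})

test_that("region scoring subtracts depth-adjusted input with a floor", {
  reg <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 200))
  s <- score_regions(reg, chip_counts = c(100, 10),
                     input_counts = c(40, 50),
                     chip_lib = 1e6, input_lib = 1e6)
  expect_equal(s$signal, c(60, 0))
  expect_error(score_regions(reg, 1, c(1, 2), 1e6, 1e6), "mismatch")

  # depth-invariance: doubling chip counts and chip library is a no-op
  withr::local_seed(12)
  chip <- runif(10, 0, 500); inp <- runif(10, 0, 200)
  reg10 <- random_intervals(10)
  a <- score_regions(reg10, chip, inp, 2e6, 1e6)
  b <- score_regions(reg10, 2 * chip, inp, 4e6, 1e6)
  expect_equal(a$signal, b$signal)
})

test_that("inflection cutoff isolates the dominant region", {
  reg <- data.frame(chrom = "chr1", start = (0:4) * 1000,
                    end = (0:4) * 1000 + 500,
                    signal = c(1, 1, 1, 1, 100))
  tab <- classify_superenhancers(reg)
  expect_equal(attr(tab, "cutoff_rank"), 4L)
  expect_equal(sum(tab$is_SE), 1)
  expect_equal(tab$signal[tab$is_SE], 100)
  # exhaustive argmax oracle over every candidate rank
  n <- nrow(tab)
  x <- (tab$rank - 1) / (n - 1)
  y <- (tab$signal - min(tab$signal)) / diff(range(tab$signal))
  expect_equal(attr(tab, "cutoff_rank"), which.max(x - y))
})

test_that("equal signals give a degenerate curve with zero SEs", {
  reg <- data.frame(chrom = "chr1", start = (0:3) * 1000,
                    end = (0:3) * 1000 + 500, signal = rep(7, 4))
  expect_warning(tab <- classify_superenhancers(reg), "degenerate")
  expect_false(any(tab$is_SE))
})

test_that("convex curve cutoff matches the slope-1 tangent closed form", {
  n <- 100
  x <- (0:(n - 1)) / (n - 1)
  reg <- data.frame(chrom = "chr1", start = (0:(n - 1)) * 1000,
                    end = (0:(n - 1)) * 1000 + 500, signal = x^3)
  tab <- classify_superenhancers(reg)
  # argmax of x - x^3 is x = 1/sqrt(3); nearest grid rank
  expect_equal(attr(tab, "cutoff_rank"),
               which.min(abs(x - 1 / sqrt(3))))
})

test_that("SE set is invariant under positive rescaling of signals", {
  withr::local_seed(90)
  reg <- random_intervals(50)
  reg$signal <- rexp(50, 1 / 50)
  a <- classify_superenhancers(reg)
  reg2 <- reg; reg2$signal <- reg$signal * 17.3
  b <- classify_superenhancers(reg2)
  expect_equal(a$is_SE, b$is_SE)
  expect_equal(attr(a, "cutoff_rank"), attr(b, "cutoff_rank"))
})
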