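# Binning, counting, normalization, smoothing, variance stabilization,
# CBS segmentation and segment merging.

test_that("bins tile contigs and split at breakend positions", {
  bins <- build_bins(c(chr1 = 100000L), bin_size = 10000)
  expect_equal(nrow(bins), 10L)
  expect_equal(bins$end - bins$start, rep(10000L, 10))

  split <- build_bins(c(chr1 = 100000L), bin_size = 10000,
                      breakpoints = tibble::tibble(contig = "chr1",
                                                   pos = 25000L))
  expect_equal(nrow(split), 11L)
  expect_true(any(split$start == 20000 & split$end == 25000))
  expect_true(any(split$start == 25000 & split$end == 30000))

  small <- build_bins(c(tiny = 7000L), bin_size = 10000)
  expect_equal(nrow(small), 1L)
  expect_equal(small$end, 7000L)
})

test_that("bins are excluded for blacklist overlap and N content", {
  bins <- build_bins(c(chr1 = 30000L), bin_size = 10000)
  blacklist <- tibble::tibble(contig = "chr1", start = 0L, end = 600L)
  out <- filter_bins(bins, blacklist = blacklist,
                     n_fraction = c(0, 0.8, 0.5))
  expect_equal(out$excluded_reason, c("blacklist", "n_fraction", NA))
  # 5% overlap is not "more than 5%"
  edge <- filter_bins(bins, blacklist = tibble::tibble(
    contig = "chr1", start = 0L, end = 500L))
  expect_false(edge$excluded[1])
})

test_that("read counting is primary-only, MAPQ-gated, start-assigned", {
  bins <- build_bins(c(chr1 = 20000L), bin_size = 10000)
  recs <- dplyr::bind_rows(
    record_row("a", start = 500L, cigar = "1000M"),
    record_row("b", start = 600L, cigar = "1000M", is_supplementary = TRUE),
    record_row("c", start = 700L, cigar = "1000M", mapq = 4L),
    record_row("d", start = 10000L, cigar = "1000M"),  # boundary start
    record_row("e", start = 800L, cigar = "1000M", sample = "normal")
  )
  out <- count_reads(recs, bins)
  expect_equal(out$tumor_count, c(1L, 1L))
  expect_equal(out$normal_count, c(1L, 0L))
})

test_that("log2 ratios use depth-scaled paired or median self normalization", {
  bins <- build_bins(c(chr1 = 40000L), bin_size = 10000)
  bins$tumor_count <- c(100L, 200L, 0L, 100L)
  bins$normal_count <- c(50L, 50L, 50L, 0L)
  out <- normalize_log2(bins, mode = "paired")
  # zero-count bins are dropped, not infinite
  expect_equal(nrow(out), 2L)
  scale <- sum(c(50, 50)) / sum(c(100, 200))
  expect_equal(out$log2r, log2(c(100 / 50, 200 / 50) * scale))

  solo <- bins
  solo$normal_count <- NULL
  solo$tumor_count <- c(100L, 200L, 100L, 400L)
  out2 <- normalize_log2(solo, mode = "tumor_only")
  med <- median(c(100, 200, 100, 400))
  expect_equal(out2$log2r, log2(c(100, 200, 100, 400) / med))
  expect_equal(out2$log2r[1], log2(100 / med))
})

test_that("single-point outliers are smoothed, runs and flats untouched", {
  flat <- rep(0.3, 21)
  expect_equal(smooth_outliers(flat), flat)

  spike <- flat
  spike[10] <- 10.3
  sm <- smooth_outliers(spike)
  expect_equal(sm[10], 0.3)
  expect_equal(sm[-10], spike[-10])

  run2 <- flat
  run2[10:11] <- 10.3
  expect_equal(smooth_outliers(run2), run2)
})

test_that("the Anscombe transform works on the ratio scale", {
  expect_equal(variance_stabilize(0), 2 * sqrt(1 + 3 / 8))
  expect_equal(variance_stabilize(-Inf), 2 * sqrt(3 / 8))
  r <- seq(-2, 2, by = 0.1)
  expect_true(all(diff(variance_stabilize(r)) > 0))
})

test_that("CBS split decisions match the exhaustive arc-scan oracle", {
  set.seed(31)
  for (trial in 1:30) {
    n <- sample(8:30, 1)
    x <- rnorm(n)
    if (trial %% 3 == 0) x[seq_len(floor(n / 2))] <- x[seq_len(floor(n / 2))] + 3
    got <- svelt:::cbs_max_stat_cpp(x)
    want <- max_arc_stat_oracle(x)
    expect_equal(got$stat, want$stat, tolerance = 1e-12)
    expect_equal(c(got$i, got$j), c(want$i, want$j))
  }
})

test_that("CBS finds a strong step and nothing in constant series", {
  expect_length(cbs_segment(rep(1, 50)), 0L)
  set.seed(8)
  x <- c(rnorm(100, 0, 1), rnorm(100, 5, 1))
  cps <- cbs_segment(x, n_perm = 500, seed = 2)
  expect_length(cps, 1L)
  expect_lte(abs(cps - 100), 2L)
  # deterministic given (series, seed)
  expect_identical(cps, cbs_segment(x, n_perm = 500, seed = 2))
})

test_that("segment merging follows the 20th-percentile rule", {
  seg <- function(means) {
    tibble::tibble(contig = "chr1",
                   start = seq(0, by = 100L, length.out = length(means)),
                   end = seq(100, by = 100L, length.out = length(means)),
                   n_bins = 10L, mean_log2r = means)
  }
  # single pair: threshold equals the only delta; strict < never merges
  expect_equal(nrow(merge_segments(seg(c(0, 3)))), 2L)
  # equal means always merge
  expect_equal(nrow(merge_segments(seg(c(0.5, 0.5, 0.5)))), 1L)

  # brute-force oracle for {0, 0.02, 1.0}: pair deltas {0.02, 0.98, 1.0},
  # 20th percentile (linear interpolation) = 0.404, so the first pair merges;
  # then the single remaining delta equals its own threshold and stops
  out <- merge_segments(seg(c(0, 0.02, 1.0)))
  expect_equal(nrow(out), 2L)
  expect_equal(out$mean_log2r[1], 0.01)
  expect_equal(out$n_bins, c(20L, 10L))
})

test_that("segmentation tiles the retained bins and is seeded", {
  cfg <- cn_genome_config(0.6, 2.0, seed = 3)
  cn <- simulate_cn_data(cfg)
  norm <- normalize_log2(cn$bins, mode = "paired")
  seg <- segment_copy_number(norm, n_perm = 300, seed = 5)
  per_contig <- split(seg$segments, seg$segments$contig)
  for (s in per_contig) {
    expect_true(all(s$start[-1] == head(s$end, -1)))
  }
  expect_equal(sum(seg$segments$n_bins), nrow(norm))
  seg2 <- segment_copy_number(norm, n_perm = 300, seed = 5)
  expect_identical(seg$segments, seg2$segments)
})
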