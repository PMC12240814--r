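# BAF bimodality, LOH block selection, the purity equation, absolute copy
# number and the ploidy grid search.

test_that("bimodality coefficient matches direct moment computation", {
  x <- c(rep(0, 5), rep(1, 5))
  n <- length(x)
  # independent evaluation from raw moments
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  g1 <- (mean((x - m)^3) / s^3) * sqrt(n * (n - 1)) / (n - 2)
  g2 <- ((n + 1) * (mean((x - m)^4) / s^4 - 3) + 6) *
    (n - 1) / ((n - 2) * (n - 3))
  want <- (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  expect_equal(bimodality_coefficient(x), want, tolerance = 1e-12)
  expect_gt(bimodality_coefficient(x), 5 / 9)

  expect_true(is.na(bimodality_coefficient(rep(0.5, 10))))
  expect_true(is.na(bimodality_coefficient(c(1, 2, 3))))

  set.seed(2)
  unimodal <- rnorm(200, 0.5, 0.05)
  bimodal <- c(rnorm(100, 0.2, 0.05), rnorm(100, 0.8, 0.05))
  expect_gt(bimodality_coefficient(bimodal),
            bimodality_coefficient(unimodal))
})

test_that("LOH block selection enforces SNP count, depth cap and top-k", {
  set.seed(4)
  mk_block <- function(i, n, baf, depth) {
    tibble::tibble(contig = "chr1",
                   position = as.integer((i - 1) * 1e5 + seq(1000, 99000,
                                                             length.out = n)),
                   depth = depth,
                   baf = baf)
  }
  blocks <- list()
  for (i in 1:12) {
    blocks[[i]] <- mk_block(i, 50, c(rnorm(25, 0.2, 0.03),
                                     rnorm(25, 0.8, 0.03)), 30L)
  }
  blocks[[13]] <- mk_block(13, 8, rep(c(0.2, 0.8), 4), 30L)      # too few
  blocks[[14]] <- mk_block(14, 50, c(rnorm(25, 0.2, 0.03),
                                     rnorm(25, 0.8, 0.03)), 90L)  # amplified
  baf <- purrr::list_rbind(blocks)
  sel <- select_loh_blocks(baf, c(chr1 = 1.5e6), block_size = 1e5)
  expect_equal(nrow(sel), 10L)
  expect_false(any(sel$block == "chr1/12"))
  expect_false(any(sel$block == "chr1/13"))
  expect_true(all(diff(sel$bimodality) <= 0))
})

test_that("the purity equation is exact on noiseless LOH modes", {
  blocks <- tibble::tibble(baf_a = rep(1, 10), baf_b = rep(0, 10))
  expect_equal(estimate_purity(blocks), 1)
  blocks2 <- tibble::tibble(baf_a = rep(0.75, 10), baf_b = rep(0.25, 10))
  expect_equal(estimate_purity(blocks2), 0.5)
  # invariant: rho = 1 - 2 * BAF_B for copy-neutral LOH at any purity,
  # and block order does not matter
  for (rho in c(0.1, 0.3, 0.62, 0.9, 1)) {
    b <- tibble::tibble(baf_a = 1 - (1 - rho) / 2, baf_b = (1 - rho) / 2)
    expect_equal(estimate_purity(b), rho, tolerance = 1e-12)
  }
  shuffled <- blocks2[sample(nrow(blocks2)), ]
  expect_equal(estimate_purity(shuffled), estimate_purity(blocks2))
  expect_error(estimate_purity(blocks2[0, ]), "no eligible")
})

test_that("purity is recovered from simulated copy-neutral LOH", {
  set.seed(6)
  rho <- 0.7
  n <- 2000
  flip <- runif(n) < 0.5
  p <- ifelse(flip, (1 - rho) / 2, 1 - (1 - rho) / 2)
  depth <- 30L
  alt <- rbinom(n, depth, p)
  baf <- tibble::tibble(
    contig = "chr1",
    position = as.integer(seq(500, by = 500, length.out = n)),
    depth = depth, baf = alt / depth
  )
  blocks <- select_loh_blocks(baf, c(chr1 = 1.1e6), block_size = 1e5)
  expect_equal(estimate_purity(blocks), rho, tolerance = 0.02)
})

test_that("absolute copy number follows the closed form", {
  expect_equal(absolute_copy_number(0, 0.37, 2.7), 2.7)
  expect_equal(absolute_copy_number(0, 1, 2), 2)
  expect_equal(absolute_copy_number(1, 1, 2), 4, tolerance = 1e-12)
  # rho 0.5, psi 2, ratio 1.5 -> 2 + 0.5 * (2 + 4 - 2) = 4
  expect_equal(absolute_copy_number(log2(1.5), 0.5, 2), 4, tolerance = 1e-12)
})

test_that("the grid search recovers noiseless truth and applies its gates", {
  rho <- 0.60; psi <- 2.00
  cn_states <- c(1, 2, 2, 3, 2)
  sizes <- c(2e5, 6e5, 4e5, 2e5, 6e5)
  r <- (rho * cn_states + 2 * (1 - rho)) /
    (rho * sum(sizes * cn_states) / sum(sizes) + 2 * (1 - rho))
  segments <- tibble::tibble(mean_log2r = log2(r), size = sizes)
  fit <- grid_search_ploidy(segments, purity_hat = 0.60)
  expect_equal(fit$purity, 0.60)
  expect_equal(fit$ploidy, 2.00)
  expect_lt(fit$fitness, 1e-10)
  expect_true(all(fit$flags))

  g <- tidy(fit)
  expect_true(all(c("purity", "ploidy", "fitness", "accepted") %in% names(g)))

  # a grid point fitting 15% of the genome to zero is rejected
  zero_heavy <- dplyr::filter(fit$grid, prop_zero > 0.1)
  expect_true(all(!zero_heavy$accepted))

  # two most frequent states two copies apart fail the step gate
  far <- tibble::tibble(
    mean_log2r = log2((1 * c(2, 4) + 0) / 3), size = c(1e6, 1e6))
  expect_error(grid_search_ploidy(far, purity_hat = 1.0,
                                  purity_halfwidth = 0.0001,
                                  ploidy_min = 2.5, ploidy_max = 4),
               "plausibility")
})

test_that("allele-specific copy number inverts the BAF model", {
  seg <- function(cn) {
    tibble::tibble(contig = "chr1", start = 0L, end = 10000L,
                   absolute_cn = cn)
  }
  mk_baf <- function(b, n = 10) {
    tibble::tibble(contig = "chr1",
                   position = as.integer(seq(100, 9000, length.out = n)),
                   baf = b, depth = 30L)
  }
  out <- allele_specific_cn(seg(2), mk_baf(0.5), purity = 1)
  expect_equal(out$minor_cn, 1L)
  out2 <- allele_specific_cn(seg(3), mk_baf(1 / 3), purity = 1)
  expect_equal(out2$minor_cn, 1L)
  out3 <- allele_specific_cn(seg(2), mk_baf(0.25), purity = 0.5)
  expect_equal(out3$minor_cn, 0L)  # LOH
  # too few SNPs leaves the segment unassigned
  sparse <- allele_specific_cn(seg(2), mk_baf(0.5, n = 3), purity = 1)
  expect_true(is.na(sparse$minor_cn))
  # minor never exceeds half the total
  for (b in seq(0, 0.5, by = 0.1)) {
    o <- allele_specific_cn(seg(3), mk_baf(b), purity = 0.8)
    expect_lte(o$minor_cn, 1L)
  }
})
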