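# Synthetic-data generators: determinism, evidence round trips, model
# inversion.

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 12, contigs = c(chrA = 2e5),
                    svs = tibble::tibble(
                      id = "d1", type = "DEL", contig = "chrA", pos = 50000L,
                      contig2 = NA_character_, pos2 = NA_integer_,
                      length = 400L, af = 0.5, haplotype = 1L,
                      germline = FALSE))
  a <- simulate_sv_alignments(cfg)
  b <- simulate_sv_alignments(cfg)
  expect_identical(a$tumor, b$tumor)
  expect_identical(a$normal, b$normal)

  cfg$cn_profile <- tibble::tibble(contig = "chrA", start = 0, end = 2e5,
                                   total_cn = 2L, minor_cn = 1L)
  expect_identical(simulate_cn_data(cfg)$bins, simulate_cn_data(cfg)$bins)
})

test_that("discovery and clustering recover planted SVs at planted support", {
  wx <- shared_worked_example()
  d <- discover_breakpoints(wx$tumor, wx$contig_lengths)
  dn <- discover_breakpoints(wx$normal, wx$contig_lengths)
  clusters <- cluster_breakpoints(dplyr::bind_rows(d$breakpoints,
                                                   dn$breakpoints))
  m <- match_breakends(clusters_to_breakends(clusters), wx$truth_breakends)
  expect_equal(m$recall, 1)
  # cluster support equals the planted supporting-read count
  for (i in seq_len(nrow(wx$truth))) {
    sv <- wx$truth[i, ]
    hit <- clusters$contig_a == sv$contig & abs(clusters$pos_a - sv$pos) <= 20
    hit <- hit | (!is.na(clusters$contig_b) & clusters$contig_b == sv$contig &
                    abs(clusters$pos_b - sv$pos) <= 20)
    expect_equal(max(clusters$tumor_support[hit]), sv$planted_support,
                 info = sv$id)
  }
  # germline SVs carry normal support, somatic ones do not
  germ <- dplyr::filter(clusters, normal_support > 0)
  expect_equal(nrow(germ), 2L)
})

test_that("the copy-number generator inverts the package's own model", {
  # pure tumor, copy-neutral LOH: BAF concentrates at 0 and 1
  cfg1 <- sim_config(seed = 3, contigs = c(c1 = 4e5), purity = 1,
                     cn_profile = tibble::tibble(
                       contig = "c1", start = 0, end = 4e5,
                       total_cn = 2L, minor_cn = 0L))
  cn1 <- simulate_cn_data(cfg1)
  expect_true(all(cn1$baf$baf %in% c(0, 1)))

  # rho = 0.5, (2,0): lower-mode median near 0.25
  cfg2 <- sim_config(seed = 3, contigs = c(c1 = 4e5), purity = 0.5,
                     cn_profile = cfg1$cn_profile, snp_depth = 60)
  cn2 <- simulate_cn_data(cfg2)
  lower <- cn2$baf$baf[cn2$baf$baf <= 0.5]
  expect_equal(median(lower), 0.25, tolerance = 0.04)

  # diploid neutral genome: log2 ratios near zero everywhere
  cfg3 <- sim_config(seed = 3, contigs = c(c1 = 4e5), purity = 0.6,
                     cn_profile = tibble::tibble(
                       contig = "c1", start = 0, end = 4e5,
                       total_cn = 2L, minor_cn = 1L))
  norm <- normalize_log2(simulate_cn_data(cfg3)$bins, mode = "paired")
  expect_lt(max(abs(norm$log2r)), 0.5)
  expect_lt(abs(mean(norm$log2r)), 0.1)
})

test_that("fold-back injection hits the configured rate", {
  cfg <- sim_config(seed = 21, contigs = c(chrA = 5e5), depth = 30,
                    foldback_rate = 0.01)
  sim <- simulate_sv_alignments(cfg)
  n_bg <- sum(grepl("_bg", unique(sim$tumor$read_name)))
  n_fb <- length(unique(grep("_fb", sim$tumor$read_name, value = TRUE)))
  expect_lte(abs(n_fb - 0.01 * n_bg), 3 * sqrt(0.01 * 0.99 * n_bg))
})
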