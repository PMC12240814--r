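# Replicate splitting, breakend matching, phasing consistency, fold-back
# rate estimation.

test_that("replicate splitting is read-level, fair and seeded", {
  set.seed(3)
  recs <- purrr::map(1:1000, function(i) {
    r <- record_row(paste0("r", i), start = 100L * i)
    if (i %% 5 == 0) {
      r <- dplyr::bind_rows(
        r, record_row(paste0("r", i), start = 100L * i + 5000L,
                      is_supplementary = TRUE))
    }
    r
  }) |> purrr::list_rbind()
  reps <- split_replicates(recs, seed = 7)
  n1 <- dplyr::n_distinct(reps$rep1$read_name)
  n2 <- dplyr::n_distinct(reps$rep2$read_name)
  expect_equal(n1 + n2, 1000L)
  expect_lte(abs(n1 - 500), 3 * sqrt(250))
  # a read's primary and supplementary records stay together
  expect_length(intersect(reps$rep1$read_name, reps$rep2$read_name), 0L)
  reps2 <- split_replicates(recs, seed = 7)
  expect_identical(reps$rep1, reps2$rep1)
})

test_that("breakend matching is buffered, one-to-one and counts correctly", {
  calls <- tibble::tibble(contig = "chr1", pos = c(1000L, 5000L),
                          type = "BND")
  truth <- tibble::tibble(contig = "chr1", pos = c(1050L, 5101L),
                          type = "BND")
  m <- match_breakends(calls, truth, buffer = 100)
  expect_equal(m$tp, 1L)          # 1050 matches, 5101 is 101 bp away
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)

  # 60 of 68 truth breakends matched with no extra calls
  truth68 <- tibble::tibble(contig = "chr1",
                            pos = as.integer(seq(1000, by = 10000,
                                                 length.out = 68)),
                            type = "BND")
  calls60 <- truth68[1:60, ]
  calls60$pos <- calls60$pos + 40L
  m2 <- match_breakends(calls60, truth68)
  expect_equal(m2$recall, 60 / 68)
  expect_equal(m2$precision, 1)
  expect_equal(m2$f_measure, 2 * (60 / 68) / (1 + 60 / 68))

  # swapping calls and truth swaps precision and recall, TP unchanged
  m3 <- match_breakends(truth68, calls60)
  expect_equal(m3$tp, m2$tp)
  expect_equal(m3$precision, m2$recall)
  expect_equal(m3$recall, m2$precision)

  # insertions only match insertions
  ins_call <- tibble::tibble(contig = "chr1", pos = 1000L, type = "INS")
  be_truth <- tibble::tibble(contig = "chr1", pos = 1000L, type = "BND")
  expect_equal(match_breakends(ins_call, be_truth)$tp, 0L)
})

test_that("phasing verdicts use the exact binomial tail with BH correction", {
  sv <- tibble::tibble(sv_id = c("a", "b", "c"),
                       allele1_count = c(10L, 10L, 3L),
                       allele2_count = c(0L, 10L, 1L))
  out <- phasing_consistency(sv)
  expect_equal(out$verdict, c("concordant", "discordant", "inconclusive"))
  expect_equal(out$p_value[3], 1 - 0.95^4, tolerance = 1e-12)

  # exact tails on enumerated cases, independent summation oracle
  for (n in c(4L, 9L, 17L, 30L)) {
    for (k in unique(c(ceiling(n / 2), n - 1L))) {
      sv1 <- tibble::tibble(sv_id = "x", allele1_count = k,
                            allele2_count = n - k)
      got <- phasing_consistency(sv1)$p_value
      kk <- max(k, n - k)
      want <- sum(choose(n, 0:kk) * 0.95^(0:kk) * 0.05^(n - (0:kk)))
      expect_equal(got, want, tolerance = 1e-10)
    }
  }

  # verdicts are invariant to allele labeling
  swapped <- phasing_consistency(
    dplyr::mutate(sv, tmp = allele1_count, allele1_count = allele2_count,
                  allele2_count = tmp))
  expect_equal(swapped$verdict, out$verdict)
})

test_that("fold-back artifact reads satisfy all three criteria", {
  fb <- dplyr::bind_rows(
    record_row("fb1", start = 1000L, cigar = "800M710S", mapq = 60L,
               sa_tag = "chr1,1041,-,710M800S,60,0;"),
    record_row("fb1", start = 1040L, cigar = "710M800S", strand = "-",
               mapq = 60L, is_supplementary = TRUE)
  )
  far <- dplyr::bind_rows(
    record_row("far1", start = 1000L, cigar = "800M710S", mapq = 60L),
    record_row("far1", start = 1200L, cigar = "710M800S", strand = "-",
               mapq = 60L, is_supplementary = TRUE)
  )
  two_supp <- dplyr::bind_rows(
    record_row("ts", start = 1000L, cigar = "500M1000S"),
    record_row("ts", start = 1040L, cigar = "500S500M500S", strand = "-",
               is_supplementary = TRUE),
    record_row("ts", start = 1100L, cigar = "1000S500M", strand = "-",
               is_supplementary = TRUE)
  )
  plain <- record_row("p1", start = 5000L, cigar = "1000M")
  lowq <- record_row("lq", start = 6000L, cigar = "1000M", mapq = 10L)

  out <- foldback_rate(dplyr::bind_rows(fb, far, two_supp, plain, lowq))
  expect_equal(out$artifact_reads, 1L)
  # far1: read start at 1000, read end at supplementary start 1200 -> 200 bp
  expect_equal(out$eligible_reads, 4L)  # all but the mapq-10 read
  expect_equal(out$rate, 0.25)
})
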