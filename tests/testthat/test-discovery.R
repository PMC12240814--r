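# Split/CIGAR/soft-clip breakpoint discovery and fold-back suppression.

test_that("segments_from_read parses SA entries in query order", {
  rec <- record_row("r1", start = 1000L, cigar = "100M100S",
                    sa_tag = "chr1,2001,+,100S100M,60,0;")
  sr <- segments_from_read(rec)
  expect_equal(nrow(sr$segments), 2L)
  expect_equal(sr$segments$query_start, c(0L, 100L))
  expect_equal(sr$segments$is_supplementary, c(FALSE, TRUE))
  expect_equal(sr$segments$start, c(1000L, 2000L))

  no_sa <- segments_from_read(record_row())
  expect_equal(nrow(no_sa$segments), 1L)
  expect_equal(nrow(no_sa$sbnd_candidates), 0L)

  expect_warning(
    bad <- segments_from_read(record_row(sa_tag = "chr1,oops;")),
    "malformed SA"
  )
  expect_equal(nrow(bad$segments), 1L)
})

test_that("low-MAPQ supplementary pieces become single-breakend candidates", {
  rec <- record_row("r1", start = 1000L, cigar = "100M100S",
                    seq = paste(rep("A", 200), collapse = ""),
                    sa_tag = "chr1,2001,+,100S100M,3,0;")
  sr <- segments_from_read(rec, sbnd_mode = TRUE, supp_mapq_floor = 5)
  expect_equal(nrow(sr$segments), 1L)
  expect_equal(nrow(sr$sbnd_candidates), 1L)
  expect_equal(sr$sbnd_candidates$pos_a, 1100L)
  expect_equal(sr$sbnd_candidates$strand_a, "+")
})

test_that("fold-back detection requires opposite strands and nearby ends", {
  seg <- function(start, end, strand) {
    tibble::tibble(contig = "chr1", start = start, end = end,
                   strand = strand)
  }
  expect_true(detect_foldback_pair(seg(1000L, 2000L, "+"),
                                   seg(900L, 1850L, "-")))
  expect_false(detect_foldback_pair(seg(1000L, 2000L, "+"),
                                    seg(900L, 2500L, "-")))
  expect_false(detect_foldback_pair(seg(1000L, 2000L, "+"),
                                    seg(900L, 2000L, "+")))
})

test_that("split junction orientations match the retained-side rule", {
  # oracle: "+" = sequence retained left of the breakend. The query-first
  # segment contributes its reference end on "+" (retained left) or its
  # reference start on "-"; the query-second segment the mirror image.
  mk_segs <- function(s1, s2) {
    dplyr::bind_rows(
      tibble::tibble(read_name = "r", contig = s1$ctg, start = s1$start,
                     end = s1$end, strand = s1$strand, mapq = 60,
                     query_start = 0L, query_end = 100L,
                     sample = "tumor", haplotype = NA_integer_,
                     phase_set = NA_integer_),
      tibble::tibble(read_name = "r", contig = s2$ctg, start = s2$start,
                     end = s2$end, strand = s2$strand, mapq = 60,
                     query_start = 100L, query_end = 200L,
                     sample = "tumor", haplotype = NA_integer_,
                     phase_set = NA_integer_)
    )
  }
  cases <- list(
    # deletion-like: + then + downstream
    list(s1 = list(ctg = "chr1", start = 9900L, end = 10000L, strand = "+"),
         s2 = list(ctg = "chr1", start = 20000L, end = 20100L, strand = "+"),
         notation = "+-", pos = c(10000L, 20000L), len = 10000),
    # duplication-like: + then + upstream
    list(s1 = list(ctg = "chr1", start = 19900L, end = 20000L, strand = "+"),
         s2 = list(ctg = "chr1", start = 10000L, end = 10100L, strand = "+"),
         notation = "-+", pos = c(10000L, 20000L), len = 10000),
    # head-to-head inversion: + then - (ends far apart, not fold-back)
    list(s1 = list(ctg = "chr1", start = 9900L, end = 10000L, strand = "+"),
         s2 = list(ctg = "chr1", start = 19900L, end = 20000L, strand = "-"),
         notation = "++", pos = c(10000L, 20000L), len = 10000),
    # tail-to-tail inversion: - then +
    list(s1 = list(ctg = "chr1", start = 10000L, end = 10100L, strand = "-"),
         s2 = list(ctg = "chr1", start = 20000L, end = 20100L, strand = "+"),
         notation = "--", pos = c(10000L, 20000L), len = 10000),
    # interchromosomal: reference span is zero
    list(s1 = list(ctg = "chr1", start = 9900L, end = 10000L, strand = "+"),
         s2 = list(ctg = "chr5", start = 20000L, end = 20100L, strand = "+"),
         notation = "+-", pos = c(10000L, 20000L), len = 0)
  )
  for (cs in cases) {
    bp <- breakpoints_from_split(mk_segs(cs$s1, cs$s2))
    expect_equal(nrow(bp), 1L)
    expect_equal(bp$notation, cs$notation)
    expect_equal(c(bp$pos_a, bp$pos_b), cs$pos)
    expect_equal(bp$sv_length, cs$len)
  }
})

test_that("fold-back junctions are suppressed, distant inversions kept", {
  segs <- dplyr::bind_rows(
    tibble::tibble(read_name = "r", contig = "chr1", start = 1000L,
                   end = 2000L, strand = "+", mapq = 60,
                   query_start = 0L, query_end = 1000L, sample = "tumor",
                   haplotype = NA_integer_, phase_set = NA_integer_),
    tibble::tibble(read_name = "r", contig = "chr1", start = 1040L,
                   end = 1850L, strand = "-", mapq = 60,
                   query_start = 1000L, query_end = 1810L, sample = "tumor",
                   haplotype = NA_integer_, phase_set = NA_integer_)
  )
  expect_equal(nrow(breakpoints_from_split(segs)), 0L)
  segs_far <- segs
  segs_far$start[2] <- 5000L
  segs_far$end[2] <- 5810L
  expect_equal(nrow(breakpoints_from_split(segs_far)), 1L)
})

test_that("CIGAR deletions and insertions respect the effective minimum", {
  seg <- function(cigar, sample = "tumor", seq = NA_character_) {
    tibble::tibble(read_name = "r", contig = "chr1", start = 10000L,
                   end = 10000L + svelt:::cigar_ref_len(cigar),
                   strand = "+", mapq = 60, cigar = cigar,
                   query_start = 0L,
                   query_end = svelt:::cigar_aligned_query_len(cigar),
                   sample = sample, haplotype = NA_integer_,
                   phase_set = NA_integer_, seq = seq)
  }
  del <- breakpoints_from_cigar(seg("100M50D100M"))
  expect_equal(nrow(del), 1L)
  expect_equal(del$sv_length, 50)
  expect_equal(del$notation, "+-")
  expect_equal(c(del$pos_a, del$pos_b), c(10100L, 10150L))

  # exactly the minimum is not "greater than"
  expect_equal(nrow(breakpoints_from_cigar(seg("100M30D100M"))), 0L)

  merged <- breakpoints_from_cigar(seg("100M40D20M40D100M"))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$sv_length, 80)  # deleted-base sum
  expect_equal(merged$span, 100)      # merged reference span
  expect_equal(c(merged$pos_a, merged$pos_b), c(10100L, 10200L))

  # normal effective minimum 30 * (1 - 0.20) = 24, so a 25 bp event passes
  ins_seq <- paste(c(rep("A", 100), rep("G", 25), rep("T", 100)),
                   collapse = "")
  ins <- breakpoints_from_cigar(seg("100M25I100M", sample = "normal",
                                    seq = ins_seq))
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$sv_length, 25)
  expect_equal(ins$inserted_sequence, paste(rep("G", 25), collapse = ""))
  expect_equal(nrow(breakpoints_from_cigar(seg("100M25I100M"))), 0L)
})

test_that("long terminal soft-clips become single breakends unless explained", {
  seg <- function(cigar, qs, qe) {
    tibble::tibble(read_name = "r", contig = "chr1", start = 5000L,
                   end = 5000L + svelt:::cigar_ref_len(cigar),
                   strand = "+", mapq = 60, cigar = cigar,
                   query_start = qs, query_end = qe, sample = "tumor",
                   haplotype = NA_integer_, phase_set = NA_integer_,
                   seq = NA_character_)
  }
  sb <- sbnd_from_softclips(seg("1200S100M", 1200L, 1300L))
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$pos_a, 5000L)
  expect_equal(sb$strand_a, "-")

  expect_equal(nrow(sbnd_from_softclips(seg("800S100M", 800L, 900L))), 0L)

  covering <- tibble::tibble(query_start = 0L, query_end = 1150L)
  expect_equal(nrow(sbnd_from_softclips(seg("1200S100M", 1200L, 1300L),
                                        other_segments = covering)), 0L)

  trail <- sbnd_from_softclips(seg("100M1500S", 0L, 100L))
  expect_equal(trail$pos_a, 5100L)
  expect_equal(trail$strand_a, "+")
})

test_that("coverage tracks count per haplotype and conserve totals", {
  contigs <- c(chr1 = 1000L)
  recs <- dplyr::bind_rows(
    record_row("a", start = 100L, cigar = "100M", haplotype = 1L),
    record_row("b", start = 150L, cigar = "100M", haplotype = 2L),
    record_row("c", start = 120L, cigar = "50M")
  )
  track <- build_coverage(recs, contigs, bin_size = 5)
  # segment [100, 200) covers bins 21..40
  at <- coverage_at(track, "chr1", 100)
  expect_equal(at$hap1, 1L)
  expect_equal(at$total, at$hap1 + at$hap2 + at$unphased)
  expect_equal(sum(track$counts$chr1["hap1", ]), 20L)
  expect_equal(sum(track$counts$chr1["hap2", ]), 20L)
  expect_equal(sum(track$counts$chr1["unphased", ]), 10L)
  expect_equal(coverage_at(track, "chr1", 160)$total, 3L)
  expect_error(coverage_at(track, "chr1", 5000), "outside")
  expect_error(coverage_at(track, "chrX", 10), "unknown")

  zero <- build_coverage(recs[0, ], contigs, bin_size = 5)
  expect_true(all(zero$counts$chr1 == 0L))

  # conservation over random records
  set.seed(7)
  rnd <- purrr::map(1:50, function(i) {
    st <- sample(0:900, 1)
    record_row(paste0("r", i), start = st,
               cigar = paste0(sample(10:99, 1), "M"),
               haplotype = sample(c(1L, 2L, NA), 1))
  }) |> purrr::list_rbind()
  tr <- build_coverage(rnd, contigs, bin_size = 5)
  expected_bins <- sum(floor((rnd$end - 1) / 5) - floor(rnd$start / 5) + 1)
  expect_equal(sum(Reduce(`+`, list(tr$counts$chr1))), expected_bins)
})

test_that("genome-binned processing is invariant to the bin size", {
  wx <- shared_worked_example()
  a <- discover_breakpoints(wx$tumor, wx$contig_lengths,
                            genome_bin_size = 1e8)
  b <- discover_breakpoints(wx$tumor, wx$contig_lengths,
                            genome_bin_size = 5e4)
  ord <- function(x) dplyr::arrange(x, contig_a, pos_a, read_name, kind)
  expect_equal(ord(a$breakpoints), ord(b$breakpoints))
})
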