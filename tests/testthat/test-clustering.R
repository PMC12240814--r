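# Position chaining, mate refinement, insertion size grouping, finalization.

bp_at <- function(pos, mate = pos + 5000L, read = paste0("r", pos),
                  notation = "+-", kind = "split", contig_b = "chr1",
                  sv_length = abs(mate - pos), sample = "tumor") {
  breakpoint_row(kind = kind, notation = notation, pos_a = pos,
                 contig_b = contig_b, pos_b = mate, read_name = read,
                 sv_length = sv_length, sample = sample)
}

test_that("position chaining uses the 10 bp window, 250 bp for insertions", {
  bps <- dplyr::bind_rows(bp_at(100L), bp_at(105L, read = "r2"),
                          bp_at(108L, read = "r3"))
  proto <- cluster_by_position(bps)
  expect_equal(dplyr::n_distinct(proto$proto_id), 1L)

  two <- cluster_by_position(dplyr::bind_rows(bp_at(100L), bp_at(120L)))
  expect_equal(dplyr::n_distinct(two$proto_id), 2L)

  chained <- cluster_by_position(dplyr::bind_rows(
    bp_at(100L), bp_at(109L, read = "r2"), bp_at(118L, read = "r3")))
  expect_equal(dplyr::n_distinct(chained$proto_id), 1L)

  ins <- dplyr::bind_rows(
    bp_at(100L, mate = 100L, notation = "INS", kind = "cigar_insertion",
          sv_length = 200),
    bp_at(300L, mate = 300L, notation = "INS", kind = "cigar_insertion",
          sv_length = 210, read = "r2"))
  expect_equal(dplyr::n_distinct(cluster_by_position(ins)$proto_id), 1L)
})

test_that("mate refinement splits by contig then chains with a 50 bp window", {
  one <- refine_by_mate(dplyr::bind_rows(
    bp_at(100L, mate = 5000L, contig_b = "chr2"),
    bp_at(101L, mate = 5040L, contig_b = "chr2", read = "r2")))
  expect_equal(dplyr::n_distinct(one$mate_group), 1L)

  two_contig <- refine_by_mate(dplyr::bind_rows(
    bp_at(100L, mate = 5000L, contig_b = "chr2"),
    bp_at(101L, mate = 5000L, contig_b = "chr3", read = "r2")))
  expect_equal(dplyr::n_distinct(two_contig$mate_group), 2L)

  two_far <- refine_by_mate(dplyr::bind_rows(
    bp_at(100L, mate = 5000L, contig_b = "chr2"),
    bp_at(101L, mate = 5060L, contig_b = "chr2", read = "r2")))
  expect_equal(dplyr::n_distinct(two_far$mate_group), 2L)
})

test_that("insertions group by comparable size", {
  mk <- function(size, read) {
    bp_at(100L, mate = 100L, notation = "INS", kind = "cigar_insertion",
          sv_length = size, read = read)
  }
  close_sizes <- group_insertions_by_size(dplyr::bind_rows(mk(100, "a"),
                                                           mk(110, "b")))
  expect_equal(dplyr::n_distinct(close_sizes$size_group), 1L)
  far_sizes <- group_insertions_by_size(dplyr::bind_rows(mk(100, "a"),
                                                         mk(300, "b")))
  expect_equal(dplyr::n_distinct(far_sizes$size_group), 2L)
  single <- group_insertions_by_size(mk(100, "a"))
  expect_equal(dplyr::n_distinct(single$size_group), 1L)
})

test_that("single breakends survive only when alone at a locus", {
  sbnd <- purrr::map(1:3, function(i) {
    breakpoint_row(kind = "softclip_sbnd", notation = "SBND", pos_a = 1002L,
                   strand_a = "+", contig_b = NA, pos_b = NA, strand_b = NA,
                   sv_length = 0, read_name = paste0("s", i))
  }) |> purrr::list_rbind()
  dels <- purrr::map(1:5, function(i) {
    breakpoint_row(pos_a = 1000L, pos_b = 3000L,
                   read_name = paste0("d", i))
  }) |> purrr::list_rbind()

  mixed <- cluster_breakpoints(dplyr::bind_rows(sbnd, dels))
  expect_equal(nrow(mixed), 1L)
  expect_equal(mixed$notation, "+-")
  expect_equal(mixed$tumor_support, 5L)
  expect_equal(nrow(attr(mixed, "dropped_sbnd")), 1L)

  alone <- cluster_breakpoints(sbnd)
  expect_equal(nrow(alone), 1L)
  expect_equal(alone$notation, "SBND")
})

test_that("gapped and split deletion evidence of one event co-cluster", {
  gapped <- purrr::map(1:2, function(i) {
    breakpoint_row(kind = "cigar_deletion", pos_a = 1000L, pos_b = 3000L,
                   read_name = paste0("g", i))
  }) |> purrr::list_rbind()
  split <- purrr::map(1:2, function(i) {
    breakpoint_row(kind = "split", pos_a = 1001L, pos_b = 3002L,
                   read_name = paste0("s", i))
  }) |> purrr::list_rbind()
  cl <- cluster_breakpoints(dplyr::bind_rows(gapped, split))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$tumor_support, 4L)
  expect_equal(cl$frac_split, 0.5)
})

test_that("clustering is permutation-invariant and conserves members", {
  set.seed(11)
  bps <- purrr::map(1:60, function(i) {
    bp_at(sample(0:2000, 1), mate = sample(5000:6000, 1),
          read = paste0("r", i),
          notation = sample(c("+-", "-+"), 1))
  }) |> purrr::list_rbind()
  a <- cluster_breakpoints(bps)
  b <- cluster_breakpoints(bps[sample(nrow(bps)), ])
  strip <- function(x) {
    x$members <- NULL
    attr(x, "dropped_sbnd") <- NULL
    x
  }
  expect_equal(strip(a), strip(b))
  n_in_clusters <- sum(purrr::map_int(a$members, nrow))
  expect_equal(n_in_clusters, nrow(bps))
})

test_that("chained clustering equals within-window connected components", {
  set.seed(23)
  for (trial in 1:25) {
    n <- sample(5:50, 1)
    window <- sample(c(5, 10, 25), 1)
    pos <- sort(sample(0:500, n, replace = TRUE))
    got <- svelt:::chain_ids(pos, window)
    want <- components_within_window(pos, window)
    expect_equal(as.integer(factor(got)), as.integer(factor(want)))
  }
})
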