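# Tumor purity from BAF bimodality at LOH blocks.
#
# In a pure tumor the BAF of heterozygous SNPs at LOH regions is 0 or 1;
# normal-cell infiltration pulls both modes toward 0.5 in proportion to
# (1 - purity). The genome is scanned in fixed blocks, blocks with the most
# bimodal BAF distributions are selected, and purity is recovered from the
# median BAF of the upper (BAF_A) and lower (BAF_B) modes.

#' Compute B-allele frequencies at heterozygous SNP sites
#'
#' Pileup-based allele counting from an indexed BAM. Sites below `min_depth`
#' informative (ref + alt) reads are dropped. For in-memory synthetic data,
#' supply a precomputed BAF table instead (see [simulate_cn_data()]).
#'
#' @param snp_sites SNP tibble from [read_snp_sites()].
#' @param bam_path Indexed BAM of the tumor sample.
#' @param min_depth Minimum informative depth (default 10).
#' @param min_mapq,min_baseq Pileup quality gates (defaults 5, 0).
#' @return Tibble with `contig`, `position`, `ref_count`, `alt_count`,
#'   `depth`, `baf`.
#' @export
compute_baf <- function(snp_sites, bam_path, min_depth = 10, min_mapq = 5,
                        min_baseq = 0) {
  which <- GenomicRanges::GRanges(snp_sites$contig,
                                  IRanges::IRanges(snp_sites$position,
                                                   snp_sites$position))
  param <- Rsamtools::ScanBamParam(
    which = which,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  pp <- Rsamtools::PileupParam(max_depth = 10000, min_mapq = min_mapq,
                               min_base_quality = min_baseq,
                               distinguish_strands = FALSE)
  pu <- Rsamtools::pileup(bam_path, scanBamParam = param, pileupParam = pp)
  if (nrow(pu) == 0L) {
    return(tibble(contig = character(), position = integer(),
                  ref_count = integer(), alt_count = integer(),
                  depth = integer(), baf = double()))
  }
  pu <- tibble(contig = as.character(pu$seqnames), position = pu$pos,
               nucleotide = as.character(pu$nucleotide), count = pu$count)
  counts <- snp_sites |>
    left_join(pu, by = c("contig", "position"),
              relationship = "one-to-many") |>
    group_by(.data$contig, .data$position, .data$ref_allele,
             .data$alt_allele) |>
    summarise(
      ref_count = sum(.data$count[.data$nucleotide == .data$ref_allele[1]],
                      na.rm = TRUE),
      alt_count = sum(.data$count[.data$nucleotide == .data$alt_allele[1]],
                      na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(depth = .data$ref_count + .data$alt_count) |>
    filter(.data$depth >= min_depth) |>
    mutate(baf = .data$alt_count / .data$depth) |>
    select("contig", "position", "ref_count", "alt_count", "depth", "baf") |>
    arrange(.data$contig, .data$position)
  counts
}

#' Bimodality coefficient of a sample
#'
#' The skewness/kurtosis form: `b = (g1^2 + 1) / (g2 + 3(n-1)^2 /
#' ((n-2)(n-3)))` with `g1` the sample skewness and `g2` the excess kurtosis.
#' A uniform distribution scores 5/9; higher values indicate bimodality.
#'
#' @param values Numeric vector (n >= 4, non-degenerate).
#' @return The coefficient, or `NA` when undefined (n < 4 or zero variance).
#' @export
bimodality_coefficient <- function(values) {
  n <- length(values)
  if (n < 4L) return(NA_real_)
  m <- mean(values)
  s <- sqrt(sum((values - m)^2) / n)
  if (s == 0) return(NA_real_)
  m3 <- sum((values - m)^3) / n
  m4 <- sum((values - m)^4) / n
  g1 <- (m3 / s^3) * sqrt(n * (n - 1)) / (n - 2)
  g2 <- ((n + 1) * (m4 / s^4 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3))
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Select the most bimodal genomic blocks as LOH candidates
#'
#' Splits the genome into fixed blocks (default 1.2 Mbp, the median phased
#' block size in long-read germline data), drops blocks with fewer than
#' `min_snps` heterozygous SNPs or mean depth above `depth_cap_factor` times
#' the genome mean (potentially amplified regions would bias the BAF
#' distribution), ranks the rest by BAF bimodality and returns the top
#' `top_k` with the median BAF of the upper mode (`baf_a`) and lower mode
#' (`baf_b`), split at BAF 0.5. With fewer than `top_k` eligible blocks, all
#' eligible blocks are returned with a warning.
#'
#' @param baf BAF observation tibble (`contig`, `position`, `depth`, `baf`).
#' @param contig_lengths Named integer vector.
#' @param block_size Block size in bp (default 1.2e6).
#' @param min_snps Minimum SNPs per block (default 10).
#' @param depth_cap_factor Depth exclusion multiplier (default 2).
#' @param top_k Number of blocks to keep (default 10).
#' @return Tibble of blocks with `bimodality`, `baf_a`, `baf_b`, ranked.
#' @export
select_loh_blocks <- function(baf, contig_lengths, block_size = 1.2e6,
                              min_snps = 10, depth_cap_factor = 2,
                              top_k = 10) {
  genome_mean_depth <- mean(baf$depth)
  blocks <- baf |>
    mutate(block = paste0(.data$contig, "/",
                          floor((.data$position - 1) / block_size))) |>
    group_by(.data$contig, .data$block) |>
    summarise(
      start = min(.data$position), end = max(.data$position),
      snp_count = dplyr::n(),
      mean_depth = mean(.data$depth),
      bimodality = bimodality_coefficient(.data$baf),
      baf_a = if (any(.data$baf > 0.5)) median(.data$baf[.data$baf > 0.5])
              else NA_real_,
      baf_b = if (any(.data$baf <= 0.5)) median(.data$baf[.data$baf <= 0.5])
              else NA_real_,
      .groups = "drop"
    ) |>
    filter(.data$snp_count >= min_snps,
           .data$mean_depth <= depth_cap_factor * genome_mean_depth,
           !is.na(.data$bimodality),
           !is.na(.data$baf_a), !is.na(.data$baf_b)) |>
    arrange(dplyr::desc(.data$bimodality))
  if (nrow(blocks) < top_k) {
    warn(paste0("only ", nrow(blocks), " eligible LOH blocks (requested ",
                top_k, "); purity is averaged over what exists"))
  }
  head(blocks, top_k)
}

#' Estimate tumor purity from LOH-block BAF modes
#'
#' For each selected block the upper- and lower-mode median BAFs each yield a
#' purity estimate — `1 - 2 * (1 - BAF_A)` and `1 - 2 * BAF_B`, exact for
#' copy-number-neutral LOH — and the estimate is their average over blocks:
#' `rho = (1/K) * sum_i ((1 - 2(1 - medBAF_A_i)) + (1 - 2 medBAF_B_i)) / 2`.
#'
#' @param blocks Block tibble from [select_loh_blocks()].
#' @return Purity estimate in (0, 1].
#' @export
estimate_purity <- function(blocks) {
  if (nrow(blocks) == 0L) abort("no eligible LOH blocks; supply purity manually")
  per_block <- ((1 - 2 * (1 - blocks$baf_a)) + (1 - 2 * blocks$baf_b)) / 2
  mean(per_block)
}
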