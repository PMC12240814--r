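# Benchmarking machinery: simulated sequencing replicates, breakend matching
# with an overlap buffer, precision/recall/F-measure, read-backed phasing
# consistency, and the fold-back artifact rate estimator.

#' Split reads into two simulated sequencing replicates
#'
#' Every read — all of its records together, so a read's evidence never
#' straddles replicates — is assigned to one of two outputs by a seeded fair
#' coin. Used to benchmark callers: true somatic SVs should be found in both
#' replicates, artifacts in only one; and running one normal replicate as
#' "tumor" against the other quantifies the false-positive rate.
#'
#' @param records Alignment-record tibble.
#' @param seed Integer seed.
#' @return A list of two alignment tibbles, `rep1` and `rep2`.
#' @export
split_replicates <- function(records, seed = 1) {
  reads <- sort(unique(records$read_name))
  set.seed(seed)
  coin <- stats::runif(length(reads)) < 0.5
  first <- reads[coin]
  list(rep1 = filter(records, .data$read_name %in% first),
       rep2 = filter(records, !.data$read_name %in% first))
}

#' Match called breakends against a truth set
#'
#' Greedy nearest-first one-to-one matching: candidate pairs on the same
#' contig within `buffer` bp are sorted by distance and assigned so that each
#' call and each truth breakend is used at most once. Insertion records are
#' compared record-to-record (only against other insertions); all other
#' breakends compare within the breakend pool.
#'
#' @param calls Breakend tibble (`contig`, `pos`, `type`; e.g. from
#'   [read_truth_vcf()] or [clusters_to_breakends()]).
#' @param truth Truth breakend tibble, same columns.
#' @param buffer Matching window in bp (default 100).
#' @return A `match_result` list with `pairs`, `unmatched_calls`,
#'   `unmatched_truth`, `precision`, `recall`, `f_measure`.
#' @export
match_breakends <- function(calls, truth, buffer = 100) {
  pool <- function(df) ifelse(!is.na(df$type) & df$type == "INS", "INS", "BE")
  calls <- mutate(calls, .idx = dplyr::row_number(), .pool = pool(calls))
  truth <- mutate(truth, .idx = dplyr::row_number(), .pool = pool(truth))
  cand <- inner_join(
    select(calls, call_idx = ".idx", contig = "contig", call_pos = "pos",
           pool = ".pool"),
    select(truth, truth_idx = ".idx", contig = "contig", truth_pos = "pos",
           pool = ".pool"),
    by = c("contig", "pool"), relationship = "many-to-many"
  ) |>
    mutate(distance = abs(.data$call_pos - .data$truth_pos)) |>
    filter(.data$distance <= buffer) |>
    arrange(.data$distance, .data$call_idx, .data$truth_idx)
  used_call <- logical(nrow(calls))
  used_truth <- logical(nrow(truth))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ci <- cand$call_idx[k]; ti <- cand$truth_idx[k]
    if (!used_call[ci] && !used_truth[ti]) {
      keep[k] <- TRUE
      used_call[ci] <- TRUE
      used_truth[ti] <- TRUE
    }
  }
  pairs <- cand[keep, c("contig", "call_idx", "truth_idx", "call_pos",
                        "truth_pos", "distance")]
  tp <- nrow(pairs)
  n_calls <- nrow(calls); n_truth <- nrow(truth)
  precision <- if (n_calls == 0L) NA_real_ else tp / n_calls
  recall <- if (n_truth == 0L) NA_real_ else tp / n_truth
  f <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  structure(
    list(pairs = pairs,
         unmatched_calls = calls[!used_call, setdiff(names(calls),
                                                     c(".idx", ".pool"))],
         unmatched_truth = truth[!used_truth, setdiff(names(truth),
                                                      c(".idx", ".pool"))],
         precision = precision, recall = recall, f_measure = f,
         n_calls = n_calls, n_truth = n_truth, tp = tp),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %d/%d calls matched %d/%d truth breakends\n  precision %.3f  recall %.3f  F %.3f\n",
    x$tp, x$n_calls, x$tp, x$n_truth, x$precision, x$recall, x$f_measure))
  invisible(x)
}

#' @export
glance.match_result <- function(x, ...) {
  tibble(precision = x$precision, recall = x$recall, f_measure = x$f_measure,
         tp = x$tp, n_calls = x$n_calls, n_truth = x$n_truth)
}

#' Convert a cluster table to a breakend tibble
#'
#' One row per breakend (two for paired clusters, one for insertions and
#' single breakends), suitable for [match_breakends()].
#'
#' @param clusters Cluster tibble.
#' @return Breakend tibble with `contig`, `pos`, `orientation`, `type`,
#'   `cluster_id`.
#' @export
clusters_to_breakends <- function(clusters) {
  if (nrow(clusters) == 0L) {
    return(tibble(contig = character(), pos = integer(),
                  orientation = character(), type = character(),
                  cluster_id = integer()))
  }
  a <- tibble(contig = clusters$contig_a, pos = clusters$pos_a,
              orientation = clusters$strand_a,
              type = ifelse(clusters$notation %in% c("INS", "SBND"),
                            clusters$notation, "BND"),
              cluster_id = clusters$cluster_id)
  b <- clusters |>
    filter(!.data$notation %in% c("INS", "SBND")) |>
    (\(cl) tibble(contig = cl$contig_b, pos = cl$pos_b,
                  orientation = cl$strand_b, type = "BND",
                  cluster_id = cl$cluster_id))()
  bind_rows(a, b) |> arrange(.data$contig, .data$pos)
}

#' Read-backed phasing consistency of SV-supporting reads
#'
#' True somatic SVs should be supported by reads phased to a single parental
#' allele; artifacts draw support from both. SVs with reads on one allele
#' only are `concordant`. For SVs with reads on both alleles, the
#' majority-allele count is tested with a one-tailed binomial test at success
#' probability `p_success` (allowing a small phasing error rate), p-values
#' are Benjamini-Hochberg corrected across tested SVs, and `q <= fdr` gives a
#' `discordant` verdict; otherwise `inconclusive`. SVs inside LOH regions
#' must be excluded upstream (one-allele support there is uninformative).
#'
#' @param sv_support Tibble with `sv_id`, `allele1_count`, `allele2_count`.
#' @param p_success Binomial success probability (default 0.95).
#' @param fdr FDR threshold (default 0.05).
#' @return Tibble with `verdict`, `p_value`, `fdr_q` per SV.
#' @export
phasing_consistency <- function(sv_support, p_success = 0.95, fdr = 0.05) {
  assert_columns(sv_support, c("sv_id", "allele1_count", "allele2_count"),
                 "SV support table")
  out <- sv_support |>
    mutate(
      n = .data$allele1_count + .data$allele2_count,
      k = pmax(.data$allele1_count, .data$allele2_count),
      tested = .data$allele1_count > 0 & .data$allele2_count > 0,
      p_value = ifelse(.data$tested,
                       pbinom(.data$k, .data$n, p_success), NA_real_)
    )
  out$fdr_q <- NA_real_
  if (any(out$tested)) {
    out$fdr_q[out$tested] <- p.adjust(out$p_value[out$tested], method = "BH")
  }
  out |>
    mutate(verdict = dplyr::case_when(
      !tested ~ "concordant",
      fdr_q <= fdr ~ "discordant",
      TRUE ~ "inconclusive"
    )) |>
    select("sv_id", "allele1_count", "allele2_count", "verdict", "p_value",
           "fdr_q")
}

#' Estimate the fold-back-like inversion artifact rate
#'
#' A read is counted as a fold-back artifact when (1) it has exactly one
#' primary and one supplementary alignment, both with MAPQ of at least
#' `mapq_min`; (2) the two alignments overlap on the same contig in opposite
#' orientations; and (3) the reference positions corresponding to the start
#' and the end of the read are less than `end_distance` bp apart. The
#' denominator is the number of reads with a primary alignment of MAPQ at
#' least `mapq_min`.
#'
#' @param records Alignment-record tibble.
#' @param mapq_min Minimum mapping quality (default 20).
#' @param end_distance Read start/end distance cutoff in bp (default 150).
#' @return Tibble with `artifact_reads`, `eligible_reads`, `rate`.
#' @export
foldback_rate <- function(records, mapq_min = 20, end_distance = 150) {
  by_read <- records |>
    group_by(.data$read_name) |>
    group_split()
  eligible <- 0L
  artifact <- 0L
  for (m in by_read) {
    prim <- m[!m$is_supplementary, ]
    supp <- m[m$is_supplementary, ]
    if (nrow(prim) != 1L || prim$mapq < mapq_min) next
    eligible <- eligible + 1L
    if (nrow(supp) != 1L || supp$mapq < mapq_min) next
    if (prim$contig != supp$contig || prim$strand == supp$strand) next
    overlap <- prim$start < supp$end && supp$start < prim$end
    if (!overlap) next
    # reference positions of the read's first and last query base
    qs <- cigar_query_span(c(prim$cigar, supp$cigar),
                           c(prim$strand, supp$strand))
    segs <- bind_rows(prim, supp)
    first_seg <- segs[which.min(qs$query_start), ]
    last_seg <- segs[which.max(qs$query_end), ]
    read_start_pos <- if (first_seg$strand == "+") first_seg$start else first_seg$end
    read_end_pos <- if (last_seg$strand == "+") last_seg$end else last_seg$start
    if (abs(read_start_pos - read_end_pos) < end_distance) {
      artifact <- artifact + 1L
    }
  }
  tibble(artifact_reads = artifact, eligible_reads = eligible,
         rate = if (eligible > 0) artifact / eligible else NA_real_)
}
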