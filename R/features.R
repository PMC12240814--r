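# Breakpoint feature encoding: the fixed 70-covariate vector consumed by the
# random-forest classifier and the conformal predictor. The manifest is
# frozen: feature identity and order are part of the model contract, and a
# serialized model refuses feature tables that do not match.

#' The frozen breakpoint feature manifest
#'
#' Returns the ordered names of the 70 covariates encoding a breakpoint
#' cluster: supporting-read MAPQ statistics, SV-length statistics, coordinate
#' spread, support counts per sample and haplotype, allele fractions, depth
#' before/at/after each breakend in tumor and normal, evidence-type
#' fractions, notation one-hot and locus descriptors.
#'
#' @return Character vector of length 70.
#' @export
sv_feature_names <- function() {
  c(
    "mean_mapq", "sd_mapq", "min_mapq", "max_mapq",
    "mean_sv_length", "sd_sv_length", "median_sv_length",
    "min_sv_length", "max_sv_length",
    "sd_start", "sd_end", "mad_start", "mad_end",
    "span",
    "tumor_support", "normal_support", "total_support",
    "tumor_support_fraction",
    "tumor_af", "tumor_af_b", "normal_af", "normal_af_b",
    "tumor_depth_before_a", "tumor_depth_at_a", "tumor_depth_after_a",
    "tumor_depth_before_b", "tumor_depth_at_b", "tumor_depth_after_b",
    "normal_depth_before_a", "normal_depth_at_a", "normal_depth_after_a",
    "normal_depth_before_b", "normal_depth_at_b", "normal_depth_after_b",
    "tumor_depth_change_a", "tumor_depth_change_b",
    "normal_depth_change_a", "normal_depth_change_b",
    "tumor_hap1_support", "tumor_hap2_support", "tumor_unphased_support",
    "normal_hap1_support", "normal_hap2_support", "normal_unphased_support",
    "unphased_support",
    "hap_imbalance_tumor", "hap_imbalance_normal",
    "n_phase_sets_tumor", "n_phase_sets_normal",
    "normal_any_cluster_reads",
    "frac_split_evidence", "frac_cigar_evidence", "frac_sbnd_evidence",
    "n_members", "insert_size", "insert_size_sd",
    "notation_pm", "notation_mp", "notation_pp", "notation_mm",
    "notation_ins", "notation_sbnd",
    "interchromosomal", "sv_length_over_span",
    "log_tumor_support", "log_sv_length",
    "paired_mode",
    "tumor_depth_min_ab", "normal_depth_min_ab",
    "support_per_depth"
  )
}

# Distinct normal read names with any putative breakpoint (of any type or
# orientation) within `window` bp of a locus.
normal_reads_near <- function(normal_breakpoints, contig, pos, window = 100) {
  if (is.null(normal_breakpoints) || nrow(normal_breakpoints) == 0L ||
      is.na(contig)) {
    return(0L)
  }
  near_a <- normal_breakpoints$contig_a == contig &
    abs(normal_breakpoints$pos_a - pos) <= window
  near_b <- !is.na(normal_breakpoints$contig_b) &
    normal_breakpoints$contig_b == contig &
    !is.na(normal_breakpoints$pos_b) &
    abs(normal_breakpoints$pos_b - pos) <= window
  dplyr::n_distinct(normal_breakpoints$read_name[near_a | near_b])
}

#' Encode breakpoint clusters as the 70-covariate feature table
#'
#' Deterministically maps each cluster to the frozen feature vector of
#' [sv_feature_names()]. Depths come from the per-haplotype coverage tracks
#' (before/at/after = one coverage bin upstream / at / downstream of each
#' breakend). Allele fraction is supporting reads over depth at the breakend,
#' clamped to [0, 1]. When no normal sample is given (`coverage_normal =
#' NULL`), all normal-derived features are 0 and the `paired_mode` flag is 0.
#'
#' @param clusters Cluster tibble from [cluster_breakpoints()].
#' @param coverage_tumor `coverage_track` for the tumor sample.
#' @param coverage_normal Optional `coverage_track` for the matched normal.
#' @param normal_breakpoints Optional tibble of all normal putative
#'   breakpoints, used for the any-orientation clustered-normal-reads
#'   covariate (100 bp window).
#' @return A tibble with `cluster_id` plus the 70 feature columns; all values
#'   finite.
#' @export
encode_features <- function(clusters, coverage_tumor, coverage_normal = NULL,
                            normal_breakpoints = NULL) {
  paired <- !is.null(coverage_normal)
  feat_names <- sv_feature_names()
  if (nrow(clusters) == 0L) {
    out <- as_tibble(setNames(
      as.data.frame(matrix(numeric(0), ncol = length(feat_names))),
      feat_names))
    return(bind_cols(tibble(cluster_id = integer()), out))
  }

  depth3 <- function(track, contig, pos) {
    if (is.null(track) || is.na(pos)) return(c(0, 0, 0))
    bs <- track$bin_size
    c(coverage_total_at(track, contig, pos - bs),
      coverage_total_at(track, contig, pos),
      coverage_total_at(track, contig, pos + bs))
  }

  rows <- map(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    m <- cl$members[[1]]
    td_a <- depth3(coverage_tumor, cl$contig_a, cl$pos_a)
    td_b <- depth3(coverage_tumor, cl$contig_b, cl$pos_b)
    nd_a <- depth3(coverage_normal, cl$contig_a, cl$pos_a)
    nd_b <- depth3(coverage_normal, cl$contig_b, cl$pos_b)
    af <- function(support, depth) {
      if (depth <= 0) 0 else min(support / depth, 1)
    }
    interchrom <- !is.na(cl$contig_b) && cl$contig_a != cl$contig_b
    span <- if (interchrom || is.na(cl$pos_b)) 0 else abs(cl$pos_b - cl$pos_a)
    h1t <- cl$tumor_hap1; h2t <- cl$tumor_hap2
    h1n <- cl$normal_hap1; h2n <- cl$normal_hap2
    imb <- function(h1, h2) if (h1 + h2 == 0) 0 else abs(h1 - h2) / (h1 + h2)
    v <- c(
      mean_mapq = cl$mean_mapq,
      sd_mapq = sd0(m$mapq),
      min_mapq = min(m$mapq),
      max_mapq = max(m$mapq),
      mean_sv_length = cl$mean_sv_length,
      sd_sv_length = cl$sd_sv_length,
      median_sv_length = cl$median_sv_length,
      min_sv_length = min(m$sv_length),
      max_sv_length = max(m$sv_length),
      sd_start = cl$sd_pos_a,
      sd_end = cl$sd_pos_b,
      mad_start = stats::mad(m$pos_a, constant = 1),
      mad_end = if (all(is.na(m$pos_b))) 0 else
        stats::mad(m$pos_b[!is.na(m$pos_b)], constant = 1),
      span = span,
      tumor_support = cl$tumor_support,
      normal_support = if (paired) cl$normal_support else 0,
      total_support = cl$tumor_support + if (paired) cl$normal_support else 0,
      tumor_support_fraction = if (cl$tumor_support + cl$normal_support == 0) 0
        else cl$tumor_support / (cl$tumor_support +
                                   if (paired) cl$normal_support else 0),
      tumor_af = af(cl$tumor_support, td_a[2]),
      tumor_af_b = af(cl$tumor_support, td_b[2]),
      normal_af = if (paired) af(cl$normal_support, nd_a[2]) else 0,
      normal_af_b = if (paired) af(cl$normal_support, nd_b[2]) else 0,
      tumor_depth_before_a = td_a[1], tumor_depth_at_a = td_a[2],
      tumor_depth_after_a = td_a[3],
      tumor_depth_before_b = td_b[1], tumor_depth_at_b = td_b[2],
      tumor_depth_after_b = td_b[3],
      normal_depth_before_a = nd_a[1], normal_depth_at_a = nd_a[2],
      normal_depth_after_a = nd_a[3],
      normal_depth_before_b = nd_b[1], normal_depth_at_b = nd_b[2],
      normal_depth_after_b = nd_b[3],
      tumor_depth_change_a = td_a[3] - td_a[1],
      tumor_depth_change_b = td_b[3] - td_b[1],
      normal_depth_change_a = nd_a[3] - nd_a[1],
      normal_depth_change_b = nd_b[3] - nd_b[1],
      tumor_hap1_support = h1t, tumor_hap2_support = h2t,
      tumor_unphased_support = cl$tumor_unphased,
      normal_hap1_support = if (paired) h1n else 0,
      normal_hap2_support = if (paired) h2n else 0,
      normal_unphased_support = if (paired) cl$normal_unphased else 0,
      unphased_support = cl$tumor_unphased +
        if (paired) cl$normal_unphased else 0,
      hap_imbalance_tumor = imb(h1t, h2t),
      hap_imbalance_normal = if (paired) imb(h1n, h2n) else 0,
      n_phase_sets_tumor = cl$n_phase_sets_tumor,
      n_phase_sets_normal = if (paired) cl$n_phase_sets_normal else 0,
      normal_any_cluster_reads = if (paired) {
        max(normal_reads_near(normal_breakpoints, cl$contig_a, cl$pos_a),
            normal_reads_near(normal_breakpoints, cl$contig_b, cl$pos_b))
      } else 0,
      frac_split_evidence = cl$frac_split,
      frac_cigar_evidence = cl$frac_cigar,
      frac_sbnd_evidence = cl$frac_sbnd,
      n_members = cl$n_members,
      insert_size = if (is.na(cl$insert_size)) 0 else cl$insert_size,
      insert_size_sd = if (cl$notation == "INS") cl$sd_sv_length else 0,
      notation_pm = as.numeric(cl$notation == "+-"),
      notation_mp = as.numeric(cl$notation == "-+"),
      notation_pp = as.numeric(cl$notation == "++"),
      notation_mm = as.numeric(cl$notation == "--"),
      notation_ins = as.numeric(cl$notation == "INS"),
      notation_sbnd = as.numeric(cl$notation == "SBND"),
      interchromosomal = as.numeric(interchrom),
      sv_length_over_span = if (span > 0) cl$median_sv_length / span else 0,
      log_tumor_support = log1p(cl$tumor_support),
      log_sv_length = log1p(cl$mean_sv_length),
      paired_mode = as.numeric(paired),
      tumor_depth_min_ab = min(td_a[2], if (is.na(cl$pos_b)) td_a[2] else td_b[2]),
      normal_depth_min_ab = if (paired) {
        min(nd_a[2], if (is.na(cl$pos_b)) nd_a[2] else nd_b[2])
      } else 0,
      support_per_depth = cl$tumor_support / (td_a[2] + 1)
    )
    as_tibble(as.list(v))
  })
  out <- list_rbind(rows)
  stopifnot(identical(names(out), feat_names))
  if (any(!is.finite(as.matrix(out)))) {
    abort("feature encoding produced non-finite values")
  }
  bind_cols(tibble(cluster_id = clusters$cluster_id), out)
}
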