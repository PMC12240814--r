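# Grouping putative breakpoints into candidate SV clusters.
#
# Clustering is single-linkage chaining: sorted breakpoints join the current
# cluster while the gap to the previous member stays within the window (10 bp
# by default; 250 bp for insertions, whose mapping location is noisier).
# Chained groups are then refined by mate contig/position (50 bp window) and,
# for insertions, by insert size, and finally summarized per notation class.

#' Chain breakpoints into proto-clusters by position
#'
#' Breakpoints are grouped by notation class (and, for single breakends, by
#' orientation) and contig, sorted, and chained: a breakpoint joins the
#' current cluster iff its position is within the window of the previous
#' member. Tumor and normal breakpoints co-cluster; normal membership later
#' drives somatic filtering.
#'
#' @param breakpoints Breakpoint tibble (see [discover_breakpoints()]).
#' @param window_default Chaining window in bp for all classes except
#'   insertions (default 10).
#' @param window_insertion Chaining window for insertions (default 250).
#' @return The breakpoints with a `proto_id` column, sorted.
#' @export
cluster_by_position <- function(breakpoints, window_default = 10,
                                window_insertion = 250) {
  if (nrow(breakpoints) == 0L) {
    return(mutate(breakpoints, proto_id = character(0)))
  }
  breakpoints |>
    mutate(.grp = ifelse(.data$notation == "SBND",
                         paste0("SBND", .data$strand_a), .data$notation)) |>
    arrange(.data$.grp, .data$contig_a, .data$pos_a, .data$contig_b,
            .data$pos_b, .data$read_name) |>
    group_by(.data$.grp, .data$contig_a) |>
    mutate(.chain = chain_ids(
      .data$pos_a,
      ifelse(.data$notation[1] == "INS", window_insertion, window_default)[1]
    )) |>
    ungroup() |>
    mutate(proto_id = paste0(.data$.grp, "/", .data$contig_a, "/",
                             .data$.chain)) |>
    select(-".grp", -".chain")
}

#' Refine a proto-cluster by mate breakend
#'
#' Members are partitioned by the contig of their mate breakend, then
#' chain-clustered on the mate position with a wider window (50 bp by
#' default) so that supporting reads of one event are not incorrectly split.
#'
#' @param proto_members Tibble of breakpoints from one proto-cluster, all
#'   carrying `locus_b`.
#' @param mate_window Chaining window for mate positions (default 50).
#' @return The members with an integer `mate_group` column.
#' @export
refine_by_mate <- function(proto_members, mate_window = 50) {
  proto_members |>
    arrange(.data$contig_b, .data$pos_b) |>
    group_by(.data$contig_b) |>
    mutate(.sub = chain_ids(.data$pos_b, mate_window)) |>
    ungroup() |>
    mutate(mate_group = as.integer(factor(
      paste0(.data$contig_b, "/", .data$.sub),
      levels = unique(paste0(.data$contig_b, "/", .data$.sub))
    ))) |>
    select(-".sub")
}

#' Split an insertion proto-cluster by insert size
#'
#' Members are sorted by insert size and chain-split when consecutive sizes
#' differ by more than `rel_tol` times the smaller size, so grouped reads
#' support insertions of comparable size.
#'
#' @param proto_members Insertion breakpoints of one proto-cluster.
#' @param rel_tol Relative size tolerance (default 0.25).
#' @return The members with an integer `size_group` column.
#' @export
group_insertions_by_size <- function(proto_members, rel_tol = 0.25) {
  proto_members |>
    arrange(.data$sv_length) |>
    mutate(size_group = chain_ids_relative(.data$sv_length, rel_tol))
}

#' Summarize final breakpoint clusters
#'
#' Computes deterministic cluster statistics (median positions with
#' lower-median tie-break, support counts per sample and haplotype, SV-length
#' and coordinate spread, mean MAPQ) and applies the single-breakend rule:
#' SBND clusters co-located (within `window_default`) with any non-SBND
#' cluster breakend are dropped, since longer reads at that locus already
#' resolved the full adjacency. Dropped SBND clusters are kept in the
#' `"dropped_sbnd"` attribute for auditability.
#'
#' @param grouped Breakpoint tibble carrying a final `group_id` column.
#' @param window_default Co-location window for the SBND rule (default 10).
#' @return A cluster tibble, one row per candidate SV.
#' @export
finalize_clusters <- function(grouped, window_default = 10) {
  if (nrow(grouped) == 0L) {
    out <- empty_clusters()
    attr(out, "dropped_sbnd") <- empty_clusters()
    return(out)
  }
  summarize_one <- function(m) {
    is_ins <- m$notation[1] == "INS"
    hap_count <- function(samp, hap) {
      sel <- m$sample == samp &
        (if (is.na(hap)) is.na(m$haplotype) else !is.na(m$haplotype) & m$haplotype == hap)
      dplyr::n_distinct(m$read_name[sel])
    }
    ins_seqs <- m$inserted_sequence[!is.na(m$inserted_sequence)]
    tibble(
      notation = m$notation[1],
      contig_a = m$contig_a[1],
      pos_a = as.integer(median_low(m$pos_a)),
      strand_a = m$strand_a[1],
      contig_b = m$contig_b[1],
      pos_b = if (all(is.na(m$pos_b))) NA_integer_
              else as.integer(median_low(m$pos_b[!is.na(m$pos_b)])),
      strand_b = m$strand_b[1],
      n_members = nrow(m),
      tumor_support = dplyr::n_distinct(m$read_name[m$sample == "tumor"]),
      normal_support = dplyr::n_distinct(m$read_name[m$sample == "normal"]),
      mean_sv_length = mean(m$sv_length),
      sd_sv_length = sd0(m$sv_length),
      median_sv_length = stats::median(m$sv_length),
      sd_pos_a = sd0(m$pos_a),
      sd_pos_b = if (all(is.na(m$pos_b))) 0 else sd0(m$pos_b[!is.na(m$pos_b)]),
      mean_mapq = mean(m$mapq),
      insert_size = if (is_ins) stats::median(m$sv_length) else NA_real_,
      inserted_sequence = if (length(ins_seqs)) {
        ins_seqs[which.max(nchar(ins_seqs))]
      } else NA_character_,
      tumor_hap1 = hap_count("tumor", 1L),
      tumor_hap2 = hap_count("tumor", 2L),
      tumor_unphased = hap_count("tumor", NA),
      normal_hap1 = hap_count("normal", 1L),
      normal_hap2 = hap_count("normal", 2L),
      normal_unphased = hap_count("normal", NA),
      frac_split = mean(m$kind == "split"),
      frac_cigar = mean(m$kind %in% c("cigar_deletion", "cigar_insertion")),
      frac_sbnd = mean(m$kind == "softclip_sbnd"),
      n_phase_sets_tumor = dplyr::n_distinct(
        m$phase_set[m$sample == "tumor" & !is.na(m$phase_set)]),
      n_phase_sets_normal = dplyr::n_distinct(
        m$phase_set[m$sample == "normal" & !is.na(m$phase_set)]),
      members = list(m)
    )
  }

  clusters <- grouped |>
    group_by(.data$group_id) |>
    group_split() |>
    map(summarize_one) |>
    list_rbind() |>
    arrange(.data$contig_a, .data$pos_a, .data$notation) |>
    mutate(cluster_id = dplyr::row_number(), .before = 1)

  is_sbnd <- clusters$notation == "SBND"
  drop <- rep(FALSE, nrow(clusters))
  if (any(is_sbnd) && any(!is_sbnd)) {
    other <- clusters[!is_sbnd, ]
    ends <- bind_rows(
      tibble(contig = other$contig_a, pos = other$pos_a),
      tibble(contig = other$contig_b, pos = other$pos_b)
    ) |> filter(!is.na(.data$contig))
    for (i in which(is_sbnd)) {
      near <- ends$contig == clusters$contig_a[i] &
        abs(ends$pos - clusters$pos_a[i]) <= window_default
      if (any(near)) drop[i] <- TRUE
    }
  }
  out <- clusters[!drop, ]
  out$cluster_id <- seq_len(nrow(out))
  attr(out, "dropped_sbnd") <- clusters[drop, ]
  out
}

empty_clusters <- function() {
  finalize_empty <- tibble(
    cluster_id = integer(), notation = character(), contig_a = character(),
    pos_a = integer(), strand_a = character(), contig_b = character(),
    pos_b = integer(), strand_b = character(), n_members = integer(),
    tumor_support = integer(), normal_support = integer(),
    mean_sv_length = double(), sd_sv_length = double(),
    median_sv_length = double(), sd_pos_a = double(), sd_pos_b = double(),
    mean_mapq = double(), insert_size = double(),
    inserted_sequence = character(),
    tumor_hap1 = integer(), tumor_hap2 = integer(), tumor_unphased = integer(),
    normal_hap1 = integer(), normal_hap2 = integer(),
    normal_unphased = integer(),
    frac_split = double(), frac_cigar = double(), frac_sbnd = double(),
    n_phase_sets_tumor = integer(), n_phase_sets_normal = integer(),
    members = list()
  )
  finalize_empty
}

#' Cluster putative breakpoints into candidate SVs
#'
#' Full clustering pass: position chaining, mate-side refinement, insertion
#' size grouping and final summarization with the single-breakend rule. The
#' result is invariant to the input row order.
#'
#' @inheritParams cluster_by_position
#' @inheritParams refine_by_mate
#' @param insertion_size_rel_tol Relative insert-size tolerance (default
#'   0.25).
#' @return A cluster tibble (see [finalize_clusters()]).
#' @export
cluster_breakpoints <- function(breakpoints, window_default = 10,
                                window_insertion = 250, mate_window = 50,
                                insertion_size_rel_tol = 0.25) {
  proto <- cluster_by_position(breakpoints, window_default, window_insertion)
  if (nrow(proto) == 0L) return(finalize_clusters(mutate(proto, group_id = character(0))))
  refined <- proto |>
    group_by(.data$proto_id) |>
    group_split() |>
    map(function(m) {
      if (m$notation[1] == "INS") {
        m <- group_insertions_by_size(m, insertion_size_rel_tol)
        mutate(m, group_id = paste0(.data$proto_id, "#", .data$size_group))
      } else if (m$notation[1] == "SBND") {
        mutate(m, group_id = .data$proto_id)
      } else {
        m <- refine_by_mate(m, mate_window)
        mutate(m, group_id = paste0(.data$proto_id, "#", .data$mate_group))
      }
    }) |>
    list_rbind()
  finalize_clusters(refined, window_default)
}
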