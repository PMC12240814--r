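# Putative breakpoint discovery from split reads, CIGAR operations and long
# soft-clips.
#
# Orientation convention: "+" = sequence retained to the left of the breakend
# (the adjacency continues rightward); "-" = retained to the right. The four
# strand pairings of query-adjacent segments map to the Pan-Cancer notation
# classes: (+ -) deletion-like, (- +) duplication-like, (+ +)/(- -)
# inversion-like.

empty_breakpoints <- function() {
  fast_tbl(
    kind = character(), notation = character(),
    contig_a = character(), pos_a = integer(), strand_a = character(),
    contig_b = character(), pos_b = integer(), strand_b = character(),
    sv_length = double(), span = double(), inserted_sequence = character(),
    read_name = character(), sample = character(), haplotype = integer(),
    phase_set = integer(), mapq = double()
  )
}

parse_sa_tag <- function(sa_tag) {
  entries <- strsplit(sa_tag, ";")[[1]]
  entries <- entries[nzchar(entries)]
  fields <- strsplit(entries, ",")
  if (any(lengths(fields) < 5)) stop("malformed SA tag")
  tibble(
    contig = map_chr(fields, 1),
    start = as.integer(map_chr(fields, 2)) - 1L,
    strand = map_chr(fields, 3),
    cigar = map_chr(fields, 4),
    mapq = as.integer(map_chr(fields, 5))
  )
}

#' Decompose a primary alignment record into read segments
#'
#' Parses the `SA` tag of a primary record and returns one segment per mapped
#' piece of the read (the primary plus each supplementary entry), ordered by
#' their offset on the read. When `sbnd_mode` is on, supplementary entries
#' with mapping quality below `supp_mapq_floor` (default 5) are treated as
#' unmapped: they are not returned as segments, and their clipped sequence
#' with the adjacent mapped position is returned as a single-breakend
#' candidate instead. A malformed `SA` tag is logged as a warning and only
#' the primary segment is returned; it is never fatal.
#'
#' @param record One-row tibble: a primary alignment record.
#' @param sbnd_mode Track low-quality supplementary pieces as single-breakend
#'   candidates.
#' @param supp_mapq_floor Supplementary entries below this MAPQ are
#'   considered unmapped (default 5).
#' @return A list with `segments` (tibble ordered by `query_start`) and
#'   `sbnd_candidates` (tibble of softclip_sbnd breakpoints, possibly empty).
#' @export
segments_from_read <- function(record, sbnd_mode = FALSE, supp_mapq_floor = 5) {
  stopifnot(nrow(record) == 1L)
  qs <- cigar_query_span(record$cigar, record$strand)
  primary <- fast_tbl(
    read_name = record$read_name, contig = record$contig,
    start = record$start, end = record$end, strand = record$strand,
    mapq = as.double(record$mapq), cigar = record$cigar,
    is_supplementary = FALSE,
    haplotype = record$haplotype, phase_set = record$phase_set,
    query_start = qs$query_start, query_end = qs$query_end,
    sample = record$sample, seq = record$seq
  )
  candidates <- empty_breakpoints()
  segs <- primary
  if (!is.na(record$sa_tag) && nzchar(record$sa_tag)) {
    sa <- tryCatch(parse_sa_tag(record$sa_tag), error = function(e) NULL)
    if (is.null(sa)) {
      warn(paste0("malformed SA tag for read ", record$read_name,
                  "; using primary segment only"))
    } else {
      sqs <- cigar_query_span(sa$cigar, sa$strand)
      sa_segs <- fast_tbl(
        read_name = record$read_name, contig = sa$contig,
        start = sa$start, end = sa$start + cigar_ref_len(sa$cigar),
        strand = sa$strand, mapq = as.double(sa$mapq), cigar = sa$cigar,
        is_supplementary = TRUE,
        haplotype = record$haplotype, phase_set = record$phase_set,
        query_start = sqs$query_start, query_end = sqs$query_end,
        sample = record$sample, seq = NA_character_
      )
      if (sbnd_mode) {
        low <- sa_segs$mapq < supp_mapq_floor
        if (any(low)) {
          cand <- sa_segs[low, ]
          # the low-quality piece hangs off one end of the primary; anchor the
          # candidate at the primary breakend facing it
          right_side <- cand$query_start >= primary$query_end
          candidates <- fast_tbl(
            kind = "softclip_sbnd", notation = "SBND",
            contig_a = primary$contig,
            pos_a = ifelse(right_side, primary$end, primary$start),
            strand_a = ifelse(right_side, "+", "-"),
            contig_b = NA_character_, pos_b = NA_integer_,
            strand_b = NA_character_,
            sv_length = 0, span = 0,
            inserted_sequence = toupper(clip_sequence(primary, right_side)),
            read_name = primary$read_name, sample = primary$sample,
            haplotype = primary$haplotype, phase_set = primary$phase_set,
            mapq = primary$mapq
          )
          sa_segs <- sa_segs[!low, ]
        }
      }
      segs <- bind_rows(primary, sa_segs)
    }
  }
  segs <- arrange(segs, .data$query_start)
  list(segments = segs, sbnd_candidates = candidates)
}

# Soft-clipped bases of a primary segment on one reference side (right_side
# TRUE = trailing clip in reference orientation). NA when SEQ was not stored.
clip_sequence <- function(seg, right_side) {
  if (is.na(seg$seq)) return(NA_character_)
  ops <- cigar_ops(seg$cigar)[[1]]
  lead <- if (ops$op[1] == "S") ops$len[1] else 0L
  trail <- if (ops$op[nrow(ops)] == "S") ops$len[nrow(ops)] else 0L
  total <- nchar(seg$seq)
  if (right_side) {
    if (trail == 0L) return(NA_character_)
    substr(seg$seq, total - trail + 1L, total)
  } else {
    if (lead == 0L) return(NA_character_)
    substr(seg$seq, 1L, lead)
  }
}

#' Detect an artifactual fold-back-like inversion junction
#'
#' Long-read sequencing produces artifact reads that align forward then
#' immediately backward over the same locus, mimicking an inversion junction.
#' A junction between two query-adjacent segments is flagged as fold-back
#' (and no inversion breakpoint is emitted) when the segments map to the same
#' contig in opposite orientations and the reference end of the first lies
#' within `window` bp of the reference end of the second.
#'
#' @param seg_i,seg_next One-row segment tibbles, query-adjacent on one read.
#' @param window Maximum end-to-end distance in bp (default 200).
#' @return Logical.
#' @export
detect_foldback_pair <- function(seg_i, seg_next, window = 200) {
  identical(seg_i$contig, seg_next$contig) &&
    seg_i$strand != seg_next$strand &&
    abs(seg_i$end - seg_next$end) <= window
}

breakend_of <- function(seg, role) {
  # role "first": junction at the query-end of the segment;
  # role "second": junction at the query-start.
  if (role == "first") {
    if (seg$strand == "+") list(pos = seg$end, orientation = "+")
    else list(pos = seg$start, orientation = "-")
  } else {
    if (seg$strand == "+") list(pos = seg$start, orientation = "-")
    else list(pos = seg$end, orientation = "+")
  }
}

#' Breakpoints from split (supplementary) alignments
#'
#' Emits one putative breakpoint per adjacent segment pair of a read (ordered
#' by query offset), after fold-back suppression. Breakend orientations
#' follow from the strands and which segment ends/begins at the junction;
#' loci are normalized so `locus_a <= locus_b` by (contig, position).
#'
#' @param segments Segment tibble for one read, ordered by `query_start`
#'   (as returned by [segments_from_read()]).
#' @param foldback_window Fold-back suppression window in bp (default 200).
#' @return A breakpoint tibble (possibly empty).
#' @export
breakpoints_from_split <- function(segments, foldback_window = 200) {
  n <- nrow(segments)
  if (n < 2L) return(empty_breakpoints())
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    s1 <- segments[i, ]; s2 <- segments[i + 1L, ]
    inversion_like <- identical(s1$contig, s2$contig) && s1$strand != s2$strand
    if (inversion_like && detect_foldback_pair(s1, s2, foldback_window)) next
    b1 <- breakend_of(s1, "first")
    b2 <- breakend_of(s2, "second")
    la <- list(contig = s1$contig, pos = b1$pos, orientation = b1$orientation)
    lb <- list(contig = s2$contig, pos = b2$pos, orientation = b2$orientation)
    if (lb$contig < la$contig ||
        (lb$contig == la$contig && lb$pos < la$pos)) {
      tmp <- la; la <- lb; lb <- tmp
    }
    same_contig <- la$contig == lb$contig
    out[[i]] <- fast_tbl(
      kind = "split",
      notation = paste0(la$orientation, lb$orientation),
      contig_a = la$contig, pos_a = as.integer(la$pos),
      strand_a = la$orientation,
      contig_b = lb$contig, pos_b = as.integer(lb$pos),
      strand_b = lb$orientation,
      sv_length = if (same_contig) abs(lb$pos - la$pos) else 0,
      span = if (same_contig) abs(lb$pos - la$pos) else 0,
      inserted_sequence = NA_character_,
      read_name = s1$read_name, sample = s1$sample,
      haplotype = s1$haplotype, phase_set = s1$phase_set,
      mapq = (s1$mapq + s2$mapq) / 2
    )
  }
  out <- purrr::compact(out)
  if (length(out) == 0L) return(empty_breakpoints())
  list_rbind(out)
}

#' Breakpoints from gapped (CIGAR) alignments
#'
#' Tracks deletion and insertion operations longer than the effective minimum
#' SV length. Large deletions interspersed with mapped stretches shorter than
#' `merge_gap` bp are merged into a single event whose `sv_length` is the sum
#' of deleted bases (the merged reference span is kept in `span`). For the
#' normal sample the minimum length is reduced by `normal_length_fraction` so
#' germline indels just below the tumor cutoff are still collected. CIGAR
#' deletions are typed `(+ -)` so they co-cluster with split-read deletions.
#'
#' @param segment One-row segment tibble with a parsed CIGAR.
#' @param min_sv_length Minimum SV length in bp (default 30; events must be
#'   strictly longer).
#' @param merge_gap Mapped stretches shorter than this merge adjacent
#'   deletions (default 30).
#' @param sample_role `"tumor"` or `"normal"`.
#' @param normal_length_fraction Fractional reduction of `min_sv_length` for
#'   the normal sample (default 0.20).
#' @return A breakpoint tibble.
#' @export
breakpoints_from_cigar <- function(segment, min_sv_length = 30,
                                   merge_gap = 30,
                                   sample_role = segment$sample,
                                   normal_length_fraction = 0.20) {
  eff_min <- if (identical(sample_role, "normal")) {
    min_sv_length * (1 - normal_length_fraction)
  } else min_sv_length
  ops <- cigar_ops(segment$cigar)[[1]]
  out <- list()

  # walk once, collecting insertion events and raw deletion ops
  ref <- segment$start
  qpos <- 0L
  dels <- list()  # each: list(start, end, len)
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      ref <- ref + len; qpos <- qpos + len
    } else if (op == "D" || op == "N") {
      dels[[length(dels) + 1L]] <- list(start = ref, end = ref + len, len = len)
      ref <- ref + len
    } else if (op == "I") {
      if (len > eff_min) {
        ins_seq <- if (!is.na(segment$seq)) {
          toupper(substr(segment$seq, qpos + 1L, qpos + len))
        } else NA_character_
        out[[length(out) + 1L]] <- fast_tbl(
          kind = "cigar_insertion", notation = "INS",
          contig_a = segment$contig, pos_a = as.integer(ref), strand_a = "+",
          contig_b = segment$contig, pos_b = as.integer(ref), strand_b = "-",
          sv_length = as.double(len), span = 0,
          inserted_sequence = ins_seq,
          read_name = segment$read_name, sample = segment$sample,
          haplotype = segment$haplotype, phase_set = segment$phase_set,
          mapq = segment$mapq
        )
      }
      qpos <- qpos + len
    } else if (op == "S") {
      qpos <- qpos + len
    }
  }

  # merge deletion runs separated by mapped stretches < merge_gap, then gate
  # the merged deleted-base sum on the effective minimum
  if (length(dels)) {
    groups <- list()
    cur <- dels[[1]]
    cur$sum <- cur$len
    if (length(dels) > 1L) {
      for (i in 2L:length(dels)) {
        gap <- dels[[i]]$start - cur$end
        if (gap < merge_gap) {
          cur$end <- dels[[i]]$end
          cur$sum <- cur$sum + dels[[i]]$len
        } else {
          groups[[length(groups) + 1L]] <- cur
          cur <- dels[[i]]; cur$sum <- cur$len
        }
      }
    }
    groups[[length(groups) + 1L]] <- cur
    for (g in groups) {
      if (g$sum > eff_min) {
        out[[length(out) + 1L]] <- fast_tbl(
          kind = "cigar_deletion", notation = "+-",
          contig_a = segment$contig, pos_a = as.integer(g$start),
          strand_a = "+",
          contig_b = segment$contig, pos_b = as.integer(g$end),
          strand_b = "-",
          sv_length = as.double(g$sum), span = as.double(g$end - g$start),
          inserted_sequence = NA_character_,
          read_name = segment$read_name, sample = segment$sample,
          haplotype = segment$haplotype, phase_set = segment$phase_set,
          mapq = segment$mapq
        )
      }
    }
  }
  if (length(out) == 0L) return(empty_breakpoints())
  arrange(list_rbind(out), .data$pos_a)
}

#' Single breakends from long terminal soft-clips
#'
#' A terminal soft-clip longer than `min_clip` whose read end is not covered
#' by any supplementary alignment indicates an adjacency whose far side could
#' not be mapped. One softclip_sbnd breakpoint is emitted at the clip
#' boundary, oriented toward the clipped side, carrying the clipped bases
#' (uppercased) when the record stored its sequence.
#'
#' @param segment One-row segment tibble.
#' @param min_clip Minimum clip length in bp (default 1000; strictly longer).
#' @param other_segments Other segments of the same read (tibble with
#'   `query_start`/`query_end`), used to decide whether a supplementary
#'   alignment accounts for the clip.
#' @return A breakpoint tibble.
#' @export
sbnd_from_softclips <- function(segment, min_clip = 1000,
                                other_segments = NULL) {
  ops <- cigar_ops(segment$cigar)[[1]]
  nops <- nrow(ops)
  lead <- if (ops$op[1] == "S") ops$len[1] else 0L
  trail <- if (ops$op[nops] == "S") ops$len[nops] else 0L
  out <- list()
  qs <- segment$query_start; qe <- segment$query_end

  covered <- function(int_start, int_end) {
    if (is.null(other_segments) || nrow(other_segments) == 0L) return(FALSE)
    any(other_segments$query_start < int_end &
          other_segments$query_end > int_start)
  }
  emit <- function(pos, orientation, right_side) {
    fast_tbl(
      kind = "softclip_sbnd", notation = "SBND",
      contig_a = segment$contig, pos_a = as.integer(pos),
      strand_a = orientation,
      contig_b = NA_character_, pos_b = NA_integer_, strand_b = NA_character_,
      sv_length = 0, span = 0,
      inserted_sequence = toupper(clip_sequence(segment, right_side)),
      read_name = segment$read_name, sample = segment$sample,
      haplotype = segment$haplotype, phase_set = segment$phase_set,
      mapq = segment$mapq
    )
  }

  if (lead > min_clip) {
    # CIGAR-leading clip sits left of the reference start; on the original
    # read it is before query_start (+ strand) or after query_end (- strand)
    int <- if (segment$strand == "+") c(qs - lead, qs) else c(qe, qe + lead)
    if (!covered(int[1], int[2])) {
      out[[length(out) + 1L]] <- emit(segment$start, "-", right_side = FALSE)
    }
  }
  if (trail > min_clip) {
    int <- if (segment$strand == "+") c(qe, qe + trail) else c(qs - trail, qs)
    if (!covered(int[1], int[2])) {
      out[[length(out) + 1L]] <- emit(segment$end, "+", right_side = TRUE)
    }
  }
  if (length(out) == 0L) return(empty_breakpoints())
  list_rbind(out)
}

#' Discover putative breakpoints for one sample
#'
#' Drives per-read discovery over an alignment-record tibble: reads are
#' processed in non-overlapping genome bins keyed by the primary alignment
#' start (so a read is owned by exactly one bin and multi-bin reads are never
#' double-counted), split-read, CIGAR and soft-clip evidence is collected,
#' fold-back artifacts suppressed, and a per-haplotype coverage track built
#' from all records.
#'
#' @param records Alignment-record tibble for one sample (primary rows carry
#'   the `SA` tag; supplementary rows contribute to coverage).
#' @param contig_lengths Named integer vector.
#' @param min_sv_length,merge_gap,foldback_window,min_softclip Discovery
#'   parameters (defaults 30, 30, 200, 1000).
#' @param sbnd_mode Track single breakends (default TRUE).
#' @param supp_mapq_floor MAPQ floor for supplementary entries (default 5).
#' @param normal_length_fraction See [breakpoints_from_cigar()].
#' @param coverage_bin_size Coverage bin size in bp (default 5).
#' @param genome_bin_size Parallelization bin size in bp (default 1e8); the
#'   result is identical for any value.
#' @return A list with `breakpoints` (tibble) and `coverage`
#'   (a `coverage_track`).
#' @export
discover_breakpoints <- function(records, contig_lengths,
                                 min_sv_length = 30, merge_gap = 30,
                                 foldback_window = 200, min_softclip = 1000,
                                 sbnd_mode = TRUE, supp_mapq_floor = 5,
                                 normal_length_fraction = 0.20,
                                 coverage_bin_size = 5,
                                 genome_bin_size = 1e8) {
  validate_alignments(records)
  coverage <- build_coverage(records, contig_lengths,
                             bin_size = coverage_bin_size)
  primaries <- filter(records, !.data$is_supplementary)
  # a record with a plain-match CIGAR and no SA tag cannot yield breakpoints
  informative <- !is.na(primaries$sa_tag) |
    !grepl("^[0-9]+(M|=)$", primaries$cigar)
  primaries <- primaries[informative, ]
  if (nrow(primaries) == 0L) {
    return(list(breakpoints = empty_breakpoints(), coverage = coverage))
  }
  primaries <- primaries |>
    mutate(.bin = paste0(.data$contig, ":",
                         floor(.data$start / genome_bin_size))) |>
    arrange(.data$.bin, .data$start)

  per_read <- function(row) {
    sr <- segments_from_read(row, sbnd_mode = sbnd_mode,
                             supp_mapq_floor = supp_mapq_floor)
    segs <- sr$segments
    bps <- list(sr$sbnd_candidates)
    if (nrow(segs) >= 2L) {
      bps[[length(bps) + 1L]] <- breakpoints_from_split(segs, foldback_window)
    }
    for (j in seq_len(nrow(segs))) {
      bps[[length(bps) + 1L]] <- breakpoints_from_cigar(
        segs[j, ], min_sv_length = min_sv_length, merge_gap = merge_gap,
        sample_role = row$sample,
        normal_length_fraction = normal_length_fraction
      )
      if (sbnd_mode) {
        bps[[length(bps) + 1L]] <- sbnd_from_softclips(
          segs[j, ], min_clip = min_softclip,
          other_segments = segs[-j, ]
        )
      }
    }
    list_rbind(bps)
  }

  bps <- seq_len(nrow(primaries)) |>
    map(function(i) per_read(primaries[i, ])) |>
    list_rbind()
  bps <- arrange(bps, .data$contig_a, .data$pos_a, .data$read_name)
  list(breakpoints = bps, coverage = coverage)
}
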