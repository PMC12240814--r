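# Breakend VCF emission and truth-set parsing.
#
# Orientation convention (shared with discovery): "+" means sequence is
# retained to the LEFT of the breakend and the adjacency continues rightward;
# "-" means sequence is retained to the RIGHT. Internally breakend positions
# are 0-based: a "+" breakend stores the exclusive end of the retained
# segment, a "-" breakend stores its inclusive start. At VCF emission a "+"
# breakend therefore prints POS = pos (1-based last retained base) and a "-"
# breakend prints POS = pos + 1 (1-based first retained base).

vcf_pos_1based <- function(pos, orientation) {
  ifelse(orientation == "-", pos + 1L, pos)
}

vcf_pos_0based <- function(pos1, orientation) {
  ifelse(orientation == "-", pos1 - 1L, pos1)
}

bnd_alt <- function(o1, contig2, pos2_1based, o2) {
  mate <- paste0(contig2, ":", pos2_1based)
  dplyr::case_when(
    o1 == "+" & o2 == "-" ~ paste0("N[", mate, "["),
    o1 == "+" & o2 == "+" ~ paste0("N]", mate, "]"),
    o1 == "-" & o2 == "+" ~ paste0("]", mate, "]N"),
    o1 == "-" & o2 == "-" ~ paste0("[", mate, "[N")
  )
}

#' Write breakpoint clusters as a breakend VCF
#'
#' Paired breakends are emitted as two `SVTYPE=BND` records with reciprocal
#' `MATEID`; insertions as a single record carrying the inserted sequence;
#' single breakends with the `s.`/`.s` ALT syntax and `SVTYPE=SBND`. The
#' `INFO` column carries the classifier label (`CLASS`), the Pan-Cancer
#' notation (`NOTATION`), support counts, allele fraction, and haplotype
#' support when the inputs were phased.
#'
#' @param clusters Finalized (and optionally classified) cluster tibble.
#' @param path Output VCF path.
#' @param metadata Optional named character vector written as extra
#'   `##key=value` header lines (e.g. sample names).
#' @return `path`, invisibly.
#' @export
write_breakpoint_vcf <- function(clusters, path, metadata = NULL) {
  assert_columns(clusters, c("cluster_id", "notation", "contig_a", "pos_a",
                             "strand_a", "contig_b", "pos_b", "strand_b",
                             "tumor_support", "normal_support"),
                 "cluster table")
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) abort(paste0("cannot write VCF, directory missing: ", dirname(path)))

  col_or <- function(name, default) {
    if (name %in% names(clusters)) clusters[[name]] else
      rep(default, nrow(clusters))
  }
  filt <- col_or("filter", "PASS")
  class_lab <- col_or("class_label", NA_character_)
  af <- col_or("tumor_af", NA_real_)
  svlen <- col_or("median_sv_length", NA_real_)
  rescued <- col_or("rescued", FALSE)
  insseq <- col_or("inserted_sequence", NA_character_)
  hp <- if (all(c("tumor_hap1", "tumor_hap2", "tumor_unphased") %in%
                names(clusters))) {
    paste0(clusters$tumor_hap1, ",", clusters$tumor_hap2, ",",
           clusters$tumor_unphased)
  } else rep(NA_character_, nrow(clusters))

  info_common <- function(i, extra = character(0)) {
    parts <- c(
      extra,
      paste0("NOTATION=", clusters$notation[i]),
      paste0("TUMOUR_SUPPORT=", clusters$tumor_support[i]),
      paste0("NORMAL_SUPPORT=", clusters$normal_support[i])
    )
    if (!is.na(af[i])) parts <- c(parts, paste0("AF=", signif(af[i], 6)))
    if (!is.na(svlen[i])) parts <- c(parts, paste0("SVLEN=", round(svlen[i])))
    if (!is.na(class_lab[i])) parts <- c(parts, paste0("CLASS=", class_lab[i]))
    if (isTRUE(rescued[i])) parts <- c(parts, "RESCUED")
    if (!is.na(hp[i])) parts <- c(parts, paste0("TUMOUR_HP=", hp[i]))
    paste(parts, collapse = ";")
  }

  rows <- character(0)
  for (i in seq_len(nrow(clusters))) {
    id <- paste0("SV", clusters$cluster_id[i])
    if (clusters$notation[i] == "INS") {
      pos1 <- clusters$pos_a[i]
      alt <- if (!is.na(insseq[i]) && nzchar(insseq[i])) {
        paste0("N", insseq[i])
      } else "<INS>"
      info <- info_common(i, c("SVTYPE=INS",
                               if (!is.na(insseq[i])) paste0("INSSEQ=", insseq[i])))
      rows <- c(rows, paste(clusters$contig_a[i], pos1, paste0(id, "_1"), "N",
                            alt, ".", filt[i], info, sep = "\t"))
    } else if (clusters$notation[i] == "SBND") {
      o <- clusters$strand_a[i]
      pos1 <- vcf_pos_1based(clusters$pos_a[i], o)
      alt <- if (o == "+") "N." else ".N"
      info <- info_common(i, "SVTYPE=SBND")
      rows <- c(rows, paste(clusters$contig_a[i], pos1, paste0(id, "_1"), "N",
                            alt, ".", filt[i], info, sep = "\t"))
    } else {
      o1 <- clusters$strand_a[i]; o2 <- clusters$strand_b[i]
      p1 <- vcf_pos_1based(clusters$pos_a[i], o1)
      p2 <- vcf_pos_1based(clusters$pos_b[i], o2)
      id1 <- paste0(id, "_1"); id2 <- paste0(id, "_2")
      info1 <- info_common(i, c("SVTYPE=BND", paste0("MATEID=", id2)))
      info2 <- info_common(i, c("SVTYPE=BND", paste0("MATEID=", id1)))
      rows <- c(rows,
        paste(clusters$contig_a[i], p1, id1, "N",
              bnd_alt(o1, clusters$contig_b[i], p2, o2), ".", filt[i], info1,
              sep = "\t"),
        paste(clusters$contig_b[i], p2, id2, "N",
              bnd_alt(o2, clusters$contig_a[i], p1, o1), ".", filt[i], info2,
              sep = "\t"))
    }
  }

  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(metadata)) paste0("##", names(metadata), "=", metadata),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV class (BND/INS/SBND)\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "##INFO=<ID=NOTATION,Number=1,Type=String,Description=\"Breakpoint notation (+-/-+/++/--/INS/SBND)\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Classifier prediction (somatic/noise)\">",
    "##INFO=<ID=TUMOUR_SUPPORT,Number=1,Type=Integer,Description=\"Tumour supporting reads\">",
    "##INFO=<ID=NORMAL_SUPPORT,Number=1,Type=Integer,Description=\"Normal supporting reads\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Tumour allele fraction\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Median SV length\">",
    "##INFO=<ID=INSSEQ,Number=1,Type=String,Description=\"Inserted sequence\">",
    "##INFO=<ID=RESCUED,Number=0,Type=Flag,Description=\"Rescued at a copy-number changepoint\">",
    "##INFO=<ID=TUMOUR_HP,Number=3,Type=Integer,Description=\"Tumour haplotype support (hap1,hap2,unphased)\">",
    "##FILTER=<ID=LIKELY_NOISE,Description=\"Predicted noise by the classifier\">",
    "##FILTER=<ID=LOW_SUPPORT,Description=\"Fewer supporting reads than the minimum\">",
    "##FILTER=<ID=LOW_AF,Description=\"Allele fraction below the minimum\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  writeLines(c(header, rows), path)
  invisible(path)
}

parse_info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

#' Read an SV truth/call VCF into a normalized breakend set
#'
#' Accepts both dialects: per-breakend `BND` records (bracketed ALT) and
#' single-line symbolic records (`SVTYPE` + `END`), which are expanded to two
#' breakends (deletion `(+,-)`, duplication `(-,+)`, inversion `(+,+)`)
#' except insertions, which stay single records. Positions are returned
#' 0-based under the package's orientation convention, so a write/read round
#' trip through [write_breakpoint_vcf()] is exact.
#'
#' @param path VCF path.
#' @return A tibble with one row per breakend: `contig`, `pos` (0-based),
#'   `orientation`, `type`, `event_id`, `record_id`, `filter`.
#' @export
read_truth_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  lines <- readLines(path)
  body_idx <- which(!grepl("^#", lines) & nzchar(lines))
  out <- list()
  for (k in body_idx) {
    f <- strsplit(lines[k], "\t")[[1]]
    if (length(f) < 8) {
      abort(paste0("malformed VCF record (fewer than 8 fields) at line ", k))
    }
    pos1 <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos1)) abort(paste0("malformed VCF POS at line ", k))
    contig <- f[1]; id <- f[3]; alt <- f[5]; filt <- f[7]; info <- f[8]
    svtype <- parse_info_field(info, "SVTYPE")

    bnd <- regmatches(alt, regexec(
      "^([ACGTNacgtn]*)([][])([^][]+):([0-9]+)([][])([ACGTNacgtn]*)$",
      alt))[[1]]
    if (length(bnd) == 7 && (nzchar(bnd[2]) || nzchar(bnd[7]))) {
      o1 <- if (nzchar(bnd[2])) "+" else "-"
      mate_id <- parse_info_field(info, "MATEID")
      event <- if (!is.na(mate_id)) {
        paste(sort(c(id, mate_id)), collapse = "|")
      } else id
      out[[length(out) + 1L]] <- tibble(
        contig = contig, pos = vcf_pos_0based(pos1, o1), orientation = o1,
        type = "BND", event_id = event, record_id = id, filter = filt
      )
    } else if (alt %in% c("N.", ".N") || grepl("^[ACGTN]+\\.$|^\\.[ACGTN]+$", alt)) {
      o1 <- if (grepl("\\.$", alt)) "+" else "-"
      out[[length(out) + 1L]] <- tibble(
        contig = contig, pos = vcf_pos_0based(pos1, o1), orientation = o1,
        type = "SBND", event_id = id, record_id = id, filter = filt
      )
    } else if (identical(svtype, "INS") || grepl("^<INS", alt) ||
               (!is.na(svtype) && svtype == "INS")) {
      out[[length(out) + 1L]] <- tibble(
        contig = contig, pos = pos1, orientation = NA_character_,
        type = "INS", event_id = id, record_id = id, filter = filt
      )
    } else if (!is.na(svtype) || grepl("^<", alt)) {
      type <- svtype %||% gsub("[<>]", "", alt)
      if (is.na(type)) type <- gsub("[<>]", "", alt)
      end1 <- suppressWarnings(as.integer(parse_info_field(info, "END")))
      if (is.na(end1)) abort(paste0("symbolic SV record without END at line ", k))
      ors <- switch(type,
        DEL = c("+", "-"), DUP = c("-", "+"), INV = c("+", "+"),
        c("+", "-")
      )
      out[[length(out) + 1L]] <- tibble(
        contig = contig,
        pos = c(vcf_pos_0based(pos1, ors[1]),
                vcf_pos_0based(end1, ors[2])),
        orientation = ors, type = type,
        event_id = id, record_id = paste0(id, c("_1", "_2")), filter = filt
      )
    } else if (nchar(f[4]) != nchar(alt) && grepl("^[ACGTNacgtn]+$", alt)) {
      # sequence-resolved insertion written as REF/ALT alleles
      out[[length(out) + 1L]] <- tibble(
        contig = contig, pos = pos1, orientation = NA_character_,
        type = "INS", event_id = id, record_id = id, filter = filt
      )
    } else {
      abort(paste0("unrecognized SV record at line ", k))
    }
  }
  if (length(out) == 0L) {
    return(tibble(contig = character(), pos = integer(),
                  orientation = character(), type = character(),
                  event_id = character(), record_id = character(),
                  filter = character()))
  }
  list_rbind(out)
}
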