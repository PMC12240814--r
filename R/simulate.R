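# Seeded synthetic data: toy genomes, SV-bearing alignment records with
# artifact injection, and copy-number/BAF profiles with known purity and
# ploidy. Alignments are synthesized directly as records (CIGAR + SA tags)
# rather than via read simulation and alignment: the tests target the caller,
# not the aligner, and stay at desk scale. Every generator is a pure function
# of (config, seed).

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a simulation configuration
#'
#' Defaults describe the study conditions the generators emulate: ~30x
#' long-read coverage with 3-8 kb reads, clonal SVs at a target allele
#' fraction, fold-back artifacts at a configurable per-read rate, clustered
#' sub-/near-threshold indel noise at microsatellite-like loci, and a
#' copy-number/BAF layer parameterized by integer total/minor copies, purity
#' and ploidy.
#'
#' @param seed Integer seed.
#' @param contigs Named integer vector of contig lengths.
#' @param svs SV table (see [make_worked_example()] for the column contract:
#'   `id`, `type`, `contig`, `pos`, `contig2`, `pos2`, `length`, `af`,
#'   `haplotype`, `germline`).
#' @param depth Haploid-genome read depth (default 30).
#' @param read_length Length range of simulated reads (default 3000-8000).
#' @param foldback_rate Fold-back artifact reads per background read
#'   (default 0).
#' @param microsat_loci Optional tibble (`contig`, `pos`) of noisy indel loci.
#' @param cn_profile Tibble (`contig`, `start`, `end`, `total_cn`,
#'   `minor_cn`).
#' @param purity,ploidy Purity in (0,1] and the profile's expected ploidy.
#' @param bin_size,bin_depth,log2r_sd Copy-number layer: bin width, expected
#'   normal count per 10 kb bin, lognormal log2R noise (defaults 10000, 100,
#'   0.1).
#' @param snp_spacing,snp_depth Heterozygous SNP spacing in bp and mean
#'   pileup depth (defaults 2000, 30).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       contigs = c(chrA = 8e5, chrB = 6e5),
                       svs = NULL,
                       depth = 30,
                       read_length = c(3000, 8000),
                       foldback_rate = 0,
                       microsat_loci = NULL,
                       cn_profile = NULL,
                       purity = 0.6, ploidy = 2,
                       bin_size = 10000, bin_depth = 100, log2r_sd = 0.1,
                       snp_spacing = 2000, snp_depth = 30) {
  structure(
    list(seed = seed, contigs = contigs, svs = svs, depth = depth,
         read_length = read_length, foldback_rate = foldback_rate,
         microsat_loci = microsat_loci, cn_profile = cn_profile,
         purity = purity, ploidy = ploidy, bin_size = bin_size,
         bin_depth = bin_depth, log2r_sd = log2r_sd,
         snp_spacing = snp_spacing, snp_depth = snp_depth),
    class = "sim_config"
  )
}

new_records <- function(read_name, contig, start, cigar, strand = "+",
                        mapq = 60, is_supplementary = FALSE,
                        haplotype = NA_integer_, phase_set = NA_integer_,
                        sample = "tumor", seq = NA_character_,
                        sa_tag = NA_character_) {
  fast_tbl(
    read_name = read_name, contig = contig, start = as.integer(start),
    end = as.integer(start + cigar_ref_len(cigar)), strand = strand,
    mapq = as.integer(mapq), cigar = cigar,
    is_supplementary = is_supplementary,
    haplotype = as.integer(haplotype), phase_set = as.integer(phase_set),
    sample = sample, seq = seq, sa_tag = sa_tag
  )
}

background_reads <- function(config, sample_role, prefix) {
  out <- imap(as.list(config$contigs), function(len, ctg) {
    rl_mean <- mean(config$read_length)
    n <- round(config$depth * len / rl_mean)
    rl <- pmin(round(runif(n, config$read_length[1], config$read_length[2])),
               len - 1L)
    start <- floor(runif(n, 0, len - rl))
    hap <- sample(c(1L, 2L, NA_integer_), n, replace = TRUE,
                  prob = c(0.45, 0.45, 0.10))
    new_records(
      read_name = paste0(prefix, "_", ctg, "_bg", seq_len(n)),
      contig = ctg, start = start, cigar = paste0(rl, "M"),
      haplotype = hap, phase_set = ifelse(is.na(hap), NA_integer_, 1L),
      sample = sample_role
    )
  })
  list_rbind(out)
}

# Evidence records for one supporting read of one SV. Returns 1-2 record
# rows; split evidence alternates with gapped evidence for deletions.
sv_read_records <- function(sv, idx, sample_role, prefix) {
  a <- sample(800:2000, 1L)
  b <- sample(800:2000, 1L)
  d <- sample(-2:2, 1L)
  name <- paste0(prefix, "_", sv$id, "_r", idx)
  hap <- sv$haplotype
  ps <- 1L
  mk <- function(...) new_records(..., haplotype = hap, phase_set = ps,
                                  sample = sample_role)
  type <- sv$type
  if (type == "DEL" && idx %% 2L == 1L) {
    # gapped evidence
    return(mk(name, sv$contig, sv$pos + d - a,
              paste0(a, "M", sv$length, "D", b, "M")))
  }
  if (type == "DEL" || type == "TRA") {
    c2 <- if (type == "TRA") sv$contig2 else sv$contig
    p2 <- if (type == "TRA") sv$pos2 + d else sv$pos + d + sv$length
    sa <- paste0(c2, ",", p2 + 1L, ",+,", a, "S", b, "M,60,0;")
    prim <- mk(name, sv$contig, sv$pos + d - a, paste0(a, "M", b, "S"),
               sa_tag = sa)
    supp <- new_records(name, c2, p2, paste0(a, "S", b, "M"),
                        is_supplementary = TRUE, haplotype = hap,
                        phase_set = ps, sample = sample_role)
    return(bind_rows(prim, supp))
  }
  if (type == "DUP") {
    # read runs off the unit end and re-enters at the unit start
    sa <- paste0(sv$contig, ",", sv$pos + d + 1L, ",+,", a, "S", b, "M,60,0;")
    prim <- mk(name, sv$contig, sv$pos2 + d - a, paste0(a, "M", b, "S"),
               sa_tag = sa)
    supp <- new_records(name, sv$contig, sv$pos + d, paste0(a, "S", b, "M"),
                        is_supplementary = TRUE, haplotype = hap,
                        phase_set = ps, sample = sample_role)
    return(bind_rows(prim, supp))
  }
  if (type == "INV_PP") {
    sa <- paste0(sv$contig, ",", sv$pos2 + d - b + 1L, ",-,",
                 b, "M", a, "S,60,0;")
    prim <- mk(name, sv$contig, sv$pos + d - a, paste0(a, "M", b, "S"),
               sa_tag = sa)
    supp <- new_records(name, sv$contig, sv$pos2 + d - b,
                        paste0(b, "M", a, "S"), strand = "-",
                        is_supplementary = TRUE, haplotype = hap,
                        phase_set = ps, sample = sample_role)
    return(bind_rows(prim, supp))
  }
  if (type == "INV_MM") {
    sa <- paste0(sv$contig, ",", sv$pos2 + d + 1L, ",+,",
                 a, "S", b, "M,60,0;")
    prim <- mk(name, sv$contig, sv$pos + d, paste0(b, "S", a, "M"),
               strand = "-", sa_tag = sa)
    supp <- new_records(name, sv$contig, sv$pos2 + d, paste0(a, "S", b, "M"),
                        is_supplementary = TRUE, haplotype = hap,
                        phase_set = ps, sample = sample_role)
    return(bind_rows(prim, supp))
  }
  if (type == "INS") {
    dd <- sample(-10:10, 1L)
    seq <- random_bases(a + sv$length + b)
    return(mk(name, sv$contig, sv$pos + dd - a,
              paste0(a, "M", sv$length, "I", b, "M"), seq = seq))
  }
  if (type == "SBND") {
    clip <- 1500L
    return(mk(name, sv$contig, sv$pos + d - a, paste0(a, "M", clip, "S"),
              seq = random_bases(a + clip)))
  }
  abort(paste0("unknown SV type: ", type))
}

foldback_reads <- function(config, n, sample_role, prefix) {
  if (n == 0L) return(empty_alignments())
  out <- map(seq_len(n), function(i) {
    ctg <- sample(names(config$contigs), 1L)
    len <- config$contigs[[ctg]]
    s <- floor(runif(1, 2000, len - 2000))
    name <- paste0(prefix, "_fb", i)
    sa <- paste0(ctg, ",", s + 41L, ",-,710M800S,60,0;")
    bind_rows(
      new_records(name, ctg, s, "800M710S", sample = sample_role, sa_tag = sa),
      new_records(name, ctg, s + 40L, "710M800S", strand = "-",
                  is_supplementary = TRUE, sample = sample_role)
    )
  })
  list_rbind(out)
}

microsat_reads <- function(loci, sample_role, prefix) {
  if (is.null(loci) || nrow(loci) == 0L) return(empty_alignments())
  out <- map(seq_len(nrow(loci)), function(i) {
    n <- sample(1:2, 1L)
    recs <- map(seq_len(n), function(k) {
      a <- sample(600:1500, 1L)
      b <- sample(600:1500, 1L)
      dl <- sample(32:55, 1L)
      d <- round(rnorm(1, 0, 8))
      new_records(paste0(prefix, "_ms", i, "_", k), loci$contig[i],
                  loci$pos[i] + d - a, paste0(a, "M", dl, "D", b, "M"),
                  mapq = sample(20:40, 1L), sample = sample_role)
    })
    list_rbind(recs)
  })
  list_rbind(out)
}

sv_truth_breakends <- function(svs) {
  out <- map(seq_len(nrow(svs)), function(i) {
    sv <- svs[i, ]
    switch(sv$type,
      DEL = tibble(contig = sv$contig, pos = c(sv$pos, sv$pos + sv$length),
                   orientation = c("+", "-"), type = "BND", event_id = sv$id),
      DUP = tibble(contig = sv$contig, pos = c(sv$pos, sv$pos2),
                   orientation = c("-", "+"), type = "BND", event_id = sv$id),
      INV_PP = tibble(contig = sv$contig, pos = c(sv$pos, sv$pos2),
                      orientation = c("+", "+"), type = "BND",
                      event_id = sv$id),
      INV_MM = tibble(contig = sv$contig, pos = c(sv$pos, sv$pos2),
                      orientation = c("-", "-"), type = "BND",
                      event_id = sv$id),
      TRA = tibble(contig = c(sv$contig, sv$contig2),
                   pos = c(sv$pos, sv$pos2),
                   orientation = c("+", "-"), type = "BND",
                   event_id = sv$id),
      INS = tibble(contig = sv$contig, pos = sv$pos,
                   orientation = NA_character_, type = "INS",
                   event_id = sv$id),
      SBND = tibble(contig = sv$contig, pos = sv$pos, orientation = "+",
                    type = "SBND", event_id = sv$id)
    )
  })
  list_rbind(out)
}

#' Simulate SV-bearing tumor/normal alignment records
#'
#' Implements each truth SV as split and/or gapped alignment evidence in the
#' expected orientations at its target allele fraction (supporting-read count
#' = `round(af * depth)`, so the fixture is unambiguous), places germline SVs
#' in both samples, injects fold-back artifact read pairs at the configured
#' per-read rate and clustered sub-/near-threshold deletion noise at
#' microsatellite-like loci, and assigns HP/PS tags consistently with a
#' simulated diplotype (SV-supporting reads ride the SV's haplotype).
#'
#' @param config A [sim_config()].
#' @return List with `tumor` and `normal` record tibbles, `truth` (the SV
#'   table with a `planted_support` column) and `truth_breakends`.
#' @export
simulate_sv_alignments <- function(config) {
  set.seed(config$seed)
  svs <- config$svs
  tumor <- list(background_reads(config, "tumor", "t"))
  normal <- list(background_reads(config, "normal", "n"))
  planted <- integer(nrow(svs) %||% 0L)
  if (!is.null(svs) && nrow(svs) > 0L) {
    for (i in seq_len(nrow(svs))) {
      sv <- svs[i, ]
      n_sup <- max(1L, round(sv$af * config$depth))
      planted[i] <- n_sup
      tumor[[length(tumor) + 1L]] <-
        map(seq_len(n_sup), function(k) sv_read_records(sv, k, "tumor", "t")) |>
        list_rbind()
      if (isTRUE(sv$germline)) {
        # support in the normal may differ from the tumor side (depth and
        # sampling differences); an optional normal_af column controls it
        naf <- if ("normal_af" %in% names(sv) && !is.na(sv$normal_af)) {
          sv$normal_af
        } else sv$af
        n_sup_n <- max(1L, round(naf * config$depth))
        normal[[length(normal) + 1L]] <-
          map(seq_len(n_sup_n), function(k) sv_read_records(sv, k, "normal", "n")) |>
          list_rbind()
      }
    }
  }
  if (config$foldback_rate > 0) {
    n_bg <- nrow(tumor[[1]])
    n_fb <- rbinom(1L, n_bg, config$foldback_rate)
    tumor[[length(tumor) + 1L]] <- foldback_reads(config, n_fb, "tumor", "t")
  }
  tumor[[length(tumor) + 1L]] <- microsat_reads(config$microsat_loci,
                                                "tumor", "t")
  normal[[length(normal) + 1L]] <- microsat_reads(config$microsat_loci,
                                                  "normal", "n")
  truth <- if (!is.null(svs)) mutate(svs, planted_support = planted) else NULL
  list(
    tumor = arrange(list_rbind(tumor), .data$contig, .data$start),
    normal = arrange(list_rbind(normal), .data$contig, .data$start),
    truth = truth,
    truth_breakends = if (!is.null(svs)) sv_truth_breakends(svs) else NULL
  )
}

#' Simulate a copy-number bin table and SNP BAF table
#'
#' Inverts the method's own model: with purity rho and a profile of integer
#' total/minor copies, the expected bin ratio is
#' `r = (rho * CN + 2(1 - rho)) / (rho * psi + 2(1 - rho))` (psi the
#' size-weighted mean total copy number), tumor counts are
#' `bin_depth * r` with lognormal noise, normal counts are `bin_depth`; and
#' each heterozygous SNP draws `alt_count ~ Binomial(depth, BAF)` with
#' `BAF = (rho * n_b + (1 - rho)) / (rho * n_T + 2(1 - rho))`, the B allele
#' assigned to a random parent per site.
#'
#' @param config A [sim_config()] with a `cn_profile`.
#' @return List with `bins` (counted bin tibble), `baf` (SNP observation
#'   tibble) and `truth` (changepoints, purity, ploidy, profile).
#' @export
simulate_cn_data <- function(config) {
  set.seed(config$seed + 1L)
  profile <- config$cn_profile
  if (is.null(profile)) abort("config$cn_profile is required")
  rho <- config$purity
  psi <- sum((profile$end - profile$start) * profile$total_cn) /
    sum(profile$end - profile$start)
  denom <- rho * psi + 2 * (1 - rho)

  bins <- build_bins(config$contigs, bin_size = config$bin_size)
  mid <- (bins$start + bins$end) / 2
  seg_idx <- vapply(seq_len(nrow(bins)), function(i) {
    hit <- which(profile$contig == bins$contig[i] & profile$start <= mid[i] &
                   profile$end > mid[i])
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  cn <- profile$total_cn[seg_idx]
  r <- (rho * cn + 2 * (1 - rho)) / denom
  width_scale <- (bins$end - bins$start) / config$bin_size
  bins$tumor_count <- as.integer(round(
    config$bin_depth * width_scale * r * 2^rnorm(nrow(bins), 0, config$log2r_sd)))
  bins$normal_count <- as.integer(round(config$bin_depth * width_scale))

  # heterozygous SNPs on a regular-ish grid
  snp <- imap(as.list(config$contigs), function(len, ctg) {
    pos <- seq(config$snp_spacing, len - 1, by = config$snp_spacing) +
      sample(-500:500, size = length(seq(config$snp_spacing, len - 1,
                                         by = config$snp_spacing)),
             replace = TRUE)
    tibble(contig = ctg, position = as.integer(sort(pmax(pos, 1))))
  }) |> list_rbind()
  sidx <- vapply(seq_len(nrow(snp)), function(i) {
    hit <- which(profile$contig == snp$contig[i] &
                   profile$start < snp$position[i] &
                   profile$end >= snp$position[i])
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  snp <- snp[!is.na(sidx), ]
  sidx <- sidx[!is.na(sidx)]
  n_t <- profile$total_cn[sidx]
  n_minor <- profile$minor_cn[sidx]
  # the B (alt) allele sits on a random parent per site
  flip <- runif(nrow(snp)) < 0.5
  n_b <- ifelse(flip, n_minor, n_t - n_minor)
  baf_true <- (rho * n_b + (1 - rho)) / (rho * n_t + 2 * (1 - rho))
  rel_depth <- (rho * n_t + 2 * (1 - rho)) / denom
  depth <- pmax(rpois(nrow(snp), config$snp_depth * rel_depth), 1L)
  alt <- rbinom(nrow(snp), depth, baf_true)
  baf <- snp |>
    mutate(ref_count = depth - alt, alt_count = alt, depth = depth,
           baf = alt / depth)

  changepoints <- profile |>
    group_by(.data$contig) |>
    reframe(pos = head(.data$end, -1L))
  list(
    bins = bins,
    baf = baf,
    truth = list(changepoints = changepoints, purity = rho, ploidy = psi,
                 profile = profile)
  )
}

#' The worked-example fixture
#'
#' A deterministic toy tumor-normal pair on two contigs (800 kb + 600 kb):
#' 12 somatic SVs spanning every notation class — deletions (split and
#' gapped), duplications, head-to-head and tail-to-tail inversion junctions,
#' interchromosomal junctions, one insertion and one single breakend — at
#' allele fractions 0.3-1.0 and 30x depth, plus two germline deletions; and a
#' matching copy-number/BAF layer at purity 0.6 with a size-weighted mean
#' ploidy of exactly 2.0 whose loss-of-heterozygosity blocks support purity
#' estimation at a 100 kb block size. Rebuilt at run time from the seed; all
#' generators are pure.
#'
#' @param seed Integer seed (default 1).
#' @return List with `config`, `tumor`, `normal`, `truth`,
#'   `truth_breakends`, `cn` (from [simulate_cn_data()]), `contig_lengths`
#'   and `block_size`.
#' @export
make_worked_example <- function(seed = 1) {
  contigs <- c(chrA = 8e5, chrB = 6e5)
  svs <- tibble(
    id = paste0("sv", 1:12),
    type = c("DEL", "DEL", "DEL", "DUP", "DUP", "INV_PP", "INV_MM",
             "TRA", "TRA", "INS", "SBND", "DEL"),
    contig = c("chrA", "chrA", "chrB", "chrA", "chrB", "chrA", "chrB",
               "chrA", "chrB", "chrA", "chrB", "chrB"),
    pos = c(50000L, 150000L, 80000L, 250000L, 160000L, 350000L, 240000L,
            450000L, 320000L, 550000L, 400000L, 480000L),
    contig2 = c(NA, NA, NA, "chrA", "chrB", "chrA", "chrB", "chrB", "chrA",
                NA, NA, NA),
    pos2 = c(NA, NA, NA, 258000L, 168000L, 356000L, 246000L, 520000L,
             650000L, NA, NA, NA),
    length = c(5000L, 300L, 1200L, NA, NA, NA, NA, NA, NA, 150L, NA, 80L),
    # clonal to near-clonal fractions: a fair-coin replicate split of
    # round(af * 30) supporting reads then keeps >= 3 reads on both sides
    # with high probability, so the fixture is decisive at half depth too
    af = c(1.0, 0.7, 0.6, 0.8, 0.7, 0.6, 0.65, 0.7, 0.6, 0.7, 0.6, 0.65),
    haplotype = rep(1L, 12),
    germline = rep(FALSE, 12)
  )
  germline <- tibble(
    id = c("germ1", "germ2"),
    type = c("DEL", "DEL"),
    contig = c("chrA", "chrB"),
    pos = c(700000L, 60000L),
    contig2 = c(NA_character_, NA_character_),
    pos2 = c(NA_integer_, NA_integer_),
    length = c(2000L, 400L),
    af = c(0.5, 0.5),
    haplotype = c(2L, 1L),
    germline = c(TRUE, TRUE)
  )
  # size-weighted mean total copy number is exactly 2.0; ten pure
  # copy-number-neutral LOH blocks of 100 kb anchor the purity estimate, and
  # the CN 1 / CN 3 segments make purity identifiable in the grid search
  cn_profile <- tibble(
    contig = c("chrA", "chrA", "chrA", "chrB", "chrB"),
    start = c(0, 1e5, 6e5, 0, 5e5),
    end = c(1e5, 6e5, 8e5, 5e5, 6e5),
    total_cn = c(1L, 2L, 3L, 2L, 1L),
    minor_cn = c(0L, 0L, 1L, 0L, 0L)
  )
  config <- sim_config(
    seed = seed, contigs = contigs, svs = bind_rows(svs, germline),
    depth = 30, cn_profile = cn_profile, purity = 0.6, ploidy = 2,
    bin_size = 10000, bin_depth = 100, log2r_sd = 0.05,
    snp_spacing = 2000, snp_depth = 30
  )
  sim <- simulate_sv_alignments(config)
  cn <- simulate_cn_data(config)
  list(
    config = config,
    tumor = sim$tumor, normal = sim$normal,
    truth = sim$truth,
    truth_breakends = sim$truth_breakends,
    somatic_truth_breakends = filter(sim$truth_breakends,
                                     !.data$event_id %in% germline$id),
    cn = cn,
    contig_lengths = contigs,
    block_size = 1e5
  )
}

# A randomized SV table for classifier training corpora. Events sit on
# disjoint 20 kb slots so that clusters of different events (and the
# microsatellite noise loci between them) never co-cluster and training
# labels stay clean.
random_sv_table <- function(n_somatic, n_germline, contigs) {
  types <- c("DEL", "DUP", "INV_PP", "INV_MM", "TRA", "INS", "SBND")
  n <- n_somatic + n_germline
  slots <- purrr::imap(as.list(contigs), function(len, cg) {
    tibble(contig = cg, pos = seq(3e4, len - 5e4, by = 2e4))
  }) |> list_rbind()
  slots <- slots[sample(nrow(slots)), ]
  if (n + n > nrow(slots)) abort("not enough slots for the requested SV count")
  take <- slots[seq_len(n), ]
  pool2 <- slots[(n + 1):nrow(slots), ]
  type <- c(sample(types, n_somatic, replace = TRUE),
            sample(c("DEL", "DUP", "INS"), n_germline, replace = TRUE))
  span <- as.integer(round(runif(n, 4000, 15000)))
  # interchromosomal mates take further slots on the other contig
  contig2 <- rep(NA_character_, n)
  pos2 <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (type[i] == "TRA") {
      cand <- which(pool2$contig != take$contig[i])
      contig2[i] <- pool2$contig[cand[1]]
      pos2[i] <- as.integer(pool2$pos[cand[1]])
      pool2 <- pool2[-cand[1], ]
    } else if (type[i] %in% c("DUP", "INV_PP", "INV_MM")) {
      contig2[i] <- take$contig[i]
      pos2[i] <- as.integer(take$pos[i] + span[i])
    }
  }
  tibble(
    id = paste0(c(rep("som", n_somatic), rep("germ", n_germline)), seq_len(n)),
    type = type,
    contig = take$contig,
    pos = as.integer(take$pos),
    contig2 = contig2,
    pos2 = pos2,
    length = ifelse(type == "DEL",
                    as.integer(round(runif(n, 50, 8000))),
                    ifelse(type == "INS",
                           as.integer(round(runif(n, 40, 400))),
                           NA_integer_)),
    af = round(runif(n, 0.2, 1.0), 2),
    normal_af = round(runif(n, 0.05, 1.0), 2),
    haplotype = sample(1:2, n, replace = TRUE),
    germline = c(rep(FALSE, n_somatic), rep(TRUE, n_germline))
  )
}

#' Build a labeled training corpus and fit the default classifier
#'
#' Simulates a paired tumor-normal genome carrying a mix of somatic SVs
#' (positive class), germline SVs (present in the matched normal, hence
#' noise) and clustered microsatellite-like indel noise, runs discovery,
#' clustering and feature encoding, labels clusters against the simulation
#' truth with [build_training_labels()], and trains the random forest. This
#' is the model used by [run_pipeline()] when none is supplied.
#'
#' @param seed Integer seed.
#' @return For [fit_default_model()] an `sv_classifier`; for
#'   [fit_default_conformal()] an `sv_conformal`; for
#'   [training_corpus_features()] a list with `features` and `labels`.
#' @export
fit_default_model <- function(seed = 1) {
  corpus <- training_corpus_features(seed)
  train_classifier(corpus$features, corpus$labels, seed = seed)
}

#' @rdname fit_default_model
#' @export
fit_default_conformal <- function(seed = 1) {
  corpus <- training_corpus_features(seed)
  mcp_calibrate(corpus$features, corpus$labels, seed = seed)
}

#' @rdname fit_default_model
#' @export
training_corpus_features <- function(seed = 1) {
  contigs <- c(trA = 1e6, trB = 8e5)
  set.seed(seed + 7L)
  svs <- random_sv_table(24, 12, contigs)
  # microsatellite-like noise loci midway between SV slots
  used <- unique(c(paste0(svs$contig, "/", svs$pos),
                   paste0(svs$contig2, "/", svs$pos2)))
  all_slots <- purrr::imap(as.list(contigs), function(len, cg) {
    tibble(contig = cg, pos = seq(3e4, len - 5e4, by = 2e4))
  }) |> purrr::list_rbind()
  free <- all_slots[!paste0(all_slots$contig, "/", all_slots$pos) %in% used, ]
  free <- free[sample(nrow(free)), ]
  microsat <- head(free, 40) |> mutate(pos = as.integer(.data$pos + 1e4))
  config <- sim_config(seed = seed + 11L, contigs = contigs, svs = svs,
                       depth = 30, microsat_loci = microsat)
  sim <- simulate_sv_alignments(config)
  dt <- discover_breakpoints(sim$tumor, contigs)
  dn <- discover_breakpoints(sim$normal, contigs)
  clusters <- cluster_breakpoints(bind_rows(dt$breakpoints, dn$breakpoints))
  feats <- encode_features(clusters, dt$coverage, dn$coverage,
                           normal_breakpoints = dn$breakpoints)
  labeled <- build_training_labels(clusters, feats,
                                   filter(sim$truth_breakends,
                                          !sim$truth$germline[
                                            match(.data$event_id,
                                                  sim$truth$id)]))
  keep <- !is.na(labeled$label)
  list(features = feats[keep, ], labels = labeled$label[keep])
}

#' Copy-number genome configuration for the recovery cohort
#'
#' Builds a two-contig (2 x 1.5 Mb) genome whose integer copy-number profile
#' has a size-weighted mean total copy number equal to the requested ploidy
#' (supported targets 1.8, 2.0, 3.1 and 4.0), always including 1.2 Mb of
#' copy-number-neutral LOH — the signal the purity estimator keys on, and a
#' widespread feature of real tumor genomes. Used by the parameter-recovery
#' experiments: simulate with [simulate_cn_data()], then re-fit with
#' [fit_purity_ploidy()].
#'
#' @param purity True tumor purity.
#' @param ploidy One of 1.8, 2.0, 3.1, 4.0.
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
cn_genome_config <- function(purity, ploidy, seed = 1) {
  key <- sprintf("%.1f", ploidy)
  # the two most frequent states are always one copy apart, as in real
  # aneuploid genomes, and >= 1 Mb of copy-number-neutral LOH anchors purity
  seg <- switch(key,
    "1.8" = list(cn = c(2L, 2L, 1L, 2L, 2L, 1L),
                 minor = c(0L, 1L, 0L, 1L, 0L, 0L),
                 len = c(6e5, 6e5, 3e5, 6e5, 6e5, 3e5)),
    "2.0" = list(cn = c(2L, 2L, 1L, 2L, 2L, 3L),
                 minor = c(0L, 1L, 0L, 1L, 0L, 1L),
                 len = c(6e5, 6e5, 3e5, 6e5, 6e5, 3e5)),
    "3.1" = list(cn = c(2L, 3L, 4L, 2L, 4L, 3L),
                 minor = c(0L, 1L, 1L, 0L, 1L, 1L),
                 len = c(6e5, 7e5, 7e5, 6e5, 8e5, 6e5)),
    "4.0" = list(cn = c(2L, 4L, 5L, 2L, 5L, 4L),
                 minor = c(0L, 2L, 2L, 0L, 2L, 1L),
                 len = c(5e5, 6e5, 9e5, 5e5, 9e5, 6e5)),
    abort("supported ploidy targets: 1.8, 2.0, 3.1, 4.0")
  )
  csize <- sum(seg$len) / 2
  contigs <- c(cnA = csize, cnB = csize)
  ctg <- rep(c("cnA", "cnB"), each = 3L)
  ends <- as.numeric(unlist(tapply(seg$len, ctg, cumsum)))
  starts <- ends - seg$len
  profile <- tibble(contig = ctg, start = starts, end = ends,
                    total_cn = seg$cn, minor_cn = seg$minor)
  sim_config(seed = seed, contigs = contigs, cn_profile = profile,
             purity = purity, ploidy = ploidy,
             bin_size = 10000, bin_depth = 100, log2r_sd = 0.1,
             snp_spacing = 2000, snp_depth = 30)
}

#' Germline-only fixture for replicate specificity experiments
#'
#' Simulates an artifact-free normal sample: background reads plus a few
#' heterozygous germline deletions and duplications, no somatic events and no
#' injected artifacts. Splitting it into two replicates with
#' [split_replicates()] and running one as "tumor" against the other
#' quantifies an SV caller's false-positive rate: an algorithm with optimal
#' specificity reports zero somatic PASS calls.
#'
#' @param seed Integer seed.
#' @param depth Read depth (default 40).
#' @return List with `records` (alignment tibble, `sample = "normal"`) and
#'   `contig_lengths`.
#' @export
make_normal_fixture <- function(seed = 1, depth = 40) {
  contigs <- c(nfA = 3e5)
  svs <- tibble(
    id = c("g1", "g2", "g3"),
    type = c("DEL", "DUP", "DEL"),
    contig = "nfA",
    pos = c(60000L, 140000L, 220000L),
    contig2 = c(NA, "nfA", NA),
    pos2 = c(NA, 146000L, NA),
    length = c(800L, NA, 2500L),
    af = c(0.5, 0.5, 1.0),
    haplotype = c(1L, 2L, 1L),
    germline = TRUE
  )
  config <- sim_config(seed = seed, contigs = contigs, svs = svs,
                       depth = depth)
  sim <- simulate_sv_alignments(config)
  records <- mutate(sim$normal, sample = "normal")
  list(records = records, contig_lengths = contigs)
}
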