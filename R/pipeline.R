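# End-to-end orchestration: discovery -> clustering -> classification (+
# conformal confidence) -> copy number -> purity/ploidy -> changepoint rescue
# -> VCF/table emission.

#' Default pipeline parameters
#'
#' All tunables of the paired/tumor-only pipelines with their defaults:
#' mapping-quality gate 5 (normal leniency 0.5), minimum SV length 30 bp
#' (normal reduction 0.20), fold-back window 200 bp, soft-clip threshold
#' 1000 bp, clustering windows 10/250/50 bp, insertion size tolerance 0.25,
#' filter gates AF 0.01 and 3 reads, copy-number bins of 10 kb with CBS at
#' 1000 permutations (0.05 find / 0.01 validate), LOH block size 1.2 Mb, and
#' rescue distance 50 bp.
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(
    min_mapq = 5, normal_leniency_fraction = 0.5,
    min_sv_length = 30, normal_length_fraction = 0.20, merge_gap = 30,
    foldback_window = 200, min_softclip = 1000, supp_mapq_floor = 5,
    sbnd_mode = TRUE,
    coverage_bin_size = 5, genome_bin_size = 1e8,
    cluster_window = 10, insertion_window = 250, mate_window = 50,
    insertion_size_rel_tol = 0.25,
    af_min = 0.01, support_min = 3,
    cn_bin_size = 10000, cn_min_mapq = 5,
    alpha_find = 0.05, alpha_validate = 0.01, n_perm = 1000,
    block_size = 1.2e6, loh_min_snps = 10, loh_top_k = 10,
    rescue_distance = 50,
    panel_buffer = 100, panel_af_threshold = 0.10,
    epsilon = 0.05
  )
}

#' Run the somatic SV and copy-number pipeline
#'
#' Executes the full analysis on tumor (and optionally matched normal)
#' alignments: breakpoint discovery, clustering, 70-feature encoding,
#' random-forest classification with Mondrian conformal confidence, copy
#' number segmentation, purity/ploidy fitting when BAF data are available,
#' rescue of non-PASS breakpoints at copy-number changepoints, and emission
#' of a breakend VCF plus bin/segment tables when `out_dir` is given.
#'
#' @param tumor Alignment-record tibble or BAM path for the tumor.
#' @param normal Optional alignment tibble or BAM path (paired mode).
#' @param contig_lengths Named integer vector.
#' @param model An `sv_classifier`; when `NULL`, a default model is trained
#'   on a synthetic corpus with [fit_default_model()] (seeded from `seed`).
#' @param conformal Optional `sv_conformal` predictor; when given, conformal
#'   p-values and prediction regions (at `params$epsilon`, default 0.05) are
#'   attached to the calls.
#' @param cn_bins Optional precomputed counted bin table (e.g. from
#'   [simulate_cn_data()]); otherwise bins are counted from the alignments.
#' @param baf Optional SNP BAF observation tibble enabling purity/ploidy
#'   estimation.
#' @param population_svs,pon_svs Optional germline panels (tumor-only mode).
#' @param params Parameter list (see [default_params()]); partial overrides
#'   are merged over the defaults.
#' @param seed Integer seed controlling every stochastic stage.
#' @param out_dir Optional output directory for the VCF and tables.
#' @return An `sv_run` list: `calls` (classified cluster tibble with
#'   conformal columns), `breakpoints`, `bins`, `segments`, `changepoints`,
#'   `fit` (purity/ploidy or NULL), `manifest`.
#' @export
run_pipeline <- function(tumor, normal = NULL, contig_lengths,
                         model = NULL, conformal = NULL, cn_bins = NULL,
                         baf = NULL, population_svs = NULL, pon_svs = NULL,
                         params = list(), seed = 1, out_dir = NULL) {
  p <- utils::modifyList(default_params(), params)
  paired <- !is.null(normal)
  load_side <- function(x, role) {
    if (is.character(x)) {
      read_alignments(x, sample_role = role, min_mapq = p$min_mapq,
                      normal_leniency_fraction = p$normal_leniency_fraction)
    } else {
      filter_alignments(mutate(x, sample = role), sample_role = role,
                        min_mapq = p$min_mapq,
                        normal_leniency_fraction = p$normal_leniency_fraction)
    }
  }
  tumor_rec <- load_side(tumor, "tumor")
  normal_rec <- if (paired) load_side(normal, "normal") else NULL

  disc_t <- discover_breakpoints(
    tumor_rec, contig_lengths, min_sv_length = p$min_sv_length,
    merge_gap = p$merge_gap, foldback_window = p$foldback_window,
    min_softclip = p$min_softclip, sbnd_mode = p$sbnd_mode,
    supp_mapq_floor = p$supp_mapq_floor,
    normal_length_fraction = p$normal_length_fraction,
    coverage_bin_size = p$coverage_bin_size,
    genome_bin_size = p$genome_bin_size
  )
  disc_n <- if (paired) {
    discover_breakpoints(
      normal_rec, contig_lengths, min_sv_length = p$min_sv_length,
      merge_gap = p$merge_gap, foldback_window = p$foldback_window,
      min_softclip = p$min_softclip, sbnd_mode = p$sbnd_mode,
      supp_mapq_floor = p$supp_mapq_floor,
      normal_length_fraction = p$normal_length_fraction,
      coverage_bin_size = p$coverage_bin_size,
      genome_bin_size = p$genome_bin_size
    )
  } else NULL

  all_bps <- bind_rows(disc_t$breakpoints,
                       if (paired) disc_n$breakpoints)
  clusters <- cluster_breakpoints(
    all_bps, window_default = p$cluster_window,
    window_insertion = p$insertion_window, mate_window = p$mate_window,
    insertion_size_rel_tol = p$insertion_size_rel_tol
  )
  feats <- encode_features(clusters, disc_t$coverage,
                           if (paired) disc_n$coverage,
                           normal_breakpoints = if (paired) disc_n$breakpoints)

  if (is.null(model)) model <- fit_default_model(seed)
  calls <- classify_and_filter(model, clusters, feats, af_min = p$af_min,
                               support_min = p$support_min)
  if (!is.null(conformal) && nrow(calls) > 0L) {
    calls <- bind_cols(calls, mcp_predict(conformal, feats,
                                          epsilon = p$epsilon))
  }

  germline_calls <- calls[0, ]
  if (!paired && (!is.null(population_svs) || !is.null(pon_svs))) {
    calls <- filter_germline_panels(calls, population_svs, pon_svs,
                                    buffer = p$panel_buffer,
                                    af_threshold = p$panel_af_threshold)
    germline_calls <- attr(calls, "germline")
    feats <- semi_join(feats, calls, by = "cluster_id")
  }

  # copy number
  pass_be <- clusters_to_breakends(filter(calls, .data$filter == "PASS")) |>
    select("contig", "pos")
  if (is.null(cn_bins)) {
    bins <- build_bins(contig_lengths, bin_size = p$cn_bin_size,
                       breakpoints = pass_be)
    bins <- count_reads(bind_rows(tumor_rec, normal_rec), bins,
                        min_mapq = p$cn_min_mapq)
  } else {
    bins <- cn_bins
  }
  cn_mode <- if (paired || (!is.null(cn_bins) &&
                            "normal_count" %in% names(cn_bins) &&
                            any(cn_bins$normal_count > 0))) {
    "paired"
  } else "tumor_only"
  norm_bins <- normalize_log2(bins, mode = cn_mode)
  seg <- segment_copy_number(norm_bins, alpha_find = p$alpha_find,
                             alpha_validate = p$alpha_validate,
                             n_perm = p$n_perm, seed = seed)

  # purity/ploidy when BAF data are available
  fit <- NULL
  segments <- seg$segments
  if (!is.null(baf) && nrow(baf) > 0L) {
    blocks <- select_loh_blocks(baf, contig_lengths,
                                block_size = p$block_size,
                                min_snps = p$loh_min_snps,
                                top_k = p$loh_top_k)
    purity_hat <- estimate_purity(blocks)
    fit <- grid_search_ploidy(segments, purity_hat)
    segments <- fit_absolute_cn(segments, fit)
    segments <- allele_specific_cn(segments, baf, fit$purity)
  }

  # rescue at changepoints, then conformal confidence on the final call set
  calls <- rescue_by_changepoints(calls, seg$changepoints,
                                  distance = p$rescue_distance,
                                  support_min = p$support_min)
  attr(calls, "germline") <- germline_calls
  manifest <- list(
    mode = if (paired) "paired" else "tumor_only", seed = seed,
    params = p,
    n_tumor_records = nrow(tumor_rec),
    n_normal_records = if (paired) nrow(normal_rec) else 0L,
    n_breakpoints = nrow(all_bps), n_clusters = nrow(clusters),
    n_pass = sum(calls$filter == "PASS"),
    n_segments = nrow(segments)
  )
  out <- structure(
    list(calls = calls, features = feats, breakpoints = all_bps,
         bins = norm_bins, segments = segments,
         changepoints = seg$changepoints, fit = fit, model = model,
         manifest = manifest),
    class = "sv_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_breakpoint_vcf(calls, file.path(out_dir, "sv_calls.vcf"),
                         metadata = c(source = "svelt"))
    utils::write.table(select(norm_bins, -dplyr::any_of("members")),
                       file.path(out_dir, "cn_bins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(segments, file.path(out_dir, "cn_segments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(fit)) {
      jsonlite::write_json(glance(fit), file.path(out_dir, "purity_ploidy.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(manifest[setdiff(names(manifest), "params")],
                         file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.sv_run <- function(x, ...) {
  m <- x$manifest
  cat("<sv_run>", m$mode, "mode;", m$n_clusters, "clusters,", m$n_pass,
      "PASS;", m$n_segments, "copy-number segments\n")
  if (!is.null(x$fit)) {
    cat("  purity", x$fit$purity, " ploidy", x$fit$ploidy, "\n")
  }
  invisible(x)
}

#' @export
tidy.sv_run <- function(x, ...) {
  select(x$calls, -dplyr::any_of("members"))
}

#' @export
glance.sv_run <- function(x, ...) {
  tibble(
    mode = x$manifest$mode, n_clusters = x$manifest$n_clusters,
    n_pass = x$manifest$n_pass, n_segments = x$manifest$n_segments,
    purity = if (is.null(x$fit)) NA_real_ else x$fit$purity,
    ploidy = if (is.null(x$fit)) NA_real_ else x$fit$ploidy
  )
}

#' Estimate purity and ploidy from a counted bin table and BAF observations
#'
#' Convenience wrapper over the copy-number stack: normalize, segment with
#' CBS, select LOH blocks, estimate purity and run the ploidy grid search.
#'
#' @param bins Counted bin tibble (tumor and, optionally, normal counts).
#' @param baf SNP BAF observation tibble.
#' @param contig_lengths Named integer vector.
#' @param block_size LOH block size in bp (default 1.2e6).
#' @param n_perm,seed CBS parameters.
#' @return A list with `fit` (`purity_ploidy_fit`), `segments`, `purity_hat`.
#' @export
fit_purity_ploidy <- function(bins, baf, contig_lengths, block_size = 1.2e6,
                              n_perm = 1000, seed = 1) {
  mode <- if ("normal_count" %in% names(bins) &&
              any(bins$normal_count > 0)) "paired" else "tumor_only"
  norm <- normalize_log2(bins, mode = mode)
  seg <- segment_copy_number(norm, n_perm = n_perm, seed = seed)
  blocks <- select_loh_blocks(baf, contig_lengths, block_size = block_size)
  purity_hat <- estimate_purity(blocks)
  fit <- grid_search_ploidy(seg$segments, purity_hat)
  segments <- allele_specific_cn(fit_absolute_cn(seg$segments, fit), baf,
                                 fit$purity)
  list(fit = fit, segments = segments, purity_hat = purity_hat,
       changepoints = seg$changepoints)
}
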