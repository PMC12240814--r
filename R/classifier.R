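# Random-forest somatic/noise classification of breakpoint clusters, with
# training-label construction from matched short-read calls and the
# AF/support vetting filters.

#' Label clusters for training against a short-read truth set
#'
#' Clusters matched to a short-read breakend within `match_buffer` bp are
#' labeled `somatic`; the rest are labeled `noise` UNLESS they look like true
#' somatic SVs that short reads simply missed, in which case they are
#' excluded from training rather than mislabeled. The exclusion gate requires
#' at least 6 tumor reads, allele fraction > 0.10, mean supporting MAPQ >= 50,
#' tight coordinates (sd < 15 for SVs longer than 100 bp; sd < 1.5 and size
#' sd < 10 for shorter ones) and, in paired mode, fewer than 2 clustered
#' normal reads of any type with at least 5x normal depth at the locus.
#'
#' @param clusters Cluster tibble.
#' @param features Feature table from [encode_features()] (same clusters).
#' @param truth_breakends Breakend tibble (e.g. from [read_truth_vcf()]).
#' @param match_buffer Matching window in bp (default 100).
#' @return `clusters` with `label` (`"somatic"`, `"noise"`, or `NA` for
#'   excluded) and `excluded` columns.
#' @export
build_training_labels <- function(clusters, features, truth_breakends,
                                  match_buffer = 100) {
  stopifnot(nrow(clusters) == nrow(features))
  f <- features
  matched <- vapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    hit <- truth_breakends$contig == cl$contig_a &
      abs(truth_breakends$pos - cl$pos_a) <= match_buffer
    if (!is.na(cl$contig_b)) {
      hit <- hit | (truth_breakends$contig == cl$contig_b &
                      abs(truth_breakends$pos - cl$pos_b) <= match_buffer)
    }
    any(hit)
  }, logical(1))

  paired <- f$paired_mode > 0
  long_sv <- clusters$median_sv_length > 100
  coord_ok <- ifelse(long_sv,
                     clusters$sd_pos_a < 15 & clusters$sd_pos_b < 15,
                     clusters$sd_pos_a < 1.5 & clusters$sd_pos_b < 1.5 &
                       clusters$sd_sv_length < 10)
  normal_ok <- ifelse(paired,
                      f$normal_any_cluster_reads < 2 &
                        f$normal_depth_at_a >= 5,
                      TRUE)
  high_conf_unmatched <- !matched &
    clusters$tumor_support >= 6 &
    f$tumor_af > 0.10 &
    clusters$mean_mapq >= 50 &
    coord_ok & normal_ok

  clusters |>
    mutate(
      label = dplyr::case_when(
        matched ~ "somatic",
        high_conf_unmatched ~ NA_character_,
        TRUE ~ "noise"
      ),
      excluded = high_conf_unmatched
    )
}

#' Train the somatic/noise random-forest classifier
#'
#' Trains a probability forest (class probability = fraction of trees voting)
#' on the 70-covariate feature table, holding out one fifth of the rows (4:1
#' split) to report an area under the ROC curve. Fully reproducible for a
#' given seed. With `groups`, use [loo_group_predictions()] for
#' leave-one-group-out evaluation.
#'
#' @param features Feature tibble (the 70 columns of [sv_feature_names()];
#'   an extra `cluster_id` column is ignored).
#' @param labels Character/factor vector, `"somatic"` or `"noise"`.
#' @param max_depth Maximum tree depth (default 20).
#' @param split_ratio Training fraction (default 0.8, i.e. a 4:1 split).
#' @param num_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return An `sv_classifier` object.
#' @export
train_classifier <- function(features, labels, max_depth = 20,
                             split_ratio = 0.8, num_trees = 500, seed = 1) {
  x <- select(features, dplyr::any_of(sv_feature_names()))
  if (!identical(names(x), sv_feature_names())) {
    abort("feature table does not match the frozen 70-feature manifest")
  }
  y <- factor(as.character(labels), levels = c("noise", "somatic"))
  if (any(is.na(y))) abort("labels must be 'somatic' or 'noise'")
  if (dplyr::n_distinct(y) < 2L) {
    abort("training data must contain both classes")
  }
  set.seed(seed)
  n <- nrow(x)
  train_idx <- sort(sample.int(n, size = floor(split_ratio * n)))
  test_idx <- setdiff(seq_len(n), train_idx)
  if (dplyr::n_distinct(y[train_idx]) < 2L) {
    abort("training split lost a class; provide more data")
  }
  dat <- bind_cols(x, tibble(.label = y))
  model <- ranger::ranger(
    dependent.variable.name = ".label",
    data = as.data.frame(dat[train_idx, ]),
    probability = TRUE, num.trees = num_trees, max.depth = max_depth,
    seed = seed, importance = "impurity"
  )
  heldout <- NULL
  auroc <- NA_real_
  if (length(test_idx) > 1L && dplyr::n_distinct(y[test_idx]) == 2L) {
    prob <- predict(model, data = as.data.frame(x[test_idx, ]))$predictions[, "somatic"]
    heldout <- tibble(truth = y[test_idx], prob_somatic = prob)
    auroc <- as.numeric(pROC::auc(pROC::roc(
      response = heldout$truth, predictor = heldout$prob_somatic,
      levels = c("noise", "somatic"), direction = "<", quiet = TRUE
    )))
  }
  structure(
    list(model = model, feature_names = sv_feature_names(),
         manifest_version = 1L, max_depth = max_depth, seed = seed,
         n_train = length(train_idx), n_test = length(test_idx),
         heldout = heldout, auroc = auroc),
    class = "sv_classifier"
  )
}

#' Probability that each cluster is somatic
#'
#' @param object An `sv_classifier`.
#' @param features Feature tibble matching the frozen manifest.
#' @param ... Unused.
#' @return Numeric vector: fraction of trees voting somatic.
#' @export
predict.sv_classifier <- function(object, features, ...) {
  x <- select(features, dplyr::any_of(sv_feature_names()))
  if (!identical(names(x), object$feature_names)) {
    abort("feature table does not match the model's feature manifest")
  }
  predict(object$model, data = as.data.frame(x))$predictions[, "somatic"]
}

#' Leave-one-group-out classifier evaluation
#'
#' For each group (e.g. tumor id), trains on all other groups and predicts
#' the held-out group, mirroring cohort-level model evaluation.
#'
#' @inheritParams train_classifier
#' @param groups Vector of group ids, one per row of `features`.
#' @return Tibble with `group`, `truth`, `prob_somatic` out-of-fold
#'   predictions.
#' @export
loo_group_predictions <- function(features, labels, groups, max_depth = 20,
                                  num_trees = 500, seed = 1) {
  x <- select(features, dplyr::any_of(sv_feature_names()))
  y <- factor(as.character(labels), levels = c("noise", "somatic"))
  out <- list()
  for (g in unique(groups)) {
    hold <- groups == g
    if (dplyr::n_distinct(y[!hold]) < 2L) {
      abort("leave-one-group-out training fold lost a class")
    }
    dat <- bind_cols(x[!hold, ], tibble(.label = y[!hold]))
    model <- ranger::ranger(
      dependent.variable.name = ".label", data = as.data.frame(dat),
      probability = TRUE, num.trees = num_trees, max.depth = max_depth,
      seed = seed
    )
    prob <- predict(model, data = as.data.frame(x[hold, ]))$predictions[, "somatic"]
    out[[length(out) + 1L]] <- tibble(group = g, truth = y[hold],
                                      prob_somatic = prob)
  }
  list_rbind(out)
}

#' Classify clusters and set the VCF filter
#'
#' Applies the classifier and the vetting thresholds in a fixed precedence:
#' predicted noise gives `LIKELY_NOISE`; predicted somatic with fewer than
#' `support_min` tumor reads gives `LOW_SUPPORT`; with allele fraction below
#' `af_min` gives `LOW_AF`; otherwise `PASS`. Ties in the tree vote (prob =
#' 0.5) break toward noise.
#'
#' @param model An `sv_classifier`.
#' @param clusters Cluster tibble.
#' @param features Matching feature table.
#' @param af_min Minimum allele fraction (default 0.01).
#' @param support_min Minimum tumor supporting reads (default 3).
#' @return `clusters` with `class_probability`, `class_label`, `filter`,
#'   `rescued`, `tumor_af` and `normal_any_cluster_reads` columns.
#' @export
classify_and_filter <- function(model, clusters, features, af_min = 0.01,
                                support_min = 3) {
  stopifnot(nrow(clusters) == nrow(features))
  if (nrow(clusters) == 0L) {
    return(mutate(clusters, class_probability = double(0),
                  class_label = character(0), filter = character(0),
                  rescued = logical(0), tumor_af = double(0),
                  normal_any_cluster_reads = double(0)))
  }
  prob <- predict(model, features)
  clusters |>
    mutate(
      class_probability = prob,
      class_label = ifelse(prob > 0.5, "somatic", "noise"),
      tumor_af = features$tumor_af,
      normal_any_cluster_reads = features$normal_any_cluster_reads,
      filter = dplyr::case_when(
        class_label == "noise" ~ "LIKELY_NOISE",
        tumor_support < support_min ~ "LOW_SUPPORT",
        tumor_af < af_min ~ "LOW_AF",
        TRUE ~ "PASS"
      ),
      rescued = FALSE
    )
}

#' @export
tidy.sv_classifier <- function(x, ...) {
  imp <- x$model$variable.importance
  tibble(feature = names(imp), importance = unname(imp)) |>
    arrange(dplyr::desc(.data$importance))
}

#' @export
glance.sv_classifier <- function(x, ...) {
  tibble(auroc = x$auroc, n_train = x$n_train, n_test = x$n_test,
         num_trees = x$model$num.trees, max_depth = x$max_depth,
         seed = x$seed)
}

#' @export
print.sv_classifier <- function(x, ...) {
  cat("<sv_classifier> random forest,", x$model$num.trees, "trees, depth <=",
      x$max_depth, "\n  trained on", x$n_train, "clusters; held-out AUROC:",
      format(x$auroc, digits = 3), "\n")
  invisible(x)
}

#' Turn model/fit objects into tidy tibbles
#'
#' @param x Object.
#' @param ... Passed on.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summaries
#'
#' @param x Object.
#' @param ... Passed on.
#' @export
glance <- function(x, ...) UseMethod("glance")
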