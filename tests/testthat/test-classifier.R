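# Feature encoding, training labels, random-forest classification, filters,
# rescue and panel filtering.

test_that("feature encoding produces the frozen 70-covariate vector", {
  expect_length(sv_feature_names(), 70L)
  expect_false(any(duplicated(sv_feature_names())))

  contigs <- c(chr1 = 100000L)
  members <- purrr::map(1:5, function(i) {
    breakpoint_row(kind = "cigar_deletion", pos_a = 10000L, pos_b = 10050L,
                   sv_length = 50, read_name = paste0("t", i))
  }) |> purrr::list_rbind()
  clusters <- finalize_clusters(dplyr::mutate(members, group_id = "g1"))
  cov_recs <- purrr::map(1:10, function(i) {
    record_row(paste0("c", i), start = 9000L, cigar = "2000M")
  }) |> purrr::list_rbind()
  cov_t <- build_coverage(cov_recs, contigs)
  cov_n <- build_coverage(cov_recs[0, ], contigs)

  f <- encode_features(clusters, cov_t, cov_n)
  expect_equal(ncol(f), 71L)  # cluster_id + 70 features
  expect_identical(names(f)[-1], sv_feature_names())
  expect_true(all(is.finite(as.matrix(f[-1]))))
  # 5 identical deletions over depth 10: AF 0.5, zero length spread
  expect_equal(f$tumor_af, 0.5)
  expect_equal(f$sd_sv_length, 0)
  expect_equal(f$sd_start, 0)
  expect_equal(f$tumor_support, 5)
  expect_equal(f$normal_support, 0)
  expect_equal(f$notation_pm, 1)
  expect_equal(f$interchromosomal, 0)

  # without a normal sample, normal features are 0 and paired_mode is off
  f0 <- encode_features(clusters, cov_t)
  expect_equal(f0$paired_mode, 0)
  expect_equal(f0$normal_depth_at_a, 0)
  expect_equal(f0$normal_support, 0)
})

test_that("training labels follow match / high-confidence-exclusion / noise", {
  clusters <- tibble::tibble(
    cluster_id = 1:3,
    contig_a = "chr1", pos_a = c(1040L, 50000L, 80000L),
    contig_b = "chr1", pos_b = c(5000L, 55000L, 85000L),
    tumor_support = c(10L, 7L, 3L),
    mean_mapq = c(60, 55, 30),
    median_sv_length = c(3960, 5000, 5000),
    sd_pos_a = c(1, 2, 30), sd_pos_b = c(1, 2, 30),
    sd_sv_length = c(1, 2, 40)
  )
  features <- tibble::tibble(
    paired_mode = 1,
    tumor_af = c(0.5, 0.15, 0.05),
    normal_any_cluster_reads = c(0, 0, 0),
    normal_depth_at_a = c(30, 30, 30)
  )
  truth <- tibble::tibble(contig = "chr1", pos = c(1000L, 5000L))

  labeled <- build_training_labels(clusters, features, truth,
                                   match_buffer = 100)
  expect_equal(labeled$label, c("somatic", NA, "noise"))
  expect_equal(labeled$excluded, c(FALSE, TRUE, FALSE))
})

test_that("the classifier separates separable classes and is reproducible", {
  set.seed(5)
  n <- 2000
  base <- matrix(rnorm(n * 70), ncol = 70,
                 dimnames = list(NULL, sv_feature_names()))
  labels <- rep(c("somatic", "noise"), each = n / 2)
  base[labels == "somatic", "tumor_support"] <-
    base[labels == "somatic", "tumor_support"] + 6
  feats <- tibble::as_tibble(base)

  m <- train_classifier(feats, labels, seed = 3)
  expect_gte(m$auroc, 0.95)
  expect_s3_class(m, "sv_classifier")

  m2 <- train_classifier(feats, labels, seed = 3)
  expect_identical(predict(m, feats), predict(m2, feats))

  g <- glance(m)
  expect_equal(g$max_depth, 20)
  expect_gt(g$n_train, g$n_test)
  imp <- tidy(m)
  expect_equal(imp$feature[1], "tumor_support")

  # identical rows duplicated into both classes carry no signal: the forest
  # sees every row with both labels and its vote collapses to a coin flip
  dup <- feats[rep(1:400, 2), ]
  dup_labels <- rep(c("somatic", "noise"), each = 400)
  m_null <- train_classifier(dup, dup_labels, seed = 3)
  prob <- predict(m_null, dup)
  auroc_null <- as.numeric(pROC::auc(pROC::roc(
    response = factor(dup_labels, levels = c("noise", "somatic")),
    predictor = prob, levels = c("noise", "somatic"), direction = "<",
    quiet = TRUE)))
  expect_lt(abs(auroc_null - 0.5), 0.1)

  expect_error(train_classifier(feats, rep("noise", n), seed = 1),
               "both classes")
})

test_that("filter precedence is LIKELY_NOISE, LOW_SUPPORT, LOW_AF, PASS", {
  clusters <- tibble::tibble(
    cluster_id = 1:4,
    tumor_support = c(10L, 2L, 10L, 10L),
    normal_support = 0L
  )
  feats <- tibble::as_tibble(
    matrix(0, nrow = 4, ncol = 70, dimnames = list(NULL, sv_feature_names()))
  )
  feats$tumor_af <- c(0.4, 0.4, 0.005, 0.4)
  model <- constant_model(c(0.9, 0.9, 0.9, 0.3))
  out <- classify_and_filter(model, clusters, feats)
  expect_equal(out$filter, c("PASS", "LOW_SUPPORT", "LOW_AF", "LIKELY_NOISE"))
  expect_equal(out$class_label, c("somatic", "somatic", "somatic", "noise"))

  # tie in the tree vote breaks toward noise
  tie <- classify_and_filter(constant_model(0.5), clusters[1, ], feats[1, ])
  expect_equal(tie$filter, "LIKELY_NOISE")
})

test_that("changepoint rescue requires distance, support and a clean normal", {
  base <- tibble::tibble(
    cluster_id = 1:4,
    contig_a = "chr1", pos_a = c(1040L, 1060L, 1040L, 1040L),
    contig_b = "chr1", pos_b = c(9000L, 9000L, 9000L, 9000L),
    tumor_support = c(4L, 4L, 4L, 2L),
    normal_support = c(0L, 0L, 0L, 0L),
    normal_any_cluster_reads = c(0, 0, 3, 0),
    filter = "LIKELY_NOISE", rescued = FALSE, class_label = "noise"
  )
  cps <- tibble::tibble(contig = "chr1", pos = 1000L)
  out <- rescue_by_changepoints(base, cps, distance = 50)
  expect_equal(out$rescued, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$filter[1], "PASS")
  expect_equal(out$class_label[1], "somatic")
  expect_equal(out$filter[2], "LIKELY_NOISE")
})

test_that("germline panels remove nearby calls subject to the AF gate", {
  clusters <- tibble::tibble(
    cluster_id = 1:3,
    contig_a = "chr1", pos_a = c(1080L, 5000L, 9000L),
    contig_b = "chr1", pos_b = c(2000L, 6000L, 9500L)
  )
  pop <- tibble::tibble(contig = "chr1", pos = c(1000L, 5050L),
                        af = c(0.2, 0.05))
  out <- filter_germline_panels(clusters, population_svs = pop)
  expect_equal(out$cluster_id, c(2L, 3L))  # AF 0.05 entry is ignored
  expect_equal(attr(out, "germline")$cluster_id, 1L)

  pon <- tibble::tibble(contig = "chr1", pos = 9040L)
  out2 <- filter_germline_panels(clusters, pon_svs = pon)
  expect_equal(out2$cluster_id, c(1L, 2L))

  unchanged <- filter_germline_panels(clusters)
  expect_equal(nrow(unchanged), 3L)
})
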