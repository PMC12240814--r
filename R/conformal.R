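# Mondrian conformal prediction on top of the random-forest vote.
#
# The calibration design: the labeled data are split once, 70% to train a
# forest and 30% to calibrate. The nonconformity score of an instance with
# respect to class c is 1 minus the fraction of trees voting c, so a
# class-typical instance scores low. Calibration scores are kept per class
# (the Mondrian taxonomy), giving a per-class validity guarantee even for the
# minority class: p_c = (#{calibration scores of class c >= query score} + 1)
# / (n_c + 1), and the prediction region at tolerance epsilon is the set of
# classes with p > epsilon ("both" when both survive, "null" when neither
# does - the instance is an outlier relative to the training data).

#' Calibrate a Mondrian conformal predictor
#'
#' @param features Feature tibble (frozen 70-feature manifest).
#' @param labels `"somatic"`/`"noise"` labels.
#' @param proper_train_fraction Fraction used to train the underlying forest
#'   (default 0.70); the rest calibrates.
#' @param max_depth,num_trees Forest hyperparameters.
#' @param seed Integer seed.
#' @return An `sv_conformal` object.
#' @export
mcp_calibrate <- function(features, labels, proper_train_fraction = 0.70,
                          max_depth = 20, num_trees = 500, seed = 1) {
  x <- select(features, dplyr::any_of(sv_feature_names()))
  if (!identical(names(x), sv_feature_names())) {
    abort("feature table does not match the frozen 70-feature manifest")
  }
  y <- factor(as.character(labels), levels = c("noise", "somatic"))
  set.seed(seed)
  n <- nrow(x)
  proper <- sort(sample.int(n, size = floor(proper_train_fraction * n)))
  calib <- setdiff(seq_len(n), proper)
  if (dplyr::n_distinct(y[proper]) < 2L ||
      dplyr::n_distinct(y[calib]) < 2L) {
    abort("both classes are required in the proper-training and calibration sets")
  }
  dat <- bind_cols(x, tibble(.label = y))
  model <- ranger::ranger(
    dependent.variable.name = ".label",
    data = as.data.frame(dat[proper, ]),
    probability = TRUE, num.trees = num_trees, max.depth = max_depth,
    seed = seed
  )
  prob <- predict(model, data = as.data.frame(x[calib, ]))$predictions
  ycal <- y[calib]
  scores <- list(
    somatic = sort(1 - prob[ycal == "somatic", "somatic"]),
    noise = sort(1 - prob[ycal == "noise", "noise"])
  )
  structure(
    list(model = model, calibration_scores = scores,
         feature_names = sv_feature_names(), seed = seed),
    class = "sv_conformal"
  )
}

#' Conformal prediction regions for breakpoint features
#'
#' @param object An `sv_conformal` predictor.
#' @param features Feature tibble.
#' @param epsilon Tolerated error rate in (0, 1) (default 0.05).
#' @return Tibble with per-class p-values `conformal_p_somatic`,
#'   `conformal_p_noise` and the region `conformal_region` in
#'   `{"somatic", "noise", "both", "null"}`.
#' @export
mcp_predict <- function(object, features, epsilon = 0.05) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 1) {
    abort("epsilon must be a single number in (0, 1)")
  }
  x <- select(features, dplyr::any_of(sv_feature_names()))
  if (!identical(names(x), object$feature_names)) {
    abort("feature table does not match the conformal model's manifest")
  }
  prob <- predict(object$model, data = as.data.frame(x))$predictions
  p_of <- function(class) {
    cal <- object$calibration_scores[[class]]
    score <- 1 - prob[, class]
    unname(vapply(score, function(s) (sum(cal >= s) + 1) / (length(cal) + 1),
                  double(1)))
  }
  p_som <- p_of("somatic")
  p_noi <- p_of("noise")
  region <- dplyr::case_when(
    p_som > epsilon & p_noi > epsilon ~ "both",
    p_som > epsilon ~ "somatic",
    p_noi > epsilon ~ "noise",
    TRUE ~ "null"
  )
  tibble(conformal_p_somatic = p_som, conformal_p_noise = p_noi,
         conformal_region = region)
}

#' @export
print.sv_conformal <- function(x, ...) {
  cat("<sv_conformal> Mondrian conformal predictor;",
      length(x$calibration_scores$somatic), "somatic /",
      length(x$calibration_scores$noise), "noise calibration scores\n")
  invisible(x)
}
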