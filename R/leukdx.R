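#' Fit the acute-leukemia differential-diagnosis model
#'
#' Fits both diagnostic models from a labeled training FPKM matrix in one
#' call: (1) the scoring model — signature genes selected by the fold-change /
#' FDR / expression filters of [select_signature()] from an AML-vs-B-ALL scan,
#' with per-gene positivity thresholds calibrated by [calibrate_thresholds()]
#' and the two-score 30/30 decision rule of [classify()]; and (2) the
#' one-vs-one sigmoid-kernel SVM of [train_svm()] on the z-standardized
#' signature genes. The reference-gene anchor for cross-cohort normalization
#' is stored so [predict.leukdx()] can place external samples on the training
#' scale.
#'
#' @param x Training expression matrix (genes x samples, FPKM).
#' @param labels Named character vector of training labels (`AML`, `B-ALL`,
#'   `MPAL`). MPAL samples are excluded from signature selection and
#'   threshold calibration but participate in SVM training.
#' @param fold_min,q_max,fpkm_min Signature filters (defaults 2, 0.05, 100).
#' @param cutoff Score cutoff of the decision rule, in percent (default 30).
#' @param reference_gene Internal-control gene for normalization
#'   (default `"ABL1"`).
#' @param cost,gamma,coef0 SVM parameters (see [train_svm()]).
#' @param k_grid Threshold-multiplier grid for [calibrate_thresholds()].
#' @return An object of class `leukdx` with components `signature`
#'   (calibrated `leukdx_signature`), `svm` (`leukdx_svm`), `cutoff`,
#'   `training` (per-sample scores and calls on the training data) and
#'   `labels`.
#' @examples
#' sim <- simulate_expression(synthetic_config(n_per_group = 10, seed = 1))
#' fit <- leukdx(sim$matrix, sim$labels)
#' fit
#' head(predict(fit, sim$matrix))
#' @export
leukdx <- function(x, labels, fold_min = 2, q_max = 0.05, fpkm_min = 100,
                   cutoff = 30, reference_gene = "ABL1", cost = 1,
                   gamma = NULL, coef0 = 0,
                   k_grid = seq(0.5, 2.0, by = 0.1)) {
  validate_expression_matrix(x)
  labels <- align_labels(x, labels)
  de <- differential_test(x, labels, "AML", "B-ALL")
  sig <- select_signature(de, fold_min = fold_min, q_max = q_max,
                          fpkm_min = fpkm_min,
                          reference_gene = reference_gene)
  sig <- calibrate_thresholds(x, labels, sig, cutoff = cutoff,
                              k_grid = k_grid)
  genes <- c(sig$aml_genes, sig$ball_genes)
  feats <- suppressWarnings(z_transform(x, genes))
  svm_fit <- train_svm(feats, labels, cost = cost, gamma = gamma,
                       coef0 = coef0)
  scores <- compute_scores(x, sig)
  training <- data.frame(scores,
                         call = classify(scores, cutoff = cutoff),
                         svm_call = predict(svm_fit, feats,
                                            standardized = TRUE),
                         true = unname(labels),
                         stringsAsFactors = FALSE)
  structure(list(signature = sig, svm = svm_fit, cutoff = cutoff,
                 training = training, labels = labels),
            class = "leukdx")
}

#' Predict the disease category of new samples
#'
#' Applies a fitted model to new expression data: when `normalize = TRUE`
#' (the default) the matrix is first anchored to the training cohort via the
#' reference gene ([abl1_normalize()] at the stored target level), then the
#' AML and B-ALL scores, the two-score call, and the SVM call are computed.
#'
#' @param object A fitted `leukdx` model.
#' @param newdata Expression matrix (genes x samples) containing all
#'   signature genes (and the reference gene when `normalize = TRUE`).
#' @param normalize Apply reference-gene normalization first (default TRUE
#'   when the model stores a reference target).
#' @param ... Unused.
#' @return `data.frame` with `sample_id`, `aml_score`, `ball_score`, `call`
#'   (two-score rule) and `svm_call`.
#' @export
predict.leukdx <- function(object, newdata,
                           normalize = !is.null(object$signature$ref_target),
                           ...) {
  if (normalize) {
    if (is.null(object$signature$ref_target))
      stop("model stores no reference target level; fit with the reference ",
           "gene present or predict with normalize = FALSE")
    newdata <- abl1_normalize(newdata, object$signature$reference_gene,
                              object$signature$ref_target)
  }
  scores <- compute_scores(newdata, object$signature)
  data.frame(scores,
             call = classify(scores, cutoff = object$cutoff),
             svm_call = predict(object$svm, newdata),
             stringsAsFactors = FALSE)
}

#' @export
print.leukdx <- function(x, ...) {
  cat("Acute-leukemia differential-diagnosis model\n\n")
  print(x$signature)
  print(x$svm)
  cat(sprintf("  score cutoff: %g%%\n", x$cutoff))
  tr <- table(x$labels)
  cat(sprintf("  trained on %d samples (%s)\n", length(x$labels),
              paste(sprintf("%s: %d", names(tr), tr), collapse = ", ")))
  invisible(x)
}

#' @export
summary.leukdx <- function(object, ...) {
  ev_score <- evaluate_predictions(object$training$true,
                                   object$training$call)
  ev_svm <- evaluate_predictions(object$training$true,
                                 object$training$svm_call)
  out <- list(model = object, score_eval = ev_score, svm_eval = ev_svm)
  class(out) <- "summary.leukdx"
  out
}

#' @export
print.summary.leukdx <- function(x, ...) {
  print(x$model)
  cat("\nTraining performance, scoring algorithm:\n")
  print(x$score_eval)
  cat("\nTraining performance, SVM:\n")
  print(x$svm_eval)
  invisible(x)
}

#' @export
coef.leukdx <- function(object, ...) {
  object$signature$thresholds
}

#' Two-score scatter plot
#'
#' Plots each sample's B-ALL score against its AML score with the decision
#' cutoffs drawn, the scatter in which AML and B-ALL samples form opposite
#' corners and MPAL samples fall in the upper-right quadrant.
#'
#' @param x A fitted `leukdx` model.
#' @param newdata Optional expression matrix to score; by default the
#'   training samples are shown.
#' @param labels Optional named labels used to color points when `newdata`
#'   is given.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.leukdx <- function(x, newdata = NULL, labels = NULL, ...) {
  if (is.null(newdata)) {
    d <- x$training
    lab <- d$true
  } else {
    d <- predict(x, newdata)
    lab <- if (is.null(labels)) rep(NA_character_, nrow(d))
           else unname(labels[d$sample_id])
  }
  col <- c("AML" = "#D55E00", "B-ALL" = "#0072B2", "MPAL" = "#009E73")
  graphics::plot(d$aml_score, d$ball_score, xlim = c(0, 100),
                 ylim = c(0, 100), xlab = "AML score (%)",
                 ylab = "B-ALL score (%)", pch = 19,
                 col = ifelse(is.na(lab), "grey40", col[lab]), ...)
  graphics::abline(v = x$cutoff, h = x$cutoff, lty = 2, col = "grey60")
  if (!all(is.na(lab)))
    graphics::legend("topright", legend = names(col), col = col, pch = 19,
                     bty = "n")
  invisible(d)
}
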