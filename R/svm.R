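#' Standardize signature-gene features
#'
#' Turns the expression of the signature genes into a samples x genes feature
#' table with each gene centered and scaled. Scaling uses the population
#' standard deviation (denominator n). When `params` is `NULL` the center and
#' scale are computed from the supplied samples and attached to the result;
#' when a stored parameter set is supplied (e.g. from a trained model) it is
#' applied unchanged, so test samples are placed on the training scale.
#' Features with zero variance in the fitting samples are dropped with a
#' warning and recorded.
#'
#' @param x Expression matrix (genes x samples).
#' @param genes Feature genes (rows of `x`).
#' @param params Optional list with `center`, `scale` (named by gene) and
#'   `dropped`, as attached by a previous call.
#' @return Numeric matrix, samples x retained genes, with attributes
#'   `center`, `scale` and `dropped`.
#' @export
z_transform <- function(x, genes, params = NULL) {
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("feature gene(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  feat <- t(x[genes, , drop = FALSE])
  if (is.null(params)) {
    center <- colMeans(feat)
    scale <- sqrt(colMeans(sweep(feat, 2L, center)^2))
    dropped <- names(scale)[scale == 0]
    if (length(dropped))
      warning("dropping zero-variance feature(s): ",
              paste(dropped, collapse = ", "))
    keep <- setdiff(colnames(feat), dropped)
    params <- list(center = center[keep], scale = scale[keep],
                   dropped = dropped)
  }
  keep <- names(params$center)
  z <- sweep(sweep(feat[, keep, drop = FALSE], 2L, params$center),
             2L, params$scale, "/")
  attr(z, "center") <- params$center
  attr(z, "scale") <- params$scale
  attr(z, "dropped") <- params$dropped
  z
}

# Extract stored standardization parameters from a z_transform() result.
z_params <- function(z) {
  list(center = attr(z, "center"), scale = attr(z, "scale"),
       dropped = attr(z, "dropped"))
}

#' Train the one-vs-one sigmoid-kernel SVM
#'
#' Fits one soft-margin binary SVM with hyperbolic-tangent (sigmoid) kernel
#' per pair of classes present in the training labels. Multiclass prediction
#' is by majority vote over the binary machines; vote ties are broken
#' deterministically by the fixed class order AML < B-ALL < MPAL. The binary
#' machines are fitted by [e1071::svm()]; the one-vs-one vote and tie rule
#' are handled here so prediction is reproducible bit-for-bit.
#'
#' @param features Standardized samples x genes table from [z_transform()].
#' @param labels Named character vector of training labels (every class to be
#'   distinguished must be present).
#' @param cost Soft-margin penalty C (default 1).
#' @param gamma Kernel scale; default `1 / ncol(features)`.
#' @param coef0 Kernel offset (default 0).
#' @return An object of class `leukdx_svm` holding the binary machines, the
#'   class set, the feature genes and the stored standardization parameters.
#' @export
train_svm <- function(features, labels, cost = 1, gamma = NULL, coef0 = 0) {
  if (is.null(rownames(features)))
    stop("feature table must carry sample row names")
  labels <- labels[rownames(features)]
  if (any(is.na(labels))) stop("every training sample must be labeled")
  classes <- LEUKDX_CLASSES[LEUKDX_CLASSES %in% unique(labels)]
  if (length(classes) < 2L)
    stop("training data must contain at least 2 classes, got: ",
         paste(unique(labels), collapse = ", "))
  if (is.null(gamma)) gamma <- 1 / ncol(features)
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  machines <- lapply(pairs, function(pr) {
    idx <- labels %in% pr
    y <- factor(as.character(labels[idx]), levels = pr)
    e1071::svm(x = features[idx, , drop = FALSE], y = y,
               kernel = "sigmoid", cost = cost, gamma = gamma,
               coef0 = coef0, scale = FALSE)
  })
  structure(
    list(machines = machines, pairs = pairs, classes = classes,
         feature_genes = colnames(features),
         standardization = z_params(features),
         cost = cost, gamma = gamma, coef0 = coef0),
    class = "leukdx_svm")
}

#' Predict disease categories with a trained SVM
#'
#' @param object A `leukdx_svm` model.
#' @param newdata Either an expression matrix (genes x samples; it is
#'   standardized with the model's stored parameters) or an already
#'   standardized samples x genes feature table (set `standardized = TRUE`).
#' @param standardized Set to `TRUE` when `newdata` is already on the
#'   training z-scale.
#' @param ... Unused.
#' @return Factor of predicted classes, named by sample.
#' @export
predict.leukdx_svm <- function(object, newdata, standardized = FALSE, ...) {
  z <- if (standardized) {
    newdata[, names(object$standardization$center), drop = FALSE]
  } else {
    z_transform(newdata, object$feature_genes,
                params = object$standardization)
  }
  votes <- matrix(0L, nrow(z), length(object$classes),
                  dimnames = list(rownames(z), object$classes))
  for (i in seq_along(object$machines)) {
    p <- as.character(stats::predict(object$machines[[i]], z))
    for (cl in object$pairs[[i]])
      votes[, cl] <- votes[, cl] + (p == cl)
  }
  # ties fall to the first class in the fixed order (columns are ordered)
  pred <- object$classes[apply(votes, 1L, which.max)]
  factor(stats::setNames(pred, rownames(z)), levels = LEUKDX_CLASSES)
}

#' @export
print.leukdx_svm <- function(x, ...) {
  cat("One-vs-one sigmoid-kernel SVM\n")
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  features: %d gene(s)", length(x$standardization$center)))
  if (length(x$standardization$dropped))
    cat(sprintf(" (%d zero-variance dropped)",
                length(x$standardization$dropped)))
  cat(sprintf("\n  cost = %g, gamma = %g, coef0 = %g\n",
              x$cost, x$gamma, x$coef0))
  invisible(x)
}

#' Leave-one-out cross-validation of the SVM
#'
#' For each sample in turn, the standardization parameters and the one-vs-one
#' SVM are refitted on the remaining samples only (so no information from the
#' held-out sample leaks into the fold), and the held-out sample is
#' predicted. Requires at least 2 samples per class so that every fold
#' retains all classes.
#'
#' @param x Expression matrix (genes x samples).
#' @param labels Named character vector of labels.
#' @param genes Feature genes (e.g. `c(model$aml_genes, model$ball_genes)`).
#' @param cost,gamma,coef0 SVM parameters, as in [train_svm()].
#' @return An object of class `leukdx_cv`: list with `predictions`
#'   (`data.frame` of `sample_id`, `true`, `predicted`), `accuracy`, and the
#'   per-class `sensitivity` and `specificity` of [evaluate_predictions()].
#' @export
leave_one_out_cv <- function(x, labels, genes, cost = 1, gamma = NULL,
                             coef0 = 0) {
  validate_expression_matrix(x)
  labels <- align_labels(x, labels)
  counts <- table(labels)
  if (any(counts < 2L))
    stop("leave-one-out needs >= 2 samples per class; short class(es): ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  n <- ncol(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    ztr <- suppressWarnings(
      z_transform(x[, -i, drop = FALSE], genes))
    fit <- train_svm(ztr, labels[-i], cost = cost, gamma = gamma,
                     coef0 = coef0)
    pred[i] <- as.character(
      predict(fit, x[, i, drop = FALSE]))
  }
  predictions <- data.frame(sample_id = colnames(x),
                            true = unname(labels),
                            predicted = pred,
                            stringsAsFactors = FALSE)
  ev <- evaluate_predictions(predictions$true, predictions$predicted)
  structure(list(predictions = predictions,
                 accuracy = ev$accuracy,
                 sensitivity = ev$sensitivity,
                 specificity = ev$specificity,
                 confusion = ev$confusion),
            class = "leukdx_cv")
}

#' @export
print.leukdx_cv <- function(x, ...) {
  cat("Leave-one-out cross-validation\n")
  cat(sprintf("  samples: %d   accuracy: %.1f%%\n",
              nrow(x$predictions), 100 * x$accuracy))
  m <- rbind(sensitivity = x$sensitivity, specificity = x$specificity)
  print(round(100 * m, 1))
  invisible(x)
}
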