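#' Calibrate per-gene positivity thresholds
#'
#' Each signature gene gets one positivity threshold separating its two
#' training expression regimes. The base threshold is the geometric mean of
#' the gene's AML and B-ALL training group means, i.e. the midpoint in log
#' space, optionally scaled by a single global multiplier `k`. `k` is chosen
#' by grid search over `k_grid` to maximize the balanced training accuracy of
#' the two-score decision rule on the AML and B-ALL training samples
#' (MPAL samples take no part in calibration); ties are broken toward
#' `k = 1`, then toward the smaller `k`. The procedure is fully deterministic.
#'
#' The reference-gene anchor `ref_target` (used by [abl1_normalize()] when a
#' model is applied to an external cohort) is stored as the median expression
#' of `model$reference_gene` across the AML and B-ALL training samples, when
#' that gene is present.
#'
#' @param x Training expression matrix (genes x samples, FPKM).
#' @param labels Named character vector of training labels.
#' @param model `leukdx_signature` with non-empty gene lists.
#' @param cutoff Score cutoff used when evaluating the grid (default 30).
#' @param k_grid Candidate global multipliers (default 0.5 to 2.0 by 0.1).
#' @return The model with `thresholds`, `k` and (if available) `ref_target`
#'   filled in; every threshold is strictly positive.
#' @export
calibrate_thresholds <- function(x, labels, model, cutoff = 30,
                                 k_grid = seq(0.5, 2.0, by = 0.1)) {
  stopifnot(inherits(model, "leukdx_signature"))
  validate_expression_matrix(x)
  labels <- align_labels(x, labels)
  genes <- c(model$aml_genes, model$ball_genes)
  if (length(genes) == 0L) stop("signature gene lists are empty")
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("signature gene(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  ia <- which(labels == "AML")
  ib <- which(labels == "B-ALL")
  if (length(ia) == 0L || length(ib) == 0L)
    stop("calibration needs both AML and B-ALL training samples")
  ma <- rowMeans(x[genes, ia, drop = FALSE])
  mb <- rowMeans(x[genes, ib, drop = FALSE])
  base <- sqrt(ma * mb)
  # a gene silent in one group would give threshold 0; keep it positive
  base[base <= 0] <- 0.1

  train_idx <- c(ia, ib)
  train_lab <- labels[train_idx]
  balanced_acc <- function(k) {
    m <- model
    m$thresholds <- base * k
    sc <- compute_scores(x[, train_idx, drop = FALSE], m)
    call <- classify(sc, cutoff = cutoff)
    mean(c(mean(call[train_lab == "AML"] == "AML"),
           mean(call[train_lab == "B-ALL"] == "B-ALL")))
  }
  acc <- vapply(k_grid, balanced_acc, numeric(1))
  best <- which(acc == max(acc))
  # ties: prefer k closest to 1, then the smaller k
  best <- best[order(abs(k_grid[best] - 1), k_grid[best])][1L]
  k <- k_grid[best]

  model$thresholds <- base * k
  model$k <- k
  if (!is.null(model$reference_gene) &&
      model$reference_gene %in% rownames(x)) {
    model$ref_target <- stats::median(x[model$reference_gene, train_idx])
  }
  model
}

#' Compute AML and B-ALL scores
#'
#' A sample's AML score is 100 times the proportion of AML-specific signature
#' genes whose FPKM strictly exceeds their positivity threshold; the B-ALL
#' score is the analogue over the B-ALL-specific genes. A value exactly equal
#' to its threshold does not count as positive.
#'
#' @param x Expression matrix (genes x samples) or a single named expression
#'   vector for one sample.
#' @param model Calibrated `leukdx_signature`.
#' @return A `data.frame` with columns `sample_id`, `aml_score`, `ball_score`,
#'   one row per sample; scores lie in \[0, 100\].
#' @export
compute_scores <- function(x, model) {
  stopifnot(inherits(model, "leukdx_signature"))
  if (is.null(model$thresholds))
    stop("model has no thresholds; run calibrate_thresholds() first")
  if (is.null(dim(x))) {
    if (is.null(names(x))) stop("a single-sample vector must be named by gene")
    x <- matrix(x, ncol = 1, dimnames = list(names(x), "sample"))
  }
  genes <- c(model$aml_genes, model$ball_genes)
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("signature gene(s) missing from input: ",
         paste(missing, collapse = ", "))
  thr_a <- model$thresholds[model$aml_genes]
  thr_b <- model$thresholds[model$ball_genes]
  pos_a <- x[model$aml_genes, , drop = FALSE] > thr_a
  pos_b <- x[model$ball_genes, , drop = FALSE] > thr_b
  data.frame(sample_id = colnames(x),
             aml_score = 100 * colMeans(pos_a),
             ball_score = 100 * colMeans(pos_b),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-score classification rule
#'
#' Calls the disease category from an (AML score, B-ALL score) pair:
#' AML when the AML score is at or above `cutoff` and the B-ALL score below
#' it; B-ALL in the mirrored case; MPAL when both scores reach the cutoff.
#' When both scores fall below the cutoff no category is supported and the
#' call is `Unclassified` (counted as incorrect in every accuracy reported by
#' this package).
#'
#' @param scores A `data.frame` from [compute_scores()] (columns `aml_score`,
#'   `ball_score`), or a numeric vector `c(aml_score, ball_score)` for a
#'   single sample.
#' @param cutoff Score cutoff in percent (default 30).
#' @return Factor with levels `AML`, `B-ALL`, `MPAL`, `Unclassified`.
#' @export
classify <- function(scores, cutoff = 30) {
  if (is.numeric(scores) && is.null(dim(scores)) && length(scores) == 2L)
    scores <- data.frame(aml_score = scores[1L], ball_score = scores[2L])
  a <- scores$aml_score
  b <- scores$ball_score
  if (any(a < 0 | a > 100 | b < 0 | b > 100))
    stop("scores must lie in [0, 100]")
  out <- ifelse(a >= cutoff & b < cutoff, "AML",
         ifelse(a < cutoff & b >= cutoff, "B-ALL",
         ifelse(a >= cutoff & b >= cutoff, "MPAL", "Unclassified")))
  factor(out, levels = c(LEUKDX_CLASSES, "Unclassified"))
}
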