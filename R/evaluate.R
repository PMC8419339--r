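#' Confusion-matrix evaluation of diagnostic calls
#'
#' Builds the true x predicted confusion matrix over the three disease
#' categories (plus `Unclassified`, which only ever appears as a prediction)
#' and derives overall accuracy and one-vs-rest sensitivity and specificity
#' per category. An `Unclassified` prediction is wrong for every true class,
#' so it lowers accuracy and the true class's sensitivity, but — not being a
#' positive call for any category — it never costs specificity.
#'
#' @param true True labels (character or factor).
#' @param predicted Predicted labels, aligned with `true`; may include
#'   `"Unclassified"`.
#' @return An object of class `leukdx_eval`: list with `confusion`,
#'   `accuracy`, `sensitivity` and `specificity` (named by class, `NA` for a
#'   class absent from `true`).
#' @export
evaluate_predictions <- function(true, predicted) {
  true <- as.character(true)
  predicted <- as.character(predicted)
  if (length(true) != length(predicted))
    stop("true and predicted labels differ in length (",
         length(true), " vs ", length(predicted), ")")
  lev <- c(LEUKDX_CLASSES, "Unclassified")
  bad <- setdiff(unique(c(true, predicted)), lev)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  confusion <- table(true = factor(true, levels = LEUKDX_CLASSES),
                     predicted = factor(predicted, levels = lev))
  n <- length(true)
  accuracy <- sum(true == predicted) / n
  sens <- spec <- stats::setNames(rep(NA_real_, 3L), LEUKDX_CLASSES)
  for (cl in LEUKDX_CLASSES) {
    tp <- sum(true == cl & predicted == cl)
    fn <- sum(true == cl & predicted != cl)
    fp <- sum(true != cl & predicted == cl)
    tn <- sum(true != cl & predicted != cl)
    if (tp + fn > 0) sens[cl] <- tp / (tp + fn)
    if (tn + fp > 0) spec[cl] <- tn / (tn + fp)
  }
  structure(list(confusion = confusion, accuracy = accuracy,
                 sensitivity = sens, specificity = spec, n = n),
            class = "leukdx_eval")
}

#' @export
print.leukdx_eval <- function(x, ...) {
  cat(sprintf("Diagnostic accuracy: %.1f%% (%d/%d)\n",
              100 * x$accuracy, round(x$accuracy * x$n), x$n))
  m <- rbind(sensitivity = x$sensitivity, specificity = x$specificity)
  print(round(100 * m, 1))
  cat("Confusion matrix (true x predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Compare scores across disease categories (ANOVA + Bonferroni)
#'
#' For each of the AML and B-ALL scores, runs a one-way ANOVA across the
#' disease categories followed by Bonferroni-corrected pairwise comparisons
#' (pooled-SD t-tests; adjusted p = min(1, 3p) for the three category pairs).
#'
#' @param scores `data.frame` from [compute_scores()] (one row per sample).
#' @param labels Named character vector of category labels.
#' @return A list with one element per score (`aml_score`, `ball_score`),
#'   each a list with `f` (ANOVA F), `p` (ANOVA p-value), `group_means`, and
#'   `pairwise`, a `data.frame` of `group1`, `group2`, `p_value`,
#'   `p_adjusted`.
#' @export
compare_scores_anova <- function(scores, labels) {
  validate_labels(labels)
  lab <- labels[scores$sample_id]
  if (any(is.na(lab))) stop("every scored sample must be labeled")
  counts <- table(lab)
  if (any(counts < 2L))
    stop("each category needs >= 2 samples; short: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  g <- factor(as.character(lab), levels = names(counts))
  one <- function(v) {
    fit <- stats::aov(v ~ g)
    tab <- summary(fit)[[1L]]
    prs <- utils::combn(levels(g), 2L, simplify = FALSE)
    raw <- suppressWarnings(
      stats::pairwise.t.test(v, g, p.adjust.method = "none",
                             pool.sd = TRUE))$p.value
    pw <- do.call(rbind, lapply(prs, function(pr) {
      p <- if (!is.na(raw[pr[2L], pr[1L]])) raw[pr[2L], pr[1L]]
           else raw[pr[1L], pr[2L]]
      data.frame(group1 = pr[1L], group2 = pr[2L], p_value = p,
                 p_adjusted = min(1, length(prs) * p),
                 stringsAsFactors = FALSE)
    }))
    list(f = tab[["F value"]][1L], p = tab[["Pr(>F)"]][1L],
         group_means = tapply(v, g, mean), pairwise = pw)
  }
  list(aml_score = one(scores$aml_score),
       ball_score = one(scores$ball_score))
}

#' Export Figure-style score scatter data
#'
#' Writes the per-sample score pairs with their true labels as a CSV ready
#' for a two-score scatter plot (AML score vs B-ALL score, one point per
#' sample, colored by category).
#'
#' @param scores `data.frame` from [compute_scores()].
#' @param labels Named character vector of labels.
#' @param path Output CSV path.
#' @export
export_score_scatter <- function(scores, labels, path) {
  lab <- labels[scores$sample_id]
  out <- data.frame(sample_id = scores$sample_id,
                    aml_score = scores$aml_score,
                    ball_score = scores$ball_score,
                    true_label = unname(lab))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
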