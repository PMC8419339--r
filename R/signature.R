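#' Per-gene differential expression between two disease categories
#'
#' Screens every gene for differential expression between two labeled groups
#' with a Welch two-sample t-test on log2(FPKM + 1), followed by
#' Benjamini-Hochberg FDR adjustment across all tested genes. Fold change is
#' the ratio of raw group means with a small offset,
#' `(mean_a + 0.1) / (mean_b + 0.1)`, so zero-expression genes stay defined.
#'
#' @param x Expression matrix (genes x samples, FPKM).
#' @param labels Named character vector of sample labels.
#' @param group_a,group_b The two categories to contrast; defaults contrast
#'   AML against B-ALL, the comparison that defines the lineage signatures.
#'   Samples from other categories (e.g. MPAL) are ignored.
#' @return A `data.frame` with one row per gene: `gene`, `mean_aml` and
#'   `mean_ball` (raw FPKM group means of `group_a` and `group_b`),
#'   `fold_change`, `p_value`, `q_value`.
#' @export
differential_test <- function(x, labels, group_a = "AML", group_b = "B-ALL") {
  validate_expression_matrix(x)
  labels <- align_labels(x, labels)
  ia <- which(labels == group_a)
  ib <- which(labels == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each group needs at least 2 samples (got ", length(ia), " ",
         group_a, ", ", length(ib), " ", group_b, ")")
  l <- log2(x + 1)
  la <- l[, ia, drop = FALSE]
  lb <- l[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- rowSums((la - ma)^2) / (na - 1L)
  vb <- rowSums((lb - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  # both groups constant and equal: no evidence against the null
  p[se2 == 0 & ma == mb] <- 1
  q <- stats::p.adjust(p, method = "BH")
  mean_a <- rowMeans(x[, ia, drop = FALSE])
  mean_b <- rowMeans(x[, ib, drop = FALSE])
  data.frame(gene = rownames(x),
             mean_aml = unname(mean_a),
             mean_ball = unname(mean_b),
             fold_change = unname((mean_a + 0.1) / (mean_b + 0.1)),
             p_value = unname(p),
             q_value = unname(q),
             stringsAsFactors = FALSE)
}

#' Select lineage-signature genes
#'
#' Applies the three signature filters to a differential-expression scan of
#' AML against B-ALL: a gene is AML-specific when its fold change exceeds
#' `fold_min`, its FDR q-value is below `q_max`, and its mean FPKM in AML is
#' at least `fpkm_min`; B-ALL-specific genes satisfy the mirrored conditions
#' (`fold_change < 1/fold_min`, `mean_ball >= fpkm_min`). The two lists are
#' disjoint by construction. Thresholds are left unset until
#' [calibrate_thresholds()] is run.
#'
#' @param results Output of [differential_test()] (AML vs B-ALL).
#' @param fold_min Minimum fold change (default 2).
#' @param q_max Maximum FDR q-value (default 0.05).
#' @param fpkm_min Minimum mean FPKM in the overexpressing group (default 100).
#' @param reference_gene Reference gene recorded for later normalization.
#' @return An object of class `leukdx_signature`: a list with `aml_genes`,
#'   `ball_genes`, `thresholds` (NULL until calibrated), `reference_gene`,
#'   `ref_target` (NULL until calibrated), and the filter settings.
#' @export
select_signature <- function(results, fold_min = 2, q_max = 0.05,
                             fpkm_min = 100, reference_gene = "ABL1") {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("empty differential-expression result")
  need <- c("gene", "mean_aml", "mean_ball", "fold_change", "q_value")
  if (!all(need %in% names(results)))
    stop("results must come from differential_test()")
  aml <- results$gene[results$fold_change > fold_min &
                        results$q_value < q_max &
                        results$mean_aml >= fpkm_min]
  ball <- results$gene[results$fold_change < 1 / fold_min &
                         results$q_value < q_max &
                         results$mean_ball >= fpkm_min]
  if (length(aml) == 0L) warning("no AML-specific genes passed the filters")
  if (length(ball) == 0L) warning("no B-ALL-specific genes passed the filters")
  structure(
    list(aml_genes = aml, ball_genes = ball, thresholds = NULL,
         reference_gene = reference_gene, ref_target = NULL, k = NULL,
         filters = list(fold_min = fold_min, q_max = q_max,
                        fpkm_min = fpkm_min)),
    class = "leukdx_signature")
}

#' @export
print.leukdx_signature <- function(x, ...) {
  cat("Lineage signature model\n")
  cat(sprintf("  AML-specific genes:   %d\n", length(x$aml_genes)))
  cat(sprintf("  B-ALL-specific genes: %d\n", length(x$ball_genes)))
  if (is.null(x$thresholds)) {
    cat("  thresholds: not calibrated\n")
  } else {
    cat(sprintf("  thresholds: calibrated (k = %.2f)\n", x$k))
  }
  if (!is.null(x$ref_target))
    cat(sprintf("  reference gene %s anchored at %.3g FPKM\n",
                x$reference_gene, x$ref_target))
  invisible(x)
}

#' Serialize a signature model to JSON
#'
#' The on-disk form is
#' `{"aml_genes": [...], "ball_genes": [...], "thresholds": {gene: value}}`
#' plus the reference-gene anchor, readable back with [read_signature()].
#'
#' @param model A `leukdx_signature` object.
#' @param path Output path.
#' @export
write_signature <- function(model, path) {
  stopifnot(inherits(model, "leukdx_signature"))
  obj <- list(aml_genes = model$aml_genes,
              ball_genes = model$ball_genes,
              thresholds = as.list(model$thresholds),
              reference_gene = model$reference_gene,
              ref_target = model$ref_target,
              k = model$k,
              filters = model$filters)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  thr <- obj$thresholds
  if (is.list(thr)) thr <- unlist(thr)
  if (length(thr) == 0L) thr <- NULL
  structure(
    list(aml_genes = as.character(obj$aml_genes),
         ball_genes = as.character(obj$ball_genes),
         thresholds = thr,
         reference_gene = obj$reference_gene,
         ref_target = obj$ref_target,
         k = obj$k,
         filters = obj$filters),
    class = "leukdx_signature")
}
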