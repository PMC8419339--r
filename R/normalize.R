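#' Reference-gene (ABL1) normalization
#'
#' Rescales every sample so that the reference gene sits at a common target
#' level: each column is multiplied by `target_level / x[reference_gene, j]`.
#' Anchoring expression to a stably expressed internal control gene lets a
#' model trained on one cohort be applied to expression data from another
#' platform or pipeline, and makes scoring invariant to any per-sample global
#' scale factor. The operation is idempotent.
#'
#' @param x Expression matrix (genes x samples).
#' @param reference_gene Reference gene symbol (default `"ABL1"`).
#' @param target_level FPKM level the reference gene is anchored to. When a
#'   fitted model is applied via [predict.leukdx()], the training-cohort
#'   median stored in the signature model is used; when `NULL` here, the
#'   median reference value of `x` itself.
#' @return The rescaled matrix; `x[reference_gene, ]` equals `target_level`
#'   in every sample.
#' @export
abl1_normalize <- function(x, reference_gene = "ABL1", target_level = NULL) {
  validate_expression_matrix(x)
  if (!reference_gene %in% rownames(x))
    stop("reference gene ", reference_gene, " absent from matrix")
  ref <- x[reference_gene, ]
  zero <- names(ref)[ref <= 0]
  if (length(zero))
    stop("reference gene ", reference_gene,
         " is zero in sample(s): ", paste(zero, collapse = ", "))
  if (is.null(target_level)) target_level <- stats::median(ref)
  if (!is.finite(target_level) || target_level <= 0)
    stop("target_level must be a positive number")
  sweep(x, 2L, target_level / ref, "*")
}
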