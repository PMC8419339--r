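#' Expression-aware detectability of DNA variants in RNA-seq
#'
#' RNA-seq can only report a variant if the host gene is transcribed: in the
#' 12-case cohort the DNA panel's variants were all recovered from RNA-seq
#' except those on genes expressed below 1 FPKM. This partitions a variant
#' table by that expression criterion and reports how well the expectation
#' agrees with the observed RNA-seq detection status.
#'
#' @param records Variant `data.frame` (see [read_variant_table()]).
#' @param fpkm_min Expression level below which detection is not expected
#'   (default 1.0 FPKM).
#' @return A list with `expected_detectable` and `expected_missed` (the two
#'   row subsets), and `concordance`, the fraction of records whose observed
#'   `detected` status matches the expression-based expectation.
#' @export
detectability_filter <- function(records, fpkm_min = 1.0) {
  validate_variant_table(records)
  missed <- records$fpkm < fpkm_min
  list(expected_detectable = records[!missed, , drop = FALSE],
       expected_missed = records[missed, , drop = FALSE],
       concordance = mean(records$detected == !missed))
}

#' DNA vs RNA-seq variant allele frequency concordance
#'
#' Pearson correlation between the VAF measured by DNA panel sequencing and
#' the VAF recovered from RNA-seq, over all records carrying both values;
#' the p-value comes from the t-distribution with n - 2 degrees of freedom.
#' Records without an RNA-seq VAF are excluded. Optionally, records on genes
#' expressed below `exclude_low_fpkm` can also be excluded.
#'
#' @param records Variant `data.frame` (see [read_variant_table()]).
#' @param exclude_low_fpkm Optional FPKM floor: records with `fpkm` below it
#'   are dropped from the correlation (default `NULL`, no exclusion).
#' @return A list with `r` (Pearson coefficient), `p` (two-sided p-value) and
#'   `n` (pairs used).
#' @export
vaf_correlation <- function(records, exclude_low_fpkm = NULL) {
  validate_variant_table(records)
  keep <- !is.na(records$rna_vaf)
  if (!is.null(exclude_low_fpkm))
    keep <- keep & records$fpkm >= exclude_low_fpkm
  d <- records[keep, , drop = FALSE]
  if (nrow(d) < 3L)
    stop("need at least 3 records with both VAFs, got ", nrow(d))
  ct <- stats::cor.test(d$dna_vaf, d$rna_vaf, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d))
}
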