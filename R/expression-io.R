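#' @keywords internal
"_PACKAGE"

# Disease categories, in the fixed order used for deterministic tie-breaking.
LEUKDX_CLASSES <- c("AML", "B-ALL", "MPAL")

#' Validate an FPKM expression matrix
#'
#' An expression matrix is a plain numeric matrix of FPKM values with genes in
#' rows and samples in columns; row names are gene symbols and column names are
#' sample identifiers. Values must be finite and non-negative, identifiers
#' unique, and the matrix non-empty.
#'
#' @param x Numeric matrix, genes x samples, with dimnames.
#' @return `x`, invisibly, if valid; otherwise an error describing the first
#'   violation (duplicated identifiers are named; offending cells are located
#'   by gene and sample).
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix (genes x samples)")
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("expression matrix must have at least 1 gene and 1 sample")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene row names and sample column names")
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g))
    stop("duplicated gene identifier(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    stop("duplicated sample identifier(s): ", paste(dup_s, collapse = ", "))
  bad <- which(!is.finite(x) | x < 0)
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(x)) + 1L
    stop(sprintf("non-finite or negative FPKM at gene '%s', sample '%s'",
                 rownames(x)[i], colnames(x)[j]))
  }
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a UTF-8 tab-separated file whose header row names the samples and
#' whose first column holds gene symbols, one gene per row. Input ordering of
#' genes and samples is preserved.
#'
#' @param path Path to the TSV file.
#' @return A validated numeric matrix (genes x samples).
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a gene column plus at least one sample column")
  genes <- as.character(df[[1L]])
  samples <- names(df)[-1L]  # keep duplicates intact for validation
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric FPKM at gene '%s', sample '%s'",
                     genes[bad[1L]], samples[j]))
      vals[[j]] <- vn
    }
  }
  x <- as.matrix(vals)
  dimnames(x) <- list(genes, samples)
  validate_expression_matrix(x)
  x
}

#' Write an expression matrix to TSV
#'
#' @param x Validated expression matrix (genes x samples).
#' @param path Output file path.
#' @param gene_column Name used for the first header field.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, gene_column = "gene") {
  validate_expression_matrix(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- gene_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a sample label table
#'
#' Labels live in a two-column TSV (`sample_id<TAB>label`) and must be one of
#' `"AML"`, `"B-ALL"`, `"MPAL"`. In R they are carried as a named character
#' vector, names being sample identifiers.
#'
#' @param path Path to the TSV file.
#' @return `read_labels()`: a named character vector of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label table needs columns sample_id and label")
  labels <- stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
  validate_labels(labels)
  labels
}

#' @rdname read_labels
#' @param labels Named character vector of labels.
#' @export
write_labels <- function(labels, path) {
  validate_labels(labels)
  utils::write.table(
    data.frame(sample_id = names(labels), label = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_labels
#' @export
validate_labels <- function(labels) {
  if (is.null(names(labels)) || any(names(labels) == ""))
    stop("every label must be named by its sample identifier")
  bad <- setdiff(unique(labels), LEUKDX_CLASSES)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "),
         " (expected AML, B-ALL or MPAL)")
  dup <- unique(names(labels)[duplicated(names(labels))])
  if (length(dup))
    stop("duplicated sample identifier(s) in labels: ",
         paste(dup, collapse = ", "))
  invisible(labels)
}

# Align a label vector to the columns of a matrix; error on unlabeled samples.
align_labels <- function(x, labels) {
  validate_labels(labels)
  missing <- setdiff(colnames(x), names(labels))
  if (length(missing))
    stop("unlabeled sample(s): ", paste(missing, collapse = ", "))
  labels[colnames(x)]
}

#' Read a variant table
#'
#' Variant tables are CSV files with header
#' `case,gene,dna_vaf,rna_vaf,fpkm,detected`. `dna_vaf` and `rna_vaf` are
#' percentages in \[0, 100\]; a missing RNA-seq VAF may be written as an empty
#' cell or `"-"` and is returned as `NA` (such rows are excluded from the
#' VAF correlation). `detected` records whether RNA-seq detected the variant.
#'
#' The packaged fixture `leukdx_example("table2_variants.csv")` holds the 14
#' mutations of the 12-case BCR-ABL1 cohort as printed in the source study,
#' with DNA-panel and RNA-seq VAFs and per-gene FPKM.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with columns `case`, `gene`, `dna_vaf`,
#'   `rna_vaf` (may contain `NA`), `fpkm`, `detected` (logical).
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        na.strings = c("", "-", "NA"))
  need <- c("case", "gene", "dna_vaf", "rna_vaf", "fpkm", "detected")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  df$dna_vaf <- as.numeric(df$dna_vaf)
  df$rna_vaf <- as.numeric(df$rna_vaf)
  df$fpkm <- as.numeric(df$fpkm)
  df$detected <- as.logical(df$detected)
  validate_variant_table(df)
  df
}

#' @rdname read_variant_table
#' @param records Variant `data.frame` as returned by `read_variant_table()`.
#' @export
write_variant_table <- function(records, path) {
  validate_variant_table(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname read_variant_table
#' @export
validate_variant_table <- function(records) {
  if (any(is.na(records$dna_vaf)))
    stop("dna_vaf must be present for every record")
  if (any(records$dna_vaf < 0 | records$dna_vaf > 100))
    stop("dna_vaf outside [0, 100]")
  rv <- records$rna_vaf[!is.na(records$rna_vaf)]
  if (any(rv < 0 | rv > 100)) stop("rna_vaf outside [0, 100]")
  if (any(is.na(records$fpkm) | records$fpkm < 0))
    stop("fpkm must be present and >= 0")
  if (any(is.na(records$detected)))
    stop("detected must be TRUE or FALSE for every record")
  invisible(records)
}

#' Locate a packaged example file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return Full path to the file.
#' @export
leukdx_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "leukdx")))
  path <- system.file("extdata", file, package = "leukdx")
  if (path == "") stop("no packaged file named ", file)
  path
}
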