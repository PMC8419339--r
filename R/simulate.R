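#' Configuration for the synthetic expression generator
#'
#' The generator emulates the expression structure the diagnostic models rely
#' on: two blocks of lineage-signature genes expressed high in their own
#' lineage and low in the other, MPAL samples that partially activate both
#' programs, a block of background genes at a common level in all categories,
#' a reference gene (`ABL1`) emitted at a fixed level, and a per-sample
#' global scale factor emulating library-size / platform variation (which
#' the reference gene tracks, so [abl1_normalize()] can undo it). FPKM noise
#' is log-normal on the log2 scale.
#'
#' @param n_per_group Samples per category. A single number gives equal
#'   groups; a vector of three is taken in the order (B-ALL, AML, MPAL), or
#'   may be named.
#' @param n_aml_sig,n_ball_sig Planted AML- and B-ALL-specific gene counts
#'   (defaults 251 and 117, the signature sizes of the 12-case study).
#' @param n_background Background genes (default 2000).
#' @param base_high FPKM level of a signature gene in its own lineage
#'   (default 200).
#' @param base_low FPKM level in the opposite lineage (default 20).
#' @param base_background Common FPKM level of background genes (default 20).
#' @param sigma_log2 Log-normal noise sd on the log2 scale (default 0.5).
#' @param mpal_mix_range Interval for the per-sample MPAL mixing fraction
#'   lambda: the fraction of each signature set an MPAL sample expresses at
#'   its own-lineage level (default c(0.3, 0.7)).
#' @param sample_scale_range Interval for the per-sample global scale factor
#'   (default c(0.5, 2)).
#' @param reference_level FPKM at which the reference gene is emitted before
#'   per-sample scaling (default 100).
#' @param reference_gene Reference gene symbol (default `"ABL1"`).
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A validated list of class `leukdx_config`.
#' @export
synthetic_config <- function(n_per_group = 20, n_aml_sig = 251,
                             n_ball_sig = 117, n_background = 2000,
                             base_high = 200, base_low = 20,
                             base_background = 20, sigma_log2 = 0.5,
                             mpal_mix_range = c(0.3, 0.7),
                             sample_scale_range = c(0.5, 2),
                             reference_level = 100,
                             reference_gene = "ABL1", seed = 0) {
  if (length(n_per_group) == 1L)
    n_per_group <- rep(n_per_group, 3L)
  if (is.null(names(n_per_group))) {
    if (length(n_per_group) != 3L)
      stop("n_per_group must be one number or three (B-ALL, AML, MPAL)")
    names(n_per_group) <- c("B-ALL", "AML", "MPAL")
  }
  n_per_group <- n_per_group[LEUKDX_CLASSES]
  if (any(is.na(n_per_group)) || any(n_per_group < 0))
    stop("n_per_group must give a non-negative count for each category")
  stopifnot(n_aml_sig >= 0, n_ball_sig >= 0, n_background >= 0,
            base_high > 0, base_low > 0, base_background > 0,
            sigma_log2 >= 0, reference_level > 0)
  if (length(mpal_mix_range) != 2L || mpal_mix_range[1] > mpal_mix_range[2] ||
      mpal_mix_range[1] <= 0 || mpal_mix_range[2] >= 1)
    stop("mpal_mix_range must be an interval inside (0, 1)")
  if (length(sample_scale_range) != 2L || sample_scale_range[1] <= 0 ||
      sample_scale_range[1] > sample_scale_range[2])
    stop("sample_scale_range must be a positive interval")
  structure(list(n_per_group = n_per_group, n_aml_sig = n_aml_sig,
                 n_ball_sig = n_ball_sig, n_background = n_background,
                 base_high = base_high, base_low = base_low,
                 base_background = base_background, sigma_log2 = sigma_log2,
                 mpal_mix_range = mpal_mix_range,
                 sample_scale_range = sample_scale_range,
                 reference_level = reference_level,
                 reference_gene = reference_gene,
                 seed = as.integer(seed)),
            class = "leukdx_config")
}

#' Generate a labeled synthetic FPKM matrix
#'
#' Draws an expression matrix under the structure described in
#' [synthetic_config()]: every signature gene of an AML sample is drawn
#' log-normally around `base_high` (its own lineage) or `base_low` (the
#' other), B-ALL mirrored; an MPAL sample draws a mixing fraction lambda
#' uniformly from `mpal_mix_range` and expresses a random lambda-fraction of
#' each signature set at the own-lineage level; background genes sit at a
#' common level in all samples. The reference gene is emitted at
#' `reference_level`, then each column is multiplied by its sample scale
#' factor. Fully reproducible from `config$seed`.
#'
#' @param config A `leukdx_config` (or arguments for one via `...`).
#' @param ... Passed to [synthetic_config()] when `config` is missing.
#' @return A list with `matrix` (validated genes x samples FPKM matrix),
#'   `labels` (named character vector) and `truth`, the ground truth
#'   (`aml_genes`, `ball_genes`, `mpal_lambda`, `scale_factors`, `labels`).
#' @export
simulate_expression <- function(config = synthetic_config(...), ...) {
  stopifnot(inherits(config, "leukdx_config"))
  set.seed(config$seed)
  npg <- config$n_per_group
  n <- sum(npg)
  if (n < 1L) stop("no samples requested")
  labels <- rep(names(npg), npg)
  sample_ids <- paste0("S", seq_len(n))
  aml_genes <- if (config$n_aml_sig)
    paste0("AMLSIG", seq_len(config$n_aml_sig)) else character()
  ball_genes <- if (config$n_ball_sig)
    paste0("BALLSIG", seq_len(config$n_ball_sig)) else character()
  bg_genes <- if (config$n_background)
    paste0("BG", seq_len(config$n_background)) else character()
  genes <- c(aml_genes, ball_genes, bg_genes, config$reference_gene)
  G <- length(genes)
  ia <- seq_along(aml_genes)
  ib <- length(aml_genes) + seq_along(ball_genes)

  mu <- matrix(log2(config$base_background), G, n,
               dimnames = list(genes, sample_ids))
  lambda <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    if (labels[j] == "AML") {
      mu[ia, j] <- log2(config$base_high)
      mu[ib, j] <- log2(config$base_low)
    } else if (labels[j] == "B-ALL") {
      mu[ia, j] <- log2(config$base_low)
      mu[ib, j] <- log2(config$base_high)
    } else {
      l <- stats::runif(1, config$mpal_mix_range[1], config$mpal_mix_range[2])
      lambda[j] <- l
      mu[ia, j] <- log2(config$base_low)
      mu[ib, j] <- log2(config$base_low)
      if (length(ia))
        mu[sample(ia, round(l * length(ia))), j] <- log2(config$base_high)
      if (length(ib))
        mu[sample(ib, round(l * length(ib))), j] <- log2(config$base_high)
    }
  }
  x <- 2^(mu + matrix(stats::rnorm(G * n, 0, config$sigma_log2), G, n))
  x[config$reference_gene, ] <- config$reference_level
  sf <- stats::runif(n, config$sample_scale_range[1],
                     config$sample_scale_range[2])
  x <- sweep(x, 2L, sf, "*")
  validate_expression_matrix(x)
  list(matrix = x,
       labels = stats::setNames(labels, sample_ids),
       truth = list(aml_genes = aml_genes, ball_genes = ball_genes,
                    mpal_lambda = stats::setNames(lambda, sample_ids),
                    scale_factors = stats::setNames(sf, sample_ids),
                    labels = stats::setNames(labels, sample_ids)))
}

#' Generate a synthetic variant table
#'
#' Emits `n` variant records with DNA VAFs uniform on \[5, 70\] and RNA VAFs
#' from a bivariate-normal construction with target correlation `rho`
#' (clipped to \[0, 100\]). A `frac_low_expression` fraction of the records is
#' assigned FPKM below 1 and, mirroring RNA-seq's inability to call variants
#' on silent genes, has its RNA VAF removed and `detected = FALSE`.
#'
#' @param n Number of records (>= 3).
#' @param rho Target DNA/RNA VAF correlation in \[-1, 1\].
#' @param frac_low_expression Proportion of records with FPKM < 1 (default 0).
#' @param seed Integer seed.
#' @return A validated variant `data.frame` (see [read_variant_table()]).
#' @export
simulate_variant_table <- function(n, rho, frac_low_expression = 0,
                                   seed = 0) {
  if (n < 3L) stop("n must be at least 3")
  if (!is.finite(rho) || rho < -1 || rho > 1)
    stop("rho must lie in [-1, 1]")
  if (frac_low_expression < 0 || frac_low_expression > 1)
    stop("frac_low_expression must lie in [0, 1]")
  set.seed(seed)
  dna <- stats::runif(n, 5, 70)
  z <- (dna - mean(dna)) / stats::sd(dna)
  rna <- mean(dna) + stats::sd(dna) *
    (rho * z + sqrt(1 - rho^2) * stats::rnorm(n))
  rna <- pmin(100, pmax(0, rna))
  fpkm <- stats::runif(n, 5, 300)
  low <- integer(0)
  n_low <- round(frac_low_expression * n)
  if (n_low > 0) {
    low <- sample.int(n, n_low)
    fpkm[low] <- stats::runif(n_low, 0.05, 0.95)
  }
  detected <- rep(TRUE, n)
  detected[low] <- FALSE
  rna[low] <- NA_real_
  records <- data.frame(case = paste0("CASE", seq_len(n)),
                        gene = paste0("GENE", seq_len(n)),
                        dna_vaf = round(dna, 2),
                        rna_vaf = round(rna, 2),
                        fpkm = round(fpkm, 2),
                        detected = detected,
                        stringsAsFactors = FALSE)
  validate_variant_table(records)
  records
}
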