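#' Run the full diagnostic pipeline from a config
#'
#' Executes every stage in order — simulate (or load) the expression data,
#' select and calibrate the signature, score and classify every sample, run
#' leave-one-out cross-validation of the SVM, and evaluate both models —
#' and writes all artifacts into `output_dir`:
#'
#' * `matrix.tsv`, `labels.tsv` — the data used (written when simulated)
#' * `signature.json` — signature genes and calibrated thresholds
#' * `scores.tsv` — per-sample scores, two-score call and SVM call
#' * `scatter.csv` — two-score scatter export with true labels
#' * `crossval.tsv` — per-sample LOOCV predictions
#' * `evaluation.json` — accuracy, per-class sensitivity/specificity for the
#'   scoring rule and the SVM LOOCV, ANOVA + Bonferroni score comparisons,
#'   and every parameter and seed used
#'
#' The config is a YAML file (or an equivalent named list) with an optional
#' `simulation` block (arguments of [synthetic_config()]) or an `inputs`
#' block (`matrix`, `labels` paths), an optional `params` block (`fold_min`,
#' `q_max`, `fpkm_min`, `cutoff`, `reference_gene`, `cost`, `coef0`) and
#' `output_dir`. A packaged demo config ships as
#' `leukdx_example("demo_config.yaml")`. Given the same config the run is
#' deterministic.
#'
#' @param config Path to a YAML config file, or a named list.
#' @param output_dir Overrides the config's `output_dir` when given.
#' @param verbose Log each stage to stderr (default TRUE).
#' @return Invisibly, a list with the fitted model, the cross-validation
#'   report, the evaluation list and the paths written.
#' @export
run_pipeline <- function(config, output_dir = NULL, verbose = TRUE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a named list")
  say <- function(...) if (verbose) message("[leukdx] ", ...)

  out <- output_dir %||% config$output_dir
  if (is.null(out)) stop("config must name an output_dir")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  if (!is.null(config$simulation)) {
    say("simulating expression data")
    cfg <- do.call(synthetic_config, config$simulation)
    sim <- simulate_expression(cfg)
    x <- sim$matrix
    labels <- sim$labels
    paths$matrix <- file.path(out, "matrix.tsv")
    paths$labels <- file.path(out, "labels.tsv")
    write_expression_matrix(x, paths$matrix)
    write_labels(labels, paths$labels)
  } else if (!is.null(config$inputs)) {
    if (is.null(config$inputs$matrix))
      stop("config inputs block must name the expression matrix file")
    if (is.null(config$inputs$labels))
      stop("config inputs block must name the labels table file")
    say("reading expression data")
    x <- read_expression_matrix(config$inputs$matrix)
    labels <- read_labels(config$inputs$labels)
  } else {
    stop("config must contain a 'simulation' or an 'inputs' block")
  }

  p <- config$params %||% list()
  fold_min <- p$fold_min %||% 2
  q_max <- p$q_max %||% 0.05
  fpkm_min <- p$fpkm_min %||% 100
  cutoff <- p$cutoff %||% 30
  reference_gene <- p$reference_gene %||% "ABL1"
  cost <- p$cost %||% 1
  coef0 <- p$coef0 %||% 0

  say("selecting signature and calibrating thresholds")
  fit <- leukdx(x, labels, fold_min = fold_min, q_max = q_max,
                fpkm_min = fpkm_min, cutoff = cutoff,
                reference_gene = reference_gene, cost = cost, coef0 = coef0)
  say(sprintf("signature: %d AML / %d B-ALL genes, k = %.2f",
              length(fit$signature$aml_genes),
              length(fit$signature$ball_genes), fit$signature$k))
  paths$signature <- file.path(out, "signature.json")
  write_signature(fit$signature, paths$signature)

  say("scoring and classifying samples")
  paths$scores <- file.path(out, "scores.tsv")
  utils::write.table(fit$training, paths$scores, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$scatter <- file.path(out, "scatter.csv")
  export_score_scatter(fit$training, labels, paths$scatter)

  say("leave-one-out cross-validation of the SVM")
  cv <- leave_one_out_cv(x, labels,
                         c(fit$signature$aml_genes,
                           fit$signature$ball_genes),
                         cost = cost, coef0 = coef0)
  paths$crossval <- file.path(out, "crossval.tsv")
  utils::write.table(cv$predictions, paths$crossval, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("evaluating both models")
  ev_score <- evaluate_predictions(fit$training$true, fit$training$call)
  anova <- compare_scores_anova(fit$training, labels)
  evaluation <- list(
    parameters = list(fold_min = fold_min, q_max = q_max,
                      fpkm_min = fpkm_min, cutoff = cutoff,
                      reference_gene = reference_gene, cost = cost,
                      coef0 = coef0, gamma = fit$svm$gamma,
                      threshold_multiplier_k = fit$signature$k,
                      seed = config$simulation$seed),
    scoring = list(accuracy = ev_score$accuracy,
                   sensitivity = as.list(ev_score$sensitivity),
                   specificity = as.list(ev_score$specificity)),
    svm_loocv = list(accuracy = cv$accuracy,
                     sensitivity = as.list(cv$sensitivity),
                     specificity = as.list(cv$specificity)),
    anova = lapply(anova, function(a)
      list(f = a$f, p = a$p, group_means = as.list(a$group_means),
           pairwise = a$pairwise)))
  paths$evaluation <- file.path(out, "evaluation.json")
  jsonlite::write_json(evaluation, paths$evaluation, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  say("done: ", out)
  invisible(list(fit = fit, crossval = cv, evaluation = evaluation,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
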