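test_that("z-transform standardizes with the population sd", {
  x <- rbind(G1 = c(1, 2, 3), G2 = c(5, 5, 8))
  colnames(x) <- paste0("s", 1:3)
  z <- z_transform(x, c("G1", "G2"))
  expect_equal(unname(z[, "G1"]), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)
  expect_equal(colMeans(z), c(G1 = 0, G2 = 0), tolerance = 1e-12)
  expect_equal(colMeans(z^2), c(G1 = 1, G2 = 1), tolerance = 1e-12)
})

test_that("zero-variance features are dropped and recorded", {
  x <- rbind(G1 = c(1, 2, 3), CONST = c(4, 4, 4))
  colnames(x) <- paste0("s", 1:3)
  expect_warning(z <- z_transform(x, c("G1", "CONST")), "CONST")
  expect_identical(colnames(z), "G1")
  expect_identical(attr(z, "dropped"), "CONST")
})

test_that("stored parameters place new samples on the training scale", {
  x <- rbind(G1 = c(1, 2, 3))
  colnames(x) <- paste0("s", 1:3)
  z <- z_transform(x, "G1")
  shifted <- rbind(G1 = c(12, 13))
  colnames(shifted) <- c("t1", "t2")
  zt <- z_transform(shifted, "G1", params = z_params_for_test(z))
  expect_true(all(zt[, "G1"] > 3))  # nonzero mean preserved, not re-centered
  expect_equal(unname(zt[, "G1"]), (c(12, 13) - 2) / sqrt(2 / 3))
})

test_that("a separable two-class toy problem is learned exactly", {
  feats <- matrix(c(-2, -1.5, 1.5, 2, -2, -1.7, 1.6, 2.2), ncol = 2,
                  dimnames = list(paste0("s", 1:4), c("G1", "G2")))
  attr(feats, "center") <- c(G1 = 0, G2 = 0)
  attr(feats, "scale") <- c(G1 = 1, G2 = 1)
  labels <- setNames(c("AML", "AML", "B-ALL", "B-ALL"), rownames(feats))
  fit <- train_svm(feats, labels)
  expect_equal(as.character(predict(fit, feats, standardized = TRUE)),
               unname(labels))
  # identical duplicated training gives identical predictions
  fit2 <- train_svm(feats, labels)
  expect_identical(predict(fit2, feats, standardized = TRUE),
                   predict(fit, feats, standardized = TRUE))
  expect_error(train_svm(feats, setNames(rep("AML", 4), rownames(feats))),
               "2 classes")
})

test_that("three-class training on synthetic defaults is near perfect", {
  fit <- default_fit()
  expect_gte(mean(fit$training$svm_call == fit$training$true), 0.95)
})

test_that("prediction is invariant to training sample order", {
  sim <- default_sim()
  genes <- c(sim$truth$aml_genes, sim$truth$ball_genes)
  x <- abl1_normalize(sim$matrix)
  z <- z_transform(x, genes)
  fit <- train_svm(z, sim$labels)
  set.seed(11)
  perm <- sample(nrow(z))
  zp <- z[perm, , drop = FALSE]
  attributes(zp)[c("center", "scale", "dropped")] <-
    attributes(z)[c("center", "scale", "dropped")]
  fit_p <- train_svm(zp, sim$labels)
  expect_identical(predict(fit, x), predict(fit_p, x))
})

test_that("the 12-case cohort cross-validates perfectly at high separation", {
  sim <- simulate_expression(cohort12_config(seed = 0))
  x <- abl1_normalize(sim$matrix)
  res <- differential_test(x, sim$labels)
  sig <- select_signature(res)
  cv <- leave_one_out_cv(x, sim$labels,
                         c(sig$aml_genes, sig$ball_genes))
  expect_equal(cv$accuracy, 1)
  expect_equal(unname(cv$sensitivity), c(1, 1, 1))
  expect_equal(unname(cv$specificity), c(1, 1, 1))
})

test_that("label permutation drops cross-validation to chance", {
  sim <- simulate_expression(cohort12_config(seed = 0))
  x <- abl1_normalize(sim$matrix)
  genes <- c(sim$truth$aml_genes, sim$truth$ball_genes)
  set.seed(1)
  shuffled <- setNames(sample(unname(sim$labels)), names(sim$labels))
  cv <- leave_one_out_cv(x, shuffled, genes)
  expect_lte(cv$accuracy, 0.6)
})

test_that("cross-validation runs at the minimal two-per-class size", {
  sim <- simulate_expression(
    synthetic_config(n_per_group = 2, n_background = 50, seed = 4))
  genes <- c(sim$truth$aml_genes, sim$truth$ball_genes)
  cv <- leave_one_out_cv(abl1_normalize(sim$matrix), sim$labels, genes)
  expect_equal(nrow(cv$predictions), 6L)
  lab <- sim$labels
  lab[names(lab) == "S1"] <- "B-ALL"  # leaves one AML sample
  expect_error(leave_one_out_cv(sim$matrix, lab, genes), "2 samples")
})

test_that("held-out samples do not influence the fold's standardization", {
  sim <- simulate_expression(
    synthetic_config(n_per_group = 2, n_aml_sig = 5, n_ball_sig = 5,
                     n_background = 10, seed = 5))
  x <- sim$matrix
  genes <- c(sim$truth$aml_genes, sim$truth$ball_genes)
  for (i in seq_len(ncol(x))) {
    p1 <- z_params_for_test(z_transform(x[, -i, drop = FALSE], genes))
    x2 <- x
    x2[, i] <- x2[, i] * 1000  # corrupt only the held-out column
    p2 <- z_params_for_test(z_transform(x2[, -i, drop = FALSE], genes))
    expect_identical(p1, p2)
  }
})

test_that("cross-validation metrics match the confusion oracle", {
  sim <- simulate_expression(cohort12_config(seed = 2))
  x <- abl1_normalize(sim$matrix)
  genes <- c(sim$truth$aml_genes, sim$truth$ball_genes)
  cv <- leave_one_out_cv(x, sim$labels, genes)
  oc <- oracle_confusion(cv$predictions$true, cv$predictions$predicted)
  expect_equal(cv$accuracy, oc$accuracy)
  expect_equal(cv$sensitivity, oc$sensitivity)
  expect_equal(cv$specificity, oc$specificity)
})
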