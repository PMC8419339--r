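test_that("perfect predictions give unit accuracy and per-class metrics", {
  true <- rep(c("AML", "B-ALL", "MPAL"), each = 2)
  ev <- evaluate_predictions(true, true)
  expect_equal(ev$accuracy, 1)
  expect_equal(unname(ev$sensitivity), c(1, 1, 1))
  expect_equal(unname(ev$specificity), c(1, 1, 1))
})

test_that("11 of 12 correct reports 91.7% accuracy", {
  true <- c(rep("B-ALL", 5), rep("AML", 3), rep("MPAL", 4))
  pred <- true
  pred[12] <- "Unclassified"
  ev <- evaluate_predictions(true, pred)
  expect_equal(ev$accuracy, 11 / 12)
  expect_equal(round(100 * ev$accuracy, 1), 91.7)
  expect_equal(round(100 * ev$accuracy), 92)
  # the unclassified call costs MPAL sensitivity but no class's specificity
  expect_equal(unname(ev$sensitivity), c(1, 1, 3 / 4))
  expect_equal(unname(ev$specificity), c(1, 1, 1))
})

test_that("a contrived confusion matrix matches hand-computed counts", {
  true <- c("AML", "AML", "AML", "B-ALL", "B-ALL", "MPAL", "MPAL", "MPAL")
  pred <- c("AML", "B-ALL", "MPAL", "B-ALL", "AML", "MPAL", "MPAL", "AML")
  ev <- evaluate_predictions(true, pred)
  expect_equal(ev$accuracy, 4 / 8)
  # AML: TP 1, FN 2, FP 2 (one B-ALL + one MPAL), TN 3
  expect_equal(unname(ev$sensitivity["AML"]), 1 / 3)
  expect_equal(unname(ev$specificity["AML"]), 3 / 5)
  # B-ALL: TP 1, FN 1, FP 1, TN 5
  expect_equal(unname(ev$sensitivity["B-ALL"]), 1 / 2)
  expect_equal(unname(ev$specificity["B-ALL"]), 5 / 6)
  expect_equal(unname(rowSums(ev$confusion)), c(3, 2, 3))
  expect_error(evaluate_predictions(true, pred[-1]), "length")
})

test_that("confusion metrics agree with the counting oracle on random draws", {
  set.seed(123)
  lev <- c("AML", "B-ALL", "MPAL", "Unclassified")
  for (i in 1:100) {
    n <- sample(6:30, 1)
    true <- sample(c("AML", "B-ALL", "MPAL"), n, replace = TRUE)
    pred <- sample(lev, n, replace = TRUE)
    ev <- evaluate_predictions(true, pred)
    oc <- oracle_confusion(true, pred)
    expect_equal(ev$accuracy, oc$accuracy, tolerance = 1e-10)
    expect_equal(ev$sensitivity, oc$sensitivity, tolerance = 1e-10)
    expect_equal(ev$specificity, oc$specificity, tolerance = 1e-10)
  }
})

anova_scores <- function(values, labels) {
  data.frame(sample_id = names(labels), aml_score = values,
             ball_score = values, stringsAsFactors = FALSE)
}

test_that("equal group means give a null ANOVA", {
  labels <- setNames(rep(c("AML", "B-ALL", "MPAL"), each = 3),
                     paste0("s", 1:9))
  v <- rep(c(10, 20, 30), 3)
  out <- compare_scores_anova(anova_scores(v, labels), labels)
  expect_lt(out$aml_score$f, 1e-12)
  expect_gt(out$aml_score$p, 0.99)
})

test_that("Bonferroni adjustment is min(1, 3p) and monotone", {
  set.seed(21)
  labels <- setNames(rep(c("AML", "B-ALL", "MPAL"), each = 6),
                     paste0("s", 1:18))
  v <- runif(18, 0, 100)
  out <- compare_scores_anova(anova_scores(v, labels), labels)
  pw <- out$aml_score$pairwise
  expect_equal(pw$p_adjusted, pmin(1, 3 * pw$p_value))
  expect_identical(order(pw$p_adjusted), order(pw$p_value))
})

test_that("two groups reduce to a pooled t-test with F = t^2", {
  set.seed(31)
  labels <- setNames(rep(c("AML", "B-ALL"), each = 8), paste0("s", 1:16))
  v <- c(rnorm(8, 60, 10), rnorm(8, 40, 10))
  out <- compare_scores_anova(anova_scores(v, labels), labels)
  tt <- t.test(v[1:8], v[9:16], var.equal = TRUE)
  expect_equal(out$aml_score$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out$aml_score$p, tt$p.value, tolerance = 1e-10)
  expect_equal(out$aml_score$pairwise$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("group sizes below two are rejected", {
  labels <- setNames(c("AML", "AML", "B-ALL", "B-ALL", "MPAL"),
                     paste0("s", 1:5))
  expect_error(
    compare_scores_anova(anova_scores(seq(10, 50, 10), labels), labels),
    "MPAL")
})

test_that("synthetic cohort scores reproduce the published group pattern", {
  fit <- default_fit()
  sim <- default_sim()
  out <- compare_scores_anova(fit$training, sim$labels)
  pw_a <- out$aml_score$pairwise
  p_of <- function(pw, g1, g2)
    pw$p_adjusted[(pw$group1 == g1 & pw$group2 == g2) |
                  (pw$group1 == g2 & pw$group2 == g1)]
  expect_lt(p_of(pw_a, "AML", "B-ALL"), 0.001)
  # the AML score separates AML from MPAL least sharply
  expect_gte(p_of(pw_a, "AML", "MPAL"), p_of(pw_a, "AML", "B-ALL"))
  pw_b <- out$ball_score$pairwise
  expect_lt(p_of(pw_b, "AML", "B-ALL"), 0.001)
  means_b <- out$ball_score$group_means
  expect_true(means_b["B-ALL"] > means_b["MPAL"] &&
              means_b["MPAL"] > means_b["AML"])
})

test_that("scatter export carries scores with true labels", {
  fit <- default_fit()
  sim <- default_sim()
  path <- withr::local_tempfile(fileext = ".csv")
  export_score_scatter(fit$training, sim$labels, path)
  back <- read.csv(path)
  expect_identical(names(back),
                   c("sample_id", "aml_score", "ball_score", "true_label"))
  expect_equal(nrow(back), length(sim$labels))
  expect_identical(back$true_label, unname(sim$labels[back$sample_id]))
})
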