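sig_of <- function(aml, ball, thresholds = NULL) {
  m <- suppressWarnings(select_signature(data.frame(
    gene = "x", mean_aml = 1, mean_ball = 1, fold_change = 1, q_value = 1)))
  m$aml_genes <- aml
  m$ball_genes <- ball
  m$thresholds <- thresholds
  m
}

test_that("thresholds are the geometric mean of the training group means", {
  # one gene per side, clean separation: every k classifies the training
  # samples perfectly, so the tie rule forces k = 1 and the pure rule shows
  x <- rbind(G1 = c(400, 400, 4, 4), G2 = c(4, 4, 400, 400))
  colnames(x) <- paste0("s", 1:4)
  labels <- setNames(c("AML", "AML", "B-ALL", "B-ALL"), colnames(x))
  m <- calibrate_thresholds(x, labels, sig_of("G1", "G2"))
  expect_equal(m$k, 1)
  expect_equal(unname(m$thresholds["G1"]), 40)  # sqrt(400 * 4)
  expect_equal(unname(m$thresholds["G2"]), 40)

  # equal group means m give threshold m (log-space midpoint of m and m)
  x2 <- rbind(G1 = c(5, 5, 5, 5), G2 = c(7, 7, 7, 7))
  colnames(x2) <- colnames(x)
  m2 <- calibrate_thresholds(x2, labels, sig_of("G1", "G2"))
  expect_equal(unname(m2$thresholds), c(5, 7))
})

test_that("calibration errors name a missing signature gene", {
  x <- rbind(G1 = c(4, 4, 1, 1))
  colnames(x) <- paste0("s", 1:4)
  labels <- setNames(c("AML", "AML", "B-ALL", "B-ALL"), colnames(x))
  expect_error(calibrate_thresholds(x, labels, sig_of("G1", "GONE")), "GONE")
})

test_that("calibration is bit-identical across repeated runs", {
  sim <- default_sim()
  keep <- sim$labels != "MPAL"
  res <- differential_test(sim$matrix[, keep], sim$labels[keep])
  sig <- select_signature(res)
  a <- calibrate_thresholds(sim$matrix, sim$labels, sig)
  b <- calibrate_thresholds(sim$matrix, sim$labels, sig)
  expect_identical(a$thresholds, b$thresholds)
  expect_identical(a$k, b$k)
})

test_that("scores count strictly positive signature genes", {
  m <- sig_of(paste0("A", 1:4), "B1",
              thresholds = setNames(rep(10, 5), c(paste0("A", 1:4), "B1")))
  v <- setNames(c(20, 15, 5, 10, 0), c(paste0("A", 1:4), "B1"))
  sc <- compute_scores(v, m)
  expect_equal(sc$aml_score, 50)  # A4 sits exactly on its threshold: not positive
  expect_equal(sc$ball_score, 0)

  zero <- setNames(rep(0, 5), names(v))
  expect_equal(unlist(compute_scores(zero, m)[, 2:3]), c(aml_score = 0,
                                                         ball_score = 0))
  expect_error(compute_scores(v[-1], m), "A1")
})

test_that("classification rules cover the score plane exhaustively", {
  expect_equal(as.character(classify(c(45, 10))), "AML")
  expect_equal(as.character(classify(c(30, 30))), "MPAL")
  expect_equal(as.character(classify(c(10, 10))), "Unclassified")

  grid <- expand.grid(a = seq(0, 100, by = 2.5), b = seq(0, 100, by = 2.5))
  calls <- classify(data.frame(aml_score = grid$a, ball_score = grid$b))
  expect_false(any(is.na(calls)))  # exhaustive
  expected <- ifelse(grid$a >= 30,
                     ifelse(grid$b >= 30, "MPAL", "AML"),
                     ifelse(grid$b >= 30, "B-ALL", "Unclassified"))
  expect_identical(as.character(calls), expected)  # mutually exclusive
  expect_error(classify(c(120, 10)), "0, 100")
})

test_that("scores are monotone with step 100/N per newly positive gene", {
  set.seed(3)
  n_a <- 8L
  genes <- c(paste0("A", 1:n_a), paste0("B", 1:5))
  m <- sig_of(paste0("A", 1:n_a), paste0("B", 1:5),
              thresholds = setNames(runif(13, 5, 50), genes))
  for (i in 1:20) {
    v <- setNames(runif(13, 0, 60), genes)
    base <- compute_scores(v, m)
    g <- sample(paste0("A", 1:n_a), 1)
    was_pos <- v[g] > m$thresholds[g]
    v2 <- v
    v2[g] <- v[g] + 100
    bumped <- compute_scores(v2, m)
    expect_gte(bumped$aml_score, base$aml_score)
    expect_equal(bumped$aml_score - base$aml_score,
                 if (was_pos) 0 else 100 / n_a)
    expect_equal(bumped$ball_score, base$ball_score)
  }
})

test_that("the fitted pipeline separates the three categories end to end", {
  sim <- simulate_expression(synthetic_config(n_per_group = 40, seed = 0))
  fit <- leukdx(sim$matrix, sim$labels)
  calls <- fit$training$call
  labels <- fit$training$true
  pure <- labels %in% c("AML", "B-ALL")
  expect_gte(mean(calls[pure] == labels[pure]), 0.90)
  sc <- fit$training
  # MPAL expresses both programs above the opposite lineage's level
  expect_gt(mean(sc$aml_score[labels == "MPAL"]),
            mean(sc$aml_score[labels == "B-ALL"]))
  expect_gt(mean(sc$ball_score[labels == "MPAL"]),
            mean(sc$ball_score[labels == "AML"]))
  # mean score ordering across groups
  expect_gt(mean(sc$ball_score[labels == "B-ALL"]),
            mean(sc$ball_score[labels == "MPAL"]))
  expect_gte(mean(sc$aml_score[labels == "AML"]),
             mean(sc$aml_score[labels == "MPAL"]))
})
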