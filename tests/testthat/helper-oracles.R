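# Independent brute-force oracles and shared fixtures.

# Cache expensive fixtures across test files within one run.
.leukdx_test_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .leukdx_test_cache))
    assign(key, fn(), envir = .leukdx_test_cache)
  get(key, envir = .leukdx_test_cache)
}

default_sim <- function() {
  cached("sim20", function()
    simulate_expression(synthetic_config(n_per_group = 20, seed = 0)))
}

default_fit <- function() {
  cached("fit20", function() {
    sim <- default_sim()
    leukdx(sim$matrix, sim$labels)
  })
}

# The 12-case design (5 B-ALL / 3 AML / 4 MPAL) at high separation.
cohort12_config <- function(seed = 0) {
  synthetic_config(n_per_group = c("B-ALL" = 5, "AML" = 3, "MPAL" = 4),
                   sigma_log2 = 0.2, mpal_mix_range = c(0.45, 0.55),
                   seed = seed)
}

# Confusion-matrix metrics by explicit per-pair counting.
oracle_confusion <- function(true, predicted,
                             classes = c("AML", "B-ALL", "MPAL")) {
  n <- length(true)
  correct <- 0L
  for (i in seq_len(n)) if (true[i] == predicted[i]) correct <- correct + 1L
  sens <- spec <- setNames(rep(NA_real_, length(classes)), classes)
  for (cl in classes) {
    tp <- fn <- fp <- tn <- 0L
    for (i in seq_len(n)) {
      if (true[i] == cl && predicted[i] == cl) tp <- tp + 1L
      if (true[i] == cl && predicted[i] != cl) fn <- fn + 1L
      if (true[i] != cl && predicted[i] == cl) fp <- fp + 1L
      if (true[i] != cl && predicted[i] != cl) tn <- tn + 1L
    }
    if (tp + fn > 0) sens[cl] <- tp / (tp + fn)
    if (tn + fp > 0) spec[cl] <- tn / (tn + fp)
  }
  list(accuracy = correct / n, sensitivity = sens, specificity = spec)
}

# Pearson r and two-sided p from first principles.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2), n = n)
}

# Per-gene Welch test on log2(FPKM + 1) via stats::t.test, BH-adjusted.
oracle_welch_q <- function(x, labels, group_a = "AML", group_b = "B-ALL") {
  l <- log2(x + 1)
  p <- apply(l, 1L, function(v)
    t.test(v[labels == group_a], v[labels == group_b])$p.value)
  p.adjust(p, method = "BH")
}

# Standardization parameters carried on a z_transform() result.
z_params_for_test <- function(z) {
  list(center = attr(z, "center"), scale = attr(z, "scale"),
       dropped = attr(z, "dropped"))
}

# Small deterministic matrix with explicit values for IO tests.
tiny_matrix <- function() {
  matrix(c(1.5, 0, 100.25, 3, 7, 0.1), nrow = 3,
         dimnames = list(c("PAX5", "MPO", "CD19"), c("s1", "s2")))
}
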