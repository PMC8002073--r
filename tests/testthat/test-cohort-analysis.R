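random_matrix <- function(n = 14, t = 4, seed = 1) {
  set.seed(seed)
  mat <- matrix(rnorm(n * t, 100, 10), n, t) + rnorm(n, 0, 5)
  dimnames(mat) <- list(seq_len(n), timepoint_levels())
  mat
}

test_that("repeated-measures ANOVA matches the aov + TukeyHSD oracle", {
  for (seed in 1:3) {
    mat <- random_matrix(seed = seed)
    res <- repeated_measures_anova(mat)
    df <- data.frame(
      y = as.vector(mat),
      patient = factor(rep(rownames(mat), ncol(mat))),
      timepoint = factor(rep(colnames(mat), each = nrow(mat)),
                         levels = colnames(mat))
    )
    fit <- aov(y ~ timepoint + patient, data = df)
    tab <- summary(fit)[[1]]
    expect_equal(res$f_statistic, tab["timepoint", "F value"], tolerance = 1e-10)
    expect_equal(res$p_value, tab["timepoint", "Pr(>F)"], tolerance = 1e-10)
    thsd <- TukeyHSD(fit, "timepoint")$timepoint
    ord <- match(res$tukey$pair, sub("-", " - ", rownames(thsd), fixed = TRUE))
    expect_false(anyNA(ord))
    expect_equal(res$tukey$estimate, unname(thsd[ord, "diff"]), tolerance = 1e-10)
    expect_equal(res$tukey$p_adj, unname(thsd[ord, "p adj"]), tolerance = 1e-8)
  }
})

test_that("ANOVA degenerate and planted-effect behaviour", {
  # no time effect at all: F ~ 0, p ~ 1
  set.seed(1)
  flat <- matrix(rep(rnorm(10, 100, 5), 4), 10, 4)
  res <- repeated_measures_anova(flat)
  expect_lt(res$f_statistic, 1e-20)
  expect_gt(res$p_value, 0.999)

  # a 5-within-SD shift at one time point is detected (p < 0.01)
  detected <- vapply(1:20, function(seed) {
    set.seed(seed)
    mat <- matrix(rnorm(14 * 4, 100, 2), 14, 4) + rnorm(14, 0, 5)
    mat[, 3] <- mat[, 3] + 5 * 2
    repeated_measures_anova(mat)$p_value
  }, numeric(1))
  expect_true(all(detected < 0.01))

  # sqrt flag is definitionally the untransformed pipeline on sqrt data
  mat <- random_matrix(seed = 9)^2
  expect_equal(repeated_measures_anova(mat, sqrt_transform = TRUE),
               repeated_measures_anova(sqrt(mat)))
  expect_error(repeated_measures_anova(matrix(c(NA, rnorm(7)), 4, 2)), "incomplete")
})

test_that("trajectory matrices exclude incomplete patients listwise", {
  coh <- generate_cohort(small_config(seed = 5))
  proc <- process_telo_cohort(coh$telo, coh$controls, theoretical_n = 100, seed = 5)
  mat <- trajectory_matrix(summarize_telo_cohort(proc), "mtl")
  expect_equal(dim(mat), c(5, 4))           # 6 patients minus the missing-sample one
  expect_false("5" %in% rownames(mat))      # small_config's missing patient
  expect_false(anyNA(mat))
})

test_that("patient clustering uses z-scored rows and 1 - Pearson distance", {
  # two copies of one trajectory and two of an uncorrelated one separate at k = 2
  a <- c(1, 2, 3, 4)
  b <- c(5, 1, 4, 0)
  mat <- rbind(a1 = a, a2 = 10 * a + 3, b1 = b, b2 = b * 2)
  cl <- cluster_patients(mat, k = 2)
  expect_equal(cl$labels[["a1"]], cl$labels[["a2"]])
  expect_equal(cl$labels[["b1"]], cl$labels[["b2"]])
  expect_false(cl$labels[["a1"]] == cl$labels[["b1"]])

  # linkage tree equals single-linkage on brute-force pairwise distances
  m <- random_matrix(n = 8, seed = 3)
  z <- t(apply(m, 1, function(r) (r - mean(r)) / sd(r)))
  brute <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    brute[i, j] <- 1 - sum((z[i, ] - mean(z[i, ])) * (z[j, ] - mean(z[j, ]))) /
      (sqrt(sum((z[i, ] - mean(z[i, ]))^2)) * sqrt(sum((z[j, ] - mean(z[j, ]))^2)))
  }
  hc <- cluster_patients(m, k = 2)$linkage
  oracle_hc <- hclust(as.dist(brute), method = "single")
  expect_equal(hc$height, oracle_hc$height, tolerance = 1e-12)
  expect_equal(hc$merge, oracle_hc$merge)
  # affine invariance per row (guaranteed by z-scoring)
  m2 <- m * 7 + 100
  expect_equal(cluster_patients(m, k = 2)$labels, cluster_patients(m2, k = 2)$labels)

  expect_error(cluster_patients(rbind(c(1, 1, 1, 1), m)), "zero variance")
})

test_that("OLS baselines match the normal-equations oracle", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 3.9, 6.2, 8.1, 9.8)
  fit <- baseline_linear_prediction(x, target_metric = y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$coefficients), as.vector(beta), tolerance = 1e-10)
  expect_equal(fit$predictor_set, "baseline-only")

  # exact linear relation: r^2 ~ 1; independent target: r^2 ~ 0
  exact <- suppressWarnings(baseline_linear_prediction(x, target_metric = 3 * x - 1))
  expect_equal(exact$r_squared, 1)
  set.seed(10)
  big <- baseline_linear_prediction(rnorm(5000), target_metric = rnorm(5000))
  expect_lt(big$r_squared, 0.01)

  # two-predictor model matches lm and reports its set
  set.seed(11)
  x2 <- rnorm(10); x1 <- rnorm(10); yy <- x1 + 2 * x2 + rnorm(10, 0, 0.1)
  both <- baseline_linear_prediction(x1, x2, yy)
  expect_equal(both$predictor_set, "baseline+4gy")
  expect_equal(unname(both$coefficients),
               unname(coef(lm(yy ~ x1 + x2))), tolerance = 1e-10)
  expect_error(baseline_linear_prediction(c(1, 1, 1), target_metric = c(1, 2, 3)),
               "collinearity")
})

test_that("longitudinal correlations are signed Pearson r", {
  a <- c(1, 3, 2, 5, 4, 6)
  expect_equal(longitudinal_correlation(a, a)$r, 1)
  expect_equal(longitudinal_correlation(a, -a)$r, -1)
  set.seed(12)
  b <- rnorm(6)
  res <- longitudinal_correlation(a, b)
  brute <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$r, brute, tolerance = 1e-12)
  expect_equal(res$r_squared, brute^2, tolerance = 1e-12)
  expect_gte(res$r_squared, 0)
  expect_error(longitudinal_correlation(a, rep(1, 6)), "zero variance")
})
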