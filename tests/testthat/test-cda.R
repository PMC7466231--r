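test_that("three groups on three colour variables yield two canonical functions", {
  ss <- simulate_sample_set(n_per_group = 30, seed = 71)
  res <- fit_cda(as.matrix(ss$colours), ss$groups)
  expect_length(res$eigenvalues, 2)
  expect_true(all(diff(res$eigenvalues) <= 0))
  expect_true(all(res$eigenvalues >= 0))
  expect_equal(sum(res$variance_pct), 100, tolerance = 1e-9)
  expect_true(all(res$canonical_correlations >= 0 &
                    res$canonical_correlations < 1))
  expect_error(fit_cda(as.matrix(ss$colours), rep("x", nrow(ss$colours))),
               "2 groups")
})

test_that("a lightness-only separation puts its weight on the L* coefficient", {
  set.seed(72)
  n <- 60
  g <- rep(c("A", "B"), each = n)
  L <- c(rnorm(n, 45, 2), rnorm(n, 60, 2))
  a <- rnorm(2 * n, 6, 2)
  b <- rnorm(2 * n, 18, 3)
  res <- fit_cda(cbind(L = L, a = a, b = b), g)
  cf <- abs(res$coefficients[, 1])
  expect_gt(cf["L"], cf["a"])
  expect_gt(cf["L"], cf["b"])
})

test_that("eigen statistics match a brute-force scatter-matrix oracle", {
  # small 9-sample fixture, 3 groups x 3 samples
  X <- rbind(
    c(55.1, 6.0, 20.3), c(57.9, 6.8, 19.2), c(56.0, 5.5, 21.0),
    c(50.2, 7.2, 19.9), c(51.8, 6.9, 18.7), c(49.5, 7.6, 20.4),
    c(52.0, 5.4, 17.1), c(50.6, 6.1, 18.0), c(51.5, 5.0, 16.8)
  )
  gr <- rep(c("c", "t1", "t2"), each = 3)
  res <- fit_cda(X, gr)

  # oracle: explicit scatter matrices and a plain nonsymmetric eigensolve
  grand <- colMeans(X)
  W <- matrix(0, 3, 3); B <- matrix(0, 3, 3)
  for (l in unique(gr)) {
    Xi <- X[gr == l, ]
    mi <- colMeans(Xi)
    W <- W + crossprod(sweep(Xi, 2, mi))
    B <- B + nrow(Xi) * tcrossprod(mi - grand)
  }
  ev <- eigen(solve(W) %*% B)
  lam <- sort(Re(ev$values), decreasing = TRUE)[1:2]
  expect_equal(res$eigenvalues, lam, tolerance = 1e-10)
  expect_equal(res$wilks[1], prod(1 / (1 + lam)), tolerance = 1e-12)
  expect_equal(res$variance_pct, 100 * lam / sum(lam), tolerance = 1e-9)

  # cross-check the discriminant directions against MASS::lda
  skip_if_not_installed("MASS")
  ld <- MASS::lda(X, grouping = gr)
  for (j in 1:2) {
    v1 <- res$raw_coefficients[, j]
    v2 <- ld$scaling[, j]
    expect_equal(unname(abs(v1 / sqrt(sum(v1^2)))),
                 unname(abs(v2 / sqrt(sum(v2^2)))), tolerance = 1e-8)
  }
})

test_that("Wilks' lambda reproduces the published two-function statistics", {
  expect_equal(round(wilks_lambda(c(0.43, 0.09), 1), 2), 0.64)
  expect_equal(round(wilks_lambda(c(0.43, 0.09), 2), 2), 0.92)
  expect_equal(wilks_lambda(c(0, 0), 1), 1)
  expect_error(wilks_lambda(c(0.43, 0.09), 3), "out of range")
  expect_error(wilks_lambda(c(-0.1), 1), ">= 0")
})

test_that("canonical correlations reproduce the published values", {
  expect_equal(round(canonical_correlation(0.43), 2), 0.55)
  expect_equal(round(canonical_correlation(0.09), 2), 0.29)
  expect_equal(canonical_correlation(0), 0)
  expect_error(canonical_correlation(-1), ">= 0")
  # strictly increasing, bounded by 1
  lams <- seq(0, 20, by = 0.5)
  r <- sapply(lams, canonical_correlation)
  expect_true(all(diff(r) > 0))
  expect_true(all(r < 1))
})

test_that("canonical function scores evaluate as printed linear combinations", {
  expect_equal(evaluate_functions(c(0.47, 0.14, 0.40), c(56.83, 6.23, 20.26)),
               35.69, tolerance = 1e-3)
  expect_equal(evaluate_functions(c(0.47, 0.14, 0.40), c(0, 0, 0)), 0)
  expect_equal(evaluate_functions(c(-0.62, 0.80, 0.32), c(0, 0, 0)), 0)
  # standardization divides the variables first
  expect_equal(evaluate_functions(c(1, 1, 1), c(10, 20, 30),
                                  standardization = c(10, 10, 10)), 6)
  expect_error(evaluate_functions(c(1, 1), c(1, 2, 3)), "coefficients")
  expect_error(evaluate_functions(c(1, 1, 1), c(1, 2, 3),
                                  standardization = c(1, 0, 1)), "positive")
})

test_that("nearest-centroid classification behaves at its limits", {
  set.seed(73)
  # well-separated groups (centroids >= 10 within-group SDs apart) -> 100%
  n <- 40
  X <- rbind(cbind(rnorm(n, 0, 1), rnorm(n, 0, 1), rnorm(n, 0, 1)),
             cbind(rnorm(n, 20, 1), rnorm(n, 0, 1), rnorm(n, 0, 1)))
  g <- rep(c("A", "B"), each = n)
  res <- fit_cda(X, g)
  expect_equal(res$classification$correct_rate_pct, 100)

  # single sample placed at a group centroid is assigned that group
  cen_feat <- colMeans(X[g == "B", ])
  cls <- classify_cda(res, matrix(cen_feat, 1))
  expect_equal(as.character(cls$labels), "B")

  # identical distributions: training rate near chance (100/g %)
  rates <- sapply(1:10, function(s) {
    set.seed(200 + s)
    Xc <- matrix(rnorm(300 * 3), 300, 3)
    gc <- rep(c("A", "B", "C"), each = 100)
    fit_cda(Xc, gc)$classification$correct_rate_pct
  })
  expect_lt(abs(mean(rates) - 100 / 3), 6)

  expect_error(classify_cda(res, X[, 1:2]), "variables")
})

test_that("classification rate approaches the analytic Bayes rate for spherical groups", {
  set.seed(74)
  n <- 3000
  delta <- 2  # Mahalanobis distance between the two means
  X <- rbind(cbind(rnorm(n), rnorm(n), rnorm(n)),
             cbind(rnorm(n, delta), rnorm(n), rnorm(n)))
  g <- rep(c("A", "B"), each = n)
  res <- fit_cda(X, g)
  bayes <- 100 * pnorm(delta / 2)
  expect_lt(abs(res$classification$correct_rate_pct - bayes), 5)
})

test_that("ANOVA letter display separates groups like a studentized-range oracle", {
  set.seed(75)
  # three identical groups -> single letter
  v0 <- rnorm(30, 10, 1)
  g3 <- rep(c("A", "B", "C"), each = 10)
  s0 <- anova_letters(v0, g3)
  expect_true(all(s0$table$letters == "a"))

  # means 0, 0, 50 with tiny SD -> a, a, b
  v1 <- c(rnorm(10, 0, 0.1), rnorm(10, 0, 0.1), rnorm(10, 50, 0.1))
  s1 <- anova_letters(v1, g3)
  expect_equal(unname(s1$table$letters), c("a", "a", "b"))

  # oracle: Tukey p-values from ptukey on the pooled MSE
  fit <- aov(v1 ~ factor(g3))
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  dfe <- summary(fit)[[1]]["Residuals", "Df"]
  means <- tapply(v1, g3, mean)
  p_ab <- ptukey(abs(means["A"] - means["B"]) / sqrt(mse / 10), 3, dfe,
                 lower.tail = FALSE)
  p_ac <- ptukey(abs(means["A"] - means["C"]) / sqrt(mse / 10), 3, dfe,
                 lower.tail = FALSE)
  expect_equal(s1$p_matrix["A", "B"], unname(p_ab), tolerance = 1e-8)
  expect_equal(s1$p_matrix["A", "C"], unname(p_ac), tolerance = 1e-8)
  expect_gt(p_ab, 0.05); expect_lt(p_ac, 0.05)

  # two groups reduce to the two-sample comparison outcome
  v2 <- c(rnorm(10, 0, 1), rnorm(10, 20, 1))
  g2 <- rep(c("A", "B"), each = 10)
  s2 <- anova_letters(v2, g2)
  expect_equal(unname(s2$table$letters), c("a", "b"))
  v3 <- rnorm(20, 5, 1)
  s3 <- anova_letters(v3, g2)
  expect_true(all(s3$table$letters == "a"))

  expect_error(anova_letters(v2, rep("A", 20)), "2 groups")
})

test_that("overlapping group separations produce shared-letter displays", {
  # means 0, 3, 6 with SD chosen so only the extremes differ -> a, ab, b
  set.seed(76)
  v <- c(rnorm(8, 0, 2.2), rnorm(8, 3, 2.2), rnorm(8, 6, 2.2))
  g <- rep(c("lo", "mid", "hi"), each = 8)
  s <- anova_letters(v, g)
  tab <- s$table
  # letters must encode exactly the significance pattern of the p-matrix
  for (i in tab$group) for (j in tab$group) {
    if (i != j) {
      share <- length(intersect(strsplit(tab$letters[tab$group == i], "")[[1]],
                                strsplit(tab$letters[tab$group == j], "")[[1]])) > 0
      expect_equal(share, s$p_matrix[i, j] >= 0.05,
                   info = paste(i, j))
    }
  }
})
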