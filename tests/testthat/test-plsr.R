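test_that("calibration split sizes follow the rounding rule and seed", {
  sp <- split_samples(89, 2 / 3, seed = 1)
  expect_length(sp$calibration, 59)
  expect_length(sp$validation, 30)
  expect_length(intersect(sp$calibration, sp$validation), 0)
  expect_setequal(c(sp$calibration, sp$validation), 1:89)

  expect_identical(split_samples(89, seed = 7), split_samples(89, seed = 7))

  sp3 <- split_samples(3, 2 / 3, seed = 1)
  expect_length(sp3$calibration, 2)
  expect_length(sp3$validation, 1)

  expect_error(split_samples(89, fraction = 1.2), "fraction")
  expect_error(split_samples(89, fraction = 0), "fraction")
})

test_that("NIPALS fit is exact in the noiseless single-component limit", {
  set.seed(21)
  n <- 20; p <- 8
  w <- rnorm(p); w <- w / sqrt(sum(w^2))
  X <- outer(rnorm(n), w) + 0.5          # rank-1 signal + offset
  y <- as.numeric(X %*% w) * 2 + 3
  m <- fit_plsr(X, y, 1)
  mm <- compute_metrics(y, predict(m, X))
  expect_equal(mm$r2, 1, tolerance = 1e-8)
  expect_lt(mm$rmse, 1e-8)
})

test_that("PLSR with all components equals OLS on full-rank tall data", {
  set.seed(22)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- rnorm(30)
  m <- fit_plsr(X, y, 5)
  ols <- lm(y ~ X)
  expect_equal(predict(m, X), unname(fitted(ols)), tolerance = 1e-8)
  expect_equal(unname(m$coefficients), unname(coef(ols)[-1]), tolerance = 1e-8)
})

test_that("NIPALS scores and loadings match an independent power-iteration oracle", {
  set.seed(23)
  X <- matrix(rnorm(24), 6, 4)
  y <- rnorm(6)
  m <- fit_plsr(X, y, 2)

  # oracle: explicit NIPALS on centred data, iterated to 1e-12
  E <- scale(X, scale = FALSE); f <- y - mean(y)
  for (a in 1:2) {
    u <- f
    repeat {
      w <- drop(crossprod(E, u)); w <- w / sqrt(sum(w^2))
      tt <- drop(E %*% w)
      q <- sum(f * tt) / sum(tt^2)
      u_new <- f / q
      if (max(abs(u_new - u)) < 1e-12) break
      u <- u_new
    }
    p_load <- drop(crossprod(E, tt)) / sum(tt^2)
    expect_equal(abs(m$weights[, a]), abs(w), tolerance = 1e-10)
    expect_equal(abs(m$scores[, a]), abs(tt), tolerance = 1e-10)
    expect_equal(abs(m$x_loadings[, a]), abs(p_load), tolerance = 1e-10)
    E <- E - outer(tt, p_load)
    f <- f - q * tt
  }
})

test_that("prediction obeys centring and linearity identities", {
  set.seed(24)
  X <- matrix(rnorm(60), 15, 4)
  y <- rnorm(15)
  m <- fit_plsr(X, y, 3)
  expect_equal(predict(m, X), m$fitted)
  expect_equal(predict(m, matrix(m$x_mean, 1)), m$y_mean, tolerance = 1e-12)
  shift <- c(1, -2, 0.5, 3)
  expect_equal(predict(m, sweep(X, 2, -shift)),
               predict(m, X) + sum(shift * m$coefficients), tolerance = 1e-10)
  expect_error(predict(m, X[, 1:3]), "bands")
})

test_that("training R2 is non-decreasing and RMSEC non-increasing in components", {
  set.seed(25)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- X %*% rnorm(10) + rnorm(40)
  r2 <- rmse <- numeric(6)
  for (a in 1:6) {
    m <- fit_plsr(X, y, a)
    mm <- compute_metrics(y, predict(m, X))
    r2[a] <- mm$r2; rmse[a] <- mm$rmse
  }
  expect_true(all(diff(r2) >= -1e-12))
  expect_true(all(diff(rmse) <= 1e-12))
})

test_that("cross-validation finds the true latent dimension of 2-factor data", {
  set.seed(26)
  n <- 24; p <- 10
  Tm <- matrix(rnorm(n * 2), n, 2)
  P <- matrix(rnorm(2 * p), 2, p)
  X <- Tm %*% P
  y <- Tm %*% c(2, -1)
  cv <- cross_validate(X, y, max_components = 5, scheme = "loo")
  expect_equal(cv$optimal, 2)
  expect_lt(cv$rmsecv[2], 1e-6)
  expect_true(all(cv$rmsecv >= 0))
})

test_that("leave-one-out predictions are invariant to sample order", {
  set.seed(27)
  X <- matrix(rnorm(15 * 6), 15, 6)
  y <- X %*% rnorm(6) + rnorm(15, 0, 0.2)
  cv1 <- cross_validate(X, y, 3, scheme = "loo")
  perm <- sample(15)
  cv2 <- cross_validate(X[perm, ], y[perm], 3, scheme = "loo")
  expect_equal(cv2$predictions[order(perm), ], cv1$predictions, tolerance = 1e-10)
  expect_equal(cv2$rmsecv, cv1$rmsecv, tolerance = 1e-10)

  expect_error(cross_validate(X, y, 3, scheme = "kfold", k = 20), "folds exceeds")
})

test_that("metrics match hand-computed values and error contracts", {
  m <- compute_metrics(1:4, 1:4)
  expect_equal(m$r2, 1); expect_equal(m$rmse, 0)

  m0 <- compute_metrics(c(1, 2, 3, 4), rep(2.5, 4))
  expect_equal(m0$r2, 0)

  # residuals 0.1, -0.1, 0.2, -0.2 -> mse 0.025
  m2 <- compute_metrics(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
  expect_equal(m2$rmse, sqrt(0.025), tolerance = 1e-12)
  expect_equal(m2$r2, 1 - 0.1 / 5, tolerance = 1e-12)

  expect_error(compute_metrics(rep(1, 4), 1:4), "zero variance")
  expect_error(fit_plsr(matrix(rnorm(20), 5, 4), rep(1, 5), 2), "zero variance")
  expect_error(fit_plsr(matrix(rnorm(20), 5, 4), rnorm(5), 5), "n_components")
})

test_that("R2 quality grading reproduces the published bands", {
  expect_equal(grade_model(0.73), "acceptable")
  expect_equal(grade_model(0.82), "good")
  expect_equal(grade_model(0.95), "excellent")
  expect_equal(grade_model(0.5), "insufficient")
  expect_equal(grade_model(0.66), "acceptable")
  expect_equal(grade_model(0.81), "acceptable")
  expect_equal(grade_model(0.90), "good")
  expect_equal(grade_model(0.91), "excellent")
})

test_that("colour parameters of noiseless synthetic samples are fully recoverable", {
  ss <- simulate_sample_set(n_per_group = 20, noise_sd = 0, seed = 31)
  for (ch in c("L", "a", "b")) {
    m <- fit_plsr(ss$spectra, ss$colours[[ch]], 3, grid = ss$grid)
    mm <- compute_metrics(ss$colours[[ch]], predict(m, ss$spectra))
    expect_equal(mm$r2, 1, tolerance = 1e-8)
    expect_lt(mm$rmse, 1e-6)
  }
})

test_that("with moderate noise RMSECV is usually at least RMSEC", {
  wins <- 0
  for (s in 1:20) {
    ss <- simulate_sample_set(n_per_group = 10, noise_sd = 0.01, seed = 300 + s,
                              grid = tiny_grid(20))
    y <- ss$colours$L
    m <- fit_plsr(ss$spectra, y, 3)
    rmsec <- compute_metrics(y, predict(m, ss$spectra))$rmse
    cv <- cross_validate(ss$spectra, y, 3, scheme = "kfold", k = 5, seed = s)
    if (cv$rmsecv[3] >= rmsec) wins <- wins + 1
  }
  expect_gt(wins, 10)  # majority over 20 seeds
})

test_that("full evaluation pipeline reports coherent split metrics", {
  ss <- simulate_sample_set(n_per_group = 15, noise_sd = 0.005, seed = 33,
                            grid = tiny_grid(25))
  split <- split_samples(nrow(ss$spectra), 2 / 3, seed = 2)
  ev <- evaluate_plsr(ss$spectra, ss$colours$L, ss$grid, treatment = "snv",
                      max_components = 5, split = split,
                      cv_scheme = "kfold", k = 5, seed = 2)
  expect_true(all(c("r2_c", "r2_p", "r2_cv", "rmsec", "rmsep", "rmsecv") %in%
                    names(ev$metrics)))
  expect_gte(ev$metrics$rmsec, 0)
  expect_equal(ev$metrics$rmse_gap,
               abs(ev$metrics$rmsec - ev$metrics$rmsecv), tolerance = 1e-12)
  expect_lte(ev$metrics$r2_c, 1)
})
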