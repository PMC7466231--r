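#' Random calibration/validation split
#'
#' Draws a seeded uniform random split of `n` samples into calibration and
#' validation sets. The default fraction follows the two-thirds calibration
#' convention (e.g. 89 samples split 59/30).
#'
#' @param n Total number of samples (>= 3).
#' @param fraction Calibration share in (0, 1); calibration size is
#'   `round(n * fraction)`.
#' @param seed Integer seed; the same seed reproduces the same plan.
#' @param method `"random"` (default) or `"kennard_stone"`; the latter picks
#'   calibration samples by maximin coverage of `X` and needs `X` supplied.
#' @param X Spectra matrix, required for Kennard-Stone.
#' @return List of class `split_plan` with `calibration`, `validation`
#'   (disjoint index vectors covering `1:n`), `fraction`, `seed`.
#' @export
split_samples <- function(n, fraction = 2 / 3, seed = 1,
                          method = c("random", "kennard_stone"), X = NULL) {
  method <- match.arg(method)
  stopifnot(n >= 3)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_cal <- round(n * fraction)
  n_cal <- max(1L, min(n - 1L, as.integer(n_cal)))
  cal <- if (method == "random") {
    with_seed(seed, sort(sample.int(n, n_cal)))
  } else {
    if (is.null(X) || nrow(X) != n) stop("Kennard-Stone needs X with n rows")
    sort(kennard_stone(X, n_cal))
  }
  structure(list(calibration = cal, validation = setdiff(seq_len(n), cal),
                 fraction = fraction, seed = seed, method = method),
            class = "split_plan")
}

kennard_stone <- function(X, k) {
  D <- as.matrix(stats::dist(X))
  sel <- which(D == max(D), arr.ind = TRUE)[1, ]
  sel <- as.integer(sel)
  while (length(sel) < k) {
    rest <- setdiff(seq_len(nrow(X)), sel)
    dmin <- apply(D[rest, sel, drop = FALSE], 1, min)
    sel <- c(sel, rest[which.max(dmin)])
  }
  sel[seq_len(k)]
}

# Run expr under a seed without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Fit a PLS1 regression by NIPALS
#'
#' Partial least squares regression of a single response on mean-centred
#' spectra, extracting components by the NIPALS algorithm (power iteration
#' with deflation of both blocks; convergence 1e-12 or 500 iterations per
#' component). Neither block is variance-scaled, the usual convention for
#' spectral data. The component loadings are folded into a single
#' regression-coefficient vector per band (the "BW" weighted regression
#' coefficients used for wavelength ranking) plus an intercept, so prediction
#' is `X %*% coefficients + intercept`.
#'
#' @param X Spectra matrix (n x bands), pre-treated as desired.
#' @param y Numeric response (length n), e.g. a CIELAB colour attribute.
#' @param n_components Number of latent variables, at most
#'   `min(n - 1, ncol(X))`.
#' @param grid Optional wavelength grid (length `ncol(X)`) carried in the
#'   model for wavelength-based reporting.
#' @param pretreatment Label of the pre-treatment chain applied to `X`,
#'   stored for provenance.
#' @param msc_reference Optional frozen MSC reference carried with the model.
#' @return Object of class `plsr_model`: weights `W`, loadings `P` and `q`,
#'   scores `T`, `coefficients`, `intercept`, centring vectors, and the
#'   training fit.
#' @export
fit_plsr <- function(X, y, n_components, grid = NULL, pretreatment = "raw",
                     msc_reference = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values not allowed")
  if (stats::var(y) == 0) stop("response has zero variance")
  if (n_components > min(n - 1, p)) {
    stop(sprintf("n_components = %d exceeds min(n - 1, bands) = %d",
                 n_components, min(n - 1, p)))
  }
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  E <- Xc; f <- yc
  tol <- 1e-12
  norm0 <- sqrt(sum(crossprod(Xc, yc)^2))
  if (norm0 == 0) stop("X has no covariance with y")
  actual_components <- n_components
  for (a in seq_len(n_components)) {
    # residual covariance exhausted (noiseless low-rank data): keep the
    # components extracted so far rather than fitting numerical noise
    if (sqrt(sum(crossprod(E, f)^2)) < norm0 * 1e-10) {
      actual_components <- a - 1L
      break
    }
    u <- f
    w_old <- rep(0, p)
    for (it in seq_len(500)) {
      w <- crossprod(E, u)[, 1]
      nw <- sqrt(sum(w^2))
      w <- w / nw
      tt <- E %*% w
      qa <- sum(f * tt) / sum(tt^2)
      u_new <- f / qa  # single-response inner relation
      if (sqrt(sum((w - w_old)^2)) < tol) break
      w_old <- w
      u <- u_new
    }
    tt <- as.numeric(E %*% w)
    tt2 <- sum(tt^2)
    pa <- crossprod(E, tt)[, 1] / tt2
    qa <- sum(f * tt) / tt2
    W[, a] <- w; P[, a] <- pa; q[a] <- qa; Tm[, a] <- tt
    E <- E - tcrossprod(tt, pa)
    f <- f - qa * tt
  }
  if (actual_components < n_components) {
    W <- W[, seq_len(actual_components), drop = FALSE]
    P <- P[, seq_len(actual_components), drop = FALSE]
    Tm <- Tm[, seq_len(actual_components), drop = FALSE]
    q <- q[seq_len(actual_components)]
  }
  R <- W %*% solve(crossprod(P, W))
  coef <- as.numeric(R %*% q)
  intercept <- y_mean - sum(x_mean * coef)
  fitted <- as.numeric(X %*% coef) + intercept
  structure(list(
    n_components = actual_components, x_mean = x_mean, y_mean = y_mean,
    weights = W, x_loadings = P, y_loadings = q, scores = Tm,
    coefficients = coef, intercept = intercept,
    fitted = fitted, residuals = y - fitted,
    grid = grid, pretreatment = pretreatment, msc_reference = msc_reference
  ), class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d component(s), %d bands, pre-treatment: %s\n",
              x$n_components, length(x$coefficients), x$pretreatment))
  m <- compute_metrics(x$fitted + x$residuals, x$fitted)
  cat(sprintf("  training R2 = %.4f, RMSE = %.4g\n", m$r2, m$rmse))
  invisible(x)
}

#' Predict from a fitted PLS1 model
#'
#' @param object A `plsr_model`.
#' @param newdata Spectra matrix with the model's band count, carrying the
#'   same pre-treatment chain as the training spectra.
#' @param ... Unused.
#' @return Numeric vector `newdata %*% coefficients + intercept`.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop(sprintf("newdata has %d bands; model expects %d",
                 ncol(newdata), length(object$coefficients)))
  }
  as.numeric(newdata %*% object$coefficients) + object$intercept
}

#' R-squared and root-mean-square error
#'
#' `r2 = 1 - SS_res / SS_tot` and `rmse = sqrt(mean((y - yhat)^2))`, the
#' standard calibration/prediction/cross-validation metrics (RMSEC, RMSEP,
#' RMSECV depending on which pairs are supplied).
#'
#' @param y_true,y_pred Equal-length numeric vectors (length >= 2).
#' @return List with `r2` and `rmse`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("y_true has zero variance; R2 undefined")
  ss_res <- sum((y_true - y_pred)^2)
  list(r2 = 1 - ss_res / ss_tot, rmse = sqrt(mean((y_true - y_pred)^2)))
}

#' Cross-validate a PLS1 model over component counts
#'
#' Computes RMSECV and cross-validated R-squared for 1..`max_components`
#' latent variables by leave-one-out or seeded k-fold cross-validation. The
#' entire fit — including any data-dependent pre-treatment statistics, when a
#' `pretreat_fun` factory is given — is redone inside each training fold.
#' The optimal component count is the smallest one whose RMSECV lies within
#' `rel_tol` (default 2%) of the global minimum, guarding against fitting
#' noise with extra components.
#'
#' @param X Spectra matrix (already treated, unless `pretreat_fun` given).
#' @param y Response vector.
#' @param max_components Largest component count to assess.
#' @param scheme `"loo"` or `"kfold"`.
#' @param k Number of folds for `"kfold"`.
#' @param seed Seed for the fold assignment.
#' @param rel_tol Relative tolerance for the parsimony rule.
#' @param pretreat_fun Optional factory: called as `pretreat_fun(X_train)`,
#'   must return a function that maps any spectra matrix to treated form
#'   (statistics learned on the fold's training rows only).
#' @return List with `rmsecv`, `r2cv` (per component count), `optimal`
#'   (selected count), `scheme`, `predictions` (n x max_components matrix of
#'   held-out predictions).
#' @export
cross_validate <- function(X, y, max_components, scheme = c("loo", "kfold"),
                           k = 10, seed = 1, rel_tol = 0.02,
                           pretreat_fun = NULL) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  folds <- if (scheme == "loo") {
    seq_len(n)
  } else {
    if (k > n) stop(sprintf("k = %d folds exceeds n = %d samples", k, n))
    with_seed(seed, sample(rep_len(seq_len(k), n)))
  }
  nf <- length(unique(folds))
  max_train <- n - max(table(folds))
  if (max_components > max_train - 1) {
    stop(sprintf("max_components = %d too large for training folds of %d samples",
                 max_components, max_train))
  }
  pred <- matrix(NA_real_, n, max_components)
  for (f in unique(folds)) {
    hold <- which(folds == f)
    Xtr <- X[-hold, , drop = FALSE]; ytr <- y[-hold]
    Xte <- X[hold, , drop = FALSE]
    if (!is.null(pretreat_fun)) {
      tf <- pretreat_fun(Xtr)
      Xtr <- tf(Xtr); Xte <- tf(Xte)
    }
    for (a in seq_len(max_components)) {
      m <- fit_plsr(Xtr, ytr, n_components = a)
      pred[hold, a] <- predict(m, Xte)
    }
  }
  rmsecv <- apply(pred, 2, function(p) sqrt(mean((y - p)^2)))
  r2cv <- apply(pred, 2, function(p) 1 - sum((y - p)^2) / sum((y - mean(y))^2))
  optimal <- min(which(rmsecv <= min(rmsecv) * (1 + rel_tol)))
  list(rmsecv = rmsecv, r2cv = r2cv, optimal = optimal, scheme = scheme,
       predictions = pred)
}

#' Grade a model's R-squared into prediction-quality bands
#'
#' The chemometrics rule of thumb for vis/NIR calibration quality: R-squared
#' below 0.66 is insufficient; 0.66--0.81 acceptable for approximate
#' quantitative prediction; above 0.81 up to 0.90 good; above 0.90 excellent.
#'
#' @param r2 Determination coefficient (<= 1).
#' @return One of `"insufficient"`, `"acceptable"`, `"good"`, `"excellent"`.
#' @export
grade_model <- function(r2) {
  stopifnot(is.numeric(r2), length(r2) == 1, r2 <= 1)
  if (r2 < 0.66) "insufficient"
  else if (r2 <= 0.81) "acceptable"
  else if (r2 <= 0.90) "good"
  else "excellent"
}

#' Full-spectrum model evaluation on a calibration/validation split
#'
#' Convenience wrapper reproducing the standard calibration-table workflow:
#' pre-treat, split, fit on the calibration set, evaluate RMSEC/RMSEP/RMSECV
#' and the matching R-squared values.
#'
#' @param X Untreated spectra matrix.
#' @param y Response vector.
#' @param grid Wavelength grid.
#' @param treatment Pre-treatment name (see [pretreat()]).
#' @param n_components Latent variables; `NULL` selects by cross-validation
#'   on the calibration set.
#' @param max_components Search ceiling when selecting.
#' @param split A `split_plan`; `NULL` fits on all rows (no RMSEP).
#' @param cv_scheme,k,seed Passed to [cross_validate()].
#' @return List with `model`, `metrics` (r2_c/r2_p/r2_cv, rmsec/rmsep/rmsecv,
#'   rmse_gap), `split`, `cv`.
#' @export
evaluate_plsr <- function(X, y, grid, treatment = "raw", n_components = NULL,
                          max_components = 10, split = NULL,
                          cv_scheme = "loo", k = 10, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  cal <- if (is.null(split)) seq_len(nrow(X)) else split$calibration
  val <- if (is.null(split)) integer(0) else split$validation
  ptf <- function(Xtr) {
    st <- pretreat(Xtr, grid, treatment)
    function(Xnew) pretreat(Xnew, grid, treatment,
                            msc_reference = st$state$msc_reference)$X
  }
  tf <- ptf(X[cal, , drop = FALSE])
  Xcal <- tf(X[cal, , drop = FALSE])
  max_components <- min(max_components, length(cal) - 2, ncol(X))
  cv <- cross_validate(X[cal, , drop = FALSE], y[cal], max_components,
                       scheme = cv_scheme, k = k, seed = seed,
                       pretreat_fun = ptf)
  a <- if (is.null(n_components)) cv$optimal else n_components
  model <- fit_plsr(Xcal, y[cal], a, grid = grid, pretreatment = treatment)
  mc <- compute_metrics(y[cal], predict(model, Xcal))
  metrics <- list(r2_c = mc$r2, rmsec = mc$rmse,
                  r2_cv = cv$r2cv[a], rmsecv = cv$rmsecv[a],
                  rmse_gap = abs(mc$rmse - cv$rmsecv[a]),
                  n_components = a)
  if (length(val)) {
    Xval <- tf(X[val, , drop = FALSE])
    mp <- compute_metrics(y[val], predict(model, Xval))
    metrics$r2_p <- mp$r2; metrics$rmsep <- mp$rmse
  }
  list(model = model, metrics = metrics, split = split, cv = cv)
}
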