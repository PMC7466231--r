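#' Canonical discriminant analysis
#'
#' Solves the generalized eigenproblem of between-group versus within-group
#' scatter of the feature matrix (here CIELAB colour triplets), yielding
#' min(groups - 1, variables) canonical functions that maximally separate the
#' groups. Conventions follow the common statistical-package output: raw
#' coefficients are scaled so canonical scores have unit pooled within-group
#' variance; standardized coefficients multiply the raw ones by the pooled
#' within-group standard deviations; Wilks' lambda per function sequence is
#' tested by Bartlett's chi-square approximation; classification is by
#' nearest group centroid in canonical-score space with equal priors.
#'
#' @param features Numeric matrix or data frame, rows = samples, columns =
#'   variables (e.g. L*, a*, b*).
#' @param groups Group label per row (factor or coercible).
#' @return Object of class `cda_result` with `eigenvalues`,
#'   `coefficients` (standardized), `raw_coefficients`, `variance_pct`,
#'   `canonical_correlations`, `wilks`, `chi_sq`, `df`, `p_values`,
#'   `group_centroids`, `scores`, `classification` (confusion matrix and
#'   correct rate in percent on the training data), `means`, `within_sd`.
#' @export
fit_cda <- function(features, groups) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  g <- factor(groups)
  if (nrow(X) != length(g)) stop("features and groups lengths differ")
  n <- nrow(X); p <- ncol(X)
  lev <- levels(g)
  if (length(lev) < 2) stop("need at least 2 groups")
  ng <- table(g)
  if (any(ng < 2)) stop("every group needs at least 2 samples")
  grand <- colMeans(X)
  means <- do.call(rbind, lapply(lev, function(l) colMeans(X[g == l, , drop = FALSE])))
  rownames(means) <- lev
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (l in lev) {
    Xi <- X[g == l, , drop = FALSE]
    ci <- sweep(Xi, 2, means[l, ])
    W <- W + crossprod(ci)
    dm <- means[l, ] - grand
    B <- B + nrow(Xi) * tcrossprod(dm)
  }
  ev_w <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_w) <= max(ev_w) * 1e-12) {
    stop("within-group scatter matrix is singular; remove collinear or constant variables")
  }
  # symmetrise via Cholesky: eigen of L^-1 B L^-T, back-transform vectors
  L <- t(chol(W))
  M <- forwardsolve(L, t(forwardsolve(L, B)))
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  nf <- min(length(lev) - 1, p)
  lambda <- pmax(es$values[seq_len(nf)], 0)
  V <- backsolve(t(L), es$vectors[, seq_len(nf), drop = FALSE])
  # scale: unit pooled within-group variance of scores, v' (W/(n-g)) v = 1
  Sw <- W / (n - length(lev))
  sc <- sqrt(diag(t(V) %*% Sw %*% V))
  V <- sweep(V, 2, sc, "/")
  # sign convention: largest-|coefficient| entry positive
  for (j in seq_len(nf)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  within_sd <- sqrt(diag(Sw))
  std_coef <- V * within_sd
  dimnames(V) <- dimnames(std_coef) <-
    list(colnames(X) %||% paste0("V", seq_len(p)), paste0("F", seq_len(nf)))
  scores <- sweep(X, 2, grand) %*% V
  centroids <- do.call(rbind, lapply(lev, function(l) {
    colMeans(scores[g == l, , drop = FALSE])
  }))
  rownames(centroids) <- lev
  wilks <- vapply(seq_len(nf), function(k) wilks_lambda(lambda, k), numeric(1))
  chi_sq <- -(n - 1 - (p + length(lev)) / 2) * log(wilks)
  df <- vapply(seq_len(nf), function(k) (p - k + 1) * (length(lev) - k), numeric(1))
  p_values <- stats::pchisq(chi_sq, df, lower.tail = FALSE)
  res <- structure(list(
    eigenvalues = lambda,
    coefficients = std_coef,
    raw_coefficients = V,
    variance_pct = 100 * lambda / sum(lambda),
    canonical_correlations = vapply(lambda, canonical_correlation, numeric(1)),
    wilks = wilks, chi_sq = chi_sq, df = df, p_values = p_values,
    group_centroids = centroids, scores = scores,
    grand_mean = grand, means = means, within_sd = within_sd,
    groups = g
  ), class = "cda_result")
  cls <- classify_cda(res, X)
  res$classification <- list(labels = cls$labels,
                             confusion = table(observed = g, predicted = cls$labels),
                             correct_rate_pct = 100 * mean(cls$labels == g))
  res
}

#' @export
print.cda_result <- function(x, ...) {
  nf <- length(x$eigenvalues)
  cat(sprintf("<cda_result> %d canonical function(s), %d groups\n",
              nf, nrow(x$group_centroids)))
  tab <- data.frame(
    eigenvalue = round(x$eigenvalues, 3),
    variance_pct = round(x$variance_pct, 1),
    canonical_corr = round(x$canonical_correlations, 2),
    wilks = round(x$wilks, 2),
    p_value = signif(x$p_values, 3)
  )
  rownames(tab) <- paste("Function", seq_len(nf))
  print(tab)
  cat(sprintf("training classification rate: %.2f%%\n",
              x$classification$correct_rate_pct))
  invisible(x)
}

#' Wilks' lambda of a canonical-function sequence
#'
#' `Lambda_k = prod(1 / (1 + lambda_i))` over functions `i >= k`. Small
#' values indicate strong residual discrimination from function `k` onward;
#' e.g. eigenvalues (0.43, 0.09) give 0.64 for the full sequence and 0.92
#' for the second function alone.
#'
#' @param eigenvalues Nonnegative canonical eigenvalues, descending.
#' @param k Starting function (1-based).
#' @return Wilks' lambda.
#' @export
wilks_lambda <- function(eigenvalues, k = 1) {
  if (any(eigenvalues < 0)) stop("eigenvalues must be >= 0")
  if (k < 1 || k > length(eigenvalues)) {
    stop(sprintf("k = %d out of range 1..%d", k, length(eigenvalues)))
  }
  prod(1 / (1 + eigenvalues[k:length(eigenvalues)]))
}

#' Canonical correlation from an eigenvalue
#'
#' `r = sqrt(lambda / (1 + lambda))` — the correlation between a canonical
#' function's scores and group membership.
#'
#' @param eigenvalue Nonnegative canonical eigenvalue.
#' @return Canonical correlation in `[0, 1)`.
#' @export
canonical_correlation <- function(eigenvalue) {
  if (eigenvalue < 0) stop("eigenvalue must be >= 0")
  sqrt(eigenvalue / (1 + eigenvalue))
}

#' Evaluate a canonical function on colour triplets
#'
#' Computes the linear combination `sum(coefficients * x)` per row, with
#' optional standardization (division by within-group SDs) first — the form
#' in which canonical functions are usually printed, e.g.
#' `0.47 L* + 0.14 a* + 0.40 b*`.
#'
#' @param coefficients Coefficient vector, one per variable.
#' @param triplets Numeric vector (one observation) or matrix (rows =
#'   observations).
#' @param standardization Optional positive within-group SDs to divide the
#'   variables by before combining; `NULL` applies the coefficients to raw
#'   values.
#' @return Numeric vector of function scores.
#' @export
evaluate_functions <- function(coefficients, triplets, standardization = NULL) {
  x <- if (is.null(dim(triplets))) matrix(triplets, nrow = 1) else as.matrix(triplets)
  if (ncol(x) != length(coefficients)) {
    stop(sprintf("%d coefficients for %d variables", length(coefficients), ncol(x)))
  }
  if (!is.null(standardization)) {
    if (any(standardization <= 0)) stop("standardization SDs must be positive")
    x <- sweep(x, 2, standardization, "/")
  }
  as.numeric(x %*% coefficients)
}

#' Classify observations by nearest canonical centroid
#'
#' Projects new feature rows into the fitted canonical space and assigns
#' each to the group whose centroid is nearest (Euclidean distance, equal
#' priors).
#'
#' @param result A fitted `cda_result`.
#' @param features Feature matrix with the training dimensionality.
#' @return List with `labels` (factor), `correct_rate_pct` (`NA` unless
#'   `truth` given), `confusion`, `scores`.
#' @param truth Optional true labels to tabulate against.
#' @export
classify_cda <- function(result, features, truth = NULL) {
  stopifnot(inherits(result, "cda_result"))
  X <- as.matrix(features)
  if (ncol(X) != length(result$grand_mean)) {
    stop(sprintf("features have %d variables; model expects %d",
                 ncol(X), length(result$grand_mean)))
  }
  sc <- sweep(X, 2, result$grand_mean) %*% result$raw_coefficients
  C <- result$group_centroids
  d2 <- sapply(seq_len(nrow(C)), function(i) {
    rowSums(sweep(sc, 2, C[i, ])^2)
  })
  d2 <- matrix(d2, nrow = nrow(sc))
  labels <- factor(rownames(C)[max.col(-d2, ties.method = "first")],
                   levels = rownames(C))
  out <- list(labels = labels, scores = sc,
              correct_rate_pct = NA_real_, confusion = NULL)
  if (!is.null(truth)) {
    truth <- factor(truth, levels = rownames(C))
    out$correct_rate_pct <- 100 * mean(labels == truth)
    out$confusion <- table(observed = truth, predicted = labels)
  }
  out
}

#' One-way ANOVA with Tukey letter display
#'
#' Tests for a group effect by one-way ANOVA; when significant at `alpha`,
#' compresses Tukey HSD pairwise comparisons into a compact letter display
#' (groups sharing a letter are not significantly different); letter sets
#' are assigned in ascending order of group mean.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation.
#' @param alpha Significance level (default 0.05).
#' @return List of class `group_summary`: per-group `mean`, `sd`, `n`,
#'   `letters`, plus `anova_p` and the Tukey `p_matrix`.
#' @export
anova_letters <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  stopifnot(length(values) == length(g))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 values")
  fit <- stats::aov(values ~ g)
  p_anova <- summary(fit)[[1]][["Pr(>F)"]][1]
  lev <- levels(g)
  stats_tab <- data.frame(
    group = lev,
    mean = tapply(values, g, mean)[lev],
    sd = tapply(values, g, stats::sd)[lev],
    n = as.integer(table(g)[lev])
  )
  k <- nlevels(g)
  pmat <- matrix(1, k, k, dimnames = list(lev, lev))
  if (!is.na(p_anova) && p_anova < alpha) {
    tk <- stats::TukeyHSD(fit)$g
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (i in seq_along(pairs)) {
      a <- pairs[[i]][1]; b <- pairs[[i]][2]
      pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
    }
  }
  letters_vec <- letter_display(pmat, stats_tab$mean, alpha)
  stats_tab$letters <- letters_vec
  structure(list(table = stats_tab, anova_p = p_anova, p_matrix = pmat,
                 alpha = alpha),
            class = "group_summary")
}

# Compact letter display from a pairwise p-value matrix: letters are the
# maximal cliques of the non-significance graph (exact enumeration — the
# number of groups in composition tables is small), lettered in ascending
# order of the clique mean.
letter_display <- function(pmat, means, alpha) {
  k <- nrow(pmat)
  nonsig <- pmat >= alpha
  diag(nonsig) <- TRUE
  is_clique <- function(s) all(nonsig[s, s])
  subsets <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  cliques <- Filter(is_clique, subsets)
  maximal <- Filter(function(s) {
    !any(vapply(cliques, function(t) length(t) > length(s) && all(s %in% t),
                logical(1)))
  }, cliques)
  maximal <- maximal[order(vapply(maximal, function(s) mean(means[s]), numeric(1)))]
  out <- character(k)
  for (s in seq_along(maximal)) {
    out[maximal[[s]]] <- paste0(out[maximal[[s]]], letters[s])
  }
  out
}

#' @export
print.group_summary <- function(x, ...) {
  tab <- x$table
  cat(sprintf("one-way ANOVA p = %.4g (alpha = %g)\n", x$anova_p, x$alpha))
  tab$mean <- round(tab$mean, 2); tab$sd <- round(tab$sd, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
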