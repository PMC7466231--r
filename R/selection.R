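#' Rank wavelengths by regression-coefficient magnitude
#'
#' Orders the model's wavelengths by descending absolute weighted regression
#' coefficient (BW), irrespective of sign — large |BW| marks bands that carry
#' predictive information. Ties break by ascending wavelength.
#'
#' @param model A fitted `plsr_model` carrying a wavelength grid.
#' @return Data frame with `wavelength_nm`, `index` (grid position), and
#'   `bw`, sorted by descending |BW|.
#' @export
rank_by_bw <- function(model) {
  stopifnot(inherits(model, "plsr_model"))
  wl <- if (is.null(model$grid)) seq_along(model$coefficients)
        else as.numeric(model$grid)
  ord <- order(-abs(model$coefficients), wl)
  data.frame(wavelength_nm = wl[ord], index = ord, bw = model$coefficients[ord])
}

#' Backward elimination of uninformative wavelengths
#'
#' Selects important optimal wavelengths (IOW) by iterative backward feature
#' selection on PLSR regression coefficients: at each step the candidate
#' wavelengths are tried in order of ascending |BW| (recomputed after every
#' refit), and the first one whose removal keeps the cross-validated RMSECV
#' within `(1 + tolerance)` times the best RMSECV seen so far is discarded.
#' The procedure stops when no wavelength can be removed without a
#' significant accuracy loss, or when `min_keep` wavelengths remain.
#'
#' @param X Spectra matrix (treated), columns in grid order.
#' @param y Response vector.
#' @param grid Wavelength grid matching `ncol(X)`.
#' @param tolerance Allowed relative RMSECV increase per removal (>= 0,
#'   default 0.05).
#' @param min_keep Minimum number of wavelengths to retain (default 2).
#' @param max_components Component-count ceiling for the CV refits; each
#'   reduced model's count is re-optimised by cross-validation.
#' @param cv_scheme,k,seed Cross-validation controls (see
#'   [cross_validate()]); the seed is reused at every refit so the criterion
#'   sequence is replayable.
#' @return Object of class `iow_set`: `wavelengths_nm` (sorted ascending),
#'   `indices` (positions on the grid), `source_model` (full-spectrum fit),
#'   and `criterion_log` (one row per attempted removal with RMSECV before /
#'   after and whether it was accepted).
#' @export
backward_eliminate <- function(X, y, grid, tolerance = 0.05, min_keep = 2,
                               max_components = 10, cv_scheme = "loo", k = 10,
                               seed = 1) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  X <- as.matrix(X)
  stopifnot(length(grid) == ncol(X))
  wl <- as.numeric(grid)
  cv_rmse <- function(cols) {
    a_max <- min(max_components, length(cols), nrow(X) - 2)
    cv <- cross_validate(X[, cols, drop = FALSE], y, a_max, scheme = cv_scheme,
                         k = k, seed = seed)
    list(rmsecv = cv$rmsecv[cv$optimal], ncomp = cv$optimal)
  }
  current <- seq_len(ncol(X))
  full <- cv_rmse(current)
  source_model <- fit_plsr(X, y, full$ncomp, grid = grid)
  best <- full$rmsecv
  log_rows <- list()
  repeat {
    if (length(current) <= min_keep) break
    a <- min(full$ncomp, length(current), nrow(X) - 2)
    m <- fit_plsr(X[, current, drop = FALSE], y,
                  min(a, length(current)))
    cand_order <- current[order(abs(m$coefficients), wl[current])]
    removed <- FALSE
    base <- cv_rmse(current)$rmsecv
    for (cand in cand_order) {
      trial <- setdiff(current, cand)
      res <- cv_rmse(trial)
      ok <- res$rmsecv <= best * (1 + tolerance)
      log_rows[[length(log_rows) + 1]] <- data.frame(
        wavelength_nm = wl[cand], rmsecv_before = base,
        rmsecv_after = res$rmsecv, accepted = ok
      )
      if (ok) {
        current <- trial
        best <- min(best, res$rmsecv)
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  structure(list(
    wavelengths_nm = sort(wl[current]),
    indices = sort(current),
    source_model = source_model,
    criterion_log = do.call(rbind, log_rows),
    tolerance = tolerance, seed = seed
  ), class = "iow_set")
}

#' @export
print.iow_set <- function(x, ...) {
  cat(sprintf("<iow_set> %d wavelengths retained of %d (%.1f%% removed)\n",
              length(x$indices), length(x$source_model$coefficients),
              100 * (1 - length(x$indices) / length(x$source_model$coefficients))))
  cat("  ", paste(x$wavelengths_nm, collapse = ", "), "nm\n")
  invisible(x)
}

#' Construct an IOW set from known wavelengths
#'
#' Wraps a published or externally chosen wavelength list as an `iow_set`,
#' validating every entry against the grid — used to drive mapping with
#' fixed band subsets.
#'
#' @param wavelengths_nm Wavelengths to keep (nm).
#' @param grid Wavelength grid they must lie on.
#' @return An `iow_set` (without a source model or criterion log).
#' @export
iow_from_wavelengths <- function(wavelengths_nm, grid) {
  if (!length(wavelengths_nm)) stop("IOW set must be non-empty")
  idx <- vapply(wavelengths_nm, band_index, integer(1), grid = grid)
  ord <- order(as.numeric(grid)[idx])
  structure(list(wavelengths_nm = as.numeric(grid)[idx][ord],
                 indices = idx[ord], source_model = NULL,
                 criterion_log = NULL),
            class = "iow_set")
}

#' Refit a PLSR model on a reduced wavelength set
#'
#' Restricts the spectra to the selected bands and refits, re-optimising the
#' component count by the same cross-validation scheme as the full model so
#' full- and reduced-model metrics are comparable.
#'
#' @param X Spectra matrix on the full grid (treated).
#' @param y Response vector.
#' @param iow An `iow_set`.
#' @param n_components Latent variables; `NULL` re-optimises by CV (capped at
#'   the IOW size).
#' @param grid Full wavelength grid.
#' @param cv_scheme,k,seed Cross-validation controls.
#' @return List with `model` (fitted on the reduced bands), `metrics`
#'   (r2_c/rmsec/r2_cv/rmsecv), and `iow`.
#' @export
refit_iow <- function(X, y, iow, n_components = NULL, grid = NULL,
                      cv_scheme = "loo", k = 10, seed = 1) {
  stopifnot(inherits(iow, "iow_set"))
  X <- as.matrix(X)
  Xr <- X[, iow$indices, drop = FALSE]
  if (!is.null(n_components) && n_components > length(iow$indices)) {
    stop(sprintf("n_components = %d exceeds IOW size %d",
                 n_components, length(iow$indices)))
  }
  a_max <- min(10, length(iow$indices), nrow(X) - 2)
  cv <- cross_validate(Xr, y, a_max, scheme = cv_scheme, k = k, seed = seed)
  a <- if (is.null(n_components)) cv$optimal else n_components
  sub_grid <- if (is.null(grid)) NULL else {
    structure(as.numeric(grid)[iow$indices], class = c("wavelength_grid", "numeric"))
  }
  model <- fit_plsr(Xr, y, a, grid = sub_grid)
  mc <- compute_metrics(y, predict(model, Xr))
  list(model = model,
       metrics = list(r2_c = mc$r2, rmsec = mc$rmse,
                      r2_cv = cv$r2cv[a], rmsecv = cv$rmsecv[a],
                      n_components = a),
       iow = iow)
}

#' Fraction of wavelengths removed by a selection
#'
#' On the full 125-band grid, retaining 10, 10 and 7 bands corresponds to
#' removing 92.0%, 92.0% and 94.4% of the wavelengths.
#'
#' @param n_selected Number of retained wavelengths.
#' @param n_total Grid length.
#' @return Percentage removed.
#' @export
removal_fraction <- function(n_selected, n_total) {
  stopifnot(n_selected >= 0, n_selected <= n_total)
  100 * (n_total - n_selected) / n_total
}
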