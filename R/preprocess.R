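#' Extract the centred square region of interest
#'
#' Selects a `size` x `size` pixel window centred on the spatial centre of
#' the cube (floor convention when the margin is odd), unfolds it row-wise
#' into a pixels x bands matrix, and returns the mean spectrum — the
#' calibration protocol averages the central 50 x 50 window of each sample
#' for model development.
#'
#' @param cube A `reflectance_cube` (or raw `hypercube`).
#' @param size Window side length in pixels (default 50).
#' @return List with `spectra` (size^2 x bands matrix, window pixels in
#'   row-major order), `mean_spectrum` (length-bands vector), and `window`
#'   (the line/pixel index ranges used).
#' @export
extract_center_roi <- function(cube, size = 50) {
  stopifnot(inherits(cube, "hypercube"), size >= 1)
  d <- dim(cube$data)
  if (d[1] < size || d[2] < size) {
    stop(sprintf("cube spatial extent %dx%d smaller than ROI %dx%d",
                 d[1], d[2], size, size))
  }
  l0 <- floor((d[1] - size) / 2) + 1L
  p0 <- floor((d[2] - size) / 2) + 1L
  lines <- l0:(l0 + size - 1L)
  pixels <- p0:(p0 + size - 1L)
  win <- cube$data[lines, pixels, , drop = FALSE]
  # row-major unfolding: pixel index varies fastest within each line
  X <- matrix(aperm(win, c(2, 1, 3)), nrow = size * size, ncol = d[3])
  colnames(X) <- format(as.numeric(cube$grid), trim = TRUE)
  list(spectra = X,
       mean_spectrum = colMeans(X),
       window = list(lines = range(lines), pixels = range(pixels)))
}

#' Threshold segmentation of sample pixels
#'
#' Marks pixels whose reflectance at a single wavelength strictly exceeds a
#' threshold. The protocol segments sample from background at 690 nm for L*
#' and 685 nm for a* and b*, threshold 0.05 reflectance units.
#'
#' @param cube A `reflectance_cube`.
#' @param band_nm Wavelength in nm; snapped to the nearest grid band within
#'   half a step.
#' @param threshold Reflectance threshold (strict `>`).
#' @return Object of class `pixel_mask`: logical lines x pixels matrix with
#'   the generating rule attached as attributes.
#' @export
segment_threshold <- function(cube, band_nm, threshold = 0.05) {
  stopifnot(inherits(cube, "hypercube"))
  i <- band_index(cube$grid, band_nm)
  mask <- cube$data[, , i] > threshold
  structure(mask,
            rule = list(band_nm = as.numeric(cube$grid[i]), band_index = i,
                        threshold = threshold, comparison = ">"),
            class = c("pixel_mask", "matrix", "array"))
}

#' Standard normal variate transform
#'
#' Centres each spectrum (row) to mean zero and scales to unit sample
#' standard deviation (n-1 denominator), removing additive offset and
#' multiplicative scatter per spectrum.
#'
#' @param X Spectra matrix, rows = samples or pixels, columns = bands.
#' @return Transformed matrix of the same shape.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  mu <- rowMeans(X)
  s <- apply(X, 1, stats::sd)
  flat <- which(s == 0 | !is.finite(s))
  if (length(flat)) {
    stop("constant row(s) with zero spread: ", paste(flat, collapse = ", "))
  }
  (X - mu) / s
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum (default: the column mean
#' of `X`) and returns `(x - intercept) / slope`, removing additive and
#' multiplicative scatter relative to the reference. When correcting new
#' data with a fitted model, pass the calibration-set reference so the
#' transform matches the one frozen at training time.
#'
#' @param X Spectra matrix (rows = spectra).
#' @param reference Reference spectrum; defaults to `colMeans(X)`.
#' @return Corrected matrix with the reference attached as
#'   `attr(, "reference")`.
#' @export
msc <- function(X, reference = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("MSC needs at least 2 bands")
  if (is.null(reference)) reference <- colMeans(X)
  stopifnot(length(reference) == ncol(X))
  r <- as.numeric(reference)
  rc <- r - mean(r)
  vr <- sum(rc^2)
  if (vr == 0) stop("reference spectrum has zero variance")
  out <- t(apply(X, 1, function(x) {
    b <- sum((x - mean(x)) * rc) / vr
    a <- mean(x) - b * mean(r)
    (x - a) / b
  }))
  dimnames(out) <- dimnames(X)
  attr(out, "reference") <- r
  out
}

#' Unit-area normalisation
#'
#' Scales each spectrum so its area under the curve, by the trapezoid rule
#' over the wavelength grid, equals 1 — putting spectra of different overall
#' intensity on a common footing for comparison.
#'
#' @param X Spectra matrix.
#' @param grid Wavelength grid matching `ncol(X)`.
#' @param method `"area"` (trapezoidal unit area, default), `"max"` (peak =
#'   1) or `"vector"` (Euclidean norm = 1).
#' @return Normalised matrix.
#' @export
area_normalize <- function(X, grid, method = c("area", "max", "vector")) {
  X <- as.matrix(X)
  method <- match.arg(method)
  stopifnot(length(grid) == ncol(X))
  denom <- switch(method,
    area = apply(X, 1, function(x) trapz_area(as.numeric(grid), x)),
    max = apply(X, 1, max),
    vector = sqrt(rowSums(X^2))
  )
  zero <- which(denom == 0)
  if (length(zero)) {
    stop("row(s) with zero ", method, ": ", paste(zero, collapse = ", "))
  }
  X / denom
}

trapz_area <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-n] + y[-1]) / 2)
}

#' Savitzky-Golay derivative
#'
#' Differentiates each spectrum by local polynomial (Savitzky-Golay)
#' filtering, scaled by the grid step to physical units: per nm for the
#' first derivative, per nm^2 for the second. Edge bands are handled by
#' evaluating the fitted window polynomial at the edge positions, so the
#' band count is preserved.
#'
#' @param X Spectra matrix.
#' @param grid Wavelength grid (uniform step) matching `ncol(X)`.
#' @param order Derivative order, 1 or 2.
#' @param window Odd window length (default 11 bands).
#' @param polyorder Polynomial order; default 2 for the first derivative and
#'   3 for the second. Must satisfy `order <= polyorder < window`.
#' @return Matrix of derivatives, same shape as `X`.
#' @export
sg_derivative <- function(X, grid, order = 1, window = 11,
                          polyorder = if (order == 1) 2 else 3) {
  X <- as.matrix(X)
  stopifnot(length(grid) == ncol(X))
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")
  if (window %% 2 != 1) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (polyorder < order) stop("polyorder must be >= derivative order")
  if (window > ncol(X)) stop("window larger than band count")
  step <- grid_step(as.numeric(grid))
  if (is.na(step)) stop("derivative needs at least 2 bands")
  out <- t(apply(X, 1, signal::sgolayfilt, p = polyorder, n = window,
                 m = order, ts = step))
  dimnames(out) <- dimnames(X)
  out
}

#' Apply a named pre-treatment chain
#'
#' Dispatcher over the five standard spectral pre-treatments. Statistics
#' learned from data (the MSC reference) are learned from `X` unless
#' supplied, and returned so they can be frozen inside fitted models and
#' re-applied to validation spectra.
#'
#' @param X Spectra matrix.
#' @param grid Wavelength grid.
#' @param treatment One of `"raw"`, `"snv"`, `"msc"`, `"norm"`, `"d1"`,
#'   `"d2"`.
#' @param msc_reference Optional frozen MSC reference spectrum.
#' @param window,polyorder Savitzky-Golay parameters for `"d1"`/`"d2"`;
#'   `NULL` uses the per-order defaults of [sg_derivative()].
#' @return List with `X` (treated matrix), `treatment`, and `state` (frozen
#'   statistics, e.g. the MSC reference).
#' @export
pretreat <- function(X, grid, treatment = c("raw", "snv", "msc", "norm", "d1", "d2"),
                     msc_reference = NULL, window = 11, polyorder = NULL) {
  treatment <- match.arg(treatment)
  state <- list()
  Xt <- switch(treatment,
    raw = as.matrix(X),
    snv = snv(X),
    msc = {
      out <- msc(X, reference = msc_reference)
      state$msc_reference <- attr(out, "reference")
      out
    },
    norm = area_normalize(X, grid),
    d1 = sg_derivative(X, grid, order = 1, window = window,
                       polyorder = polyorder %||% 2),
    d2 = sg_derivative(X, grid, order = 2, window = window,
                       polyorder = polyorder %||% 3)
  )
  list(X = Xt, treatment = treatment, state = state)
}
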