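#' Unfold masked pixel spectra at selected wavelengths
#'
#' Converts the 3-D cube into a 2-D matrix whose rows are the masked pixels
#' in row-major (line-by-line) order and whose columns are the selected IOW
#' bands — the standard unfolding step before pixel-wise prediction. The
#' row-to-pixel correspondence is returned so the predictions can be folded
#' back.
#'
#' @param cube A `reflectance_cube`.
#' @param mask A `pixel_mask` (or logical matrix) matching the cube's spatial
#'   shape.
#' @param iow An `iow_set`, or `NULL` to keep all bands.
#' @return List with `X` (pixels x bands matrix), `pixels` (data frame of
#'   `line`, `pixel` per row), `iow`.
#' @export
unfold_cube <- function(cube, mask, iow = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == d[1:2])) {
    stop(sprintf("mask %dx%d does not match cube %dx%d",
                 nrow(mask), ncol(mask), d[1], d[2]))
  }
  if (!any(mask)) stop("mask selects no pixels")
  cols <- if (is.null(iow)) seq_len(d[3]) else iow$indices
  # row-major pixel enumeration: pixel index varies fastest within a line
  tm <- t(mask)
  keep <- which(tm)
  pixels <- data.frame(line = ((keep - 1L) %/% d[2]) + 1L,
                       pixel = ((keep - 1L) %% d[2]) + 1L)
  flat <- matrix(aperm(cube$data, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  X <- flat[keep, cols, drop = FALSE]
  colnames(X) <- format(as.numeric(cube$grid)[cols], trim = TRUE)
  list(X = X, pixels = pixels, iow = iow)
}

#' Pixel-wise prediction from an unfolded matrix
#'
#' Multiplies each pixel spectrum (already carrying the model's
#' pre-treatment, and restricted to the model's bands) by the PLSR
#' regression coefficients and adds the intercept.
#'
#' @param X Pixels x bands matrix from [unfold_cube()].
#' @param model A `plsr_model` with matching band count.
#' @return Numeric vector, one predicted value per pixel row.
#' @export
predict_pixels <- function(X, model) {
  stopifnot(inherits(model, "plsr_model"))
  predict(model, X)
}

#' Fold predicted values back into a spatial map
#'
#' Places per-pixel predictions at their masked positions; background pixels
#' carry `NA` (a sentinel outside every valid colour range, since 0 is a
#' legitimate a*/b* value) and are rendered in a separate colour. Linear
#' colour-scale limits are recorded for rendering.
#'
#' @param values Numeric vector, one per masked pixel.
#' @param pixels Data frame of `line`, `pixel` rows (from [unfold_cube()]).
#' @param shape Spatial shape `c(lines, pixels)`.
#' @param attribute `"L"`, `"a"` or `"b"`.
#' @param scale Length-2 colour-scale limits; default the data range.
#' @return Object of class `prediction_map`: `values` (lines x pixels matrix
#'   with `NA` background), `attribute`, `scale`.
#' @export
fold_map <- function(values, pixels, shape, attribute = c("L", "a", "b"),
                     scale = NULL) {
  attribute <- match.arg(attribute)
  if (length(values) != nrow(pixels)) {
    stop(sprintf("%d values for %d masked pixels", length(values), nrow(pixels)))
  }
  m <- matrix(NA_real_, shape[1], shape[2])
  m[cbind(pixels$line, pixels$pixel)] <- values
  if (is.null(scale)) scale <- range(values)
  if (!all(is.finite(scale)) || scale[1] >= scale[2]) {
    scale <- c(scale[1] - 0.5, scale[1] + 0.5)  # degenerate: constant map
  }
  structure(list(values = m, attribute = attribute, scale = scale),
            class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  n <- sum(!is.na(x$values))
  cat(sprintf("<prediction_map> %s*: %dx%d, %d sample pixels, scale [%.2f, %.2f]\n",
              x$attribute, nrow(x$values), ncol(x$values), n,
              x$scale[1], x$scale[2]))
  invisible(x)
}

#' End-to-end colour map from cube + model
#'
#' Convenience chain: segment at the attribute's band (690 nm for L*, 685 nm
#' for a* and b*, threshold 0.05), apply the model's pre-treatment to the
#' full pixel spectra, subset to the model's IOW bands, predict, and fold.
#' Full-spectrum pre-treatments (derivatives, SNV) are applied before band
#' subsetting so the transform keeps its spectral context.
#'
#' @param cube A `reflectance_cube`.
#' @param model A `plsr_model` fitted on the IOW bands.
#' @param iow The `iow_set` the model was fitted on (`NULL` = full grid).
#' @param attribute `"L"`, `"a"` or `"b"`; picks the segmentation band.
#' @param threshold Segmentation threshold (default 0.05).
#' @return A `prediction_map`.
#' @export
map_attribute <- function(cube, model, iow = NULL,
                          attribute = c("L", "a", "b"), threshold = 0.05) {
  attribute <- match.arg(attribute)
  seg_nm <- c(L = 690, a = 685, b = 685)[[attribute]]
  mask <- segment_threshold(cube, seg_nm, threshold)
  uf <- unfold_cube(cube, mask, iow = NULL)  # full spectra first
  Xt <- pretreat(uf$X, cube$grid, model$pretreatment,
                 msc_reference = model$msc_reference)$X
  cols <- if (is.null(iow)) seq_len(ncol(Xt)) else iow$indices
  vals <- predict_pixels(Xt[, cols, drop = FALSE], model)
  fold_map(vals, uf$pixels, dim(cube$data)[1:2], attribute)
}

#' Render a prediction map with a linear colour scale
#'
#' @param x A `prediction_map`.
#' @param palette Colour ramp function (levels -> colours).
#' @param bg Background colour for unmasked pixels.
#' @param ... Passed to [graphics::image()].
#' @export
plot.prediction_map <- function(x, palette = grDevices::hcl.colors,
                                bg = "grey85", ...) {
  v <- pmin(pmax(x$values, x$scale[1]), x$scale[2])  # clip at render time only
  graphics::image(t(v)[, nrow(v):1], col = palette(64), zlim = x$scale,
                  axes = FALSE, asp = nrow(v) / ncol(v),
                  main = sprintf("%s* prediction map", x$attribute), ...)
  graphics::rect(graphics::par("usr")[1], graphics::par("usr")[3],
                 graphics::par("usr")[2], graphics::par("usr")[4],
                 border = bg)
  invisible(x)
}
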