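#' Hypercube containers
#'
#' A hypercube is a 3-D array in (line, pixel, band) order — the natural
#' layout of a push-broom line-scan acquisition, where each stage position
#' contributes one line of pixels and every pixel carries a full spectrum.
#' Raw cubes hold sensor counts before reflectance correction; reflectance
#' cubes hold corrected relative reflectance.
#'
#' @param data 3-D numeric array, dimensions (lines, pixels, bands).
#' @param grid Wavelength grid; its length must equal `dim(data)[3]`.
#' @param meta Optional named list of acquisition descriptors (e.g. stage
#'   speed in mm/s, spatial resolution in mm/pixel).
#' @param kind `"raw"` (sensor counts) or `"reflectance"`.
#' @param provenance For reflectance cubes, a record of the references used.
#'
#' @return Object of class `hypercube` (and `reflectance_cube` when
#'   `kind = "reflectance"`).
#' @export
hypercube <- function(data, grid, meta = list(), kind = c("raw", "reflectance"),
                      provenance = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[3] != length(grid)) {
    stop(sprintf("cube has %d bands but grid has %d wavelengths",
                 dim(data)[3], length(grid)))
  }
  if (any(!is.finite(data))) stop("cube data must be finite")
  if (kind == "raw" && any(data < 0)) stop("raw counts must be >= 0")
  structure(
    list(data = data, grid = grid, meta = meta, kind = kind,
         provenance = provenance),
    class = c(if (kind == "reflectance") "reflectance_cube", "hypercube")
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s cube> %d lines x %d pixels x %d bands (%g-%g nm)\n",
              x$kind, d[1], d[2], d[3], min(x$grid), max(x$grid)))
  if (x$kind == "reflectance") {
    oor <- mean(x$data < 0 | x$data > 1.1)
    cat(sprintf("  out-of-range reflectance fraction: %.4f\n", oor))
  }
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' White or dark reference frame
#'
#' References may be full frames (same lines x pixels x bands shape as the
#' cube), per-band vectors broadcast over the spatial plane, or scalars.
#' The acquisition protocol records a white ceramic tile (about 99%
#' reflectance) and a lens-cap dark current frame.
#'
#' @param data Numeric scalar, per-band vector, or 3-D array.
#' @param kind `"white"` or `"dark"`.
#' @return Object of class `reference_frame`.
#' @export
reference_frame <- function(data, kind = c("white", "dark")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(data))
  if (any(!is.finite(data))) stop("reference frame must be finite")
  structure(list(data = data, kind = kind), class = "reference_frame")
}

# Broadcast a reference to the cube's full (lines, pixels, bands) shape.
broadcast_reference <- function(ref, dims) {
  x <- if (inherits(ref, "reference_frame")) ref$data else ref
  if (is.array(x) && length(dim(x)) == 3) {
    if (!all(dim(x) == dims)) {
      stop(sprintf("reference shape (%s) does not match cube (%s)",
                   paste(dim(x), collapse = "x"), paste(dims, collapse = "x")))
    }
    return(x)
  }
  if (is.null(dim(x)) && length(x) == 1) {
    return(array(x, dims))
  }
  if (is.null(dim(x)) && length(x) == dims[3]) {
    return(aperm(array(x, dims[c(3, 1, 2)]), c(2, 3, 1)))
  }
  stop("reference must be a scalar, a per-band vector, or a full frame")
}

#' Reflectance correction against white and dark references
#'
#' Converts raw counts to relative reflectance,
#' `R = (raw - dark) / (white - dark)`, elementwise. Values outside the
#' nominal 0--1.1 range are retained (the out-of-range fraction is reported
#' by `print`), never silently clipped; clipping happens only when a map is
#' rendered.
#'
#' @param raw A raw `hypercube`.
#' @param white,dark `reference_frame`s (or bare numerics) broadcastable to
#'   the cube shape. `white` must exceed `dark` at every used element.
#' @return A `reflectance_cube` with the grid preserved and the references
#'   recorded in `provenance`.
#' @export
correct_reflectance <- function(raw, white, dark) {
  stopifnot(inherits(raw, "hypercube"))
  if (raw$kind != "raw") stop("cube is already reflectance-corrected")
  dims <- dim(raw$data)
  w <- broadcast_reference(white, dims)
  d <- broadcast_reference(dark, dims)
  denom <- w - d
  bad <- which(denom <= 0)
  if (length(bad)) {
    idx <- arrayInd(bad[seq_len(min(5, length(bad)))], dims)
    stop(sprintf(
      "white - dark <= 0 at %d element(s); first offenders (line, pixel, band): %s",
      length(bad),
      paste(apply(idx, 1, function(r) paste0("(", paste(r, collapse = ","), ")")),
            collapse = " ")
    ))
  }
  refl <- (raw$data - d) / denom
  hypercube(refl, raw$grid, meta = raw$meta, kind = "reflectance",
            provenance = list(white = white, dark = dark))
}
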