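#' Construct a wavelength grid
#'
#' Builds the uniformly spaced wavelength axis of a hyperspectral cube. The
#' default instrument range is 380--1000 nm sampled every 5 nm, i.e. 125
#' spectral bands covering the visible and short near-infrared.
#'
#' @param start_nm First wavelength in nm.
#' @param stop_nm Last wavelength in nm; must be reachable from `start_nm` in
#'   whole steps of `step_nm`.
#' @param step_nm Band spacing in nm; must be positive.
#'
#' @return Numeric vector of class `wavelength_grid`, strictly increasing,
#'   including both endpoints.
#' @examples
#' g <- make_wavelength_grid()
#' length(g) # 125
#' @export
make_wavelength_grid <- function(start_nm = 380, stop_nm = 1000, step_nm = 5) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (step_nm <= 0) stop("step_nm must be > 0")
  if (stop_nm < start_nm) stop("stop_nm must be >= start_nm")
  span <- stop_nm - start_nm
  k <- span / step_nm
  if (abs(k - round(k)) > 1e-8) {
    stop(sprintf(
      "wavelength range %g nm is not divisible by step %g nm (remainder %g nm)",
      span, step_nm, span - floor(k) * step_nm
    ))
  }
  grid <- start_nm + step_nm * seq(0L, round(k))
  structure(grid, class = c("wavelength_grid", "numeric"))
}

#' Find the grid index nearest a requested wavelength
#'
#' Snaps `band_nm` to the nearest wavelength on the grid. The request must
#' fall within half a grid step of an actual band, so that e.g. asking for
#' 687 nm on a 5 nm grid is rejected rather than silently rounded.
#'
#' @param grid Wavelength grid (nm).
#' @param band_nm Requested wavelength in nm.
#' @return Integer index into `grid`.
#' @export
band_index <- function(grid, band_nm) {
  stopifnot(is.numeric(grid), length(grid) >= 1, is.numeric(band_nm),
            length(band_nm) == 1)
  if (band_nm < min(grid) || band_nm > max(grid)) {
    stop(sprintf("wavelength %g nm outside grid range [%g, %g] nm",
                 band_nm, min(grid), max(grid)))
  }
  i <- which.min(abs(grid - band_nm))
  step <- if (length(grid) > 1) grid[2] - grid[1] else Inf
  if (abs(grid[i] - band_nm) > step / 2 + 1e-9) {
    stop(sprintf("wavelength %g nm is more than half a step from the grid", band_nm))
  }
  i
}

grid_step <- function(grid) {
  if (length(grid) < 2) return(NA_real_)
  diff(grid[1:2])
}
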