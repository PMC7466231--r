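#' Generate smooth endmember spectra
#'
#' Builds `n` pure-constituent reflectance spectra by a Gaussian-absorption
#' construction: a smooth baseline (gentle sigmoidal rise into the NIR, as
#' meat reflectance shows) minus a sum of Gaussian absorption bands. The
#' first endmember always carries a band centred at 680 nm, emulating the
#' oxymyoglobin-related absorption dip seen in sausage spectra. All values
#' are kept in [0, 1].
#'
#' Stream order under `seed`: per endmember, baseline level, slope, then the
#' extra band centres, widths and depths.
#'
#' @param grid Wavelength grid (nm).
#' @param n Number of endmembers (>= 2).
#' @param seed Integer seed; the same seed reproduces the same matrix.
#' @param n_bands_each Number of Gaussian absorption bands per endmember
#'   (besides the fixed 680 nm band of endmember 1).
#' @return Object of class `endmember_set`: `spectra` (n x bands matrix in
#'   [0, 1]), `names`, `grid`.
#' @export
make_endmembers <- function(grid, n = 3, seed = 1, n_bands_each = 2) {
  if (n < 2) stop("need n >= 2 endmembers; mixtures are undefined otherwise")
  wl <- as.numeric(grid)
  rng <- range(wl)
  E <- with_seed(seed, {
    t(vapply(seq_len(n), function(j) {
      level <- stats::runif(1, 0.45, 0.75)
      rise <- stats::runif(1, 0.10, 0.25)
      base <- level + rise * stats::plogis((wl - 620) / 90)
      s <- base
      if (j == 1) {
        s <- s - 0.15 * exp(-0.5 * ((wl - 680) / 14)^2)
      }
      for (b in seq_len(n_bands_each)) {
        centre <- stats::runif(1, rng[1] + 40, rng[2] - 40)
        if (j == 1) {
          # keep random bands clear of the fixed 680 nm dip's flanks
          while (centre > 560 && centre < 800) {
            centre <- stats::runif(1, rng[1] + 40, rng[2] - 40)
          }
        }
        width <- stats::runif(1, 12, 45)
        depth <- stats::runif(1, 0.05, 0.18)
        s <- s - depth * exp(-0.5 * ((wl - centre) / width)^2)
      }
      pmin(pmax(s, 0.05), 1)
    }, numeric(length(wl))))
  })
  endmember_set(E, grid)
}

#' Construct an endmember set from given spectra
#'
#' @param spectra n x bands matrix of reflectance values in [0, 1].
#' @param grid Wavelength grid matching the band count.
#' @param names Optional endmember labels.
#' @return Object of class `endmember_set`.
#' @export
endmember_set <- function(spectra, grid, names = NULL) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(grid)) stop("spectra and grid band counts differ")
  if (any(spectra < 0 | spectra > 1)) stop("endmember reflectance must be in [0, 1]")
  if (is.null(names)) names <- paste0("endmember", seq_len(nrow(spectra)))
  structure(list(spectra = spectra, names = names, grid = grid),
            class = "endmember_set")
}

#' Default colour model mapping abundances to CIELAB
#'
#' A deterministic full-rank 3 x k linear map assigning each endmember a
#' plausible sausage-core colour (L* near 42--62, a* near 4--8, b* near
#' 15--21); a pixel's colour is the abundance-weighted blend of its
#' endmember colours.
#'
#' @param k Number of endmembers.
#' @return 3 x k matrix with rows L, a, b.
#' @export
default_colour_model <- function(k) {
  j <- seq_len(k)
  rbind(L = 52 + 10 * cos(j),
        a = 6 + 2 * sin(2 * j),
        b = 18 + 3 * cos(3 * j))
}

#' Simulate a hyperspectral scene with known ground truth
#'
#' Generates a raw-count hypercube plus its white and dark reference frames,
#' with every sample-region pixel a nonnegative unit-sum linear mixture of
#' the endmembers plus i.i.d. Gaussian sensor noise. The sample occupies a
#' centred ellipse (a sliced sausage core on a dark stage); background pixels
#' get flat reflectance 0.02, safely below the 0.05 segmentation threshold.
#' Raw counts follow `raw = dark + reflectance * (white - dark)` with mildly
#' spatially structured reference frames, so calibrating the scene with its
#' own references inverts exactly.
#'
#' Stream order under `seed`: abundance-field coefficients per endmember,
#' then reference-frame spatial fields, then the noise cube.
#'
#' @param grid Wavelength grid.
#' @param endmembers An `endmember_set` on the same grid.
#' @param height,width Spatial extent in pixels (>= 1).
#' @param colour_model 3 x k linear map from abundances to (L*, a*, b*);
#'   must be full rank. Default [default_colour_model()].
#' @param noise_sd Reflectance noise SD (>= 0) applied inside the sample
#'   region.
#' @param seed Integer seed.
#' @return Object of class `synthetic_scene`: `raw` (raw `hypercube`),
#'   `white`, `dark` (`reference_frame`s), `truth_reflectance` (noise-free
#'   mixtures incl. background), `truth_colour` (lines x pixels x 3 array,
#'   `NA` off-sample), `truth_abundances` (lines x pixels x k, `NA`
#'   off-sample), `sample_mask`, `seed`.
#' @export
simulate_scene <- function(grid, endmembers, height = 60, width = 60,
                           colour_model = NULL, noise_sd = 0.005, seed = 1) {
  stopifnot(inherits(endmembers, "endmember_set"))
  if (height < 1 || width < 1) stop("height and width must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  E <- endmembers$spectra
  k <- nrow(E)
  nb <- ncol(E)
  if (nb != length(grid)) stop("endmembers and grid band counts differ")
  if (is.null(colour_model)) colour_model <- default_colour_model(k)
  colour_model <- as.matrix(colour_model)
  if (nrow(colour_model) != 3 || ncol(colour_model) != k) {
    stop("colour_model must be 3 x n_endmembers")
  }
  if (qr(colour_model)$rank < min(3, k)) stop("colour_model must be full rank")

  lc <- (seq_len(height) - (height + 1) / 2) / max(height / 2, 1)
  pc <- (seq_len(width) - (width + 1) / 2) / max(width / 2, 1)
  mask <- outer(lc, pc, function(u, v) (u / 0.8)^2 + (v / 0.8)^2 <= 1)

  smooth_field <- function(n_terms = 3, amp = 1) {
    f <- matrix(0, height, width)
    for (m in seq_len(n_terms)) {
      fr <- stats::runif(2, 0.3, 1.6)
      ph <- stats::runif(2, 0, 2 * pi)
      a <- stats::runif(1, 0.3, 1)
      f <- f + a * outer(lc, pc, function(u, v) {
        cos(pi * fr[1] * u + ph[1]) * cos(pi * fr[2] * v + ph[2])
      })
    }
    amp * f / n_terms
  }

  scene <- with_seed(seed, {
    # abundances: softmax of smooth fields -> nonnegative, unit sum
    Z <- array(0, c(height, width, k))
    for (j in seq_len(k)) Z[, , j] <- smooth_field(3, amp = 1.5)
    Zmax <- apply(Z, c(1, 2), max)
    Aexp <- exp(Z - array(Zmax, c(height, width, k)))
    Asum <- apply(Aexp, c(1, 2), sum)
    A <- Aexp / array(Asum, c(height, width, k))

    Aflat <- matrix(A, height * width, k)
    mix <- Aflat %*% E                       # (pixels) x bands, column-major order
    refl_true <- array(mix, c(height, width, nb))
    bg <- !mask
    for (b in seq_len(nb)) {
      plane <- refl_true[, , b]
      plane[bg] <- 0.02
      refl_true[, , b] <- plane
    }

    # reference frames: mild smooth spatial structure, per-band shape
    wshape <- 2500 + 1500 * stats::plogis((as.numeric(grid) - 500) / 150)
    wspat <- 1 + 0.04 * smooth_field(2)
    dspat <- 1 + 0.10 * smooth_field(2)
    white <- outer(wspat, wshape)
    dark <- outer(dspat, rep(90, nb)) + 0.01 *
      aperm(array(as.numeric(grid) - min(grid), c(nb, height, width)), c(2, 3, 1))

    refl <- refl_true
    if (noise_sd > 0) {
      noise <- array(stats::rnorm(height * width * nb, 0, noise_sd),
                     c(height, width, nb))
      noise[array(bg, c(height, width, nb))] <- 0
      refl <- refl + noise
    }
    raw <- dark + refl * (white - dark)
    list(refl_true = refl_true, white = white, dark = dark, raw = raw, A = A)
  })

  truth_colour <- array(NA_real_, c(height, width, 3),
                        dimnames = list(NULL, NULL, c("L", "a", "b")))
  Aflat <- matrix(scene$A, height * width, k)
  lab <- Aflat %*% t(colour_model)
  for (c3 in 1:3) {
    plane <- matrix(lab[, c3], height, width)
    plane[!mask] <- NA_real_
    truth_colour[, , c3] <- plane
  }
  truth_abund <- scene$A
  truth_abund[array(!mask, c(height, width, k))] <- NA_real_

  structure(list(
    raw = hypercube(scene$raw, grid, kind = "raw",
                    meta = list(stage_speed_mm_s = 2.08,
                                resolution_mm_per_pixel = 0.75)),
    white = reference_frame(scene$white, "white"),
    dark = reference_frame(scene$dark, "dark"),
    truth_reflectance = scene$refl_true,
    truth_colour = truth_colour,
    truth_abundances = truth_abund,
    sample_mask = mask,
    colour_model = colour_model,
    endmembers = endmembers,
    seed = seed
  ), class = "synthetic_scene")
}

#' Default casing-treatment colour parameters
#'
#' Per-group CIELAB means and SDs for the three casing treatments of the
#' reference study: natural casing control, and two surfactant/lactic-acid
#' modifications.
#'
#' @return Named list of lists with `mean` and `sd` vectors (L, a, b).
#' @export
default_group_params <- function() {
  list(
    control    = list(mean = c(L = 56.83, a = 6.23, b = 20.26),
                      sd = c(L = 5.48, a = 2.42, b = 4.81)),
    treatment1 = list(mean = c(L = 50.86, a = 7.09, b = 19.75),
                      sd = c(L = 8.90, a = 2.41, b = 4.17)),
    treatment2 = list(mean = c(L = 51.09, a = 5.72, b = 17.66),
                      sd = c(L = 8.56, a = 1.74, b = 2.89))
  )
}

#' Default linear colour-to-spectrum link
#'
#' Maps a colour triplet to a mean ROI spectrum: a smooth base spectrum with
#' the 680 nm absorption dip, plus per-channel smooth basis spectra scaled so
#' that one within-group SD of colour moves reflectance by a few percent —
#' L* raises the overall level, a* deepens the red-region (500--650 nm)
#' absorption, b* tilts the blue end.
#'
#' @param grid Wavelength grid.
#' @return List with `base` (length-bands vector), `coef` (3 x bands matrix,
#'   rows L, a, b), and `center` (colour triplet at which the base applies).
#' @export
default_spectral_link <- function(grid) {
  wl <- as.numeric(grid)
  base <- 0.45 + 0.18 * stats::plogis((wl - 620) / 90) -
    0.12 * exp(-0.5 * ((wl - 680) / 14)^2)
  coef <- rbind(
    L = 0.004 * (0.8 + 0.2 * stats::plogis((wl - 550) / 120)),
    a = -0.006 * exp(-0.5 * ((wl - 560) / 60)^2),
    b = -0.005 * exp(-0.5 * ((wl - 460) / 40)^2)
  )
  list(base = base, coef = coef, center = c(L = 52.93, a = 6.35, b = 19.22))
}

#' Simulate a labelled sample set of ROI spectra and reference colours
#'
#' Draws per-group colour triplets from independent normal distributions
#' (diagonal within-group covariance; defaults are the casing-treatment
#' means/SDs of [default_group_params()]), then generates each sample's mean
#' ROI spectrum through a linear colour-to-spectrum link plus i.i.d. noise.
#'
#' Stream order under `seed`: colours per group (L, a, b in group order),
#' then the spectral noise matrix.
#'
#' @param n_per_group Samples per group (>= 2).
#' @param group_params Named list of `list(mean, sd)` per group; defaults to
#'   [default_group_params()].
#' @param spectral_link List with `base`, `coef` (3 x bands), `center`; see
#'   [default_spectral_link()].
#' @param noise_sd Spectral noise SD (reflectance units).
#' @param seed Integer seed.
#' @param grid Wavelength grid (default full 380--1000 nm instrument grid).
#' @return Object of class `sample_set`: `spectra` (n x bands), `colours`
#'   (data frame L, a, b), `groups` (factor), `grid`, `seed`.
#' @export
simulate_sample_set <- function(n_per_group = 30, group_params = NULL,
                                spectral_link = NULL, noise_sd = 0.003,
                                seed = 1, grid = make_wavelength_grid()) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(group_params)) group_params <- default_group_params()
  for (gp in group_params) {
    if (any(gp$sd < 0)) stop("group SDs must be >= 0")
  }
  if (is.null(spectral_link)) spectral_link <- default_spectral_link(grid)
  nb <- length(spectral_link$base)
  if (nb != length(grid)) stop("spectral_link and grid band counts differ")
  groups <- factor(rep(names(group_params), each = n_per_group),
                   levels = names(group_params))
  n <- length(groups)
  out <- with_seed(seed, {
    cols <- do.call(rbind, lapply(group_params, function(gp) {
      cbind(L = stats::rnorm(n_per_group, gp$mean[1], gp$sd[1]),
            a = stats::rnorm(n_per_group, gp$mean[2], gp$sd[2]),
            b = stats::rnorm(n_per_group, gp$mean[3], gp$sd[3]))
    }))
    centred <- sweep(cols, 2, spectral_link$center)
    X <- matrix(spectral_link$base, n, nb, byrow = TRUE) +
      centred %*% spectral_link$coef
    if (noise_sd > 0) X <- X + matrix(stats::rnorm(n * nb, 0, noise_sd), n, nb)
    list(cols = cols, X = X)
  })
  colnames(out$X) <- format(as.numeric(grid), trim = TRUE)
  structure(list(spectra = out$X,
                 colours = as.data.frame(out$cols),
                 groups = groups, grid = grid, seed = seed),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples (%s), %d bands\n",
              nrow(x$spectra),
              paste(sprintf("%s: %d", levels(x$groups), table(x$groups)),
                    collapse = ", "),
              ncol(x$spectra)))
  invisible(x)
}
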