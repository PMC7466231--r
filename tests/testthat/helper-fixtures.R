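# Shared in-code fixtures: small grids and cubes built at test time.

tiny_grid <- function(n = 10, start = 380, step = 5) {
  make_wavelength_grid(start, start + (n - 1) * step, step)
}

# cube filled from a function f(line, pixel, band_index)
fill_cube <- function(lines, pixels, grid, f, kind = "reflectance") {
  nb <- length(grid)
  arr <- array(0, c(lines, pixels, nb))
  for (l in seq_len(lines)) for (p in seq_len(pixels)) for (b in seq_len(nb)) {
    arr[l, p, b] <- f(l, p, b)
  }
  hypercube(arr, grid, kind = kind)
}

constant_cube <- function(lines, pixels, grid, value = 0.3) {
  hypercube(array(value, c(lines, pixels, length(grid))), grid,
            kind = "reflectance")
}
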