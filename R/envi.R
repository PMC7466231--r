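#' Write a hypercube as an ENVI-style header + flat binary pair
#'
#' The container is the conventional ENVI layout: an ASCII `.hdr` file
#' describing dimensions, interleave, data type and the wavelength list (in
#' nm), next to a headerless binary payload. Doubles (`data type = 5`) give a
#' bit-exact roundtrip; `data type = 4` (float32) is accepted on read for
#' interoperability.
#'
#' @param cube A `hypercube`.
#' @param path Path of the binary payload; the header is written to
#'   `paste0(path, ".hdr")` unless `path` ends in `.dat`/`.img`, in which case
#'   the extension is replaced by `.hdr`.
#' @param interleave `"bil"`, `"bip"` or `"bsq"` byte order of the payload.
#' @return `path`, invisibly.
#' @seealso [read_cube()]
#' @export
write_cube <- function(cube, path, interleave = c("bil", "bip", "bsq")) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$data)
  hdr_path <- envi_header_path(path)
  # ENVI: samples = pixels across the line, lines = scan lines
  hdr <- c(
    "ENVI",
    sprintf("description = {hsicolor %s cube}", cube$kind),
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("kind = %s", cube$kind),
    "wavelength units = nm",
    sprintf("wavelength = {%s}", paste(format(as.numeric(cube$grid), trim = TRUE),
                                       collapse = ", "))
  )
  for (nm in names(cube$meta)) {
    hdr <- c(hdr, sprintf("%s = %s", nm, format(cube$meta[[nm]])))
  }
  writeLines(hdr, hdr_path)
  # payload element order: sample fastest, then (interleave-dependent)
  perm <- switch(interleave,
    bsq = c(2, 1, 3),  # sample, line, band
    bil = c(2, 3, 1),  # sample, band, line
    bip = c(3, 2, 1)   # band, sample, line
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(cube$data, perm)), con, size = 8, endian = "little")
  invisible(path)
}

envi_header_path <- function(path) {
  if (grepl("\\.(dat|img)$", path)) sub("\\.(dat|img)$", ".hdr", path)
  else paste0(path, ".hdr")
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  # join multi-line { ... } values
  txt <- paste(lines, collapse = "\n")
  fields <- list()
  # scan key = value pairs; values in braces may span lines
  pos <- gregexpr("(?m)^\\s*([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*", txt, perl = TRUE)[[1]]
  if (pos[1] == -1) stop("not an ENVI header: no key = value fields found")
  starts <- as.integer(pos)
  lens <- attr(pos, "match.length")
  for (i in seq_along(starts)) {
    key_val <- substr(txt, starts[i], if (i < length(starts)) starts[i + 1] - 1 else nchar(txt))
    key <- trimws(sub("=.*", "", key_val))
    val <- trimws(sub("^[^=]*=", "", key_val))
    if (startsWith(val, "{")) {
      val <- gsub("^\\{|\\}\\s*$", "", val)
    }
    fields[[tolower(key)]] <- val
  }
  fields
}

#' Read an ENVI-style hypercube
#'
#' Parses the ASCII header next to `path`, validates the payload size against
#' the declared dimensions, and returns a raw or reflectance `hypercube`
#' depending on the header's `kind` field (defaulting to raw when absent, as
#' for files written by other software).
#'
#' @param path Path of the binary payload written by [write_cube()] or any
#'   ENVI-convention writer (BIL/BIP/BSQ, data types 4 and 5, byte order 0).
#' @return A `hypercube`.
#' @export
read_cube <- function(path) {
  hdr_path <- envi_header_path(path)
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path)
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "interleave", "data type")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("ENVI header missing field(s): ", paste(miss, collapse = ", "))
  samples <- as.integer(h$samples); nlines <- as.integer(h$lines)
  bands <- as.integer(h$bands)
  dtype <- as.integer(h[["data type"]])
  if (!dtype %in% c(4L, 5L)) stop("unsupported ENVI data type: ", dtype)
  size <- if (dtype == 5L) 8L else 4L
  interleave <- tolower(trimws(h$interleave))
  if (!interleave %in% c("bsq", "bil", "bip")) {
    stop("unsupported interleave: ", interleave)
  }
  n <- as.double(samples) * nlines * bands
  expected <- n * size
  actual <- file.size(path)
  if (is.na(actual) || actual != expected) {
    stop(sprintf("payload size mismatch: expected %.0f bytes (%d x %d x %d x %d), found %.0f",
                 expected, nlines, samples, bands, size,
                 if (is.na(actual)) NA_real_ else actual))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = size, endian = "little")
  arr <- switch(interleave,
    bsq = aperm(array(v, c(samples, nlines, bands)), c(2, 1, 3)),
    bil = aperm(array(v, c(samples, bands, nlines)), c(3, 1, 2)),
    bip = aperm(array(v, c(bands, samples, nlines)), c(3, 2, 1))
  )
  if (!is.null(h$wavelength)) {
    wl <- as.numeric(strsplit(h$wavelength, ",")[[1]])
    if (length(wl) != bands) {
      stop(sprintf("header declares %d bands but lists %d wavelengths",
                   bands, length(wl)))
    }
    units <- tolower(h[["wavelength units"]] %||% "nm")
    if (grepl("micro", units) || units == "um") wl <- wl * 1000
    grid <- structure(wl, class = c("wavelength_grid", "numeric"))
  } else {
    grid <- structure(seq_len(bands), class = c("wavelength_grid", "numeric"))
  }
  kind <- if (identical(h$kind, "reflectance")) "reflectance" else "raw"
  meta <- h[setdiff(names(h), c(need, "wavelength", "wavelength units", "kind",
                                "byte order", "header offset", "file type",
                                "description"))]
  hypercube(arr, grid, meta = meta, kind = kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
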