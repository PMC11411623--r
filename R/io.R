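#' Write a hypercube in ENVI format
#'
#' Writes the standard ENVI pair: a text header (`.hdr`) carrying the
#' dimensions, interleave, data type and wavelength list, and a flat
#' binary file of 32-bit little-endian floats. Band-sequential (BSQ)
#' interleave only.
#'
#' @param cube a [hypercube()].
#' @param path output path without extension; `path.hdr` and `path.bsq`
#'   are created.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = {hsibruise reflectance cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, trim = TRUE), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".bsq"), "wb")
  on.exit(close(con))
  # BSQ: full plane per band; R arrays are column-major, ENVI rows are
  # lines, so transpose each plane to row-major.
  for (b in seq_len(d[3]))
    writeBin(as.numeric(t(cube$data[, , b])), con, size = 4,
             endian = "little")
  invisible(path)
}

#' Read a hypercube from ENVI format
#'
#' Reads a BSQ-interleaved ENVI header/binary pair written by
#' [write_envi()] or any compliant writer using data type 4 (float32) or
#' 5 (float64), byte order 0.
#'
#' @param path path without extension, or the `.hdr` path.
#' @return a [hypercube()].
#' @export
read_envi <- function(path) {
  path <- sub("\\.(hdr|bsq)$", "", path)
  hdr_lines <- readLines(paste0(path, ".hdr"), warn = FALSE)
  hdr <- paste(hdr_lines, collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(hdr, regexec(sprintf("%s\\s*=\\s*([0-9]+)", key), hdr))[[1]]
    if (length(m) < 2) stop(sprintf("ENVI header missing '%s'", key))
    as.integer(m[2])
  }
  samples <- get_num("samples")
  lines_n <- get_num("lines")
  bands <- get_num("bands")
  dtype <- get_num("data type")
  il <- regmatches(hdr, regexec("interleave\\s*=\\s*(\\w+)", hdr))[[1]][2]
  if (!identical(tolower(il), "bsq"))
    stop("only BSQ interleave is supported")
  wl_m <- regmatches(hdr,
                     regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", hdr))[[1]]
  if (length(wl_m) < 2) stop("ENVI header missing wavelength list")
  wl <- as.numeric(strsplit(wl_m[2], ",")[[1]])
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type ", dtype))
  con <- file(paste0(path, ".bsq"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = samples * lines_n * bands,
                  size = size, endian = "little")
  cube <- array(0, c(lines_n, samples, bands))
  plane <- samples * lines_n
  for (b in seq_len(bands))
    cube[, , b] <- t(matrix(vals[((b - 1) * plane + 1):(b * plane)],
                            samples, lines_n))
  hypercube(cube, wl)
}

#' Write a hypercube as multi-band TIFF with a wavelength sidecar
#'
#' One 32-bit float TIFF page per band, plus `path.wavelengths.csv`
#' holding the band/wavelength table (TIFF carries no wavelength axis).
#'
#' @param cube a [hypercube()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_cube_tiff <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  planes <- lapply(seq_len(d[3]), function(b) cube$data[, , b])
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  utils::write.csv(
    data.frame(band = seq_len(d[3]), wavelength_nm = cube$wavelengths),
    paste0(path, ".wavelengths.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a multi-band TIFF cube with its wavelength sidecar
#'
#' @param path `.tif` path written by [write_cube_tiff()] (or any float
#'   multi-page TIFF with a `path.wavelengths.csv` sidecar).
#' @return a [hypercube()].
#' @export
read_cube_tiff <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  wl <- utils::read.csv(paste0(path, ".wavelengths.csv"))$wavelength_nm
  cube <- array(0, c(dim(planes[[1]]), length(planes)))
  for (b in seq_along(planes)) cube[, , b] <- planes[[b]]
  hypercube(cube, wl)
}

#' Write a binary mask as PNG
#'
#' @param mask logical matrix.
#' @param path `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' @param path `.png` path.
#' @return logical matrix (pixel > 0.5).
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' Write per-sample mean spectra as long-format CSV
#'
#' Columns: `sample_id`, `wavelength`, `reflectance`.
#'
#' @param spectra samples x bands matrix with rownames as sample ids.
#' @param wavelengths band wavelengths (nm).
#' @param path `.csv` path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, wavelengths, path) {
  ids <- rownames(spectra) %||% paste0("sample", seq_len(nrow(spectra)))
  out <- data.frame(
    sample_id = rep(ids, each = ncol(spectra)),
    wavelength = rep(wavelengths, times = nrow(spectra)),
    reflectance = as.vector(t(spectra)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
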