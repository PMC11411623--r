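#' Hyperspectral reflectance cube
#'
#' Container for a hyperspectral image: an H x W x B array of reflectance
#' with a strictly increasing wavelength axis in nanometres.
#'
#' @param data numeric H x W x B array.
#' @param wavelengths numeric vector of length B, strictly increasing (nm).
#' @param meta optional named list of acquisition tags.
#' @return an object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, meta = list()) {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3-D array (rows x cols x bands)")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop("length of 'wavelengths' must equal the number of bands")
  if (any(diff(wavelengths) <= 0))
    stop("'wavelengths' must be strictly increasing")
  structure(list(data = data, wavelengths = wavelengths, meta = meta),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Hyperspectral cube: %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Index of the band nearest a target wavelength
#'
#' @param cube a [hypercube()].
#' @param nm target wavelength in nanometres.
#' @return integer band index.
#' @export
band_index <- function(cube, nm) {
  which.min(abs(cube$wavelengths - nm))
}

#' Flat-field (black/white reference) correction
#'
#' Converts raw intensity to relative reflectance per pixel and band:
#' `Ic = (IR - ID) / (IW - ID)` where `IR` is the captured cube, `IW` the
#' white-reference cube (near-perfect diffuse reflector) and `ID` the dark
#' current cube. Removes illumination non-uniformity and sensor dark
#' current. Pixels where the white and dark references coincide (within
#' `eps`) get an `eps` denominator; their count is recorded in
#' `meta$zero_denominator`. Corrected reflectance is clipped to
#' `[0, clip_max]` to bound specular outliers; the clipped-pixel count is
#' recorded in `meta$clipped`.
#'
#' @param raw,white,dark [hypercube()] objects of identical shape (white
#'   and dark may also be plain arrays of the same shape).
#' @param eps denominator guard (default 1e-8).
#' @param clip_max upper reflectance clip (default 1.5).
#' @return a corrected [hypercube()].
#' @examples
#' wl <- c(1000, 1100)
#' w <- hypercube(array(1, c(2, 2, 2)), wl)
#' d <- hypercube(array(0, c(2, 2, 2)), wl)
#' r <- hypercube(array(0.5, c(2, 2, 2)), wl)
#' range(flat_field_correct(r, w, d)$data)  # all 0.5
#' @export
flat_field_correct <- function(raw, white, dark, eps = 1e-8,
                               clip_max = 1.5) {
  r <- if (inherits(raw, "hypercube")) raw$data else raw
  w <- if (inherits(white, "hypercube")) white$data else white
  dk <- if (inherits(dark, "hypercube")) dark$data else dark
  if (!identical(dim(r), dim(w)) || !identical(dim(r), dim(dk)))
    stop("'raw', 'white' and 'dark' must have identical shapes")
  denom <- w - dk
  n_zero <- sum(abs(denom) < eps)
  denom[abs(denom) < eps] <- eps
  ic <- (r - dk) / denom
  n_clip <- sum(ic < 0 | ic > clip_max)
  ic[ic < 0] <- 0
  ic[ic > clip_max] <- clip_max
  wl <- if (inherits(raw, "hypercube")) raw$wavelengths else
    stop("'raw' must be a hypercube to carry wavelengths")
  meta <- raw$meta
  meta$zero_denominator <- n_zero
  meta$clipped <- n_clip
  hypercube(ic, wl, meta)
}

#' Trim a cube to a wavelength interval
#'
#' Retains the bands whose wavelength lies inside the closed interval
#' `keep_range_nm`. The instrument's extreme bands are noisy, so analysis
#' conventionally restricts to 950-1650 nm.
#'
#' @param cube a [hypercube()].
#' @param keep_range_nm length-2 numeric `c(low, high)` in nm.
#' @return the trimmed [hypercube()].
#' @export
trim_bands <- function(cube, keep_range_nm = c(950, 1650)) {
  stopifnot(inherits(cube, "hypercube"), length(keep_range_nm) == 2L)
  keep <- cube$wavelengths >= keep_range_nm[1] &
    cube$wavelengths <= keep_range_nm[2]
  if (!any(keep))
    stop("no bands fall inside the requested wavelength range")
  hypercube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep],
            cube$meta)
}

#' Histogram-threshold foreground mask
#'
#' Binary segmentation of a single-band grayscale image by Otsu's
#' threshold on a 256-bin histogram: the threshold maximizes the
#' between-class variance of the two gray-level populations, and the
#' foreground is the above-threshold class (fruit brighter than
#' background). The band with maximal class contrast (near 1081 nm on
#' real fruit) is the conventional input.
#'
#' @param band_image 2-D numeric matrix.
#' @return a logical matrix, TRUE on foreground.
#' @export
segment_mask <- function(band_image) {
  if (!is.matrix(band_image)) stop("'band_image' must be a 2-D matrix")
  rng <- range(band_image)
  if (rng[1] == rng[2])
    stop("constant image: no threshold separates foreground from background")
  thr <- EBImage::otsu(EBImage::as.Image(band_image), range = rng,
                       levels = 256)
  band_image > thr
}

#' Masked, centred region-of-interest crop
#'
#' Zeroes background pixels, then crops a fixed-size plane centred on the
#' mask centroid; overflow past the image border is zero-padded, so the
#' output plane is exactly `size`. One fruit per cube is assumed.
#'
#' @param cube a [hypercube()].
#' @param mask logical matrix matching the cube plane; must be non-empty.
#' @param size output plane `c(rows, cols)`; default `c(80, 70)`.
#' @return a list of class `sample_roi` with elements `image`
#'   (size[1] x size[2] x B array), `mask` (cropped logical plane),
#'   `wavelengths`, `mean_spectrum` (per-band mean over mask pixels) and
#'   `label` (NA until assigned).
#' @export
apply_mask_and_crop <- function(cube, mask, size = c(80, 70)) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
    stop("'mask' must be a logical matrix matching the cube plane")
  if (!any(mask)) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  cen <- colMeans(idx)
  r0 <- as.integer(round(cen[1] - (size[1] - 1) / 2))
  c0 <- as.integer(round(cen[2] - (size[2] - 1) / 2))

  img <- array(0, c(size[1], size[2], d[3]))
  mk <- matrix(FALSE, size[1], size[2])
  rows <- r0:(r0 + size[1] - 1L)
  cols <- c0:(c0 + size[2] - 1L)
  ok_r <- rows >= 1L & rows <= d[1]
  ok_c <- cols >= 1L & cols <= d[2]
  masked <- cube$data
  mask3 <- array(rep(mask, d[3]), d)
  masked[!mask3] <- 0
  img[ok_r, ok_c, ] <- masked[rows[ok_r], cols[ok_c], , drop = FALSE]
  mk[ok_r, ok_c] <- mask[rows[ok_r], cols[ok_c]]
  if (!any(mk)) stop("mask fell entirely outside the crop window")

  roi <- structure(list(image = img, mask = mk,
                        wavelengths = cube$wavelengths,
                        label = NA_character_),
                   class = "sample_roi")
  roi$mean_spectrum <- mean_spectrum(roi)
  roi
}

#' Mean reflectance spectrum over the mask
#'
#' @param roi a `sample_roi` from [apply_mask_and_crop()].
#' @return numeric vector, one mean reflectance per band.
#' @export
mean_spectrum <- function(roi) {
  stopifnot(inherits(roi, "sample_roi"), any(roi$mask))
  apply(roi$image, 3L, function(plane) mean(plane[roi$mask]))
}

#' @export
print.sample_roi <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("Sample ROI: %d x %d plane, %d bands, %d mask pixels, label %s\n",
              d[1], d[2], d[3], sum(x$mask), x$label))
  invisible(x)
}
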