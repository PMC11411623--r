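make_cube <- function(values, wl) {
  hypercube(array(values, c(4, 5, length(wl))), wl)
}

test_that("flat-field correction satisfies its closed-form identities", {
  wl <- c(1000, 1100, 1200)
  white <- make_cube(0.9, wl)
  dark <- make_cube(0.1, wl)
  expect_equal(unique(as.vector(
    flat_field_correct(white, white, dark)$data)), 1)
  expect_equal(unique(as.vector(
    flat_field_correct(dark, white, dark)$data)), 0)
  mid <- make_cube(0.5, wl)
  expect_equal(unique(as.vector(
    flat_field_correct(mid, white, dark)$data)), 0.5)
  # idempotence on already-corrected data with ideal references
  corr <- flat_field_correct(mid, white, dark)
  again <- flat_field_correct(corr, make_cube(1, wl), make_cube(0, wl))
  expect_equal(again$data, corr$data)
})

test_that("flat-field correction guards zero denominators and clips", {
  wl <- c(1000, 1100)
  raw <- hypercube(array(0.5, c(2, 2, 2)), wl)
  white <- array(0.5, c(2, 2, 2))
  dark <- array(0.5, c(2, 2, 2))      # white == dark everywhere
  out <- flat_field_correct(raw, white, dark)
  expect_equal(out$meta$zero_denominator, 8)
  expect_true(all(is.finite(out$data)))
  # specular outlier clipped to the cap and counted
  white2 <- array(1, c(2, 2, 2)); dark2 <- array(0, c(2, 2, 2))
  hot <- array(0.5, c(2, 2, 2)); hot[1, 1, 1] <- 5
  out2 <- flat_field_correct(hypercube(hot, wl), white2, dark2)
  expect_equal(max(out2$data), 1.5)
  expect_equal(out2$meta$clipped, 1)
  expect_error(flat_field_correct(raw, array(1, c(3, 2, 2)), dark))
})

test_that("band trimming keeps exactly the in-range bands", {
  wl <- seq(900, 1700, by = 50)
  cube <- hypercube(array(runif(4 * 5 * length(wl)), c(4, 5, length(wl))),
                    wl)
  expect_equal(trim_bands(cube, range(wl))$wavelengths, wl)
  one <- trim_bands(cube, c(1000, 1000))
  expect_equal(one$wavelengths, 1000)
  expect_equal(dim(one$data)[3], 1L)
  expect_error(trim_bands(cube, c(10, 20)))

  # the default synthetic grid keeps exactly 200 bands in 950-1650 nm,
  # verified against a direct scan
  spec <- scene_spec(n_per_class = 2)
  scan <- sum(spec$wavelengths >= 950 & spec$wavelengths <= 1650)
  cube2 <- hypercube(array(0.5, c(2, 2, spec$bands)), spec$wavelengths)
  expect_equal(dim(trim_bands(cube2, c(950, 1650))$data)[3], scan)
  expect_equal(scan, 200L)

  # nested trims collapse to the inner range
  t1 <- trim_bands(trim_bands(cube, c(950, 1600)), c(1000, 1400))
  t2 <- trim_bands(cube, c(1000, 1400))
  expect_equal(t1$data, t2$data)
  expect_equal(t1$wavelengths, t2$wavelengths)
})

test_that("histogram-threshold segmentation recovers clean shapes", {
  img <- matrix(0.1, 40, 40)
  disc <- (row(img) - 20)^2 + (col(img) - 20)^2 <= 100
  img[disc] <- 0.8
  expect_identical(segment_mask(img), disc)
  # inverted image yields the complementary mask under the same rule
  expect_identical(segment_mask(1 - img), !disc)
  expect_error(segment_mask(matrix(0.5, 10, 10)), "constant")
})

test_that("segmentation threshold agrees with exhaustive Otsu", {
  set.seed(21)
  for (rep in 1:5) {
    img <- matrix(c(rnorm(600, 0.25, 0.05), rnorm(400, 0.75, 0.05)), 25, 40)
    thr <- oracle_otsu(img)
    expect_true(thr > 0.25 && thr < 0.75)   # between the two modes
    mask <- segment_mask(img)
    # package mask equals thresholding at the brute-force optimum, up to
    # pixels lying within one histogram bin of the threshold
    bin <- diff(range(img)) / 256
    hard <- img > thr
    disagree <- which(mask != hard)
    expect_true(all(abs(img[disagree] - thr) <= bin + 1e-12))
  }
})

test_that("mask-and-crop centres, pads and sizes the ROI", {
  wl <- c(1000, 1100)
  n <- 100
  img <- matrix(0.1, n, n)
  disc <- (row(img) - 50)^2 + (col(img) - 50)^2 <= 20^2
  cube <- hypercube(array(rep(img + 0.7 * disc, 2), c(n, n, 2)), wl)
  roi <- apply_mask_and_crop(cube, disc, size = c(80, 70))
  expect_equal(dim(roi$image), c(80L, 70L, 2L))
  expect_equal(sum(roi$mask), sum(disc))          # disc fully inside
  # background zeroed in every band
  bg3 <- array(rep(!roi$mask, 2), dim(roi$image))
  expect_true(all(roi$image[bg3] == 0))

  # corner mask: padding keeps the plane size
  corner <- matrix(FALSE, n, n); corner[1:5, 1:5] <- TRUE
  roi2 <- apply_mask_and_crop(cube, corner, size = c(80, 70))
  expect_equal(dim(roi2$image), c(80L, 70L, 2L))
  expect_equal(sum(roi2$mask), 25L)

  # all-true mask on an exactly 80 x 70 cube is the identity crop
  cube3 <- hypercube(array(runif(80 * 70 * 2), c(80, 70, 2)), wl)
  roi3 <- apply_mask_and_crop(cube3, matrix(TRUE, 80, 70))
  expect_equal(roi3$image, cube3$data)

  expect_error(apply_mask_and_crop(cube, matrix(FALSE, n, n)), "empty")
})

test_that("mean spectrum averages masked pixels per band", {
  wl <- c(1000, 1100, 1200)
  cube <- hypercube(array(0.42, c(80, 70, 3)), wl)
  roi <- apply_mask_and_crop(cube, matrix(TRUE, 80, 70))
  expect_equal(roi$mean_spectrum, rep(0.42, 3))

  # half zeros, half ones under the mask
  plane <- matrix(rep(c(0, 1), length.out = 80 * 70), 80, 70)
  cube2 <- hypercube(array(rep(plane, 3), c(80, 70, 3)), wl)
  roi2 <- apply_mask_and_crop(cube2, matrix(TRUE, 80, 70))
  expect_equal(roi2$mean_spectrum, rep(0.5, 3))

  # invariance under mask-preserving pixel permutation
  perm <- sample(80 * 70)
  planep <- matrix(plane[perm], 80, 70)
  if (mean(planep) == mean(plane)) {
    cube3 <- hypercube(array(rep(planep, 3), c(80, 70, 3)), wl)
    roi3 <- apply_mask_and_crop(cube3, matrix(TRUE, 80, 70))
    expect_equal(roi3$mean_spectrum, roi2$mean_spectrum)
  }

  # single-pixel mask returns that pixel's spectrum
  m1 <- matrix(FALSE, 80, 70); m1[40, 35] <- TRUE
  roi4 <- apply_mask_and_crop(cube2, m1)
  expect_equal(roi4$mean_spectrum, rep(plane[40, 35], 3))
})
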