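#' Scene specification for the synthetic-cube generator
#'
#' Describes the statistical structure of a simulated imaging session:
#' near-infrared reflectance cubes of single fruit on a dark background,
#' two classes (sound and bruised) sharing the same spectral shape. The
#' sound class reflects more strongly; both classes carry water/pigment
#' absorption dips near 980, 1081, 1206 and 1280 nm. Bruised tissue
#' additionally has a shorter spatial texture correlation length,
#' mimicking the subtle skin change of an early bruise. Fruit-to-fruit
#' brightness variation (`sample_scale_sd`) is what makes the classes
#' overlap: the class offset competes with natural sample variability.
#'
#' @param n_per_class samples per class (>= 2).
#' @param bands number of spectral bands (default 224).
#' @param wl_start first wavelength in nm (default 935).
#' @param wl_step band spacing in nm; the default `(1720 - 935) / 224`
#'   places exactly 200 bands inside the 950-1650 nm analysis window.
#' @param class_offset reflectance gap subtracted from bruised spectra
#'   (default 0.035).
#' @param absorption_centers,absorption_widths,absorption_depths Gaussian
#'   dip parameters (nm, nm, reflectance units).
#' @param baseline_hi,baseline_lo smooth baseline reflectance at the first
#'   and last band.
#' @param noise_sd i.i.d. noise sd per pixel and band (default 0.02).
#' @param sample_scale_sd sd of the per-fruit multiplicative brightness
#'   factor (default 0.04).
#' @param texture_corr_length named vector `c(sound = , bruised = )` of
#'   Gaussian texture correlation lengths in pixels.
#' @param texture_amp relative amplitude of the spatial texture field.
#' @param plane generated cube plane `c(rows, cols)`.
#' @param crop ROI crop size `c(rows, cols)` (default 80 x 70).
#' @param mask_band_nm wavelength of the segmentation/texture band
#'   (default 1081 nm).
#' @param background background reflectance level.
#' @return a list of class `scene_spec`.
#' @export
scene_spec <- function(n_per_class = 50L, bands = 224L, wl_start = 935,
                       wl_step = (1720 - 935) / 224,
                       class_offset = 0.045,
                       absorption_centers = c(980, 1081, 1206, 1280),
                       absorption_widths = c(22, 16, 20, 16),
                       absorption_depths = c(0.10, 0.06, 0.09, 0.05),
                       baseline_hi = 0.82, baseline_lo = 0.58,
                       noise_sd = 0.03, sample_scale_sd = 0.04,
                       texture_corr_length = c(sound = 5, bruised = 4),
                       texture_amp = 0.05,
                       plane = c(96L, 84L), crop = c(80L, 70L),
                       mask_band_nm = 1081, background = 0.06) {
  if (n_per_class < 2L) stop("need at least 2 samples per class")
  wl <- wl_start + (seq_len(bands) - 1L) * wl_step
  spec <- structure(
    list(n_per_class = as.integer(n_per_class), bands = as.integer(bands),
         wavelengths = wl, class_offset = class_offset,
         absorption_centers = absorption_centers,
         absorption_widths = absorption_widths,
         absorption_depths = absorption_depths,
         baseline_hi = baseline_hi, baseline_lo = baseline_lo,
         noise_sd = noise_sd, sample_scale_sd = sample_scale_sd,
         texture_corr_length = texture_corr_length,
         texture_amp = texture_amp, plane = as.integer(plane),
         crop = as.integer(crop), mask_band_nm = mask_band_nm,
         background = background),
    class = "scene_spec")
  base <- class_base_spectrum(spec, "bruised")
  if (any(base <= 0))
    stop("spectral parameters produce non-positive reflectance")
  spec
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "Scene: %d + %d samples, %d bands (%.1f-%.1f nm), class offset %.3f\n",
    x$n_per_class, x$n_per_class, x$bands, min(x$wavelengths),
    max(x$wavelengths), x$class_offset))
  invisible(x)
}

# Noise-free class spectrum: smooth decreasing baseline minus Gaussian
# absorption dips, minus the class offset for bruised tissue.
class_base_spectrum <- function(spec, class) {
  wl <- spec$wavelengths
  u <- (wl - min(wl)) / (max(wl) - min(wl))
  base <- spec$baseline_hi + (spec$baseline_lo - spec$baseline_hi) * u
  for (k in seq_along(spec$absorption_centers))
    base <- base - spec$absorption_depths[k] *
      exp(-((wl - spec$absorption_centers[k]) /
              spec$absorption_widths[k])^2)
  if (class == "bruised") base <- base - spec$class_offset
  base
}

#' Simulate one mean reflectance spectrum
#'
#' Smooth baseline minus Gaussian absorption dips at the configured
#' centres, minus the class offset for bruised tissue, times a per-fruit
#' brightness factor, plus i.i.d. noise. With `noise_sd = 0` and
#' `sample_scale_sd = 0` the sound and bruised spectra differ by exactly
#' `class_offset` at every band.
#'
#' @param class `"sound"` or `"bruised"`.
#' @param spec a [scene_spec()].
#' @return list with `wavelengths` and `reflectance`.
#' @export
make_spectrum <- function(class = c("sound", "bruised"), spec = scene_spec()) {
  class <- match.arg(class)
  base <- class_base_spectrum(spec, class)
  s <- if (spec$sample_scale_sd > 0)
    stats::rnorm(1, 1, spec$sample_scale_sd) else 1
  refl <- base * s + stats::rnorm(spec$bands, 0, spec$noise_sd)
  list(wavelengths = spec$wavelengths, reflectance = refl)
}

gaussian_field <- function(plane, corr_length) {
  z <- matrix(stats::rnorm(prod(plane)), plane[1], plane[2])
  sm <- EBImage::imageData(EBImage::gblur(EBImage::as.Image(z),
                                          sigma = corr_length))
  (sm - mean(sm)) / stats::sd(sm)
}

#' Simulate one hyperspectral fruit cube with its ground-truth mask
#'
#' An elliptical fruit region carries the class spectrum modulated by a
#' spatially correlated multiplicative texture field (Gaussian-filtered
#' white noise with a class-specific correlation length); the background
#' is dark. Pixel noise is added everywhere. Reflectance is floored at 0.
#'
#' @param class `"sound"` or `"bruised"`.
#' @param spec a [scene_spec()].
#' @return list with `cube` (a [hypercube()]) and `mask` (logical
#'   ground-truth fruit mask).
#' @export
make_hypercube <- function(class = c("sound", "bruised"),
                           spec = scene_spec()) {
  class <- match.arg(class)
  pl <- spec$plane
  cen <- (pl + 1) / 2
  radii <- pmin(floor((spec$crop - 6) / 2), floor((pl - 6) / 2))
  rr <- matrix(seq_len(pl[1]), pl[1], pl[2])
  cc <- matrix(seq_len(pl[2]), pl[1], pl[2], byrow = TRUE)
  mask <- ((rr - cen[1]) / radii[1])^2 + ((cc - cen[2]) / radii[2])^2 <= 1

  base <- class_base_spectrum(spec, class)
  s <- if (spec$sample_scale_sd > 0)
    stats::rnorm(1, 1, spec$sample_scale_sd) else 1
  tex <- gaussian_field(pl, spec$texture_corr_length[[class]]) *
    spec$texture_amp
  modulation <- ifelse(mask, 1 + tex, 0)

  cube <- array(0, c(pl[1], pl[2], spec$bands))
  for (b in seq_len(spec$bands))
    cube[, , b] <- base[b] * s * modulation + spec$background * !mask
  if (spec$noise_sd > 0)
    cube <- cube + array(stats::rnorm(length(cube), 0, spec$noise_sd),
                         dim(cube))
  cube[cube < 0] <- 0
  list(cube = hypercube(cube, spec$wavelengths,
                        list(class = class)),
       mask = mask)
}

#' Preprocess one cube into a sample ROI
#'
#' Standard preprocessing chain for a reflectance cube: trim to the
#' analysis window, segment the fruit on the configured mask band, and
#' crop a centred ROI.
#'
#' @param cube a [hypercube()] of reflectance.
#' @param keep_range_nm analysis wavelength window (default
#'   `c(950, 1650)`).
#' @param mask_band_nm segmentation band (default 1081 nm).
#' @param crop ROI size (default `c(80, 70)`).
#' @param label optional class label attached to the ROI.
#' @return a `sample_roi` (see [apply_mask_and_crop()]).
#' @export
preprocess_cube <- function(cube, keep_range_nm = c(950, 1650),
                            mask_band_nm = 1081, crop = c(80, 70),
                            label = NA_character_) {
  trimmed <- trim_bands(cube, keep_range_nm)
  mask <- segment_mask(trimmed$data[, , band_index(trimmed, mask_band_nm)])
  roi <- apply_mask_and_crop(trimmed, mask, size = crop)
  roi$label <- label
  roi
}

#' Simulate a scene and extract per-sample features
#'
#' Generates `2 * n_per_class` cubes one at a time (sound first), runs
#' each through the preprocessing chain, and collects the mean spectrum
#' and the 28-value GLCM descriptor of the mask-band ROI plane. Cubes are
#' discarded after feature extraction, so memory stays flat.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed; the same spec and seed reproduce the scene
#'   exactly.
#' @param glcm_levels,glcm_distance GLCM quantization and offset.
#' @return list with `spectral` and `image` [feature_table()]s (same
#'   sample order) and `wavelengths` of the trimmed bands.
#' @export
simulate_scene_features <- function(spec = scene_spec(), seed = 1L,
                                    glcm_levels = 8L, glcm_distance = 1L) {
  set.seed(seed)
  classes <- rep(c("sound", "bruised"), each = spec$n_per_class)
  spectra <- NULL
  glcms <- NULL
  wl <- NULL
  for (i in seq_along(classes)) {
    sample <- make_hypercube(classes[i], spec)
    roi <- preprocess_cube(sample$cube, mask_band_nm = spec$mask_band_nm,
                           crop = spec$crop, label = classes[i])
    if (is.null(wl)) {
      wl <- roi$wavelengths
      spectra <- matrix(0, length(classes), length(wl))
      glcms <- matrix(0, length(classes), 28L)
    }
    spectra[i, ] <- roi$mean_spectrum
    plane <- roi$image[, , which.min(abs(wl - spec$mask_band_nm))]
    v <- glcm_feature_vector(plane, glcm_levels, glcm_distance)
    glcms[i, ] <- v
    if (i == 1L) colnames(glcms) <- names(v)
  }
  labels <- factor(classes, levels = c("sound", "bruised"))
  rownames(spectra) <- rownames(glcms) <-
    sprintf("%s_%03d", classes, seq_along(classes))
  list(spectral = spectral_features(spectra, wl, labels),
       image = image_features(glcms, labels),
       wavelengths = wl)
}

#' Run the full bruise-detection experiment on a synthetic scene
#'
#' End-to-end pipeline: simulate a scene, split 7:3 stratified, select
#' wavelengths by SPA on the training rows, build the five feature
#' categories (full spectrum, SPA subset, GLCM descriptor, and the two
#' fusions), min-max scale each on the training rows, and evaluate the
#' requested classifiers on the held-out test rows. Optionally tunes the
#' SVM on one category with [tune_svm()].
#'
#' @param spec a [scene_spec()].
#' @param models classifier kinds to evaluate.
#' @param categories feature categories to evaluate (subset of
#'   `"spectral_full"`, `"spectral_spa"`, `"image_glcm"`, `"fused_full"`,
#'   `"fused_spa"`).
#' @param seed global seed; stage seeds are derived from it.
#' @param spa_k_max,spa_starts SPA settings (see [spa_select()]).
#' @param tune optional list activating SVM tuning, with elements
#'   `algorithm` (`"bwo"` or `"msbwo"`), `category`, and `protocol`
#'   (a [tuning_protocol()]).
#' @return a list of class `bruise_experiment`: `metrics` data frame
#'   (category, model, n_features, accuracy, precision, recall, f1),
#'   `reports` (named list of `metric_report`s), `spa` (the `spa_result`),
#'   `split`, `tuning` (if requested), `seed`.
#' @export
run_experiment <- function(spec = scene_spec(),
                           models = c("svm_rbf", "random_forest", "plsda"),
                           categories = c("spectral_full", "spectral_spa",
                                          "image_glcm", "fused_full",
                                          "fused_spa"),
                           seed = 1L, spa_k_max = 40L, spa_starts = "all",
                           tune = NULL) {
  feats <- simulate_scene_features(spec, seed = derive_seed(seed, 1L))
  evaluate_scene(feats, models = models, categories = categories,
                 seed = seed, spa_k_max = spa_k_max,
                 spa_starts = spa_starts, tune = tune)
}

#' Evaluate classifiers over feature categories of an extracted scene
#'
#' Downstream half of [run_experiment()], reusable on features extracted
#' from cubes on disk.
#'
#' @param feats list with `spectral` and `image` [feature_table()]s (as
#'   returned by [simulate_scene_features()]).
#' @inheritParams run_experiment
#' @return see [run_experiment()].
#' @export
evaluate_scene <- function(feats,
                           models = c("svm_rbf", "random_forest", "plsda"),
                           categories = c("spectral_full", "spectral_spa",
                                          "image_glcm", "fused_full",
                                          "fused_spa"),
                           seed = 1L, spa_k_max = 40L, spa_starts = "all",
                           tune = NULL) {
  spectral <- feats$spectral
  image <- feats$image
  split <- split_table(spectral, 0.7, seed = derive_seed(seed, 2L))
  tr <- split$train

  spa <- NULL
  if (any(c("spectral_spa", "fused_spa") %in% categories)) {
    spa <- spa_select(spectral$x[tr, , drop = FALSE], spectral$labels[tr],
                      k_max = spa_k_max, starts = spa_starts,
                      seed = derive_seed(seed, 3L))
  }

  tables <- list()
  for (cat in categories) {
    tables[[cat]] <- switch(cat,
      spectral_full = scale_features(spectral, tr),
      spectral_spa = scale_features(
        select_features(spectral, spa$selected_indices), tr),
      image_glcm = scale_features(image, tr),
      fused_full = fuse_features(spectral, image, tr),
      fused_spa = fuse_features(
        select_features(spectral, spa$selected_indices), image, tr),
      stop("unknown feature category '", cat, "'"))
  }

  reports <- list()
  rows <- list()
  for (cat in names(tables)) {
    full <- tables[[cat]]
    train_ft <- feature_table(full$x[tr, , drop = FALSE], full$labels[tr],
                              full$provenance)
    test_ft <- feature_table(full$x[split$test, , drop = FALSE],
                             full$labels[split$test], full$provenance)
    for (m in models) {
      rep <- train_eval(m, train_ft, test_ft,
                        seed = derive_seed(seed, 10L + length(reports)))
      key <- paste(cat, m, sep = ".")
      reports[[key]] <- rep
      rows[[key]] <- data.frame(
        category = cat, model = m, n_features = ncol(train_ft$x),
        accuracy = rep$accuracy, precision = rep$precision,
        recall = rep$recall, f1 = rep$f1)
    }
  }

  tuning <- NULL
  if (!is.null(tune)) {
    cat <- tune$category %||% "fused_spa"
    full <- tables[[cat]]
    train_ft <- feature_table(full$x[tr, , drop = FALSE], full$labels[tr],
                              full$provenance)
    test_ft <- feature_table(full$x[split$test, , drop = FALSE],
                             full$labels[split$test], full$provenance)
    tuning <- tune_svm(train_ft, algorithm = tune$algorithm %||% "msbwo",
                       protocol = tune$protocol %||% tuning_protocol(),
                       seed = derive_seed(seed, 4L))
    pred <- factor(as.character(stats::predict(tuning$model, test_ft$x)),
                   levels = levels(train_ft$labels))
    rep <- compute_metrics(table(truth = test_ft$labels, predicted = pred),
                           positive = positive_level(train_ft$labels))
    key <- paste(cat, "svm_rbf", tuning$algorithm, sep = ".")
    reports[[key]] <- rep
    rows[[key]] <- data.frame(
      category = cat, model = paste0("svm_rbf+", tuning$algorithm),
      n_features = ncol(train_ft$x), accuracy = rep$accuracy,
      precision = rep$precision, recall = rep$recall, f1 = rep$f1)
  }

  structure(list(metrics = do.call(rbind, c(rows, make.row.names = FALSE)),
                 reports = reports, spa = spa, split = split,
                 tuning = tuning, seed = seed),
            class = "bruise_experiment")
}

#' @export
print.bruise_experiment <- function(x, ...) {
  cat("Bruise-detection experiment\n")
  df <- x$metrics
  df[, 4:7] <- round(df[, 4:7], 2)
  print(df, row.names = FALSE)
  invisible(x)
}
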