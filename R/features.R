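#' Feature table
#'
#' Samples x features matrix with provenance-tagged column names
#' (`spectral:<wavelength>` or `glcm:<statistic>`), per-sample class
#' labels, and optional min-max scaler parameters fitted on a training
#' split.
#'
#' @param x numeric matrix (samples x features) with column names.
#' @param labels factor of class labels (`sound`/`bruised`), one per row.
#' @param provenance single tag or per-column character vector
#'   (`"spectral"` or `"glcm"`).
#' @param scaler optional list with `min` and `max` per feature.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(x, labels, provenance, scaler = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("'x' must have column names")
  labels <- as.factor(labels)
  if (length(labels) != nrow(x))
    stop("'labels' must have one entry per row")
  if (length(provenance) == 1L)
    provenance <- rep(provenance, ncol(x))
  if (length(provenance) != ncol(x))
    stop("'provenance' must match the number of columns")
  structure(list(x = x, labels = labels, provenance = provenance,
                 scaler = scaler),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s: %d", names(table(x$provenance)),
                            table(x$provenance)), collapse = ", ")))
  print(table(x$labels))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

#' Subset the columns of a feature table
#'
#' @param ft a [feature_table()].
#' @param cols column indices or names.
#' @return a [feature_table()] with the selected features.
#' @export
select_features <- function(ft, cols) {
  feature_table(ft$x[, cols, drop = FALSE], ft$labels,
                ft$provenance[if (is.character(cols))
                  match(cols, colnames(ft$x)) else cols])
}

#' Build a spectral feature table from mean spectra
#'
#' @param spectra samples x bands matrix of mean reflectance.
#' @param wavelengths band wavelengths in nm.
#' @param labels class labels.
#' @return a [feature_table()] with columns `spectral:<nm>nm`.
#' @export
spectral_features <- function(spectra, wavelengths, labels) {
  spectra <- as.matrix(spectra)
  colnames(spectra) <- sprintf("spectral:%.0fnm", wavelengths)
  feature_table(spectra, labels, "spectral")
}

#' Build an image (GLCM) feature table from texture descriptors
#'
#' @param descriptors samples x 28 matrix of [glcm_feature_vector()]
#'   values.
#' @param labels class labels.
#' @return a [feature_table()] with columns `glcm:<name>`.
#' @export
image_features <- function(descriptors, labels) {
  descriptors <- as.matrix(descriptors)
  colnames(descriptors) <- paste0("glcm:", colnames(descriptors))
  feature_table(descriptors, labels, "glcm")
}

#' Fuse spectral and image feature tables
#'
#' Min-max scales every feature to `[0, 1]` using the training rows only,
#' then concatenates the blocks column-wise (spectral first). Training
#' rows span `[0, 1]` after scaling; test rows may exceed it. A feature
#' constant on the training rows is scaled to 0 with a warning.
#'
#' @param spectral,image [feature_table()] objects over the same samples
#'   in the same order.
#' @param train_rows integer indices of the training rows used to fit the
#'   scaler.
#' @return a fused [feature_table()] carrying the scaler parameters.
#' @export
fuse_features <- function(spectral, image, train_rows) {
  if (nrow(spectral$x) != nrow(image$x))
    stop("feature tables must cover the same samples")
  if (!identical(as.character(spectral$labels), as.character(image$labels)))
    stop("feature tables disagree on labels")
  x <- cbind(spectral$x, image$x)
  sc <- fit_minmax(x[train_rows, , drop = FALSE])
  feature_table(apply_minmax(x, sc), spectral$labels,
                c(spectral$provenance, image$provenance), scaler = sc)
}

fit_minmax <- function(xtr) {
  mn <- apply(xtr, 2, min)
  mx <- apply(xtr, 2, max)
  if (any(mx == mn))
    warning(sprintf("%d constant training feature(s) scaled to 0",
                    sum(mx == mn)), call. = FALSE)
  list(min = mn, max = mx)
}

apply_minmax <- function(x, sc) {
  rng <- sc$max - sc$min
  rng[rng == 0] <- 1           # constant features map to 0
  sweep(sweep(x, 2, sc$min, `-`), 2, rng, `/`)
}

#' Min-max scale a feature table on its training rows
#'
#' Same scaler as [fuse_features()] applied to a single block: every
#' feature mapped to `[0, 1]` using the training-row min and max, so all
#' feature categories enter the classifiers on a common scale.
#'
#' @param ft a [feature_table()].
#' @param train_rows integer indices of the training rows.
#' @return a scaled [feature_table()] carrying the scaler parameters.
#' @export
scale_features <- function(ft, train_rows) {
  sc <- fit_minmax(ft$x[train_rows, , drop = FALSE])
  feature_table(apply_minmax(ft$x, sc), ft$labels, ft$provenance,
                scaler = sc)
}

#' Write a feature table as CSV (+ scaler sidecar)
#'
#' Header row holds the provenance-tagged feature names plus a final
#' `label` column; scaler parameters, if fitted, go to a JSON sidecar.
#'
#' @param ft a [feature_table()].
#' @param path `.csv` output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- as.data.frame(ft$x, check.names = FALSE)
  df$label <- as.character(ft$labels)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(ft$scaler))
    jsonlite::write_json(ft$scaler, paste0(path, ".scaler.json"),
                         auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path `.csv` path.
#' @return a [feature_table()] (provenance recovered from column-name
#'   tags).
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- df$label
  df$label <- NULL
  x <- as.matrix(df)
  prov <- sub(":.*$", "", colnames(x))
  sc_path <- paste0(path, ".scaler.json")
  sc <- if (file.exists(sc_path)) {
    raw <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    list(min = unlist(raw$min), max = unlist(raw$max))
  }
  feature_table(x, labels, prov, scaler = sc)
}
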