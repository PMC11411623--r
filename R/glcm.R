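#' Quantize a grayscale image to discrete levels
#'
#' Uniform binning of `[min, max]` into `levels` gray levels. A constant
#' image maps entirely to level 1.
#'
#' @param image 2-D numeric matrix.
#' @param levels number of gray levels (default 8).
#' @return integer matrix with values in `1:levels`.
#' @export
quantize_gray <- function(image, levels = 8L) {
  if (!is.matrix(image)) stop("'image' must be a 2-D matrix")
  rng <- range(image)
  if (rng[1] == rng[2]) return(matrix(1L, nrow(image), ncol(image)))
  q <- floor((image - rng[1]) / (rng[2] - rng[1]) * levels) + 1L
  q[q > levels] <- as.integer(levels)
  matrix(as.integer(q), nrow(image), ncol(image))
}

glcm_offset <- function(direction, distance) {
  switch(as.character(direction),
         "0"   = c(0L, distance),
         "45"  = c(-distance, distance),
         "90"  = c(-distance, 0L),
         "135" = c(-distance, -distance),
         stop("'direction' must be one of 0, 45, 90, 135 (degrees)"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts pairs of gray levels separated by `distance` pixels along one of
#' the four standard directions (0, 45, 90, 135 degrees), accumulates the
#' offset and its negation (symmetric Haralick convention), and normalizes
#' so the entries are relative frequencies summing to 1.
#'
#' @param image 2-D numeric matrix; quantized internally with
#'   [quantize_gray()] (pass an integer matrix of levels together with
#'   `quantized = TRUE` to skip quantization).
#' @param levels number of gray levels (default 8).
#' @param distance offset in pixels (default 1).
#' @param direction one of 0, 45, 90, 135 (degrees).
#' @param quantized set TRUE if `image` already holds levels `1:levels`.
#' @return an object of class `glcm`: list with `P` (levels x levels
#'   matrix summing to 1), `levels`, `distance`, `direction`.
#' @examples
#' img <- matrix(c(0, 1, 0, 1), 2, 2)  # checkerboard
#' compute_glcm(img, levels = 2, direction = 0)$P
#' @export
compute_glcm <- function(image, levels = 8L, distance = 1L, direction = 0,
                         quantized = FALSE) {
  q <- if (quantized) image else quantize_gray(image, levels)
  off <- glcm_offset(direction, as.integer(distance))
  h <- nrow(q); w <- ncol(q)
  rows <- seq_len(h)[seq_len(h) + off[1] >= 1L & seq_len(h) + off[1] <= h]
  cols <- seq_len(w)[seq_len(w) + off[2] >= 1L & seq_len(w) + off[2] <= w]
  if (!length(rows) || !length(cols))
    stop("image is smaller than the requested offset")
  a <- q[rows, cols, drop = FALSE]
  b <- q[rows + off[1], cols + off[2], drop = FALSE]
  counts <- table(factor(a, levels = seq_len(levels)),
                  factor(b, levels = seq_len(levels)))
  counts <- unclass(counts) + t(unclass(counts))   # symmetrize
  structure(list(P = counts / sum(counts), levels = as.integer(levels),
                 distance = as.integer(distance), direction = direction),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("GLCM: %d levels, distance %d, direction %s deg\n",
              x$levels, x$distance, x$direction))
  print(round(x$P, 4))
  invisible(x)
}

#' Texture statistics of a co-occurrence matrix
#'
#' The four Haralick-style statistics of a normalized GLCM `P` with gray
#' levels indexed `i, j = 0..N-1`:
#' contrast `sum P_ij (i-j)^2`; energy `sum P_ij^2`; entropy
#' `sum P_ij (-ln P_ij)` (natural log, `0 ln 0 := 0`); homogeneity
#' `sum P_ij / (1 + (i-j)^2)`.
#'
#' @param P a `glcm` object or a normalized square matrix (entries sum
#'   to 1).
#' @return named numeric vector `c(contrast, energy, entropy,
#'   homogeneity)`.
#' @examples
#' glcm_statistics(matrix(0.25, 2, 2))
#' # contrast 0.5, energy 0.25, entropy log(4), homogeneity 0.75
#' @export
glcm_statistics <- function(P) {
  if (inherits(P, "glcm")) P <- P$P
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("'P' must be a square matrix")
  if (any(P < 0) || abs(sum(P) - 1) > 1e-8)
    stop("'P' must be a normalized co-occurrence matrix (sum 1)")
  n <- nrow(P)
  i <- matrix(0:(n - 1), n, n)
  j <- t(i)
  d2 <- (i - j)^2
  plogp <- ifelse(P > 0, P * log(P), 0)
  c(contrast = sum(P * d2),
    energy = sum(P^2),
    entropy = -sum(plogp),
    homogeneity = sum(P / (1 + d2)))
}

glcm_stat_names <- c("contrast", "energy", "entropy", "homogeneity")
glcm_directions <- c(0, 45, 90, 135)

#' 28-value GLCM texture descriptor
#'
#' Canonical texture descriptor of a single image plane: the four GLCM
#' statistics (contrast, energy, entropy, homogeneity) in each of the four
#' directions (16 values), followed by the mean, population standard
#' deviation and variance of each statistic across the four directions
#' (12 values). Ordering is fixed: per statistic, directions
#' 0, 45, 90, 135; then per statistic, mean, sd, var.
#'
#' @param image 2-D numeric matrix (the chosen band plane of a sample).
#' @param levels gray levels for quantization (default 8).
#' @param distance co-occurrence offset in pixels (default 1).
#' @return named numeric vector of length 28.
#' @export
glcm_feature_vector <- function(image, levels = 8L, distance = 1L) {
  q <- quantize_gray(image, levels)
  stats <- sapply(glcm_directions, function(dir)
    glcm_statistics(compute_glcm(q, levels, distance, dir,
                                 quantized = TRUE)))
  # stats: 4 statistics (rows) x 4 directions (cols)
  per_dir <- as.vector(t(stats))
  names(per_dir) <- paste0(rep(glcm_stat_names, each = 4), "_",
                           rep(glcm_directions, times = 4))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  moments <- unlist(lapply(glcm_stat_names, function(s) {
    x <- stats[s, ]
    out <- c(mean(x), pop_sd(x), pop_sd(x)^2)
    names(out) <- paste0(s, c("_mean", "_sd", "_var"))
    out
  }))
  c(per_dir, moments)
}
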