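#' Successive projections algorithm wavelength selection
#'
#' Forward selection of minimally collinear bands. For each candidate
#' starting band a chain is grown by repeatedly adding the band whose
#' column has maximal norm after orthogonal projection onto the complement
#' of the span of the already-selected columns (classic SPA chain
#' construction). Each candidate subset (start band, first k links of its
#' chain) is then scored by the cross-validated RMSE of an ordinary
#' least-squares fit of the numerically coded labels on the selected
#' bands; the returned curve holds, for each k, the best RMSE over the
#' starting bands, and `chosen_k` is the global minimizer (the smallest k
#' whose RMSE is numerically indistinguishable from the minimum, so a
#' perfectly explained response selects the parsimonious subset).
#'
#' @param X samples x bands numeric matrix (e.g. mean spectra).
#' @param y class labels: a factor (second level coded 1) or a 0/1
#'   numeric vector.
#' @param k_max largest subset size to explore (default 40); clamped so
#'   every CV training fold keeps more rows than coefficients.
#' @param starts candidate starting bands: `"all"` (default) or an integer
#'   vector of band indices.
#' @param folds number of CV folds (default 5).
#' @param seed optional seed fixing the fold assignment.
#' @return an object of class `spa_result`: `selected_indices` (ordered,
#'   distinct band indices of the winning subset), `rmse_curve` (length
#'   `k_max`), `chosen_k`, `start` (winning start band), `k_max`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40 * 6), 40, 6)
#' y <- as.numeric(X[, 2] + X[, 5] > 0)
#' spa_select(X, y, k_max = 4, seed = 1)$selected_indices
#' @export
spa_select <- function(X, y, k_max = 40L, starts = "all", folds = 5L,
                       seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  yv <- if (is.factor(y)) as.numeric(y) - 1 else as.numeric(y)
  if (length(yv) != n) stop("'y' must have one label per row of 'X'")
  # every CV training fold must keep more rows than k coefficients
  k_cap <- min(p, n - 1L, floor(n * (folds - 1) / folds) - 2L)
  k_max <- as.integer(min(k_max, k_cap))
  if (k_max < 1L) stop("too few samples for SPA cross-validation")
  start_set <- if (identical(starts, "all")) seq_len(p) else as.integer(starts)

  if (!is.null(seed)) set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))

  chains <- lapply(start_set, function(s) spa_chain(X, s, k_max))
  best <- list(rmse = Inf, start = NA_integer_, k = NA_integer_)
  curve <- rep(Inf, k_max)
  for (ci in seq_along(chains)) {
    chain <- chains[[ci]]
    for (k in seq_len(min(k_max, length(chain)))) {
      r <- cv_rmse_ols(X[, chain[seq_len(k)], drop = FALSE], yv, fold_id)
      if (is.na(r)) next                       # rank-deficient candidate
      if (r < curve[k]) curve[k] <- r
      if (r < best$rmse) best <- list(rmse = r, start = start_set[ci], k = k)
    }
  }
  if (!is.finite(best$rmse))
    stop("SPA found no full-rank candidate subset")
  # parsimony tie-break: smallest k whose RMSE is numerically
  # indistinguishable from the global minimum
  m <- min(curve)
  chosen_k <- which(curve <= m + 1e-10 + 1e-8 * abs(m))[1]
  best_start <- best$start
  if (chosen_k < best$k) {
    # re-identify the start achieving the minimum at the smaller k
    for (ci in seq_along(chains)) {
      chain <- chains[[ci]]
      if (length(chain) >= chosen_k) {
        r <- cv_rmse_ols(X[, chain[seq_len(chosen_k)], drop = FALSE], yv,
                         fold_id)
        if (!is.na(r) && r <= curve[chosen_k] + 1e-12) {
          best_start <- start_set[ci]
          break
        }
      }
    }
  }
  sel <- chains[[match(best_start, start_set)]][seq_len(chosen_k)]
  structure(list(selected_indices = sel, rmse_curve = curve,
                 chosen_k = chosen_k, start = best_start,
                 k_max = k_max),
            class = "spa_result")
}

# Grow one SPA chain from starting band s: at each step pick the band with
# maximal residual column norm after projecting out the selected columns.
spa_chain <- function(X, s, k_max) {
  p <- ncol(X)
  chain <- integer(k_max)
  chain[1L] <- s
  R <- X
  for (k in seq_len(k_max - 1L)) {
    u <- R[, chain[k]]
    nu <- sum(u^2)
    if (nu < 1e-12) return(chain[seq_len(k)])   # degenerate: stop early
    R <- R - u %*% crossprod(u, R) / nu
    norms <- colSums(R^2)
    norms[chain[seq_len(k)]] <- -Inf
    nxt <- which.max(norms)
    if (norms[nxt] < 1e-12) return(chain[seq_len(k)])  # all collinear
    chain[k + 1L] <- nxt
  }
  chain
}

# k-fold CV RMSE of OLS with intercept; NA if any fold is rank-deficient.
cv_rmse_ols <- function(Xs, y, fold_id) {
  err2 <- 0
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    A <- cbind(1, Xs[tr, , drop = FALSE])
    fit <- tryCatch(stats::lm.fit(A, y[tr]), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) {
      warning("rank-deficient SPA candidate skipped", call. = FALSE)
      return(NA_real_)
    }
    pred <- cbind(1, Xs[!tr, , drop = FALSE]) %*% fit$coefficients
    err2 <- err2 + sum((y[!tr] - pred)^2)
  }
  sqrt(err2 / length(y))
}

#' @export
print.spa_result <- function(x, ...) {
  cat(sprintf("SPA selection: %d band(s) (start %d, RMSE %.4f at k = %d)\n",
              length(x$selected_indices), x$start,
              min(x$rmse_curve), x$chosen_k))
  cat("  indices:", paste(x$selected_indices, collapse = ", "), "\n")
  invisible(x)
}

#' Plot the SPA RMSE curve
#'
#' @param x a `spa_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spa_result <- function(x, ...) {
  ok <- is.finite(x$rmse_curve)
  graphics::plot(seq_along(x$rmse_curve)[ok], x$rmse_curve[ok], type = "b",
                 xlab = "number of selected bands", ylab = "CV RMSE",
                 main = "SPA selection", ...)
  graphics::abline(v = x$chosen_k, lty = 2)
  invisible(x)
}
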