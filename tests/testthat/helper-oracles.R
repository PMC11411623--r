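# Independent brute-force oracles used to verify the package's
# implementations. These deliberately avoid the package's code paths.

# Exhaustive Otsu: scan all 256 histogram thresholds, maximize
# between-class variance, return the threshold value.
oracle_otsu <- function(img, levels = 256L) {
  rng <- range(img)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- hist(img, breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  total <- sum(h)
  best_var <- -Inf
  best_t <- mids[1]
  for (t in seq_len(levels - 1L)) {
    w0 <- sum(h[1:t]); w1 <- total - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:t] * mids[1:t]) / w0
    mu1 <- sum(h[(t + 1):levels] * mids[(t + 1):levels]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_var) {
      best_var <- v
      best_t <- breaks[t + 1L]
    }
  }
  best_t
}

# Double-loop GLCM with symmetrization, on an already-quantized matrix.
oracle_glcm <- function(q, levels, distance, direction) {
  off <- switch(as.character(direction),
                "0" = c(0, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0), "135" = c(-distance, -distance))
  P <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) {
    for (c in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        P[q[r, c], q[r2, c2]] <- P[q[r, c], q[r2, c2]] + 1
        P[q[r2, c2], q[r, c]] <- P[q[r2, c2], q[r, c]] + 1
      }
    }
  }
  P / sum(P)
}

# Double-loop texture statistics of a normalized GLCM.
oracle_glcm_stats <- function(P) {
  n <- nrow(P)
  contrast <- energy <- entropy <- homog <- 0
  for (i in 0:(n - 1)) {
    for (j in 0:(n - 1)) {
      p <- P[i + 1, j + 1]
      contrast <- contrast + p * (i - j)^2
      energy <- energy + p^2
      if (p > 0) entropy <- entropy - p * log(p)
      homog <- homog + p / (1 + (i - j)^2)
    }
  }
  c(contrast = contrast, energy = energy, entropy = entropy,
    homogeneity = homog)
}

# Straight-line hand-stepped trace of the classic optimizer: a literal
# transcription of the published iteration scheme consuming R's random
# stream in the documented order. Independent of the package's loop.
oracle_bwo_trace <- function(objective, lower, upper, n, Tmax, seed) {
  set.seed(seed)
  d <- length(lower)
  X <- matrix(runif(n * d), n, d)
  X <- sweep(sweep(X, 2, upper - lower, `*`), 2, lower, `+`)
  fit <- apply(X, 1, objective)
  best_f <- min(fit)
  best_x <- X[which.min(fit), ]
  curve <- numeric(Tmax)
  sg <- (gamma(2.5) * sin(0.75 * pi) / (gamma(1.25) * 1.5 * 2^0.25))^(1 / 1.5)
  for (T in seq_len(Tmax)) {
    Wf <- 0.1 - 0.05 * T / Tmax
    Bf <- runif(n) * (1 - T / (2 * Tmax))
    for (i in seq_len(n)) {
      others <- seq_len(n)[-i]
      if (Bf[i] > 0.5) {
        xr <- X[others[sample.int(n - 1, 1)], ]
        perm <- sample.int(d)
        r1 <- runif(d)
        r2 <- runif(d)
        xnew <- numeric(d)
        for (j in seq_len(d)) {
          trig <- if (j %% 2 == 0) sin(2 * pi * r2[j]) else
            cos(2 * pi * r2[j])
          xnew[j] <- X[i, perm[j]] +
            (xr[perm[1]] - X[i, perm[j]]) * (1 + r1[j]) * trig
        }
      } else {
        xr <- X[others[sample.int(n - 1, 1)], ]
        r3 <- runif(1); r4 <- runif(1)
        mu <- rnorm(1); nu <- rnorm(1)
        lf <- 0.05 * mu * sg / abs(nu)^(1 / 1.5)
        C1 <- 2 * r4 * (1 - T / Tmax)
        xnew <- r3 * best_x - r4 * X[i, ] + C1 * lf * (xr - X[i, ])
      }
      xnew <- pmin(pmax(xnew, lower), upper)
      fnew <- objective(xnew)
      if (fnew < fit[i]) {
        X[i, ] <- xnew
        fit[i] <- fnew
      }
    }
    for (i in seq_len(n)) {
      if (Bf[i] <= Wf) {
        others <- seq_len(n)[-i]
        xr <- X[others[sample.int(n - 1, 1)], ]
        r5 <- runif(1); r6 <- runif(1); r7 <- runif(1)
        xstep <- (upper - lower) * exp(-2 * Wf * n * T / Tmax)
        xnew <- pmin(pmax(r5 * X[i, ] - r6 * xr + r7 * xstep, lower), upper)
        fnew <- objective(xnew)
        if (fnew < fit[i]) {
          X[i, ] <- xnew
          fit[i] <- fnew
        }
      }
    }
    ib <- which.min(fit)
    if (fit[ib] < best_f) {
      best_f <- fit[ib]
      best_x <- X[ib, ]
    }
    curve[T] <- best_f
  }
  list(best_position = best_x, best_fitness = best_f, convergence = curve)
}

# Small fast scene for unit tests: few samples, coarse wavelength grid.
tiny_scene <- function(n_per_class = 6L, ...) {
  scene_spec(n_per_class = n_per_class, bands = 24L,
             wl_step = (1720 - 935) / 24, ...)
}
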