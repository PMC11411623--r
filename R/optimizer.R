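#' Box-constrained search space
#'
#' Defines the feasible region for the beluga whale optimizers: a
#' d-dimensional box with finite bounds. Every position emitted by every
#' move operator is clamped back into this box.
#'
#' @param lower,upper numeric vectors of equal length with
#'   `lower[j] < upper[j]` for all j.
#' @return an object of class `search_space` with elements `lower`, `upper`
#'   and `dim`.
#' @examples
#' search_space(c(-5, -5), c(5, 5))
#' @export
search_space <- function(lower, upper) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper))
    stop("'lower' and 'upper' must have the same length")
  if (length(lower) < 1L)
    stop("search space must have dimension >= 1")
  if (!all(is.finite(lower)) || !all(is.finite(upper)))
    stop("bounds must be finite")
  if (!all(lower < upper))
    stop("'lower' must be strictly below 'upper' in every dimension")
  structure(list(lower = lower, upper = upper, dim = length(lower)),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("Search space: %d dimension(s)\n", x$dim))
  for (j in seq_len(x$dim))
    cat(sprintf("  [%g, %g]\n", x$lower[j], x$upper[j]))
  invisible(x)
}

#' Good point set initialization
#'
#' Deterministic low-discrepancy point set on a box. For dimension s the
#' generator uses the smallest prime p with (p - 3)/2 >= s and the good
#' point r_k = frac(2 cos(2 pi k / p)), k = 1..s; point i has unit-cube
#' coordinate frac(r_k * i), mapped affinely onto the bounds. Compared with
#' uniform random seeding the points cover the box more evenly, which is
#' why the improved optimizer initializes its population this way.
#'
#' @param space a [search_space()].
#' @param n number of points (>= 1).
#' @return an `n x dim` matrix of in-bounds positions.
#' @examples
#' good_point_set(search_space(c(0, 0), c(1, 1)), 5)
#' @export
good_point_set <- function(space, n) {
  stopifnot(inherits(space, "search_space"), n >= 1)
  s <- space$dim
  p <- good_point_prime(s)
  r <- (2 * cos(2 * pi * seq_len(s) / p)) %% 1
  u <- outer(seq_len(n), r) %% 1        # frac(r_k * i)
  sweep(sweep(u, 2, space$upper - space$lower, `*`), 2, space$lower, `+`)
}

#' Smallest prime p with (p - 3)/2 >= s
#' @param s dimension.
#' @return a prime number.
#' @keywords internal
good_point_prime <- function(s) {
  p <- max(2L * as.integer(s) + 3L, 5L)
  repeat {
    if (is_prime(p)) return(p)
    p <- p + 2L
  }
}

is_prime <- function(p) {
  if (p < 2L) return(FALSE)
  if (p %in% c(2L, 3L)) return(TRUE)
  if (p %% 2L == 0L) return(FALSE)
  k <- 3L
  while (k * k <= p) {
    if (p %% k == 0L) return(FALSE)
    k <- k + 2L
  }
  TRUE
}

#' Balance factor schedule
#'
#' Per-whale schedule deciding exploration versus exploitation:
#' `Bf = B0 * (1 - T / (2 * Tmax))` with `B0 ~ U(0, 1)` redrawn per whale
#' per iteration. Whales with `Bf > 0.5` explore (paired swimming); the
#' rest exploit (prey capture). The factor decays from `B0` at T = 0 to
#' `B0 / 2` at T = Tmax, shifting the population towards exploitation.
#'
#' @param B0 per-whale uniform(0, 1) draw(s).
#' @param T current iteration (0 <= T <= Tmax).
#' @param Tmax maximum iteration count (> 0).
#' @return numeric balance factor(s).
#' @examples
#' balance_factor(0.8, 10, 10)  # 0.4
#' @export
balance_factor <- function(B0, T, Tmax) {
  if (Tmax <= 0) stop("'Tmax' must be positive")
  if (T < 0 || T > Tmax) stop("'T' must lie in [0, Tmax]")
  B0 * (1 - T / (2 * Tmax))
}

#' Whale fall probability schedule
#'
#' Probability that a whale is replaced through the whale-fall respawn
#' step: `Wf = 0.1 - 0.05 * T / Tmax`, decaying linearly from 0.1 to 0.05
#' over the run.
#'
#' @inheritParams balance_factor
#' @return a value in `[0.05, 0.1]`.
#' @export
whale_fall_probability <- function(T, Tmax) {
  if (Tmax <= 0) stop("'Tmax' must be positive")
  if (T < 0 || T > Tmax) stop("'T' must lie in [0, Tmax]")
  0.1 - 0.05 * T / Tmax
}

#' Levy flight scale constant
#'
#' Closed-form Mantegna scale
#' `sigma_mu = (Gamma(1+b) sin(pi b / 2) / (Gamma((1+b)/2) b 2^((b-1)/2)))^(1/b)`
#' for Levy exponent `b`.
#'
#' @param beta Levy exponent in (1, 3].
#' @return the scale sigma_mu.
#' @examples
#' levy_sigma(1.5)  # ~0.6966
#' @export
levy_sigma <- function(beta) {
  if (beta <= 1 || beta > 3) stop("'beta' must lie in (1, 3]")
  base <- gamma(1 + beta) * sin(pi * beta / 2) /
    (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2))
  # real signed root: keeps the scale defined where sin(pi*beta/2) <= 0
  sign(base) * abs(base)^(1 / beta)
}

#' Levy flight step
#'
#' Heavy-tailed random step `LF = 0.05 * mu * sigma_mu / |nu|^(1/beta)`
#' with `mu, nu ~ N(0, 1)`. Symmetric about zero with tails much heavier
#' than Gaussian; the 0.05 prefactor keeps typical steps small relative to
#' the search box.
#'
#' @param beta Levy exponent in (1, 3].
#' @param size number of draws.
#' @param mu,nu optional standard normal draws (supplied by the optimizer
#'   loop so the random stream is documented; defaults draw fresh values).
#' @return numeric vector of `size` Levy steps.
#' @export
levy_flight <- function(beta = 1.5, size = 1L,
                        mu = stats::rnorm(size), nu = stats::rnorm(size)) {
  0.05 * mu * levy_sigma(beta) / abs(nu)^(1 / beta)
}

#' Exploration move (paired swimming)
#'
#' Position update for whales in the exploration phase. Dimensions are
#' visited through a random permutation `perm`; the j-th new coordinate
#' starts from the whale's own coordinate in dimension `perm[j]` and moves
#' towards a partner whale's coordinate in dimension `perm[1]`, modulated
#' by `(1 + r1) sin(2 pi r2)` for even j and the cosine form for odd j
#' (mirrored versus synchronized fin orientation). The result is clamped
#' to the bounds.
#'
#' @param xi current position (d-vector).
#' @param xr partner whale position (must come from a population of >= 2).
#' @param space a [search_space()].
#' @param perm a permutation of `1:d`.
#' @param r1,r2 uniform(0, 1) draws, one per dimension.
#' @return the clamped new position.
#' @export
exploration_move <- function(xi, xr, space,
                             perm = sample.int(space$dim),
                             r1 = stats::runif(space$dim),
                             r2 = stats::runif(space$dim)) {
  d <- space$dim
  xnew <- numeric(d)
  for (j in seq_len(d)) {
    base <- xi[perm[j]]
    pull <- xr[perm[1]] - xi[perm[j]]
    trig <- if (j %% 2 == 0) sin(2 * pi * r2[j]) else cos(2 * pi * r2[j])
    xnew[j] <- base + pull * (1 + r1[j]) * trig
  }
  clamp(xnew, space$lower, space$upper)
}

#' Classic exploitation move (Levy-assisted predation)
#'
#' `X' = r3 * X_best - r4 * X_i + C1 * LF * (X_r - X_i)` with jump
#' strength `C1 = 2 * r4 * (1 - T / Tmax)` and `LF` a [levy_flight()]
#' step. At T = Tmax the Levy term vanishes. Clamped to bounds.
#'
#' @param xi current position.
#' @param xbest best position found so far (guide).
#' @param xr partner whale position.
#' @param space a [search_space()].
#' @param T,Tmax iteration schedule.
#' @param r3,r4 uniform(0, 1) draws.
#' @param lf Levy flight step (scalar).
#' @return the clamped new position.
#' @export
exploitation_move_classic <- function(xi, xbest, xr, space, T, Tmax,
                                      r3 = stats::runif(1),
                                      r4 = stats::runif(1),
                                      lf = levy_flight()) {
  C1 <- 2 * r4 * (1 - T / Tmax)
  xnew <- r3 * xbest - r4 * xi + C1 * lf * (xr - xi)
  clamp(xnew, space$lower, space$upper)
}

#' Adaptive Levy flight move
#'
#' Exploitation step of the improved optimizer:
#' `x' = x + alpha(t) * mu * sigma_mu / |nu|^(1/beta)` with the scale
#' `alpha(t) = alpha0 * (1 - t/T)^gamma` decaying from `alpha0` to zero so
#' that early iterations take large exploratory Levy steps and late
#' iterations refine locally. Per-dimension draws; clamped to bounds.
#'
#' @param xi current position.
#' @param space a [search_space()].
#' @param T,Tmax iteration schedule.
#' @param alpha0 initial step scale per dimension; default
#'   `0.1 * (upper - lower)` (scale-free in the box width).
#' @param gamma decay exponent, 1 or 2.
#' @param beta Levy exponent.
#' @param mu,nu standard normal draws, one per dimension.
#' @return the clamped new position.
#' @export
adaptive_levy_move <- function(xi, space, T, Tmax, alpha0 = NULL, gamma = 2,
                               beta = 1.5,
                               mu = stats::rnorm(space$dim),
                               nu = stats::rnorm(space$dim)) {
  if (!gamma %in% c(1, 2)) stop("'gamma' must be 1 or 2")
  if (is.null(alpha0)) alpha0 <- 0.1 * (space$upper - space$lower)
  alpha_t <- alpha0 * (1 - T / Tmax)^gamma
  step <- alpha_t * mu * levy_sigma(beta) / abs(nu)^(1 / beta)
  clamp(xi + step, space$lower, space$upper)
}

#' Spiral search move
#'
#' Whale-optimization style contraction towards the guide:
#' `D = |C * X_guide - X|`, `X' = X_guide - A * D`, with coefficient
#' vectors `A = 2 a(t) r - a(t)` and `C = 2 r'`, where `a(t)` decreases
#' linearly from 2 to 0 over the run. Late in the run `|A|` shrinks to 0
#' and the move collapses onto the guide. Clamped to bounds.
#'
#' @param xi current position.
#' @param xbest guide position (best solution or elite-pool member).
#' @param space a [search_space()].
#' @param T,Tmax iteration schedule.
#' @param r,rc uniform(0, 1) draw vectors of length d for A and C.
#' @return the clamped new position.
#' @export
spiral_move <- function(xi, xbest, space, T, Tmax,
                        r = stats::runif(space$dim),
                        rc = stats::runif(space$dim)) {
  a <- 2 * (1 - T / Tmax)
  A <- 2 * a * r - a
  C <- 2 * rc
  D <- abs(C * xbest - xi)
  clamp(xbest - A * D, space$lower, space$upper)
}

#' Elite pool
#'
#' Candidate guides for the improved optimizer: the three best positions
#' in the population plus their arithmetic mean. With fewer than three
#' whales the pool degrades gracefully to the available members (plus
#' their mean).
#'
#' @param positions n x d matrix of positions.
#' @param fitness length-n fitness vector.
#' @return a matrix whose rows are the pool members (at most 4).
#' @export
elite_pool <- function(positions, fitness) {
  n <- nrow(positions)
  k <- min(3L, n)
  ord <- order(fitness)[seq_len(k)]
  top <- positions[ord, , drop = FALSE]
  rbind(top, colMeans(top))
}

#' Draw a guide from the elite pool
#'
#' Selects one pool member uniformly at random; replacing the single best
#' solution with this randomized guide helps the population escape local
#' optima.
#'
#' @param pool matrix returned by [elite_pool()].
#' @param idx optional row index (supplied by the optimizer loop).
#' @return a guide position (d-vector).
#' @export
elite_pool_guide <- function(pool, idx = sample.int(nrow(pool), 1L)) {
  pool[idx, ]
}

#' Whale fall move
#'
#' Respawn step for whales drawn into the whale-fall phase:
#' `X' = r5 * X_i - r6 * X_r + r7 * X_step` with step length
#' `X_step = (ub - lb) * exp(-C2 * T / Tmax)` and step factor
#' `C2 = 2 * Wf * N`. The step length decays from the full box width to
#' `(ub - lb) * exp(-2 Wf N)` at the final iteration. Clamped to bounds.
#'
#' @param xi current position.
#' @param xr partner whale position.
#' @param space a [search_space()].
#' @param T,Tmax iteration schedule.
#' @param n population size N.
#' @param r5,r6,r7 uniform(0, 1) draws.
#' @return the clamped new position.
#' @export
whale_fall_move <- function(xi, xr, space, T, Tmax, n,
                            r5 = stats::runif(1), r6 = stats::runif(1),
                            r7 = stats::runif(1)) {
  Wf <- whale_fall_probability(T, Tmax)
  C2 <- 2 * Wf * n
  xstep <- (space$upper - space$lower) * exp(-C2 * T / Tmax)
  clamp(r5 * xi - r6 * xr + r7 * xstep, space$lower, space$upper)
}

#' Golden-sine position update step
#'
#' One golden-sine proposal for a single whale:
#' `V' = V * |sin r1| - r2 * sin(r1) * |x1 * D - x2 * V|` with
#' `r1 ~ U[0, 2 pi]`, `r2 ~ U[0, pi]`, `D` the target (best) position and
#' `x1`, `x2` golden-section coefficients. The sine modulation lets the
#' update traverse the unit circle while contracting towards the target.
#'
#' @param v current position (d-vector).
#' @param d_target target position (d-vector).
#' @param x1,x2 golden-section coefficients.
#' @param r1 draw in `[0, 2 pi]`.
#' @param r2 draw in `[0, pi]`.
#' @return the proposed position (unclamped; callers clamp).
#' @export
golden_sine_step <- function(v, d_target, x1, x2,
                             r1 = stats::runif(1, 0, 2 * pi),
                             r2 = stats::runif(1, 0, pi)) {
  v * abs(sin(r1)) - r2 * sin(r1) * abs(x1 * d_target - x2 * v)
}

golden_tau <- (sqrt(5) - 1) / 2

# Initial golden-section coefficients on [-pi, pi].
golden_init <- function() {
  a <- -pi; b <- pi
  list(a = a, b = b,
       x1 = a + (1 - golden_tau) * (b - a),
       x2 = a + golden_tau * (b - a))
}

# Standard golden-section interval shrink, applied when the golden-sine
# stage improves the global best; the interval is reset once it collapses.
golden_shrink <- function(g) {
  g$b <- g$x2
  g$x2 <- g$x1
  g$x1 <- g$a + (1 - golden_tau) * (g$b - g$a)
  if (g$b - g$a < 1e-8) g <- golden_init()
  g
}

#' Control parameters for the multi-strategy improved optimizer
#'
#' @param beta Levy exponent (default 1.5).
#' @param alpha0 initial adaptive-Levy scale; default
#'   `0.1 * (upper - lower)` per dimension.
#' @param gamma adaptive-Levy decay exponent, 1 or 2 (default 2).
#' @param fusion_prob probability of taking the adaptive-Levy branch in the
#'   exploitation fusion (otherwise the spiral branch); default 0.5.
#' @param exploit `"moves"` (default): the fused exploitation step is one of
#'   the two full moves; `"skeleton"`: the classic exploitation skeleton is
#'   retained and only its Levy term is replaced by the adaptive step (the
#'   spiral branch is a full move in either mode); `"classic"`: the
#'   unmodified Levy exploitation of [bwo()].
#' @param golden_scope `"population"` (default): in iterations where at
#'   least one whale fell, the golden-sine update is applied to the whole
#'   population; `"fallen"`: only to the whales that fell.
#' @param use_good_point,use_elite_pool,use_golden strategy switches
#'   (default TRUE). With all three FALSE and `exploit = "classic"` the
#'   improved optimizer degenerates exactly to [bwo()], draw for draw.
#' @return a list of class `msbwo_control`.
#' @export
msbwo_control <- function(beta = 1.5, alpha0 = NULL, gamma = 2,
                          fusion_prob = 0.5,
                          exploit = c("moves", "skeleton", "classic"),
                          golden_scope = c("population", "fallen"),
                          use_good_point = TRUE, use_elite_pool = TRUE,
                          use_golden = TRUE) {
  if (beta <= 1 || beta > 3) stop("'beta' must lie in (1, 3]")
  if (!gamma %in% c(1, 2)) stop("'gamma' must be 1 or 2")
  if (fusion_prob < 0 || fusion_prob > 1) stop("'fusion_prob' must be in [0, 1]")
  structure(list(beta = beta, alpha0 = alpha0, gamma = gamma,
                 fusion_prob = fusion_prob,
                 exploit = match.arg(exploit),
                 golden_scope = match.arg(golden_scope),
                 use_good_point = isTRUE(use_good_point),
                 use_elite_pool = isTRUE(use_elite_pool),
                 use_golden = isTRUE(use_golden)),
            class = "msbwo_control")
}

# Evaluate the objective and insist on a finite value.
eval_objective <- function(objective, x, context = "") {
  f <- objective(x)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f))
    stop(sprintf("objective returned a non-finite value%s at position (%s)",
                 context, paste(signif(x, 6), collapse = ", ")),
         call. = FALSE)
  f
}

#' Initialize a random population
#'
#' Positions i.i.d. uniform within the bounds, with fitness evaluated and
#' the incumbent best tracked.
#'
#' @param objective function mapping a d-vector to a finite scalar
#'   (minimized).
#' @param space a [search_space()].
#' @param n population size (>= 2).
#' @param seed optional integer seed.
#' @return a list with `positions`, `fitness`, `best_position`,
#'   `best_fitness`.
#' @export
init_random <- function(objective, space, n, seed = NULL) {
  if (n < 2) stop("population size must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  d <- space$dim
  positions <- matrix(stats::runif(n * d), n, d)
  positions <- sweep(sweep(positions, 2, space$upper - space$lower, `*`),
                     2, space$lower, `+`)
  finalize_population(objective, positions)
}

finalize_population <- function(objective, positions) {
  fitness <- apply(positions, 1L, function(x)
    eval_objective(objective, x, " during initialization"))
  ib <- which.min(fitness)
  list(positions = positions, fitness = fitness,
       best_position = positions[ib, ], best_fitness = fitness[ib])
}

#' Classic beluga whale optimization
#'
#' Population metaheuristic minimizing `objective` over a box. Each
#' iteration: (i) whales with balance factor above 0.5 take the
#' exploration move, the rest the Levy-assisted exploitation move;
#' (ii) whales whose balance factor falls below the whale-fall probability
#' are respawned through the whale-fall move. Every proposal is clamped to
#' the bounds, evaluated, and accepted greedily (kept only if it improves
#' that whale's fitness), which makes the convergence curve non-increasing.
#'
#' Random draws are consumed from R's generator in a fixed documented
#' order per iteration: first `B0` for all whales (`runif(n)`); then per
#' whale in index order, for exploration the partner index
#' (`sample.int(n - 1, 1)`), the dimension permutation (`sample.int(d)`),
#' the vector `r1` (`runif(d)`) and the vector `r2` (`runif(d)`); for
#' exploitation the partner index, `r3`, `r4`, and the two normals of the
#' Levy step; then per fallen whale the partner index and `r5`, `r6`,
#' `r7`.
#'
#' @param objective function mapping a d-vector to a finite scalar;
#'   minimized (wrap maximization targets with negation).
#' @param space a [search_space()].
#' @param n population size (>= 2); default 50.
#' @param Tmax number of iterations (>= 1); default 100.
#' @param seed optional integer seed for reproducible runs.
#' @return an object of class `bwo_result`: list with `best_position`,
#'   `best_fitness`, `convergence` (best fitness after each iteration,
#'   length `Tmax`, non-increasing), `evaluations`, `seed`, `algorithm`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- bwo(sphere, search_space(c(-5, -5), c(5, 5)), n = 20, Tmax = 50,
#'            seed = 1)
#' res$best_fitness
#' @seealso [msbwo()] for the multi-strategy improved variant.
#' @export
bwo <- function(objective, space, n = 50, Tmax = 100, seed = NULL) {
  if (Tmax < 1) stop("'Tmax' must be at least 1")
  pop <- init_random(objective, space, n, seed)
  run_bwo_loop(objective, space, pop, n, Tmax, seed, improved = FALSE,
               control = NULL)
}

#' Multi-strategy improved beluga whale optimization
#'
#' Variant of [bwo()] with four modifications: (1) the population is
#' initialized from the deterministic [good_point_set()] rather than
#' uniform draws; (2) an elite pool (top three solutions plus their mean)
#' is refreshed each iteration and a random pool member replaces the
#' single best solution as the guide; (3) the exploitation step is a
#' fusion of the adaptive Levy move and the spiral move, chosen by a
#' Bernoulli draw with probability `fusion_prob`; (4) after the whale-fall
#' stage the population is updated by the golden-sine rule with
#' golden-section coefficients that shrink when the global best improves.
#' Greedy acceptance throughout, so the convergence curve is
#' non-increasing.
#'
#' @inheritParams bwo
#' @param control an [msbwo_control()] list of strategy constants.
#' @return an object of class `bwo_result` (see [bwo()]).
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- msbwo(sphere, search_space(c(-5, -5), c(5, 5)), n = 20,
#'              Tmax = 50, seed = 1)
#' res$best_fitness
#' @export
msbwo <- function(objective, space, n = 50, Tmax = 100, seed = NULL,
                  control = msbwo_control()) {
  if (Tmax < 1) stop("'Tmax' must be at least 1")
  if (n < 2) stop("population size must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  pop <- if (control$use_good_point) {
    finalize_population(objective, good_point_set(space, n))
  } else {
    d <- space$dim
    u <- matrix(stats::runif(n * d), n, d)
    finalize_population(objective,
                        sweep(sweep(u, 2, space$upper - space$lower, `*`),
                              2, space$lower, `+`))
  }
  run_bwo_loop(objective, space, pop, n, Tmax, seed, improved = TRUE,
               control = control)
}

# Shared iteration loop for bwo() and msbwo(). `improved` toggles the
# elite pool, exploitation fusion and golden-sine stages.
run_bwo_loop <- function(objective, space, pop, n, Tmax, seed, improved,
                         control) {
  d <- space$dim
  X <- pop$positions
  fit <- pop$fitness
  best_x <- pop$best_position
  best_f <- pop$best_fitness
  evals <- n
  curve <- numeric(Tmax)
  if (improved) {
    pool <- elite_pool(X, fit)
    gold <- golden_init()
    alpha0 <- control$alpha0 %||% (0.1 * (space$upper - space$lower))
  }

  pick_partner <- function(i) {
    others <- seq_len(n)[-i]
    others[sample.int(n - 1L, 1L)]
  }

  for (T in seq_len(Tmax)) {
    Wf <- whale_fall_probability(T, Tmax)
    Bf <- balance_factor(stats::runif(n), T, Tmax)

    for (i in seq_len(n)) {
      # draws are hoisted into locals so the stream order is exactly the
      # documented one (promises would otherwise evaluate in use order)
      if (Bf[i] > 0.5) {
        xr <- X[pick_partner(i), ]
        perm <- sample.int(d)
        r1 <- stats::runif(d)
        r2 <- stats::runif(d)
        xnew <- exploration_move(X[i, ], xr, space, perm = perm,
                                 r1 = r1, r2 = r2)
      } else if (!improved) {
        xr <- X[pick_partner(i), ]
        r3 <- stats::runif(1); r4 <- stats::runif(1)
        lf <- levy_flight(1.5, 1L, stats::rnorm(1), stats::rnorm(1))
        xnew <- exploitation_move_classic(X[i, ], best_x, xr, space, T,
                                          Tmax, r3 = r3, r4 = r4, lf = lf)
      } else if (control$exploit == "classic") {
        guide <- if (control$use_elite_pool) elite_pool_guide(pool) else best_x
        xr <- X[pick_partner(i), ]
        r3 <- stats::runif(1); r4 <- stats::runif(1)
        lf <- levy_flight(control$beta, 1L, stats::rnorm(1),
                          stats::rnorm(1))
        xnew <- exploitation_move_classic(X[i, ], guide, xr, space, T,
                                          Tmax, r3 = r3, r4 = r4, lf = lf)
      } else {
        guide <- if (control$use_elite_pool) elite_pool_guide(pool) else best_x
        take_levy <- stats::runif(1) < control$fusion_prob
        if (control$exploit == "moves") {
          if (take_levy) {
            mu <- stats::rnorm(d); nu <- stats::rnorm(d)
            xnew <- adaptive_levy_move(X[i, ], space, T, Tmax, alpha0,
                                       control$gamma, control$beta,
                                       mu = mu, nu = nu)
          } else {
            rs <- stats::runif(d); rc <- stats::runif(d)
            xnew <- spiral_move(X[i, ], guide, space, T, Tmax, r = rs,
                                rc = rc)
          }
        } else {
          if (take_levy) {
            xr <- X[pick_partner(i), ]
            r3 <- stats::runif(1); r4 <- stats::runif(1)
            mu <- stats::rnorm(d); nu <- stats::rnorm(d)
            C1 <- 2 * r4 * (1 - T / Tmax)
            alpha_t <- alpha0 * (1 - T / Tmax)^control$gamma
            step <- alpha_t * mu * levy_sigma(control$beta) /
              abs(nu)^(1 / control$beta)
            xnew <- clamp(r3 * guide - r4 * X[i, ] + C1 * step * (xr - X[i, ]),
                          space$lower, space$upper)
          } else {
            rs <- stats::runif(d); rc <- stats::runif(d)
            xnew <- spiral_move(X[i, ], guide, space, T, Tmax, r = rs,
                                rc = rc)
          }
        }
      }
      fnew <- eval_objective(objective, xnew,
                             sprintf(" at iteration %d (whale %d)", T, i))
      evals <- evals + 1L
      if (fnew < fit[i]) {          # greedy position validation
        X[i, ] <- xnew
        fit[i] <- fnew
      }
    }

    fell <- which(Bf <= Wf)
    for (i in fell) {
      xr <- X[pick_partner(i), ]
      r5 <- stats::runif(1); r6 <- stats::runif(1); r7 <- stats::runif(1)
      xnew <- whale_fall_move(X[i, ], xr, space, T, Tmax, n,
                              r5 = r5, r6 = r6, r7 = r7)
      fnew <- eval_objective(objective, xnew,
                             sprintf(" at iteration %d (whale fall %d)", T, i))
      evals <- evals + 1L
      if (fnew < fit[i]) {
        X[i, ] <- xnew
        fit[i] <- fnew
      }
    }

    ib <- which.min(fit)
    if (fit[ib] < best_f) {
      best_f <- fit[ib]
      best_x <- X[ib, ]
    }

    if (improved && control$use_golden) {
      scope <- if (control$golden_scope == "population") {
        if (length(fell)) seq_len(n) else integer(0)
      } else fell
      improved_best <- FALSE
      for (i in scope) {
        r1 <- stats::runif(1, 0, 2 * pi)
        r2 <- stats::runif(1, 0, pi)
        xnew <- clamp(golden_sine_step(X[i, ], best_x, gold$x1, gold$x2,
                                       r1, r2),
                      space$lower, space$upper)
        fnew <- eval_objective(objective, xnew,
                               sprintf(" at iteration %d (golden sine %d)",
                                       T, i))
        evals <- evals + 1L
        if (fnew < fit[i]) {
          X[i, ] <- xnew
          fit[i] <- fnew
          if (fnew < best_f) {
            best_f <- fnew
            best_x <- xnew
            improved_best <- TRUE
          }
        }
      }
      if (improved_best) gold <- golden_shrink(gold)
    }
    if (improved && control$use_elite_pool) pool <- elite_pool(X, fit)

    curve[T] <- best_f
  }

  structure(list(best_position = best_x, best_fitness = best_f,
                 convergence = curve, evaluations = evals,
                 seed = seed,
                 algorithm = if (improved) "msbwo" else "bwo",
                 population = list(positions = X, fitness = fit)),
            class = "bwo_result")
}

#' @export
print.bwo_result <- function(x, ...) {
  cat(sprintf("%s run: %d iterations, %d objective evaluations\n",
              toupper(x$algorithm), length(x$convergence), x$evaluations))
  cat(sprintf("  best fitness: %.6g\n", x$best_fitness))
  cat("  best position:", paste(signif(x$best_position, 6), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
coef.bwo_result <- function(object, ...) object$best_position

#' Plot the convergence curve of an optimizer run
#'
#' @param x a `bwo_result`.
#' @param log use a log10 fitness axis where all values are positive
#'   (default TRUE).
#' @param ... passed to [graphics::plot()].
#' @export
plot.bwo_result <- function(x, log = TRUE, ...) {
  y <- x$convergence
  use_log <- log && all(y > 0)
  graphics::plot(seq_along(y), y, type = "l",
                 log = if (use_log) "y" else "",
                 xlab = "iteration", ylab = "best fitness",
                 main = sprintf("%s convergence", toupper(x$algorithm)), ...)
  invisible(x)
}

#' Export an optimizer result
#'
#' Writes the result as JSON (best position, fitness, convergence curve,
#' seed) and optionally the convergence curve as CSV.
#'
#' @param result a `bwo_result`.
#' @param json_path path for the JSON export (NULL to skip).
#' @param csv_path path for the convergence CSV (NULL to skip).
#' @return `result`, invisibly.
#' @export
write_bwo_result <- function(result, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(result, "bwo_result"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(algorithm = result$algorithm,
           best_position = result$best_position,
           best_fitness = result$best_fitness,
           convergence = result$convergence,
           evaluations = result$evaluations,
           seed = result$seed),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(
      data.frame(iteration = seq_along(result$convergence),
                 best_fitness = result$convergence),
      csv_path, row.names = FALSE)
  }
  invisible(result)
}
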