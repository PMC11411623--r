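test_that("schedules hit their endpoints and stay in range", {
  expect_equal(balance_factor(1, 0, 100), 1.0)
  expect_equal(balance_factor(0.8, 100, 100), 0.4)
  expect_equal(balance_factor(0.5, 50, 100), 0.375)
  expect_error(balance_factor(0.5, 1, 0))
  expect_equal(whale_fall_probability(0, 100), 0.1)
  expect_equal(whale_fall_probability(100, 100), 0.05)
  expect_equal(whale_fall_probability(50, 100), 0.075)
  for (T in seq(0, 200, by = 10)) {
    wf <- whale_fall_probability(T, 200)
    expect_true(wf >= 0.05 && wf <= 0.1)
  }
})

test_that("good point set uses the right primes and stays in bounds", {
  # independent prime scan: smallest prime p with (p - 3) / 2 >= s
  scan_prime <- function(s) {
    is_p <- function(x) x > 1 && all(x %% seq(2, max(2, floor(sqrt(x)))) != 0)
    p <- 2
    repeat {
      if (is_p(p) && (p - 3) / 2 >= s) return(p)
      p <- p + 1
    }
  }
  for (s in 1:6)
    expect_equal(hsibruise:::good_point_prime(s), scan_prime(s))
  expect_equal(scan_prime(1), 5)
  expect_equal(scan_prime(2), 7)
  expect_equal(scan_prime(3), 11)

  # numeric value of the first good point coordinate for s = 2 (p = 7)
  sp01 <- search_space(c(0, 0), c(1, 1))
  pts <- good_point_set(sp01, 10)
  expect_equal(pts[1, 1], (2 * cos(2 * pi / 7)) %% 1, tolerance = 1e-12)
  expect_equal(pts[1, 1], 0.2469796, tolerance = 1e-6)

  sp <- search_space(c(-3, 10, 0), c(2, 20, 1))
  pts <- good_point_set(sp, 57)
  expect_true(all(sweep(pts, 2, sp$lower, `>=`)))
  expect_true(all(sweep(pts, 2, sp$upper, `<=`)))
  # deterministic: no RNG involved
  expect_identical(pts, good_point_set(sp, 57))
})

test_that("good point set covers the box more evenly than random seeding", {
  min_pair_dist <- function(P) min(dist(P))
  sp <- search_space(c(0, 0), c(1, 1))
  gps <- min_pair_dist(good_point_set(sp, 100))
  set.seed(404)
  rand <- replicate(100, min_pair_dist(matrix(runif(200), 100, 2)))
  expect_gt(gps, median(rand))
})

test_that("Levy scale constant matches independent evaluation", {
  # frozen high-precision values (30-digit arithmetic, signed real root)
  expect_equal(levy_sigma(1.1), 0.93829087578483525, tolerance = 1e-10)
  expect_equal(levy_sigma(1.5), 0.69657450255769679, tolerance = 1e-10)
  # independent transcription via lgamma for the whole grid
  indep <- function(b) {
    base <- exp(lgamma(1 + b) - lgamma((1 + b) / 2)) * sin(pi * b / 2) /
      (b * 2^((b - 1) / 2))
    sign(base) * abs(base)^(1 / b)
  }
  for (b in c(1.1, 1.5, 2.0, 3.0))
    expect_equal(levy_sigma(b), indep(b), tolerance = 1e-10)
  expect_error(levy_sigma(1))
  expect_error(levy_sigma(3.5))
})

test_that("Levy flight is symmetric and heavy-tailed", {
  set.seed(99)
  lf <- levy_flight(1.5, 1e5)
  expect_lt(abs(mean(lf)), 0.05)
  kurt <- mean((lf - mean(lf))^4) / stats::var(lf)^2
  expect_gt(kurt, 30)  # far beyond the Gaussian value of 3
})

test_that("exploration move obeys its trigonometric algebra and bounds", {
  sp <- search_space(c(-1, -1), c(1, 1))
  xi <- c(0.2, -0.3); xr <- c(0.9, 0.5)
  # r2 = 0, even j: sin term vanishes -> coordinate stays at x_{i, pj}
  out <- exploration_move(xi, xr, sp, perm = c(1, 2), r1 = c(0.4, 0.4),
                          r2 = c(0, 0))
  expect_equal(out[2], xi[2])
  # r1 = r2 = 0, odd j: cos(0) = 1 -> full move onto x_{r, p1}
  out0 <- exploration_move(xi, xr, sp, perm = c(1, 2), r1 = c(0, 0),
                           r2 = c(0, 0))
  expect_equal(out0[1], xr[1])
  expect_equal(out0[2], xi[2])
  set.seed(7)
  for (rep in 1:20) {
    out <- exploration_move(runif(2, -1, 1), runif(2, -1, 1), sp)
    expect_true(all(out >= sp$lower & out <= sp$upper))
  }
  expect_error(
    bwo(function(x) sum(x^2), search_space(0, 1), n = 1, Tmax = 1))
})

test_that("classic exploitation move reduces correctly in special cases", {
  sp <- search_space(c(-1, -1), c(1, 1))
  xi <- c(0.5, -0.5); xb <- c(0.1, 0.2); xr <- c(-0.4, 0.9)
  expect_equal(
    exploitation_move_classic(xi, xb, xr, sp, 10, 100, r3 = 1, r4 = 0,
                              lf = 0),
    xb)
  expect_equal(
    exploitation_move_classic(xi, xb, xr, sp, 10, 100, r3 = 0, r4 = 1,
                              lf = 0),
    pmin(pmax(-xi, sp$lower), sp$upper))
  # T = Tmax: C1 = 0, Levy term vanishes regardless of lf
  expect_equal(
    exploitation_move_classic(xi, xb, xr, sp, 100, 100, r3 = 0.3, r4 = 0.2,
                              lf = 1e6),
    pmin(pmax(0.3 * xb - 0.2 * xi, sp$lower), sp$upper))
})

test_that("adaptive Levy step scale decays to zero", {
  sp <- search_space(c(0, 0), c(10, 10))
  xi <- c(4, 6)
  # t = Tmax: alpha = 0, position unchanged
  expect_equal(adaptive_levy_move(xi, sp, 50, 50, mu = c(3, 3),
                                  nu = c(1, 1)), xi)
  # gamma = 1, t = T/2: step exactly half the t = 0 step
  s0 <- adaptive_levy_move(xi, sp, 0, 100, gamma = 1, mu = c(1, 1),
                           nu = c(1, 1)) - xi
  s_half <- adaptive_levy_move(xi, sp, 50, 100, gamma = 1, mu = c(1, 1),
                               nu = c(1, 1)) - xi
  expect_equal(s_half, s0 / 2)
})

test_that("spiral move contracts onto the guide", {
  sp <- search_space(c(-5, -5), c(5, 5))
  xb <- c(1, -2); xi <- c(3, 3)
  # r = 0.5 makes A = 0 at any a(t)
  expect_equal(spiral_move(xi, xb, sp, 10, 100, r = c(0.5, 0.5),
                           rc = c(0.7, 0.7)), xb)
  # fixed point: X = X*, C = 1 -> D = 0
  expect_equal(spiral_move(xb, xb, sp, 10, 100, r = c(0.9, 0.1),
                           rc = c(0.5, 0.5)), xb)
  # t = Tmax: a* = 0 -> A = 0 for every draw
  set.seed(3)
  for (rep in 1:10)
    expect_equal(spiral_move(runif(2, -5, 5), xb, sp, 100, 100), xb)
})

test_that("elite pool holds the top three and their mean", {
  pos <- rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3), c(4, 4))
  fit <- c(5, 1, 3, 2, 4)
  pool <- elite_pool(pos, fit)
  expect_equal(nrow(pool), 4L)
  expect_equal(pool[1, ], c(1, 1))      # best
  expect_equal(pool[2, ], c(3, 3))
  expect_equal(pool[3, ], c(2, 2))
  expect_equal(pool[4, ], c(2, 2))      # arithmetic mean of the three
  # identical elites: every pool member identical
  pool2 <- elite_pool(rbind(c(7, 7), c(7, 7), c(7, 7), c(0, 0)),
                      c(1, 1, 1, 9))
  expect_true(all(apply(pool2, 1, identical, c(7, 7))))
  # degraded pool for tiny populations
  expect_equal(nrow(elite_pool(rbind(c(1, 2), c(3, 4)), c(1, 2))), 3L)
})

test_that("elite pool guide is drawn uniformly", {
  pool <- rbind(c(1, 0), c(2, 0), c(3, 0), c(4, 0))
  set.seed(11)
  draws <- replicate(1e4, elite_pool_guide(pool)[1])
  freq <- table(draws) / 1e4
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("whale fall move follows its step-length schedule", {
  sp <- search_space(0, 10)
  xi <- 4; xr <- 7
  # r7 = 0: pure combination of own and partner position
  expect_equal(whale_fall_move(xi, xr, sp, 5, 10, 20, r5 = 0.5, r6 = 0.2,
                               r7 = 0),
               0.5 * 4 - 0.2 * 7)
  # T = 0: exp(0) = 1, full box-width step
  expect_equal(whale_fall_move(0, 0, sp, 0, 10, 20, r5 = 0, r6 = 0, r7 = 1),
               10)
  # T = Tmax, N = 50: step = (ub - lb) * exp(-2 * 0.05 * 50) = range * e^-5
  expect_equal(whale_fall_move(0, 0, sp, 10, 10, 50, r5 = 0, r6 = 0,
                               r7 = 1),
               10 * exp(-5))
})

test_that("golden sine step matches its closed form", {
  v <- c(0.4, -0.2); d <- c(1, 1)
  g <- hsibruise:::golden_init()
  # r2 = 0: pure |sin| contraction
  expect_equal(golden_sine_step(v, d, g$x1, g$x2, r1 = 1, r2 = 0),
               v * abs(sin(1)))
  # V = 0: remaining term is -r2 sin(r1) |x1 D|
  expect_equal(golden_sine_step(c(0, 0), d, g$x1, g$x2, r1 = 2, r2 = 0.5),
               -0.5 * sin(2) * abs(g$x1 * d))
  # golden coefficients sit at the golden sections of [-pi, pi]
  tau <- (sqrt(5) - 1) / 2
  expect_equal(g$x1, -pi + (1 - tau) * 2 * pi)
  expect_equal(g$x2, -pi + tau * 2 * pi)
})

test_that("random initialization evaluates fitness and tracks the best", {
  sp <- search_space(c(0, 0), c(1, 1))
  sphere <- function(x) sum(x^2)
  pop <- init_random(sphere, sp, 4, seed = 5)
  expect_equal(dim(pop$positions), c(4L, 2L))
  expect_true(all(pop$positions >= 0 & pop$positions <= 1))
  expect_equal(pop$fitness, apply(pop$positions, 1, sphere))
  expect_equal(pop$best_fitness, min(pop$fitness))
  pop50 <- init_random(sphere, sp, 50, seed = 6)
  expect_lte(pop50$best_fitness, mean(pop50$fitness))
  # near-degenerate bounds stay inside
  spd <- search_space(c(0.5, 0.5), c(0.5 + 1e-9, 0.5 + 1e-9))
  popd <- init_random(sphere, spd, 5, seed = 7)
  expect_true(all(popd$positions >= spd$lower & popd$positions <= spd$upper))
  expect_error(init_random(function(x) NaN, sp, 3, seed = 1),
               "non-finite")
})

test_that("classic optimizer reproduces a hand-stepped trace", {
  quad <- function(x) (x - 0.3)^2
  for (seed in c(1, 7, 23)) {
    res <- bwo(quad, search_space(-1, 2), n = 3, Tmax = 2, seed = seed)
    tr <- oracle_bwo_trace(quad, -1, 2, n = 3, Tmax = 2, seed = seed)
    expect_equal(res$best_position, tr$best_position)
    expect_equal(res$best_fitness, tr$best_fitness)
    expect_equal(res$convergence, tr$convergence)
  }
  # and on a longer 2-D run
  sphere <- function(x) sum(x^2)
  res <- bwo(sphere, search_space(c(-5, -5), c(5, 5)), n = 6, Tmax = 10,
             seed = 42)
  tr <- oracle_bwo_trace(sphere, c(-5, -5), c(5, 5), n = 6, Tmax = 10,
                         seed = 42)
  expect_equal(res$convergence, tr$convergence)
})

test_that("both optimizers converge on the sphere with monotone curves", {
  b <- make_benchmark("sphere", 2)
  res <- bwo(b$fn, b$space, n = 30, Tmax = 200, seed = 1)
  expect_lt(res$best_fitness, 1e-3)
  expect_true(all(diff(res$convergence) <= 0))
  expect_equal(length(res$convergence), 200L)
  resm <- msbwo(b$fn, b$space, n = 30, Tmax = 200, seed = 1)
  expect_lt(resm$best_fitness, 1e-6)
  expect_true(all(diff(resm$convergence) <= 0))
  # Tmax = 1: single update round, result no worse than the seeding
  res1 <- bwo(b$fn, b$space, n = 10, Tmax = 1, seed = 3)
  pop0 <- init_random(b$fn, b$space, 10, seed = 3)
  expect_lte(res1$best_fitness, pop0$best_fitness)
  expect_equal(length(res1$convergence), 1L)
})

test_that("move operators keep arbitrary seeded runs inside the bounds", {
  rosen <- make_benchmark("rosenbrock", 3)
  for (seed in 1:3) {
    res <- msbwo(rosen$fn, rosen$space, n = 12, Tmax = 30, seed = seed)
    pos <- res$population$positions
    expect_true(all(sweep(pos, 2, rosen$space$lower, `>=`)))
    expect_true(all(sweep(pos, 2, rosen$space$upper, `<=`)))
    expect_true(all(diff(res$convergence) <= 0))
  }
})

test_that("disabling every strategy degenerates msbwo to bwo exactly", {
  b <- make_benchmark("rastrigin", 2)
  ctrl <- msbwo_control(exploit = "classic", use_good_point = FALSE,
                        use_elite_pool = FALSE, use_golden = FALSE)
  for (seed in c(2, 31)) {
    r1 <- bwo(b$fn, b$space, n = 8, Tmax = 20, seed = seed)
    r2 <- msbwo(b$fn, b$space, n = 8, Tmax = 20, seed = seed,
                control = ctrl)
    expect_identical(r1$convergence, r2$convergence)
    expect_identical(r1$best_position, r2$best_position)
  }
})

test_that("optimizer results export to JSON and CSV", {
  b <- make_benchmark("sphere", 2)
  res <- bwo(b$fn, b$space, n = 5, Tmax = 5, seed = 1)
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_bwo_result(res, jp, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$best_fitness, res$best_fitness)
  expect_equal(back$seed, 1L)
  curve <- read.csv(cp)
  expect_equal(curve$best_fitness, res$convergence)
  unlink(c(jp, cp))
})

test_that("benchmark objectives are exact at their optima", {
  for (nm in c("sphere", "rastrigin", "rosenbrock")) {
    b <- make_benchmark(nm, 3)
    expect_identical(b$fn(b$optimum), b$optimal_value)
  }
  expect_error(make_benchmark("ackley", 2))
})
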