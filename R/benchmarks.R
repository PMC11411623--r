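#' Benchmark objectives for the optimizers
#'
#' Closed-form test functions with known optima, used to exercise and
#' compare the beluga whale optimizers:
#' \describe{
#'   \item{sphere}{`sum(x^2)`, optimum 0 at the origin.}
#'   \item{rastrigin}{`10 d + sum(x^2 - 10 cos(2 pi x))`, highly
#'     multimodal, optimum 0 at the origin.}
#'   \item{rosenbrock}{`sum(100 (x[j+1] - x[j]^2)^2 + (1 - x[j])^2)`,
#'     optimum 0 at the all-ones vector.}
#' }
#'
#' @param name one of `"sphere"`, `"rastrigin"`, `"rosenbrock"`.
#' @param dim dimension (>= 1; rosenbrock requires >= 2).
#' @return a list of class `benchmark_objective` with elements `name`,
#'   `dim`, `fn`, `optimum` (position), `optimal_value`, and `space`
#'   (a conventional [search_space()] for the function).
#' @examples
#' b <- make_benchmark("sphere", 2)
#' b$fn(b$optimum)  # 0
#' @export
make_benchmark <- function(name = c("sphere", "rastrigin", "rosenbrock"),
                           dim = 2L) {
  name <- match.arg(name)
  dim <- as.integer(dim)
  if (dim < 1L) stop("'dim' must be >= 1")
  obj <- switch(name,
    sphere = list(
      fn = function(x) sum(x^2),
      optimum = rep(0, dim), optimal_value = 0,
      space = search_space(rep(-100, dim), rep(100, dim))),
    rastrigin = list(
      fn = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
      optimum = rep(0, dim), optimal_value = 0,
      space = search_space(rep(-5.12, dim), rep(5.12, dim))),
    rosenbrock = {
      if (dim < 2L) stop("rosenbrock requires dim >= 2")
      list(
        fn = function(x) {
          j <- seq_len(length(x) - 1L)
          sum(100 * (x[j + 1L] - x[j]^2)^2 + (1 - x[j])^2)
        },
        optimum = rep(1, dim), optimal_value = 0,
        space = search_space(rep(-5, dim), rep(10, dim)))
    })
  structure(c(list(name = name, dim = dim), obj),
            class = "benchmark_objective")
}

#' @export
print.benchmark_objective <- function(x, ...) {
  cat(sprintf("Benchmark '%s' (d = %d), optimum value %g\n",
              x$name, x$dim, x$optimal_value))
  invisible(x)
}
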