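#' Clamp values to box bounds
#'
#' Out-of-bounds coordinates produced by any position update are projected
#' onto the nearest bound.
#'
#' @param x numeric vector.
#' @param lower,upper numeric vectors (recycled) with `lower < upper`.
#' @return `x` with every element forced into `[lower, upper]`.
#' @keywords internal
clamp <- function(x, lower, upper) {
  pmin(pmax(x, lower), upper)
}

#' Derive a stage seed from a global seed
#'
#' All stochastic stages of a run derive their seeds from one global seed so
#' that a single integer reproduces every artifact. The derivation is a
#' fixed affine map kept below 2^31.
#'
#' @param seed global integer seed.
#' @param stage small non-negative integer identifying the stage.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 10007 + 7919 * stage) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
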