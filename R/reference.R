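#' Externally reported reference metrics
#'
#' Published evaluation quartets (accuracy, precision, recall, F1, in
#' percent) for sound/bruised blueberry classifiers built on spectral,
#' image and fused features, including the reported tuned SVM
#' hyperparameters `c` and `g` for the classic and multi-strategy
#' improved beluga whale optimizers. Shipped as plain CSV and used by the
#' consistency checks that recompute F1 from the reported precision and
#' recall. These are reference values from the originating study's fruit
#' data, not quantities this package can recompute.
#'
#' @return data frame with columns `model`, `feature_category`,
#'   `selection_method`, `n_features`, `optimizer`, `c`, `g`, `accuracy`,
#'   `precision`, `recall`, `f1`.
#' @examples
#' ref <- reference_metrics()
#' f1 <- 2 * ref$precision * ref$recall / (ref$precision + ref$recall)
#' max(abs(f1 - ref$f1))  # reported F1 values are internally consistent
#' @export
reference_metrics <- function() {
  utils::read.csv(system.file("extdata", "reference_metrics.csv",
                              package = "hsibruise"),
                  stringsAsFactors = FALSE)
}
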