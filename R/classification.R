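#' Stratified train/test split
#'
#' Random split preserving class ratios (within one sample per class),
#' reproducible by seed. Both classes must end up in both partitions.
#'
#' @param ft a [feature_table()] (or any object with a `labels` factor),
#'   with at least 2 samples per class.
#' @param train_fraction fraction of samples in the training split
#'   (default 0.7, the conventional 7:3 ratio).
#' @param seed optional integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_table <- function(ft, train_fraction = 0.7, seed = NULL) {
  labels <- if (inherits(ft, "feature_table")) ft$labels else as.factor(ft)
  if (any(table(labels) < 2L))
    stop("each class needs at least 2 samples to split")
  if (!is.null(seed)) set.seed(seed)
  train <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_tr <- round(length(idx) * train_fraction)
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)  # both classes both sides
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Metric quartet from a 2x2 confusion matrix
#'
#' Computes accuracy, precision, recall and F1 (harmonic mean of
#' precision and recall) as percentages, with the bruised class as the
#' positive class: `accuracy = (TP + TN) / total`,
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`. A metric with
#' a zero denominator is reported as `NA`.
#'
#' @param confusion 2x2 table/matrix of counts with truth in rows and
#'   prediction in columns, dimnames naming the classes; or a named
#'   numeric vector `c(tp =, fp =, fn =, tn =)`.
#' @param positive name of the positive class (default `"bruised"`).
#' @return an object of class `metric_report`: list with `accuracy`,
#'   `precision`, `recall`, `f1` (percent) and `confusion`.
#' @examples
#' compute_metrics(c(tp = 58, fp = 2, fn = 4, tn = 56))
#' @export
compute_metrics <- function(confusion, positive = "bruised") {
  if (is.numeric(confusion) && !is.matrix(confusion) &&
      all(c("tp", "fp", "fn", "tn") %in% names(confusion))) {
    tp <- confusion[["tp"]]; fp <- confusion[["fp"]]
    fn <- confusion[["fn"]]; tn <- confusion[["tn"]]
    confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
                        dimnames = list(truth = c(positive, "other"),
                                        predicted = c(positive, "other")))
  } else {
    confusion <- as.matrix(unclass(confusion))
    if (!identical(dim(confusion), c(2L, 2L)))
      stop("'confusion' must be a 2x2 matrix")
    if (sum(confusion) == 0) stop("empty confusion matrix")
    if (!positive %in% rownames(confusion))
      stop(sprintf("positive class '%s' not found in confusion dimnames",
                   positive))
    pos <- match(positive, rownames(confusion))
    tp <- confusion[pos, pos]
    fn <- sum(confusion[pos, ]) - tp
    fp <- sum(confusion[, pos]) - tp
    tn <- sum(confusion) - tp - fn - fp
  }
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix")
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  precision <- rate(tp, tp + fp)
  recall <- rate(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(accuracy = rate(tp + tn, total), precision = precision,
                 recall = recall, f1 = f1, confusion = confusion,
                 positive = positive),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf("Accuracy %s | Precision %s | Recall %s | F1 %s (positive: %s)\n",
              fmt(x$accuracy), fmt(x$precision), fmt(x$recall), fmt(x$f1),
              x$positive))
  invisible(x)
}

# Library-style default RBF hyperparameters: C = 1 and
# g = 1 / (n_features * overall feature variance).
default_svm_params <- function(x) {
  v <- stats::var(as.vector(x))
  list(C = 1, g = 1 / (ncol(x) * if (v > 0) v else 1))
}

fit_classifier <- function(kind, x, y, params = NULL, seed = NULL) {
  if (nlevels(droplevels(y)) < 2L)
    stop("training data contain a single class")
  if (!is.null(seed)) set.seed(seed)
  switch(kind,
    svm_rbf = {
      p <- params %||% default_svm_params(x)
      e1071::svm(x, y, kernel = "radial", cost = p$C, gamma = p$g,
                 scale = FALSE)
    },
    random_forest = randomForest::randomForest(
      x, y, ntree = 500, mtry = max(1L, floor(sqrt(ncol(x))))),
    plsda = fit_plsda(x, y, max_comp = 10L),
    stop("unknown model kind '", kind, "'"))
}

predict_classifier <- function(kind, fit, x, levels_y) {
  if (kind == "plsda") return(predict_plsda(fit, x))
  factor(as.character(stats::predict(fit, x)), levels = levels_y)
}

# PLS-DA via mixOmics; the number of components (<= max_comp) is chosen by
# 5-fold CV accuracy on the training rows, and the class is assigned by a
# 0.5 threshold on the predicted positive-class score.
fit_plsda <- function(x, y, max_comp = 10L) {
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  ncomp_cap <- max(1L, min(max_comp, ncol(x), nrow(x) - 2L))
  fold_id <- sample(rep(seq_len(5L), length.out = nrow(x)))
  acc <- numeric(ncomp_cap)
  for (nc in seq_len(ncomp_cap)) {
    hits <- 0L
    for (f in seq_len(5L)) {
      tr <- fold_id != f
      if (nlevels(droplevels(y[tr])) < 2L) next
      m <- mixOmics::plsda(x[tr, , drop = FALSE], y[tr], ncomp = nc)
      pr <- plsda_scores(m, x[!tr, , drop = FALSE], nc)
      hits <- hits + sum((pr > 0.5) == (y[!tr] == positive_level(y)))
    }
    acc[nc] <- hits
  }
  ncomp <- which.max(acc)
  model <- mixOmics::plsda(x, y, ncomp = ncomp)
  structure(list(model = model, ncomp = ncomp, levels = levels(y),
                 positive = positive_level(y), features = colnames(x)),
            class = "hsibruise_plsda")
}

positive_level <- function(y) {
  if ("bruised" %in% levels(y)) "bruised" else levels(y)[2L]
}

plsda_scores <- function(model, x, ncomp) {
  pr <- stats::predict(model, x)
  pos <- if ("bruised" %in% dimnames(pr$predict)[[2]]) "bruised" else
    dimnames(pr$predict)[[2]][2]
  pr$predict[, pos, ncomp]
}

predict_plsda <- function(fit, x) {
  colnames(x) <- fit$features
  sc <- plsda_scores(fit$model, x, fit$ncomp)
  factor(ifelse(sc > 0.5, fit$positive,
                setdiff(fit$levels, fit$positive)[1]),
         levels = fit$levels)
}

#' Train a classifier and evaluate the metric quartet on a test split
#'
#' Fits the requested model on the training rows and fills a
#' [compute_metrics()] report from its test-set confusion matrix, with
#' bruised as the positive class.
#'
#' Models: `svm_rbf` (RBF-kernel SVM; default hyperparameters are C = 1
#' and g = 1/(n_features * feature variance) unless `params` supplies
#' `C`, `g`), `random_forest` (500 trees, sqrt(p) features per split),
#' `plsda` (partial least squares discriminant analysis, components
#' chosen by CV up to 10, class by 0.5 score threshold).
#'
#' @param model_kind one of `"svm_rbf"`, `"random_forest"`, `"plsda"`.
#' @param train,test [feature_table()] objects (same feature columns).
#' @param params optional list with `C` and `g` for `svm_rbf`.
#' @param seed optional seed for the stochastic learners.
#' @return a `metric_report` with attributes `model_kind` and `n_features`.
#' @export
train_eval <- function(model_kind = c("svm_rbf", "random_forest", "plsda"),
                       train, test, params = NULL, seed = NULL) {
  model_kind <- match.arg(model_kind)
  fit <- fit_classifier(model_kind, train$x, droplevels(train$labels),
                        params, seed)
  pred <- predict_classifier(model_kind, fit, test$x, levels(train$labels))
  confusion <- table(truth = test$labels, predicted = pred)
  rep <- compute_metrics(confusion,
                         positive = positive_level(train$labels))
  attr(rep, "model_kind") <- model_kind
  attr(rep, "n_features") <- ncol(train$x)
  rep
}

#' k-fold cross-validated SVM accuracy
#'
#' Mean accuracy of an RBF SVM over a fixed fold assignment; used as the
#' (negated) tuning fitness so that hyperparameter search never touches
#' the test split.
#'
#' @param x feature matrix, `y` factor labels.
#' @param y factor labels.
#' @param C,g SVM penalty and kernel width.
#' @param fold_id integer fold assignment per row.
#' @return mean CV accuracy in `[0, 1]`.
#' @export
svm_cv_accuracy <- function(x, y, C, g, fold_id) {
  hits <- 0L
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    if (nlevels(droplevels(y[tr])) < 2L) return(0)
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = C, gamma = g, scale = FALSE)
    pred <- stats::predict(fit, x[!tr, , drop = FALSE])
    hits <- hits + sum(pred == y[!tr])
  }
  hits / length(y)
}

stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  id
}

#' Tuning protocol for the SVM hyperparameter search
#'
#' Defaults follow the study conditions: population 50, 100 iterations,
#' 30 independent repeats whose tuned `(C, g)` are averaged, fitness
#' `1 - (5-fold stratified CV accuracy)` on the training rows.
#'
#' @param population optimizer population size.
#' @param iterations optimizer iterations.
#' @param repeats independent seeded optimization runs.
#' @param folds CV folds for the fitness.
#' @return a list of class `tuning_protocol`.
#' @export
tuning_protocol <- function(population = 50L, iterations = 100L,
                            repeats = 30L, folds = 5L) {
  if (repeats < 1L) stop("'repeats' must be >= 1")
  structure(list(population = as.integer(population),
                 iterations = as.integer(iterations),
                 repeats = as.integer(repeats),
                 folds = as.integer(folds)),
            class = "tuning_protocol")
}

#' Tune SVM hyperparameters with a beluga whale optimizer
#'
#' Runs `repeats` seeded optimizations of the fitness
#' `1 - mean k-fold CV accuracy` over `(C, g)` searched on a log10 scale
#' inside `bounds`, using either the classic ([bwo()]) or multi-strategy
#' improved ([msbwo()]) optimizer. The per-run optima are averaged
#' arithmetically on the original scale (the conventional aggregation)
#' and an SVM is refit on the full training rows with the mean
#' hyperparameters. A failed repeat is recorded and excluded from the
#' mean with a warning.
#'
#' @param train a [feature_table()] (training rows only; the test split
#'   must not leak into the fitness).
#' @param algorithm `"bwo"` or `"msbwo"`.
#' @param protocol a [tuning_protocol()].
#' @param bounds list with elements `C` and `g`, each `c(lower, upper)`;
#'   default `C` in `[0.01, 100]`, `g` in `[0.001, 10]`.
#' @param seed global seed; per-repeat seeds are derived from it.
#' @return an object of class `svm_tuning`: `C`, `g` (mean tuned values),
#'   `per_run` data frame (seed, C, g, fitness), `cv_accuracy` of the mean
#'   parameters, `model` (refit SVM), `algorithm`, `protocol`.
#' @export
tune_svm <- function(train, algorithm = c("bwo", "msbwo"),
                     protocol = tuning_protocol(),
                     bounds = list(C = c(0.01, 100), g = c(0.001, 10)),
                     seed = 1L) {
  algorithm <- match.arg(algorithm)
  x <- train$x
  y <- droplevels(train$labels)
  if (nlevels(y) < 2L) stop("training data contain a single class")
  space <- search_space(log10(c(bounds$C[1], bounds$g[1])),
                        log10(c(bounds$C[2], bounds$g[2])))
  runs <- vector("list", protocol$repeats)
  for (r in seq_len(protocol$repeats)) {
    seed_r <- derive_seed(seed, r)
    set.seed(seed_r)
    fold_id <- stratified_folds(y, protocol$folds)
    objective <- function(z)
      1 - svm_cv_accuracy(x, y, C = 10^z[1], g = 10^z[2], fold_id)
    res <- tryCatch({
      if (algorithm == "bwo")
        bwo(objective, space, n = protocol$population,
            Tmax = protocol$iterations, seed = seed_r)
      else
        msbwo(objective, space, n = protocol$population,
              Tmax = protocol$iterations, seed = seed_r)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("tuning repeat %d failed (%s); excluded from mean",
                      r, conditionMessage(res)), call. = FALSE)
      runs[[r]] <- data.frame(seed = seed_r, C = NA_real_, g = NA_real_,
                              fitness = NA_real_)
    } else {
      runs[[r]] <- data.frame(seed = seed_r, C = 10^res$best_position[1],
                              g = 10^res$best_position[2],
                              fitness = res$best_fitness)
    }
  }
  per_run <- do.call(rbind, runs)
  ok <- !is.na(per_run$C)
  if (!any(ok)) stop("all tuning repeats failed")
  C_mean <- mean(per_run$C[ok])
  g_mean <- mean(per_run$g[ok])
  set.seed(derive_seed(seed, 0L))
  fold_id <- stratified_folds(y, protocol$folds)
  cv_acc <- svm_cv_accuracy(x, y, C_mean, g_mean, fold_id)
  model <- e1071::svm(x, y, kernel = "radial", cost = C_mean,
                      gamma = g_mean, scale = FALSE)
  structure(list(C = C_mean, g = g_mean, per_run = per_run,
                 cv_accuracy = cv_acc, model = model,
                 algorithm = algorithm, protocol = protocol, seed = seed),
            class = "svm_tuning")
}

#' @export
print.svm_tuning <- function(x, ...) {
  cat(sprintf("SVM tuning (%s, %d repeat(s)): C = %.4f, g = %.4f\n",
              toupper(x$algorithm), nrow(x$per_run), x$C, x$g))
  cat(sprintf("  CV accuracy at mean parameters: %.2f%%\n",
              100 * x$cv_accuracy))
  invisible(x)
}

#' @export
coef.svm_tuning <- function(object, ...) c(C = object$C, g = object$g)
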