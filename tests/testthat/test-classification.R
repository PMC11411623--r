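sep_tables <- function(n_per_class = 20, gap = 4, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- factor(rep(c("sound", "bruised"), each = n_per_class),
                   levels = c("sound", "bruised"))
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, sprintf("spectral:%dnm", 1:5)))
  x[labels == "bruised", 1:2] <- x[labels == "bruised", 1:2] + gap
  feature_table(x, labels, "spectral")
}

test_that("stratified split preserves ratios and reproduces by seed", {
  labels <- factor(rep(c("sound", "bruised"), each = 400))
  s1 <- split_table(labels, 0.7, seed = 9)
  expect_length(s1$train, 560L)
  expect_length(s1$test, 240L)
  expect_equal(sum(labels[s1$train] == "bruised"), 280L)
  s2 <- split_table(labels, 0.7, seed = 9)
  expect_identical(s1, s2)
  # uneven class sizes: ratios within one sample
  lab2 <- factor(rep(c("sound", "bruised"), times = c(17, 11)))
  s3 <- split_table(lab2, 0.7, seed = 2)
  expect_equal(sum(lab2[s3$train] == "sound"), round(0.7 * 17))
  expect_equal(sum(lab2[s3$train] == "bruised"), round(0.7 * 11))
  expect_true(all(table(lab2[s3$test]) >= 1))
  expect_error(split_table(factor(c("a", "b", "b")), 0.7))
})

test_that("the metric quartet matches hand-computed confusion matrices", {
  # integer confusion consistent with a 96.67/93.55 precision/recall pair
  m <- compute_metrics(c(tp = 58, fp = 2, fn = 4, tn = 56))
  expect_equal(m$accuracy, 95.00, tolerance = 0.005)
  expect_equal(m$precision, 96.67, tolerance = 0.005)
  expect_equal(m$recall, 93.55, tolerance = 0.005)
  expect_equal(m$f1, 95.08, tolerance = 0.005)

  # harmonic-mean identity reproduces a reported F1 from its
  # precision/recall pair
  f1 <- 2 * 91.67 * 88.71 / (91.67 + 88.71)
  expect_equal(f1, 90.17, tolerance = 0.005)

  all_correct <- compute_metrics(c(tp = 30, fp = 0, fn = 0, tn = 30))
  expect_equal(all_correct$accuracy, 100)
  expect_equal(all_correct$f1, 100)

  # all-positive predictions: recall 100, precision = prevalence
  ap <- compute_metrics(c(tp = 20, fp = 30, fn = 0, tn = 0))
  expect_equal(ap$recall, 100)
  expect_equal(ap$precision, 40)

  # zero denominator reported as undefined
  nopos <- compute_metrics(c(tp = 0, fp = 0, fn = 5, tn = 45))
  expect_true(is.na(nopos$precision))
  expect_error(compute_metrics(c(tp = 0, fp = 0, fn = 0, tn = 0)), "empty")

  # table input with named dimensions
  tab <- table(truth = factor(c("bruised", "bruised", "sound"),
                              levels = c("sound", "bruised")),
               predicted = factor(c("bruised", "sound", "sound"),
                                  levels = c("sound", "bruised")))
  m2 <- compute_metrics(tab)
  expect_equal(m2$recall, 50)
  expect_equal(m2$precision, 100)
})

test_that("reported reference metrics are internally F1-consistent", {
  ref <- reference_metrics()
  complete <- !is.na(ref$precision) & !is.na(ref$recall) & !is.na(ref$f1)
  f1 <- 2 * ref$precision * ref$recall / (ref$precision + ref$recall)
  expect_true(all(abs(f1[complete] - ref$f1[complete]) <= 0.011))
})

test_that("all three models separate well-separated classes perfectly", {
  train <- sep_tables(20, gap = 6, seed = 3)
  test <- sep_tables(15, gap = 6, seed = 4)
  for (kind in c("svm_rbf", "random_forest", "plsda")) {
    rep <- train_eval(kind, train, test, seed = 5)
    expect_equal(rep$accuracy, 100, info = kind)
    expect_equal(rep$f1, 100, info = kind)
    # quartet self-consistency
    expect_equal(rep$f1,
                 2 * rep$precision * rep$recall /
                   (rep$precision + rep$recall))
  }
  # single-class training data refuse to fit
  bad <- sep_tables(6)
  bad$labels <- factor(rep("sound", 12), levels = c("sound", "bruised"))
  expect_error(train_eval("svm_rbf", bad, test), "single class")
})

test_that("train_eval is deterministic given the seed", {
  train <- sep_tables(15, gap = 1.2, seed = 6)
  test <- sep_tables(12, gap = 1.2, seed = 7)
  for (kind in c("svm_rbf", "random_forest", "plsda")) {
    r1 <- train_eval(kind, train, test, seed = 11)
    r2 <- train_eval(kind, train, test, seed = 11)
    expect_identical(unclass(r1)[c("accuracy", "precision", "recall", "f1")],
                     unclass(r2)[c("accuracy", "precision", "recall", "f1")])
  }
})

test_that("SVM tuning improves CV accuracy and aggregates repeats", {
  train <- sep_tables(15, gap = 1.0, seed = 8)
  proto <- tuning_protocol(population = 8, iterations = 8, repeats = 2,
                           folds = 3)
  tun <- tune_svm(train, "msbwo", proto, seed = 21)
  expect_s3_class(tun, "svm_tuning")
  expect_equal(nrow(tun$per_run), 2L)
  expect_equal(tun$C, mean(tun$per_run$C))
  expect_equal(tun$g, mean(tun$per_run$g))
  expect_true(tun$C > 0 && tun$g > 0)
  # repeats = 1: the mean is that single run
  tun1 <- tune_svm(train, "bwo", tuning_protocol(6, 6, 1, 3), seed = 22)
  expect_equal(tun1$C, tun1$per_run$C[1])
  expect_equal(tun1$g, tun1$per_run$g[1])
  # tuned parameters do at least as well as the library default on the
  # same folds
  y <- droplevels(train$labels)
  dp <- hsibruise:::default_svm_params(train$x)
  set.seed(hsibruise:::derive_seed(21, 0L))
  fid <- hsibruise:::stratified_folds(y, 5)
  expect_gte(tun$cv_accuracy,
             svm_cv_accuracy(train$x, y, dp$C, dp$g, fid))
})
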