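test_that("k-fold evaluation aggregates out-of-fold predictions into one matrix", {
  # perfectly separable clouds -> diagonal confusion matrix with 1-NN
  set.seed(3)
  n <- 30
  X <- rbind(matrix(rnorm(n * 2, -5, 0.2), n, 2),
             matrix(rnorm(n * 2, 5, 0.2), n, 2))
  fm <- feature_matrix(X, rep(c("neg", "pos"), each = n))
  cm <- kfold_evaluate(fm, "fknn", k = 5, seed = 1)
  expect_equal(sum(cm), 2 * n)
  expect_equal(sum(diag(unclass(cm))), 2 * n)

  # aggregate prediction count equals N exactly
  fm10 <- feature_matrix(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
  cm10 <- kfold_evaluate(fm10, "fknn", k = 5, seed = 2)
  expect_equal(sum(cm10), 10)

  # seeded: identical matrices
  expect_equal(unclass(kfold_evaluate(fm, "fknn", k = 5, seed = 9)),
               unclass(kfold_evaluate(fm, "fknn", k = 5, seed = 9)),
               ignore_attr = TRUE)

  expect_error(kfold_evaluate(fm10, "fknn", k = 6, seed = 1), "smaller k")
  expect_error(kfold_evaluate(fm, "nope", k = 5, seed = 1), "unknown classifier")
})

test_that("every registry classifier runs on a small separable problem", {
  set.seed(12)
  n <- 20
  X <- rbind(matrix(rnorm(n * 3, -3, 0.5), n, 3),
             matrix(rnorm(n * 3, 3, 0.5), n, 3))
  fm <- feature_matrix(X, rep(c("a", "b"), each = n))
  for (clf in names(classifier_registry())) {
    cm <- kfold_evaluate(fm, clf, k = 4, seed = 5)
    rep <- compute_metrics(cm)
    expect_equal(sum(cm), 2 * n)
    expect_gte(rep$accuracy, 90)  # trivially separable
  }
})

test_that("metrics match hand-derived values", {
  # identity matrix: everything perfect
  perfect <- compute_metrics(confusion_matrix(diag(25L, 3)))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$kappa, 100)
  expect_equal(perfect$mcc, 100)
  expect_equal(perfect$fpr, 0)

  # hand-computed 2x2: po = 0.8, pe = 0.5
  m <- compute_metrics(confusion_matrix(matrix(c(40L, 10L, 10L, 40L), 2, 2)))
  expect_equal(m$accuracy, 80)
  expect_equal(m$kappa, 60)
  expect_equal(m$mcc, 60)

  # one-class-only predictions on balanced truth: chance agreement
  cm1 <- confusion_matrix(matrix(c(50L, 50L, 0L, 0L), 2, 2))
  m1 <- compute_metrics(cm1)
  expect_equal(m1$kappa, 0)
  expect_true(m1$degenerate)
})

test_that("kappa equals MCC on random symmetric 2x2 matrices", {
  set.seed(14)
  for (i in 1:50) {
    a <- sample(1:100, 1); b <- sample(1:100, 1)
    off <- sample(0:min(a, b), 1)
    cm <- confusion_matrix(matrix(c(a, off, off, b), 2, 2))
    m <- compute_metrics(cm)
    expect_equal(m$kappa, m$mcc, tolerance = 1e-9)
  }
})

test_that("metrics are recomputable from the stored confusion matrix and permutation-invariant", {
  set.seed(15)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    cm <- confusion_matrix(matrix(sample(0:30, k * k, TRUE), k, k) + diag(5L, k))
    m <- compute_metrics(cm)
    m2 <- compute_metrics(confusion_matrix(m$confusion))
    expect_equal(tidy(m)$value, tidy(m2)$value, tolerance = 1e-9)

    perm <- sample(k)
    mp <- compute_metrics(confusion_matrix(unclass(cm)[perm, perm]))
    expect_equal(mp$accuracy, m$accuracy, tolerance = 1e-9)
    expect_equal(mp$kappa, m$kappa, tolerance = 1e-9)
    expect_equal(mp$mcc, m$mcc, tolerance = 1e-9)
  }
})

test_that("margin of error implements the z * sd / sqrt(n) half-width", {
  eq <- margin_of_error(rep(5, 4))
  expect_equal(eq$half_width, 0)
  expect_equal(eq$center, 5)

  set.seed(16)
  v <- rnorm(8, 80, 5)
  lo <- margin_of_error(v, 0.683)
  hi <- margin_of_error(v, 0.95)
  expect_equal(hi$half_width / lo$half_width, 1.960)
  expect_equal(lo$center, mean(v))
  expect_equal(hi$half_width, 1.960 * sd(v) / sqrt(8))
  expect_equal(hi$percent, 100 * hi$half_width / mean(v))

  # the published-range style input: center is the midrange of two values
  two <- margin_of_error(c(77.13, 86.63), 0.95)
  expect_equal(two$center, 81.88)

  expect_error(margin_of_error(5), "at least 2")
  expect_error(margin_of_error(c(1, 2), 1.5), "confidence")
})

test_that("confusion matrices plot and reports tidy/glance", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
  expect_s3_class(autoplot(cm), "ggplot")
  m <- compute_metrics(cm)
  expect_equal(nrow(tidy(m)), 7)
  expect_named(glance(m),
               c("classifier", "precision", "sensitivity", "f1", "fpr",
                 "kappa", "mcc", "accuracy", "time_s"))
})
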