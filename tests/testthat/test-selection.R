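test_that("Levy steps are seeded, heavy-tailed and respect the count contract", {
  set.seed(1); a <- levy_step(1.5, 100)
  set.seed(1); b <- levy_step(1.5, 100)
  expect_identical(a, b)
  expect_length(levy_step(1.5, 0), 0)
  expect_error(levy_step(0.5, 10), "lambda")
  expect_error(levy_step(3, 10), "lambda")

  set.seed(123)
  s <- levy_step(1.5, 1e5)
  expect_true(hill_estimate(s, 1000) > 1.2 && hill_estimate(s, 1000) < 1.8)
})

test_that("pollination moves have the stated fixed points and stay in the unit box", {
  y <- runif(10)
  expect_equal(global_pollination(y, y, theta = 0.01), y)
  z <- runif(10)
  # theta in (0, 1e-300]: vanishing scale leaves y unchanged in the limit
  expect_equal(global_pollination(y, z, theta = 1e-300), y)

  expect_equal(local_pollination(y, z, z), y)
  expect_equal(local_pollination(rep(0, 5), rep(0.3, 5), rep(0, 5), mu = 1),
               rep(0.3, 5))

  set.seed(17)
  for (i in 1:200) {
    y <- runif(8); B <- runif(8)
    g <- global_pollination(y, B, theta = runif(1, 0.01, 2))
    l <- local_pollination(runif(8), runif(8), runif(8))
    expect_true(all(g >= 0 & g <= 1))
    expect_true(all(l >= 0 & l <= 1))
  }
})

test_that("binarisation thresholds positions and never yields an empty mask", {
  expect_equal(binarize(c(0.2, 0.8), 0.5), c(FALSE, TRUE))
  expect_equal(binarize(c(0.1, 0.4, 0.2), 0.5), c(FALSE, TRUE, FALSE))
  # tie: lowest index wins
  expect_equal(binarize(c(0.3, 0.3), 0.9), c(TRUE, FALSE))
  expect_equal(fpcrf_config()$tau0, 0.5)
})

test_that("the wrapper fitness separates clouds, is chance-level on permuted labels, and is seeded", {
  set.seed(2)
  n <- 40
  X <- cbind(c(rnorm(n / 2, -10, 0.1), rnorm(n / 2, 10, 0.1)),
             matrix(rnorm(n * 3), n, 3))
  labs <- rep(c("a", "b"), each = n / 2)
  fm <- feature_matrix(X, labs)
  cfg <- fpcrf_config(seed = 1)
  expect_equal(fitness(c(TRUE, FALSE, FALSE, FALSE), fm, cfg), 0)

  errs <- sapply(1:20, function(s) {
    perm <- withr::with_seed(s, sample(labs))
    fitness(rep(TRUE, 4), feature_matrix(X, perm), fpcrf_config(seed = s))
  })
  expect_lt(abs(mean(errs) - 0.5), 0.15)

  # same config -> same value; folds are seeded
  expect_identical(fitness(rep(TRUE, 4), fm, cfg),
                   fitness(rep(TRUE, 4), fm, cfg))
  expect_error(fitness(rep(FALSE, 4), fm, cfg), "no features")
  expect_error(fitness(TRUE, feature_matrix(X[, 1, drop = FALSE],
                                            rep("a", n)), cfg),
               "two classes")
})

test_that("regula falsi matches a bisection oracle and handles the degenerate cases", {
  # linear function: exact in one iterate
  rf <- regula_falsi(function(x) x - 3, 0, 10)
  expect_equal(rf$root, 3)
  expect_equal(rf$iterations, 1)

  rf2 <- regula_falsi(function(x) x^2 - 4, 0, 4, tol = 1e-10)
  bis <- oracle_bisection(function(x) x^2 - 4, 0, 4)
  expect_equal(rf2$root, 2, tolerance = 1e-8)
  expect_equal(rf2$root, bis, tolerance = 1e-8)
  expect_true(rf2$root >= 0 && rf2$root <= 4)

  expect_error(regula_falsi(function(x) x^2 + 1, 0, 4), "sign change")

  # bracket containment and bisection agreement on smooth monotone functions
  fs <- list(function(x) exp(x) - 2, function(x) x^3 - 1,
             function(x) atan(x) - 0.5)
  for (f in fs) {
    rf <- regula_falsi(f, -2, 3, tol = 1e-12, max_iter = 200)
    expect_true(all(rf$history >= -2 & rf$history <= 3))
    expect_equal(rf$root, oracle_bisection(f, -2, 3), tolerance = 1e-8)
  }
})

test_that("threshold refinement recovers a planted separation and never regresses", {
  set.seed(6)
  # construct data where the 5 planted columns are informative
  fm <- make_features(n_per_class = 40, d_informative = 5, d_noise = 15,
                      effect = 4, seed = 5)
  planted <- attr(fm, "informative")
  cfg <- fpcrf_config(seed = 5)
  # best position with planted coordinates at 0.95, noise at 0.05
  B <- rep(0.05, 20); B[planted] <- 0.95
  ref <- refine_threshold(B, fm, cfg)
  expect_equal(which(ref$mask), planted, ignore_attr = TRUE)
  base <- fitness(binarize(B, cfg$tau0), fm, cfg)
  expect_lte(ref$fitness, base)

  # degenerate constant best vector
  refc <- refine_threshold(rep(0.4, 20), fm, cfg)
  expect_equal(refc$Vn, cfg$tau0)
  expect_equal(refc$mask, binarize(rep(0.4, 20), cfg$tau0))

  # no-regression holds on random positions too
  for (s in 1:5) {
    B <- withr::with_seed(s, runif(20))
    r <- refine_threshold(B, fm, cfg)
    expect_lte(r$fitness, fitness(binarize(B, cfg$tau0), fm, cfg))
  }
})

test_that("FPcRF is reproducible, elitist and feasible", {
  fm <- make_features(n_per_class = 20, d_informative = 2, d_noise = 6,
                      effect = 2, seed = 3)
  cfg <- fpcrf_config(pop = 2, iters = 1, seed = 11)
  r1 <- fpcrf_select(fm, cfg)
  r2 <- fpcrf_select(fm, cfg)
  expect_identical(r1, r2)

  cfg2 <- fpcrf_config(pop = 8, iters = 10, seed = 4)
  r <- fpcrf_select(fm, cfg2)
  expect_true(all(diff(r$trace) <= 0))
  expect_gte(length(r$selected), 1)
  expect_true(all(r$best_position >= 0 & r$best_position <= 1))
  expect_true(r$Vn >= 0 && r$Vn <= 1)
  expect_equal(length(r$trace), 10)

  expect_error(fpcrf_select(feature_matrix(matrix(rnorm(10), 10, 1),
                                           rep(c("a", "b"), 5)), cfg),
               "2 feature")
})

test_that("tidy, glance and autoplot expose the selection result", {
  fm <- make_features(n_per_class = 15, d_informative = 2, d_noise = 4,
                      effect = 2, seed = 9)
  r <- fpcrf_select(fm, fpcrf_config(pop = 5, iters = 3, seed = 9, folds = 3))
  td <- tidy(r)
  expect_equal(nrow(td), 6)
  expect_equal(sum(td$selected), length(r$selected))
  gl <- glance(r)
  expect_equal(gl$n_selected, length(r$selected))
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})
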