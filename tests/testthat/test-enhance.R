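test_that("grayscale conversion honours the luma weights and shape contract", {
  # all channels equal -> pass-through
  arr <- array(42, dim = c(3, 4, 3))
  expect_equal(as.numeric(to_grayscale(arr)), rep(42, 12))
  # pure red pixel, BT.601: 0.299 * 255
  red <- array(0, dim = c(1, 1, 3)); red[1, 1, 1] <- 255
  expect_equal(as.numeric(to_grayscale(red)), 76.245)
  # 1x1x3 -> 1x1
  expect_equal(dim(to_grayscale(red)), c(1L, 1L))
  # matrices pass through, bad shapes error
  m <- matrix(1:6 / 1, 2, 3)
  expect_equal(unclass(to_grayscale(m))[1:6], m[1:6])
  expect_error(to_grayscale(array(0, c(2, 2, 4))), "3 channels")
  expect_error(to_grayscale(1:5), "matrix")
})

test_that("intensity histogram is a proper pdf/cdf and conserves counts", {
  const <- grayscale_image(matrix(17, 4, 4))
  h <- intensity_histogram(const)
  expect_equal(h$pdf[18], 1)
  expect_equal(sum(h$pdf), 1)
  expect_equal(h$cdf[17], 0)
  expect_equal(h$cdf[256], 1)

  two <- grayscale_image(matrix(c(0, 255), 2, 1))
  h2 <- intensity_histogram(two)
  expect_equal(h2$pdf[c(1, 256)], c(0.5, 0.5))

  set.seed(11)
  for (i in 1:20) {
    img <- random_image(7)
    h <- intensity_histogram(grayscale_image(img))
    expect_equal(sum(h$counts), length(img))
    expect_equal(sum(h$pdf), 1, tolerance = 1e-12)
    expect_true(all(diff(h$cdf) >= 0))
    expect_equal(h$cdf[256], 1, tolerance = 1e-12)
  }
  expect_error(intensity_histogram(matrix(numeric(0), 0, 0)), "empty")
})

test_that("histogram transform maps through the cdf over the observed range", {
  # constant image: degenerate range, returned unchanged
  const <- grayscale_image(matrix(9, 3, 3))
  expect_equal(unclass(histogram_transform(const)), unclass(const),
               ignore_attr = TRUE)

  two <- grayscale_image(matrix(c(0, 255), 2, 1))
  out <- histogram_transform(two)
  expect_equal(sort(as.numeric(out)), c(127.5, 255))

  # a full-range uniform ramp is (approximately) its own equalisation
  ramp <- grayscale_image(matrix(0:255, 16, 16))
  out <- histogram_transform(ramp)
  expect_lt(max(abs(unclass(out) - unclass(ramp))), 1 + 1e-9)
})

test_that("local statistics match hand values and the global mean is exact", {
  const <- matrix(7, 5, 5)
  ls <- local_stats(const, 3)
  expect_equal(ls$mu, matrix(7, 5, 5))
  expect_equal(ls$sigma, matrix(0, 5, 5))
  expect_equal(ls$gm, 7)

  m <- matrix(1:9, 3, 3)
  ls <- local_stats(m, 3)
  expect_equal(ls$mu[2, 2], 5)     # mean of 1..9
  expect_equal(ls$gm, mean(m))
  expect_true(all(ls$sigma >= 0))
  expect_error(local_stats(m, 4), "odd")
})

test_that("contrast stretch has the identity limit and matches the pixel-loop oracle", {
  set.seed(5)
  img <- grayscale_image(random_image(6))
  # Q forced to 1 with c = a = 1: exact identity
  out <- contrast_stretch(img, enhance_params(c = 1, a = 1, window = 3),
                          Q_override = 1)
  expect_equal(unclass(out), unclass(img), ignore_attr = TRUE)

  # constant image stays constant for c = a = 1
  cimg <- grayscale_image(matrix(33, 4, 4))
  expect_equal(as.numeric(contrast_stretch(cimg, enhance_params(window = 3))),
               rep(33, 16))

  # oracle equivalence on random 5x5 images
  for (i in 1:10) {
    F <- random_image(5)
    K <- runif(1, 0.2, 2); beta <- runif(1, 0.5, 2)
    cc <- runif(1, 0.5, 1.5); a <- runif(1, 0.8, 1.2)
    got <- contrast_stretch(grayscale_image(F),
                            enhance_params(K = K, beta = beta, c = cc,
                                           a = a, window = 3))
    want <- oracle_contrast_stretch(F, K, beta, cc, a, 3)
    expect_equal(unclass(got), want, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("the mu term supports the multiplicative reading", {
  F <- matrix(c(10, 20, 30, 40), 2, 2)
  pm <- enhance_params(K = 1, beta = 1, c = 1, a = 2, window = 3,
                       mu_term = "multiply")
  ls <- local_stats(F, 3)
  want <- pmin(pmax((1 * ls$gm / (ls$sigma + 1)) * (F - ls$mu) + ls$mu * 2,
                    0), 255)
  expect_equal(unclass(contrast_stretch(grayscale_image(F), pm)), want,
               ignore_attr = TRUE)
})

test_that("enhance is deterministic, range-safe and improves contrast on fixtures", {
  sim <- make_images(n_per_class = 2, seed = 42)
  img <- sim$images[[1]]
  e1 <- enhance(img); e2 <- enhance(img)
  expect_identical(unclass(e1), unclass(e2))

  # constant image -> constant image
  expect_equal(as.numeric(enhance(matrix(50, 8, 8))), rep(50, 64))

  # range safety over many random images
  set.seed(99)
  for (i in 1:100) {
    out <- enhance(random_image(sample(5:12, 1)),
                   enhance_params(window = 3))
    expect_true(min(out) >= 0 && max(out) <= 255)
  }

  # contrast (intensity sd) improves on the low-contrast lesion fixtures
  for (nm in names(sim$images)) {
    expect_gte(sd(as.numeric(enhance(sim$images[[nm]]))),
               sd(as.numeric(sim$images[[nm]])))
  }
})

test_that("parameter validation rejects bad enhancement settings", {
  expect_error(enhance_params(K = 0), "K")
  expect_error(enhance_params(beta = 0), "beta")
  expect_error(enhance_params(window = 4), "odd")
  expect_error(grayscale_image(matrix(-1, 2, 2)), "0, L - 1")
})

test_that("PNG round-trip preserves 8-bit images", {
  path <- withr::local_tempfile(fileext = ".png")
  img <- grayscale_image(matrix(as.numeric(0:63) * 4, 8, 8))
  write_image(img, path)
  back <- read_image(path)
  expect_equal(unclass(back), unclass(img), tolerance = 1e-8,
               ignore_attr = TRUE)
})
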