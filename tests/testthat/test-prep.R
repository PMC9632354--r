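test_that("fft smoothing preserves constants and the identity window", {
  x <- rep(3.7, 40)
  expect_equal(fft_smooth(x, 5), x, tolerance = 1e-12)
  y <- rnorm(25)
  expect_identical(fft_smooth(y, 1), y)
  expect_error(fft_smooth(y, 4), "odd")
  expect_error(fft_smooth(y, 27), "between")
  expect_error(fft_smooth(c(1, NA, 3), 3), "finite")
})

test_that("unit impulse smooths to a centred boxcar of height 1/window", {
  x <- numeric(41); x[21] <- 1
  s5 <- fft_smooth(x, 5)
  expect_equal(s5[19:23], rep(0.2, 5), tolerance = 1e-12)
  expect_equal(sum(abs(s5[-(19:23)])), 0, tolerance = 1e-10)
  s9 <- fft_smooth(x, 9)
  expect_equal(s9[17:25], rep(1 / 9, 9), tolerance = 1e-12)
})

test_that("fft smoothing matches a direct moving-average oracle", {
  set.seed(21)
  x <- rnorm(200)
  w <- 5; m <- (w - 1) / 2
  padded <- c(x[m:1], x, x[length(x):(length(x) - m + 1)])
  oracle <- stats::filter(padded, rep(1 / w, w), sides = 2)
  oracle <- as.numeric(oracle[(m + 1):(m + length(x))])
  expect_equal(fft_smooth(x, w), oracle, tolerance = 1e-10)
})

test_that("fft smoothing is linear", {
  set.seed(31)
  for (i in 1:10) {
    a <- rnorm(64); b <- rnorm(64)
    expect_equal(fft_smooth(a + b, 7),
                 fft_smooth(a, 7) + fft_smooth(b, 7), tolerance = 1e-10)
  }
})

test_that("eigenvalues of the correlation extraction sum to the variable count", {
  set.seed(41)
  for (i in 1:5) {
    n <- sample(60:200, 1)
    x <- matrix(rnorm(n * 11), n, 11)
    # add correlation structure
    x[, 2] <- x[, 1] + 0.5 * x[, 2]
    x[, 7] <- -x[, 3] + 0.3 * x[, 7]
    fm <- fit_factor_model(x)
    expect_equal(sum(fm$eigenvalues), 11, tolerance = 1e-8)
    expect_equal(fm$cumulative[11], 100, tolerance = 1e-8)
    expect_true(all(diff(fm$eigenvalues) <= 1e-10))
    expect_true(all(diff(fm$cumulative) >= -1e-10))
  }
})

test_that("independent columns give near-equal eigenvalues; rank-1 gives (2, 0)", {
  set.seed(51)
  x <- matrix(rnorm(20000 * 11), 20000, 11)
  fm <- fit_factor_model(x)
  expect_equal(fm$percent, rep(100 / 11, 11), tolerance = 0.05)
  y1 <- rnorm(100)
  fm2 <- fit_factor_model(cbind(a = y1, b = 2 * y1 + 1),
                          variance_threshold = 95)
  expect_equal(fm2$eigenvalues, c(2, 0), tolerance = 1e-10)
})

test_that("retention keeps the smallest k reaching the variance threshold", {
  set.seed(61)
  base <- matrix(rnorm(500 * 3), 500, 3)
  x <- cbind(base, base + matrix(rnorm(500 * 3, sd = 0.05), 500, 3),
             matrix(rnorm(500 * 5), 500, 5))
  fm95 <- fit_factor_model(x, variance_threshold = 95)
  expect_equal(fm95$k, which(fm95$cumulative >= 95)[1])
  fm90 <- fit_factor_model(x, variance_threshold = 90)
  expect_lte(fm90$k, fm95$k)
})

test_that("varimax rotation preserves per-variable communalities", {
  set.seed(71)
  for (i in 1:5) {
    base <- matrix(rnorm(300 * 4), 300, 4)
    x <- base %*% matrix(rnorm(44), 4, 11) +
      matrix(rnorm(300 * 11, sd = 0.6), 300, 11)
    fm <- fit_factor_model(x, variance_threshold = 80)
    unrot <- fit_factor_model(x, variance_threshold = 80, rotate = "none")
    expect_equal(rowSums(fm$loadings_rotated^2),
                 rowSums(unrot$loadings_rotated^2), tolerance = 1e-8)
  }
})

test_that("zero-variance and non-finite columns are rejected by name", {
  x <- matrix(rnorm(50 * 3), 50, 3)
  colnames(x) <- c("a", "flat", "c")
  x[, "flat"] <- 7
  expect_error(fit_factor_model(x), "flat")
  x[, "flat"] <- rnorm(50); x[1, 1] <- Inf
  expect_error(fit_factor_model(x), "non-finite")
})

test_that("factor scores centre on the training data and match the two-step oracle", {
  set.seed(81)
  x <- matrix(rnorm(400 * 11), 400, 11)
  x[, 5] <- x[, 1] + rnorm(400, sd = 0.1)
  fm <- fit_factor_model(x, variance_threshold = 90)
  sc <- factor_scores(fm, x)
  expect_equal(colMeans(sc), rep(0, fm$k), tolerance = 1e-8,
               ignore_attr = TRUE)
  # row at the training mean scores zero
  sc0 <- factor_scores(fm, matrix(fm$means, 1))
  expect_equal(as.numeric(sc0), rep(0, fm$k), tolerance = 1e-10)
  # independent standardize-and-multiply oracle
  z <- sweep(sweep(x, 2, fm$means), 2, fm$sds, "/")
  expect_equal(unname(sc), unname(z %*% fm$score_weights), tolerance = 1e-10)
  expect_error(factor_scores(fm, x[, 1:5]), "columns")
})

test_that("factor model serializes to JSON and back", {
  set.seed(91)
  x <- matrix(rnorm(200 * 11), 200, 11)
  fm <- fit_factor_model(x)
  path <- withr::local_tempfile(fileext = ".json")
  write_factor_model(fm, path)
  back <- read_factor_model(path)
  expect_equal(back$eigenvalues, fm$eigenvalues)
  expect_equal(back$k, fm$k)
  expect_equal(unname(back$loadings_rotated), unname(fm$loadings_rotated))
  sc1 <- factor_scores(fm, x[1:5, ])
  sc2 <- factor_scores(back, x[1:5, ])
  expect_equal(unname(sc1), unname(sc2))
})

test_that("explained-variance table reproduces the reporting convention", {
  ev <- explained_variance(c(33.617, 23.615, 13.331, 11.376, 8.212, 5.716))
  expect_equal(ev$cumulative[6], 95.867, tolerance = 1e-9)
  set.seed(13)
  x <- matrix(rnorm(300 * 11), 300, 11)
  fm <- fit_factor_model(x)
  tab <- explained_variance(fm)
  expect_equal(tab$percent, fm$eigenvalues / 11 * 100)
  expect_equal(tab$cumulative, cumsum(tab$percent))
})
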