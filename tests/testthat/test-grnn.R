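test_that("grnn prediction matches the brute-force kernel-average oracle", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(5:40, 1); d <- sample(1:8, 1)
    patterns <- matrix(rnorm(n * d), n, d)
    labels <- rbinom(n, 1, 0.5)
    sigma <- runif(1, 0.2, 3)
    model <- grnn(patterns, labels, sigma)
    q <- rnorm(d)
    expect_equal(grnn_predict(model, q), nw_oracle(patterns, labels, sigma, q),
                 tolerance = 1e-12)
  }
})

test_that("single-pattern and symmetric two-pattern predictions are exact", {
  one <- grnn(matrix(c(1, 2), 1, 2), 1, sigma = 0.7)
  expect_equal(grnn_predict(one, c(50, -3)), 1)
  two <- grnn(matrix(c(0, 1), 2, 1), c(0, 1), sigma = 0.4)
  expect_equal(grnn_predict(two, 0.5), 0.5)
  expect_error(grnn_predict(two, c(1, 2)), "length")
  expect_error(grnn(matrix(0, 1, 1), 2, 1), "binary")
  expect_error(grnn(matrix(0, 1, 1), 0, sigma = 0), "> 0")
})

test_that("prediction stays within label range and is permutation invariant", {
  set.seed(111)
  patterns <- matrix(rnorm(60), 20, 3)
  labels <- rbinom(20, 1, 0.4)
  model <- grnn(patterns, labels, 0.5)
  for (i in 1:20) {
    p <- grnn_predict(model, rnorm(3, sd = 3))
    expect_gte(p, min(labels)); expect_lte(p, max(labels))
  }
  perm <- sample(20)
  shuffled <- grnn(patterns[perm, ], labels[perm], 0.5)
  q <- rnorm(3)
  expect_equal(grnn_predict(model, q), grnn_predict(shuffled, q),
               tolerance = 1e-12)
})

test_that("large sigma limit approaches the label mean; tiny sigma the nearest label", {
  set.seed(121)
  patterns <- matrix(runif(30, -1, 1), 15, 2)
  labels <- rbinom(15, 1, 0.5)
  big <- grnn(patterns, labels, 1e6)
  expect_equal(grnn_predict(big, c(0.2, -0.1)), mean(labels), tolerance = 1e-6)
  tiny <- grnn(patterns, labels, 1e-12)
  q <- c(0.2, -0.1)
  nearest <- which.min(rowSums(sweep(patterns, 2, q)^2))
  expect_equal(grnn_predict(tiny, q), labels[nearest])
})

test_that("classification thresholds at 0.5 with the boundary as fatigue", {
  m <- grnn(matrix(c(0, 1), 2, 1), c(0, 1), sigma = 0.4)
  expect_equal(as.character(grnn_classify(m, 0.5)), "fatigue")
  expect_equal(as.character(grnn_classify(m, 0.05)), "non_fatigue")
  zeros <- grnn(matrix(rnorm(10), 5, 2), rep(0, 5), sigma = 1)
  for (i in 1:5)
    expect_equal(as.character(grnn_classify(zeros, rnorm(2))), "non_fatigue")
})

test_that("leave-one-out MSE matches the per-sample exclusion oracle", {
  set.seed(131)
  for (i in 1:15) {
    n <- sample(4:25, 1); d <- sample(1:5, 1)
    patterns <- matrix(rnorm(n * d), n, d)
    labels <- rbinom(n, 1, 0.5)
    sigma <- runif(1, 0.3, 2)
    expect_equal(loo_mse(patterns, labels, sigma),
                 loo_oracle(patterns, labels, sigma), tolerance = 1e-12)
  }
})

test_that("loo mse limiting cases behave as expected", {
  # coincident patterns with equal labels: each LOO prediction is the other
  same <- matrix(1, 2, 2)
  expect_equal(loo_mse(same, c(1, 1), 0.5), 0)
  # well-separated opposite labels at small sigma: each predicts the other label
  apart <- matrix(c(0, 100), 2, 1)
  expect_equal(loo_mse(apart, c(0, 1), 0.01), 1)
  expect_error(loo_mse(matrix(1, 1, 1), 1, 0.5), "at least 2")
})

test_that("window slicing counts, means and majority labels are correct", {
  set.seed(141)
  x <- matrix(rnorm(980 * 3), 980, 3)
  lab <- rep(1, 980)
  w <- make_windows(x, lab, window = 900, step = 80)
  expect_equal(nrow(w), 2)  # floor((980 - 900)/80) + 1
  expect_equal(unname(unlist(w[1, c("F1", "F2", "F3")])),
               unname(colMeans(x[1:900, ])), tolerance = 1e-10)
  expect_equal(unname(unlist(w[2, c("F1", "F2", "F3")])),
               unname(colMeans(x[81:980, ])), tolerance = 1e-10)
  expect_true(all(w$label == 1))
  w1 <- make_windows(x[1:900, ], lab[1:900], 900, 80)
  expect_equal(nrow(w1), 1)
  expect_error(make_windows(x[1:100, ], lab[1:100], 900, 80), "window")
})

test_that("window labels take the majority with ties going to fatigue", {
  x <- matrix(0, 10, 1)
  expect_equal(make_windows(x, c(rep(0, 6), rep(1, 4)), 10, 1)$label, 0L)
  expect_equal(make_windows(x, c(rep(0, 5), rep(1, 5)), 10, 1)$label, 1L)
  expect_equal(make_windows(x, rep(1, 10), 10, 1)$label, 1L)
})

test_that("grnn model serializes to JSON and back", {
  set.seed(151)
  m <- grnn(matrix(rnorm(20), 10, 2), rbinom(10, 1, 0.5), 0.37,
            decision_threshold = 0.4)
  path <- withr::local_tempfile(fileext = ".json")
  write_grnn(m, path)
  back <- read_grnn(path)
  expect_equal(back$sigma, m$sigma)
  expect_equal(back$decision_threshold, m$decision_threshold)
  q <- rnorm(2)
  expect_equal(grnn_predict(back, q), grnn_predict(m, q))
})

test_that("loo-tuned grnn separates two distant Gaussian classes", {
  set.seed(161)
  n <- 200; d <- 6
  x <- rbind(matrix(rnorm(n * d), n, d),
             matrix(rnorm(n * d, mean = 4), n, d))
  y <- rep(c(0, 1), each = n)
  tr <- sample(2 * n, n)
  d2 <- drowse:::pattern_sqdist(x[tr, ])
  sigmas <- seq(0.05, 2, by = 0.05)
  mses <- vapply(sigmas, function(s) loo_mse(x[tr, ], y[tr], s, d2 = d2),
                 numeric(1))
  best <- grnn(x[tr, ], y[tr], sigmas[which.min(mses)])
  pred <- grnn_classify(best, x[-tr, ])
  truth <- ifelse(y[-tr] == 1, "fatigue", "non_fatigue")
  expect_gte(mean(as.character(pred) == truth), 0.95)
})
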