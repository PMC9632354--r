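test_that("confusion tally matches a brute-force counting oracle", {
  set.seed(181)
  for (i in 1:10) {
    truth <- sample(c("non_fatigue", "fatigue"), 100, replace = TRUE)
    pred <- sample(c("non_fatigue", "fatigue"), 100, replace = TRUE)
    cm <- confusion(pred, truth)
    tp <- tn <- fp <- fn <- 0
    for (j in 1:100) {
      if (truth[j] == "non_fatigue" && pred[j] == "non_fatigue") tp <- tp + 1
      if (truth[j] == "fatigue" && pred[j] == "fatigue") tn <- tn + 1
      if (truth[j] == "fatigue" && pred[j] == "non_fatigue") fp <- fp + 1
      if (truth[j] == "non_fatigue" && pred[j] == "fatigue") fn <- fn + 1
    }
    expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(tp, tn, fp, fn))
  }
  all_right <- confusion(rep("fatigue", 10), rep("fatigue", 10))
  expect_equal(c(all_right$fp, all_right$fn), c(0, 0))
  flipped <- confusion(rep("fatigue", 4), rep("non_fatigue", 4))
  expect_equal(c(flipped$tp, flipped$tn), c(0, 0))
  expect_error(confusion(1:3, 1:4), "equal length")
})

test_that("metric formulas and rounding behave as specified", {
  m <- metrics(confusion_matrix(tp = 1, fn = 1, fp = 0, tn = 0))
  expect_equal(m$recall, 50.0)
  expect_equal(m$precision, 100.0)
  perfect <- metrics(confusion_matrix(10, 0, 0, 10))
  expect_equal(c(perfect$accuracy, perfect$recall, perfect$precision,
                 perfect$f1), rep(100, 4))
  # undefined denominators give NA, not 0
  nopos <- metrics(confusion_matrix(0, 0, 0, 5))
  expect_true(is.na(nopos$recall))
  expect_true(is.na(nopos$precision))
  expect_true(is.na(nopos$f1))
  expect_equal(nopos$accuracy, 100)
})

test_that("round-first and exact F1 modes differ when rounding matters", {
  cm <- confusion_matrix(1671, 157, 127, 2269)
  rf <- metrics(cm, f1_mode = "round_first")
  ex <- metrics(cm, f1_mode = "exact")
  expect_equal(rf$f1, 92.1)
  expect_equal(ex$f1, 92.2)
  pre <- 1671 / (1671 + 127) * 100
  rec <- 1671 / (1671 + 157) * 100
  expect_equal(ex$raw$f1, 2 * pre * rec / (pre + rec))
})

test_that("accuracy is invariant to the positive class; F1 symmetric in pre/rec", {
  set.seed(191)
  truth <- sample(c("non_fatigue", "fatigue"), 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.8, truth,
                 ifelse(truth == "fatigue", "non_fatigue", "fatigue"))
  m1 <- metrics(confusion(pred, truth, positive = "non_fatigue"))
  m2 <- metrics(confusion(pred, truth, positive = "fatigue"))
  expect_equal(m1$accuracy, m2$accuracy)
  # swapping precision and recall leaves F1 unchanged
  swapped <- confusion_matrix(tp = 1671, fn = 127, fp = 157, tn = 2269)
  expect_equal(metrics(swapped)$f1, metrics(confusion_matrix(1671, 157, 127, 2269))$f1)
})

test_that("stratified cross-validation compares models on identical folds", {
  set.seed(201)
  x <- rbind(matrix(rnorm(300), 50, 6), matrix(rnorm(300, mean = 4), 50, 6))
  w <- as.data.frame(x)
  names(w) <- paste0("F", 1:6)
  w$label <- rep(c(0L, 1L), each = 50)
  dummy_majority <- list(
    name = "dummy",
    fit = function(x, y) as.numeric(names(which.max(table(y)))),
    predict = function(fit, newx) rep(fit, nrow(newx)))
  res <- compare_baselines(w, models = list(baseline_knn(k = 1),
                                            dummy_majority),
                           folds = 5, rounds = 2, seed = 3)
  expect_equal(nrow(res), 2)
  expect_equal(res$evaluations, c(10, 10))
  # balanced classes: the majority dummy scores ~50% accuracy
  expect_equal(res$accuracy[res$model == "dummy"], 50, tolerance = 5)
  # classes 4 sd apart: 1-NN is essentially perfect
  expect_gte(res$accuracy[res$model == "knn_k1"], 95)
})

test_that("knn with k = 1 predicts the training set perfectly", {
  set.seed(211)
  x <- matrix(rnorm(60), 20, 3)
  y <- rbinom(20, 1, 0.5)
  spec <- baseline_knn(k = 1)
  fit <- spec$fit(x, y)
  expect_equal(spec$predict(fit, x), y)
})

test_that("random-forest baseline runs when the package is present", {
  skip_if_not_installed("randomForest")
  set.seed(221)
  x <- rbind(matrix(rnorm(150), 25, 6), matrix(rnorm(150, mean = 4), 25, 6))
  w <- as.data.frame(x); names(w) <- paste0("F", 1:6)
  w$label <- rep(c(0L, 1L), each = 25)
  res <- compare_baselines(w, models = list(baseline_random_forest(ntree = 50)),
                           folds = 5, rounds = 1, seed = 2)
  expect_gte(res$accuracy, 90)
})

test_that("pipeline is reproducible and errors name a missing landmark file", {
  cfg <- list(duration = 240, window = 300, step = 60,
              ga = list(population = 20, max_generations = 20))
  r1 <- run_pipeline(cfg, seed = 5)
  r2 <- run_pipeline(cfg, seed = 5)
  expect_identical(r1$metrics$accuracy, r2$metrics$accuracy)
  expect_identical(r1$sigma, r2$sigma)
  expect_identical(r1$windows$split, r2$windows$split)
  expect_error(run_pipeline(list(landmarks = "no/such/file.csv")),
               "no/such/file.csv")
})

test_that("pipeline separates awake from fatigued synthetic sessions", {
  r <- run_pipeline(list(duration = 600, window = 450, step = 80,
                         ga = list(population = 30, max_generations = 40)),
                    seed = 5)
  expect_gte(r$metrics$accuracy, 90)
  expect_true(r$factor_model$k >= 2)
  expect_true(all(c("train", "test", "validate") %in% r$windows$split))
  expect_gt(r$sigma, 0)
})
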