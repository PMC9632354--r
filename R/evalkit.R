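# Confusion-matrix metrics, the end-to-end pipeline, and baseline
# comparison by repeated stratified cross-validation.

#' Confusion matrix from counts
#'
#' @param tp,fn,fp,tn Non-negative counts. `tp` counts samples of the
#'   positive class predicted positive, `fn` positive samples predicted
#'   negative, `fp` negative samples predicted positive, `tn` negative
#'   samples predicted negative.
#' @param positive Name of the positive class (default `"non_fatigue"`,
#'   i.e. normal driving).
#' @return A list of class `"confusion_matrix"`.
#' @examples
#' confusion_matrix(1671, 157, 127, 2269)
#' @export
confusion_matrix <- function(tp, fn, fp, tn, positive = "non_fatigue") {
  for (nm in c("tp", "fn", "fp", "tn")) {
    v <- get(nm)
    check_scalar_number(v, nm)
    if (v < 0) stop_invalid("`", nm, "` must be >= 0")
  }
  if (tp + fn + fp + tn <= 0) stop_invalid("confusion matrix is empty")
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c(x$positive, "other"),
                              predicted = c(x$positive, "other")))
  cat("<confusion_matrix> positive class:", x$positive, "\n")
  print(m)
  invisible(x)
}

#' Tally a confusion matrix from predictions and truths
#'
#' @param predictions,truths Equal-length label vectors (factor, character
#'   or numeric).
#' @param positive The label counted as the positive class (default
#'   `"non_fatigue"`).
#' @return A [confusion_matrix()].
#' @export
confusion <- function(predictions, truths, positive = "non_fatigue") {
  if (length(predictions) != length(truths))
    stop_invalid("`predictions` and `truths` must have equal length")
  if (length(truths) < 1L) stop_invalid("need at least one sample")
  pred_pos <- as.character(predictions) == as.character(positive)
  true_pos <- as.character(truths) == as.character(positive)
  confusion_matrix(tp = sum(pred_pos & true_pos),
                   fn = sum(!pred_pos & true_pos),
                   fp = sum(pred_pos & !true_pos),
                   tn = sum(!pred_pos & !true_pos),
                   positive = as.character(positive))
}

#' Accuracy, recall, precision and F1 from a confusion matrix
#'
#' Percentages: accuracy = (TP+TN)/(FP+FN+TP+TN) x 100, recall =
#' TP/(TP+FN) x 100, precision = TP/(TP+FP) x 100, F1 = 2 Pre Rec /
#' (Pre + Rec). In `"round_first"` mode (default) precision and recall are
#' rounded to one decimal before the F1 formula; `"exact"` uses the
#' unrounded values. A metric whose denominator is zero is reported as `NA`
#' (undefined), never as 0.
#'
#' @param cm A [confusion_matrix()].
#' @param f1_mode `"round_first"` or `"exact"`.
#' @param digits Decimal places reported (default 1).
#' @return A list of class `"metrics_report"` with `accuracy`, `recall`,
#'   `precision`, `f1` (percent, rounded to `digits`), plus the unrounded
#'   values in `raw` and the `f1_mode` used.
#' @examples
#' metrics(confusion_matrix(1671, 157, 127, 2269))
#' @export
metrics <- function(cm, f1_mode = c("round_first", "exact"), digits = 1L) {
  f1_mode <- match.arg(f1_mode)
  if (!inherits(cm, "confusion_matrix"))
    stop_invalid("`cm` must be a confusion_matrix")
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  acc <- (cm$tp + cm$tn) / total * 100
  rec <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) * 100 else NA_real_
  pre <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) * 100 else NA_real_
  pr <- if (f1_mode == "round_first") round(pre, digits) else pre
  rc <- if (f1_mode == "round_first") round(rec, digits) else rec
  f1 <- if (!is.na(pr) && !is.na(rc) && pr + rc > 0)
    2 * pr * rc / (pr + rc) else NA_real_
  structure(list(accuracy = round(acc, digits), recall = round(rec, digits),
                 precision = round(pre, digits), f1 = round(f1, digits),
                 raw = list(accuracy = acc, recall = rec, precision = pre,
                            f1 = f1),
                 f1_mode = f1_mode, positive = cm$positive),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.1f%% | recall %.1f%% | precision %.1f%% | F1 %.1f%% (positive: %s, f1 mode: %s)\n",
              x$accuracy, x$recall, x$precision, x$f1, x$positive, x$f1_mode))
  invisible(x)
}

# stratified split of window indices into train/test/validate fractions
stratified_split <- function(labels, fractions = c(train = 0.55, test = 0.20,
                                                   validate = 0.25)) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop_invalid("split fractions must sum to 1")
  out <- rep(NA_character_, length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    n_train <- round(fractions[[1]] * n)
    n_test <- round(fractions[[2]] * n)
    grp <- rep("validate", n)
    grp[seq_len(n_train)] <- "train"
    if (n_test > 0 && n_train < n)
      grp[(n_train + 1):min(n, n_train + n_test)] <- "test"
    out[idx] <- grp
  }
  out
}

#' Run the full fatigue-identification pipeline
#'
#' Simulates (or ingests) landmark streams, extracts the 11 per-frame
#' features, FFT-smooths each feature series per session, fits the factor
#' model and scores every frame, slices sliding windows, trains the
#' GA-tuned GRNN on the training split, and evaluates on the held-out
#' validation split. Fully reproducible from `(config, seed)`.
#'
#' @param config A list (or path to a YAML file) with optional elements:
#'   `landmarks` (character vector of landmark CSV paths; when absent two
#'   sessions are simulated from `profile`), `profile` (arguments for
#'   [subject_profile()]), `duration` (seconds per simulated session,
#'   default 7200), `fps` (default 15), `smooth_window` (default 5),
#'   `variance_threshold` (default 95), `window`/`step` (frames, defaults
#'   900/80), `split` (train/test/validate fractions, default
#'   0.55/0.20/0.25), `ga` (arguments for [ga_config()]),
#'   `decision_threshold` (default 0.5), `seed` (default 1).
#' @param seed Overrides `config$seed` when given.
#' @return A list of class `"pipeline_result"`: `metrics` (validation
#'   [metrics()]), `confusion`, `model`, `ga`, `factor_model`, `windows`
#'   (with a `split` column), `sigma`, `log` (stage timings), `seed`.
#' @export
run_pipeline <- function(config = list(), seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_invalid("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- function(name, default) if (is.null(config[[name]])) default else config[[name]]
  seed <- if (!is.null(seed)) as.integer(seed) else as.integer(cfg("seed", 1L))
  fps <- cfg("fps", 15)
  duration <- cfg("duration", 7200)
  smooth_window <- cfg("smooth_window", 5L)
  var_threshold <- cfg("variance_threshold", 95)
  window <- cfg("window", 900L)
  step <- cfg("step", 80L)
  split <- unlist(cfg("split", c(train = 0.55, test = 0.20, validate = 0.25)))
  log <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    log[[name]] <<- proc.time()[["elapsed"]] - t0
    val
  }

  sessions <- tick("ingest", {
    if (!is.null(config$landmarks)) {
      lapply(config$landmarks, function(p) {
        if (!file.exists(p)) stop_invalid("landmark file not found: ", p)
        read_landmarks(p)
      })
    } else {
      profile <- do.call(subject_profile, as.list(cfg("profile", list())))
      list(simulate_session(profile, "awake", duration, fps, seed = seed),
           simulate_session(profile, "fatigued", duration, fps, seed = seed + 1L))
    }
  })

  feats <- tick("features", lapply(sessions, extract_features,
                                   freq_window = window, fps = fps))

  smoothed <- tick("smooth", lapply(feats, function(f) {
    for (col in feature_order) f[[col]] <- fft_smooth(f[[col]], smooth_window)
    f
  }))

  all_feats <- do.call(rbind, smoothed)
  fm <- tick("factor_model",
             fit_factor_model(as.matrix(all_feats[feature_order]),
                              variance_threshold = var_threshold))

  windows <- tick("windows", {
    w <- lapply(smoothed, function(f) {
      sc <- factor_scores(fm, as.matrix(f[feature_order]))
      make_windows(sc, f$label, window = window, step = step, t = f$t)
    })
    do.call(rbind, w)
  })

  windows$split <- with_seed(seed + 2L, stratified_split(windows$label, split))
  train <- windows[windows$split == "train", , drop = FALSE]
  holdout <- windows[windows$split == "validate", , drop = FALSE]

  ga_cfg <- do.call(ga_config, utils::modifyList(list(seed = seed + 3L),
                                                 as.list(cfg("ga", list()))))
  fit <- tick("train", train_ga_grnn(train, ga_cfg,
                                     decision_threshold = cfg("decision_threshold", 0.5)))

  res <- tick("evaluate", {
    cols <- window_feature_cols(windows)
    pred <- grnn_classify(fit$model, as.matrix(holdout[cols]))
    truth <- factor(ifelse(holdout$label == 1, "fatigue", "non_fatigue"),
                    levels = c("non_fatigue", "fatigue"))
    confusion(pred, truth, positive = "non_fatigue")
  })

  structure(list(metrics = metrics(res), confusion = res, model = fit$model,
                 ga = fit$ga, factor_model = fm, windows = windows,
                 sigma = fit$model$sigma, log = log, seed = seed),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed:", x$seed, "| sigma:",
      format(x$sigma, digits = 4), "| factors:", x$factor_model$k, "\n")
  cat("windows:", nrow(x$windows), "(",
      sum(x$windows$split == "train"), "train /",
      sum(x$windows$split == "test"), "test /",
      sum(x$windows$split == "validate"), "validate )\n")
  print(x$metrics)
  invisible(x)
}

# ---- baselines ---------------------------------------------------------

#' K-nearest-neighbour baseline classifier
#'
#' Majority vote over the `k` Euclidean-nearest training patterns
#' (distance ties broken by training order; vote ties by the lower label).
#'
#' @param k Number of neighbours (default 5).
#' @return A baseline spec usable with [compare_baselines()].
#' @export
baseline_knn <- function(k = 5L) {
  check_scalar_number(k, "k", positive = TRUE)
  list(name = sprintf("knn_k%d", as.integer(k)),
       fit = function(x, y) list(x = x, y = y, k = as.integer(k)),
       predict = function(fit, newx) {
         apply(newx, 1, function(q) {
           d2 <- rowSums(sweep(fit$x, 2, q)^2)
           nn <- order(d2)[seq_len(min(fit$k, length(d2)))]
           votes <- table(fit$y[nn])
           as.numeric(names(votes)[which.max(votes)])
         })
       })
}

#' Random-forest baseline classifier
#'
#' Thin wrapper over the `randomForest` package (required only when this
#' baseline is used).
#'
#' @param ntree Number of trees (default 200).
#' @return A baseline spec usable with [compare_baselines()].
#' @export
baseline_random_forest <- function(ntree = 200L) {
  list(name = "random_forest",
       fit = function(x, y) {
         if (!requireNamespace("randomForest", quietly = TRUE))
           stop_invalid("the random-forest baseline needs the 'randomForest' package")
         randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                    ntree = ntree)
       },
       predict = function(fit, newx) {
         as.numeric(as.character(stats::predict(fit, newx)))
       })
}

#' GRNN baseline (fixed or GA-tuned smoothing factor)
#'
#' @param sigma Fixed smoothing factor; when `NULL` the factor is tuned per
#'   fold by [ga_optimize()] on the leave-one-out MSE.
#' @param ga Optional [ga_config()] for the tuned variant.
#' @return A baseline spec usable with [compare_baselines()].
#' @export
baseline_grnn <- function(sigma = NULL, ga = NULL) {
  list(name = if (is.null(sigma)) "ga_grnn" else sprintf("grnn_sigma%.3g", sigma),
       fit = function(x, y) {
         s <- sigma
         if (is.null(s)) {
           cfg <- if (is.null(ga)) ga_config(population = 30L, max_generations = 60L)
                  else ga
           d2 <- pattern_sqdist(x)
           s <- ga_optimize(function(v) loo_mse(x, y, v, d2 = d2), cfg)$best_sigma
         }
         grnn(x, y, s)
       },
       predict = function(fit, newx) {
         as.numeric(grnn_classify(fit, newx) == "fatigue")
       })
}

#' Compare classifiers by repeated stratified cross-validation
#'
#' Runs `rounds` repetitions of stratified `folds`-fold cross-validation;
#' every model sees identical folds. Metrics are computed on the pooled
#' out-of-fold predictions of each round and averaged over rounds.
#'
#' @param windows Window data frame from [make_windows()] (columns `F*` and
#'   `label`).
#' @param models List of baseline specs (e.g. [baseline_knn()],
#'   [baseline_random_forest()], [baseline_grnn()]).
#' @param folds Folds per round (default 5).
#' @param rounds Repetitions (default 10).
#' @param seed Integer seed for the fold assignments.
#' @param positive Positive class for the metrics (default `"non_fatigue"`).
#' @return Data frame with one row per model: mean accuracy, recall,
#'   precision, F1 over rounds, plus `evaluations` (= folds x rounds).
#' @export
compare_baselines <- function(windows,
                              models = list(baseline_knn(),
                                            baseline_random_forest(),
                                            baseline_grnn(sigma = 0.5)),
                              folds = 5L, rounds = 10L, seed = 1L,
                              positive = "non_fatigue") {
  cols <- window_feature_cols(windows)
  x <- as.matrix(windows[cols])
  y <- windows$label
  check_scalar_number(folds, "folds", positive = TRUE)
  check_scalar_number(rounds, "rounds", positive = TRUE)
  if (min(table(y)) < folds)
    stop_invalid("need at least `folds` samples per class for stratification")
  with_seed(seed, {
    fold_sets <- lapply(seq_len(rounds), function(r) {
      f <- rep(NA_integer_, length(y))
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        f[idx] <- rep_len(seq_len(folds), length(idx))
      }
      f
    })
    rows <- lapply(models, function(mod) {
      per_round <- vapply(seq_len(rounds), function(r) {
        f <- fold_sets[[r]]
        pred <- rep(NA_real_, length(y))
        for (k in seq_len(folds)) {
          tr <- f != k
          fit <- mod$fit(x[tr, , drop = FALSE], y[tr])
          pred[!tr] <- mod$predict(fit, x[!tr, , drop = FALSE])
        }
        lab <- function(v) ifelse(v == 1, "fatigue", "non_fatigue")
        m <- metrics(confusion(lab(pred), lab(y), positive = positive))
        c(m$raw$accuracy, m$raw$recall, m$raw$precision, m$raw$f1)
      }, numeric(4))
      data.frame(model = mod$name,
                 accuracy = mean(per_round[1, ]),
                 recall = mean(per_round[2, ]),
                 precision = mean(per_round[3, ]),
                 f1 = mean(per_round[4, ]),
                 evaluations = folds * rounds)
    })
    do.call(rbind, rows)
  })
}
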