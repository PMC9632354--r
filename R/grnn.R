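# Generalized regression neural network (Specht-style Nadaraya-Watson
# kernel classifier) over sliding-window factor-score samples.

#' Construct a GRNN model
#'
#' A one-pass kernel estimator: the prediction for a query is the
#' Gaussian-kernel-weighted average of the stored training labels,
#' \deqn{y(X) = \frac{\sum_i Y_i \exp[-\|X - X_i\|^2 / 2\sigma^2]}
#'                   {\sum_i \exp[-\|X - X_i\|^2 / 2\sigma^2]},}
#' controlled by the single smoothing factor \eqn{\sigma}.
#'
#' @param patterns n x d numeric matrix of training patterns.
#' @param labels Length-n vector of binary labels (0/1).
#' @param sigma Smoothing factor, > 0.
#' @param decision_threshold Classification cut on the predicted fraction
#'   (default 0.5; the boundary is classified as fatigue).
#' @return A list of class `"grnn"`.
#' @examples
#' m <- grnn(matrix(c(0, 1), 2, 1), c(0, 1), sigma = 0.3)
#' grnn_predict(m, 0.5)
#' @export
grnn <- function(patterns, labels, sigma, decision_threshold = 0.5) {
  patterns <- as.matrix(patterns)
  if (!is.numeric(patterns) || nrow(patterns) < 1L || any(!is.finite(patterns)))
    stop_invalid("`patterns` must be a non-empty finite numeric matrix")
  labels <- as.numeric(labels)
  if (length(labels) != nrow(patterns))
    stop_invalid("`labels` length must match nrow(patterns)")
  if (!all(labels %in% c(0, 1)))
    stop_invalid("`labels` must be binary 0/1")
  check_scalar_number(sigma, "sigma", positive = TRUE)
  check_prob(decision_threshold, "decision_threshold")
  structure(list(patterns = patterns, labels = labels, sigma = sigma,
                 decision_threshold = decision_threshold),
            class = "grnn")
}

#' @export
print.grnn <- function(x, ...) {
  cat("<grnn>", nrow(x$patterns), "patterns, d =", ncol(x$patterns),
      ", sigma =", format(x$sigma, digits = 4),
      ", threshold =", x$decision_threshold, "\n")
  invisible(x)
}

# squared Euclidean distances from each row of `patterns` to `query`
sqdist_to <- function(patterns, query) {
  d <- sweep(patterns, 2, query)
  rowSums(d * d)
}

#' GRNN prediction for a query vector
#'
#' Exact kernel-weighted label average. Weights are computed relative to
#' the nearest pattern so the estimator degrades gracefully to the nearest
#' pattern's label (ties averaged) instead of underflowing at small sigma.
#'
#' @param model A [grnn()] model.
#' @param query Numeric vector of length `ncol(model$patterns)`, or a
#'   matrix of query rows.
#' @return Predicted fraction(s) in `[min(labels), max(labels)]`.
#' @export
grnn_predict <- function(model, query) {
  if (!inherits(model, "grnn")) stop_invalid("`model` must be a grnn")
  d <- ncol(model$patterns)
  if (is.matrix(query) || is.data.frame(query)) {
    q <- as.matrix(query)
    if (ncol(q) != d)
      stop_invalid("query has ", ncol(q), " columns; model expects ", d)
    return(vapply(seq_len(nrow(q)),
                  function(i) grnn_predict_one(model, q[i, ]), numeric(1)))
  }
  if (length(query) != d)
    stop_invalid("query has length ", length(query), "; model expects ", d)
  grnn_predict_one(model, as.numeric(query))
}

grnn_predict_one <- function(model, query) {
  if (any(!is.finite(query))) stop_invalid("query contains non-finite values")
  d2 <- sqdist_to(model$patterns, query)
  ex <- exp(-(d2 - min(d2)) / (2 * model$sigma^2))
  s <- sum(ex)
  if (!is.finite(s) || s <= 0) {            # defensive: nearest-pattern fallback
    return(model$labels[which.min(d2)])
  }
  sum(model$labels * ex) / s
}

#' Classify a query with a GRNN model
#'
#' @inheritParams grnn_predict
#' @return Factor with levels `non_fatigue`, `fatigue`; fatigue iff the
#'   predicted fraction is at or above the decision threshold.
#' @export
grnn_classify <- function(model, query) {
  p <- grnn_predict(model, query)
  factor(ifelse(p >= model$decision_threshold, "fatigue", "non_fatigue"),
         levels = c("non_fatigue", "fatigue"))
}

#' Leave-one-out mean squared error of a GRNN
#'
#' Predicts each training sample with itself excluded from the kernel sums
#' and returns the mean squared error against its label. This is the
#' genetic-algorithm fitness \eqn{MSE(\sigma)}; including the sample in its
#' own prediction would drive the error to 0 as \eqn{\sigma \to 0} for any
#' data.
#'
#' @param patterns n x d matrix (n >= 2).
#' @param labels Length-n binary labels.
#' @param sigma Smoothing factor, > 0.
#' @param d2 Optional precomputed n x n squared-distance matrix (for
#'   repeated evaluation at different sigma).
#' @return Mean squared error.
#' @export
loo_mse <- function(patterns, labels, sigma, d2 = NULL) {
  patterns <- as.matrix(patterns)
  n <- nrow(patterns)
  if (n < 2L) stop_invalid("leave-one-out needs at least 2 samples")
  labels <- as.numeric(labels)
  if (length(labels) != n) stop_invalid("`labels` length must match nrow(patterns)")
  check_scalar_number(sigma, "sigma", positive = TRUE)
  if (is.null(d2)) d2 <- pattern_sqdist(patterns)
  preds <- loo_predict(d2, labels, sigma)
  mean((preds - labels)^2)
}

# full pairwise squared-distance matrix
pattern_sqdist <- function(patterns) {
  g <- tcrossprod(patterns)
  sq <- diag(g)
  d2 <- outer(sq, sq, "+") - 2 * g
  d2[d2 < 0] <- 0
  d2
}

# leave-one-out predictions given the pairwise distance matrix
loo_predict <- function(d2, labels, sigma) {
  n <- nrow(d2)
  diag(d2) <- Inf
  mins <- apply(d2, 1, min)
  w <- exp(-(d2 - mins) / (2 * sigma^2))
  diag(w) <- 0
  s <- rowSums(w)
  preds <- as.numeric(w %*% labels) / s
  bad <- !is.finite(preds)
  if (any(bad)) {
    nn <- apply(d2, 1, which.min)
    preds[bad] <- labels[nn[bad]]
  }
  preds
}

#' Slice frame-level scores into sliding-window samples
#'
#' Windows start at frame 1 and advance by `step`; each window's feature
#' vector is the per-column mean of the score rows it covers and its label
#' the majority of the frame labels (ties go to fatigue, the
#' safety-conservative class).
#'
#' @param score_rows Frames x d numeric matrix of factor scores.
#' @param labels Per-frame binary labels (0 = non-fatigue, 1 = fatigue).
#' @param window Window length in frames (default 900).
#' @param step Sliding step in frames (default 80).
#' @param t Optional per-frame timestamps; window start/end times are
#'   reported when given.
#' @return Data frame with columns `F1..Fd`, `label`, `t_start`, `t_end`;
#'   `floor((T - window)/step) + 1` rows.
#' @examples
#' s <- matrix(rnorm(980 * 2), 980, 2)
#' nrow(make_windows(s, rep(1, 980), 900, 80))  # 2
#' @export
make_windows <- function(score_rows, labels, window = 900L, step = 80L,
                         t = NULL) {
  x <- as.matrix(score_rows)
  n <- nrow(x)
  check_scalar_number(window, "window", positive = TRUE)
  check_scalar_number(step, "step", positive = TRUE)
  window <- as.integer(window); step <- as.integer(step)
  if (n < window)
    stop_invalid("need at least `window` = ", window, " frames, got ", n)
  labels <- as.numeric(labels)
  if (length(labels) != n) stop_invalid("`labels` length must match frames")
  starts <- seq(1L, n - window + 1L, by = step)
  cs <- rbind(0, apply(x, 2, cumsum))
  csl <- c(0, cumsum(labels))
  feats <- (cs[starts + window, , drop = FALSE] -
              cs[starts, , drop = FALSE]) / window
  frac1 <- (csl[starts + window] - csl[starts]) / window
  lab <- as.integer(frac1 >= 0.5)
  out <- as.data.frame(feats)
  if (is.null(colnames(x))) names(out) <- paste0("F", seq_len(ncol(x)))
  out$label <- lab
  if (!is.null(t)) {
    out$t_start <- t[starts]
    out$t_end <- t[starts + window - 1L]
  } else {
    out$t_start <- starts - 1L
    out$t_end <- starts + window - 2L
  }
  out
}

# feature-column names of a window data frame
window_feature_cols <- function(windows) {
  setdiff(names(windows), c("label", "t_start", "t_end", "split"))
}

#' Serialize a GRNN model to JSON
#'
#' @param model A [grnn()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grnn <- function(model, path) {
  if (!inherits(model, "grnn")) stop_invalid("`model` must be a grnn")
  obj <- list(patterns = as.data.frame(model$patterns),
              labels = model$labels, sigma = model$sigma,
              decision_threshold = model$decision_threshold,
              feature_order = colnames(model$patterns))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized GRNN model
#'
#' @param path JSON file written by [write_grnn()].
#' @return A `grnn` model.
#' @export
read_grnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grnn(as.matrix(obj$patterns), obj$labels, obj$sigma, obj$decision_threshold)
}
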