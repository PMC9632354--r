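# Signal denoising and factor-analysis dimensionality reduction.
#
# Smoothing is a zero-phase moving average realized as FFT-based circular
# convolution over a reflection-padded series. Factor extraction is
# principal-component based on the correlation matrix (eigenvalues sum to
# the number of variables), with varimax rotation of the retained loadings
# and regression-method score weights.

#' FFT-based zero-phase smoothing
#'
#' Applies a moving average of odd length `window` by circular convolution
#' in the frequency domain, with edge reflection padding so the output has
#' the input's length and no phase shift.
#'
#' @param values Numeric series (finite, length >= 1).
#' @param window Odd integer, `1 <= window <= length(values)` (default 5).
#' @return Smoothed numeric series of the same length.
#' @examples
#' x <- c(0, 0, 0, 0, 1, 0, 0, 0, 0)
#' fft_smooth(x, 5)
#' @export
fft_smooth <- function(values, window = 5L) {
  if (!is.numeric(values) || length(values) < 1L || any(!is.finite(values)))
    stop_invalid("`values` must be a finite numeric series")
  check_scalar_number(window, "window")
  window <- as.integer(window)
  if (window %% 2L == 0L) stop_invalid("`window` must be odd")
  if (window < 1L || window > length(values))
    stop_invalid("`window` must be between 1 and length(values)")
  if (window == 1L) return(values)
  m <- (window - 1L) %/% 2L
  n <- length(values)
  padded <- c(values[m:1], values, values[n:(n - m + 1L)])
  len <- length(padded)
  kernel <- numeric(len)
  kernel[c(seq_len(m + 1L), (len - m + 1L):len)] <- 1 / window
  sm <- Re(stats::fft(stats::fft(padded) * stats::fft(kernel), inverse = TRUE)) / len
  sm[(m + 1L):(m + n)]
}

#' Fit a principal-component factor model
#'
#' Standardizes the columns, eigendecomposes the correlation matrix, keeps
#' the smallest number of factors whose cumulative explained variance
#' reaches `variance_threshold` percent (default 95), varimax-rotates the
#' retained loadings, and derives regression-method score weights.
#'
#' @param feature_table Numeric matrix or data frame (samples x variables),
#'   at least 2 samples per variable, no zero-variance column.
#' @param variance_threshold Retention threshold in percent (default 95).
#' @param rotate `"varimax"` (default) or `"none"`.
#' @return A list of class `"factor_model"`: `eigenvalues`, `percent`,
#'   `cumulative` (all length = number of variables), `loadings_rotated`
#'   (variables x k), `score_weights` (variables x k), `k`, `means`, `sds`,
#'   `variables`.
#' @examples
#' x <- matrix(rnorm(600), 100, 6)
#' fit_factor_model(x, variance_threshold = 90)$k
#' @export
fit_factor_model <- function(feature_table, variance_threshold = 95,
                             rotate = c("varimax", "none")) {
  rotate <- match.arg(rotate)
  x <- as.matrix(feature_table)
  if (!is.numeric(x)) stop_invalid("`feature_table` must be numeric")
  if (any(!is.finite(x))) stop_invalid("`feature_table` contains non-finite entries")
  p <- ncol(x)
  if (nrow(x) < 2L) stop_invalid("need at least 2 samples")
  check_scalar_number(variance_threshold, "variance_threshold", positive = TRUE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(p))
  sds <- apply(x, 2, stats::sd)
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero))
    stop_invalid("zero-variance column(s): ",
                 paste(colnames(x)[zero], collapse = ", "))
  means <- colMeans(x)
  z <- scale(x, center = means, scale = sds)
  rmat <- stats::cor(z)
  ev <- eigen(rmat, symmetric = TRUE)
  eigenvalues <- pmax(ev$values, 0)
  percent <- eigenvalues / p * 100
  cumulative <- cumsum(percent)
  k <- which(cumulative >= variance_threshold)[1]
  if (is.na(k)) k <- p
  loadings <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eigenvalues[seq_len(k)]), k)
  rownames(loadings) <- colnames(x)
  if (rotate == "varimax" && k > 1L) {
    vm <- stats::varimax(loadings, normalize = TRUE)
    loadings <- loadings %*% vm$rotmat
  }
  colnames(loadings) <- paste0("F", seq_len(k))
  score_weights <- tryCatch(solve(rmat, loadings),
                            error = function(e) MASS::ginv(rmat) %*% loadings)
  rownames(score_weights) <- colnames(x)
  structure(list(eigenvalues = eigenvalues, percent = percent,
                 cumulative = cumulative, loadings_rotated = loadings,
                 score_weights = score_weights, k = k,
                 means = means, sds = sds, variables = colnames(x),
                 variance_threshold = variance_threshold, rotate = rotate),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("<factor_model>", length(x$variables), "variables,", x$k,
      "factors retained (cumulative",
      sprintf("%.3f%%", x$cumulative[x$k]), ")\n")
  tab <- explained_variance(x)
  print(utils::head(tab, x$k), row.names = FALSE)
  invisible(x)
}

#' Explained-variance table of a factor model
#'
#' Reporting convention: `percent = eigenvalue / p * 100` with `p` the
#' number of variables, `cumulative` the running percent sum (last entry
#' 100 for a correlation-matrix extraction).
#'
#' @param model A [fit_factor_model()] result, or a numeric vector of
#'   per-component percentages from which only the cumulative column is
#'   built.
#' @return Data frame with columns `component`, `eigenvalue`, `percent`,
#'   `cumulative`.
#' @export
explained_variance <- function(model) {
  if (inherits(model, "factor_model")) {
    data.frame(component = seq_along(model$eigenvalues),
               eigenvalue = model$eigenvalues,
               percent = model$percent,
               cumulative = model$cumulative)
  } else {
    pct <- as.numeric(model)
    if (any(!is.finite(pct)) || any(pct < 0))
      stop_invalid("percentages must be non-negative and finite")
    data.frame(component = seq_along(pct),
               eigenvalue = NA_real_,
               percent = pct,
               cumulative = cumsum(pct))
  }
}

#' Factor scores for new observations
#'
#' Standardizes rows with the model's training means/sds and multiplies by
#' the regression-method score weights. On the training table the score
#' columns have mean zero.
#'
#' @param model A fitted [fit_factor_model()].
#' @param feature_rows Matrix or data frame with the model's column layout.
#' @return Samples x k numeric matrix of factor scores.
#' @export
factor_scores <- function(model, feature_rows) {
  if (!inherits(model, "factor_model"))
    stop_invalid("`model` must be a factor_model")
  x <- as.matrix(feature_rows)
  if (ncol(x) != length(model$variables))
    stop_invalid("`feature_rows` has ", ncol(x), " columns; model expects ",
                 length(model$variables))
  if (any(!is.finite(x))) stop_invalid("`feature_rows` contains non-finite entries")
  z <- scale(x, center = model$means, scale = model$sds)
  s <- z %*% model$score_weights
  colnames(s) <- colnames(model$score_weights)
  s
}

#' Serialize a factor model to JSON
#'
#' @param model A [fit_factor_model()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_factor_model <- function(model, path) {
  if (!inherits(model, "factor_model")) stop_invalid("`model` must be a factor_model")
  obj <- unclass(model)
  obj$loadings_rotated <- as.data.frame(obj$loadings_rotated)
  obj$score_weights <- as.data.frame(obj$score_weights)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized factor model
#'
#' @param path JSON file written by [write_factor_model()].
#' @return A `factor_model`.
#' @export
read_factor_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$loadings_rotated <- as.matrix(obj$loadings_rotated)
  obj$score_weights <- as.matrix(obj$score_weights)
  rownames(obj$loadings_rotated) <- obj$variables
  rownames(obj$score_weights) <- obj$variables
  obj$means <- stats::setNames(as.numeric(obj$means), obj$variables)
  obj$sds <- stats::setNames(as.numeric(obj$sds), obj$variables)
  structure(obj, class = "factor_model")
}
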