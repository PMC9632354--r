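# internal validators and RNG scoping shared across modules

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`", name, "` must be a single finite number")
  if (positive && x <= 0)
    stop_invalid("`", name, "` must be > 0")
  invisible(x)
}

check_prob <- function(x, name) {
  check_scalar_number(x, name)
  if (x < 0 || x > 1) stop_invalid("`", name, "` must be in [0, 1]")
  invisible(x)
}

# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Euclidean norm of rows of a 2-column matrix, or of a single vector
row_norms <- function(m) sqrt(rowSums(m^2))

vnorm <- function(v) sqrt(sum(v^2))

as_point_matrix <- function(pts, n, name) {
  pts <- as.matrix(pts)
  if (!is.numeric(pts) || nrow(pts) != n || ncol(pts) != 2L)
    stop_invalid("`", name, "` must be a ", n, " x 2 numeric matrix of (x, y) points")
  if (!all(is.finite(pts)))
    stop_invalid("`", name, "` contains non-finite coordinates")
  pts
}
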