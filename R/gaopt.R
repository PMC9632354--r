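# Real-coded genetic algorithm for the GRNN smoothing factor.
#
# Chromosome = one real gene (sigma). Tournament selection (k = 3),
# arithmetic blend crossover, Gaussian mutation clipped to the bounds,
# elitism of 1. The fitness is the leave-one-out MSE of the GRNN.

#' Genetic algorithm configuration
#'
#' Defaults follow the standard small-population real-coded setup:
#' population 80, crossover probability 0.7, mutation probability 0.25, at
#' most 200 generations, sigma searched on (0, 2\] (the lower bound opened
#' by `eps` because sigma = 0 is undefined in the GRNN kernel).
#'
#' @param population Number of chromosomes (>= 2).
#' @param p_crossover,p_mutation Operator probabilities in \[0, 1\].
#' @param max_generations Generation cap.
#' @param bounds Length-2 sigma search interval.
#' @param eps Amount by which the lower bound is opened when it is 0.
#' @param fitness_threshold Early-stop MSE threshold (default 0.03).
#' @param stall_generations Early stop after this many generations without
#'   improvement once the threshold is reached (default 25).
#' @param stop_rule `"threshold_stall"` (default: stop at the generation cap
#'   or earlier when best fitness <= threshold and stalled) or `"max_only"`
#'   (always run the full generation budget).
#' @param seed Integer seed; identical seeds give identical runs.
#' @return A list of class `"ga_config"`.
#' @export
ga_config <- function(population = 80L, p_crossover = 0.7, p_mutation = 0.25,
                      max_generations = 200L, bounds = c(0, 2), eps = 1e-6,
                      fitness_threshold = 0.03, stall_generations = 25L,
                      stop_rule = c("threshold_stall", "max_only"),
                      seed = 1L) {
  stop_rule <- match.arg(stop_rule)
  check_scalar_number(population, "population", positive = TRUE)
  if (population < 2) stop_invalid("`population` must be >= 2")
  check_prob(p_crossover, "p_crossover")
  check_prob(p_mutation, "p_mutation")
  check_scalar_number(max_generations, "max_generations", positive = TRUE)
  check_scalar_number(fitness_threshold, "fitness_threshold")
  check_scalar_number(stall_generations, "stall_generations", positive = TRUE)
  if (length(bounds) != 2L || !all(is.finite(bounds)) || bounds[1] >= bounds[2])
    stop_invalid("`bounds` must be an ordered length-2 interval")
  lower <- if (bounds[1] <= 0) bounds[1] + eps else bounds[1]
  structure(list(population = as.integer(population),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 max_generations = as.integer(max_generations),
                 bounds = c(lower, bounds[2]),
                 fitness_threshold = fitness_threshold,
                 stall_generations = as.integer(stall_generations),
                 stop_rule = stop_rule, seed = as.integer(seed)),
            class = "ga_config")
}

eval_fitness <- function(fitness, sigma, cache) {
  key <- sprintf("%.17g", sigma)
  if (!is.null(cache[[key]])) return(cache[[key]])
  f <- fitness(sigma)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f))
    stop_invalid("fitness returned a non-finite value at sigma = ",
                 format(sigma, digits = 10))
  cache[[key]] <- f
  f
}

#' Evolve one GA generation
#'
#' Produces the next population from the current one: the best parent
#' survives unchanged (elitism of 1); the remaining slots are filled by
#' tournament selection (k = 3), arithmetic blend crossover with probability
#' `p_crossover`, and Gaussian mutation (sd = 5% of the bound width,
#' clipped to the bounds) with probability `p_mutation`. Consumes the
#' current R random number stream.
#'
#' @param population Numeric vector of sigma chromosomes.
#' @param fitnesses Fitness (MSE) of each chromosome; lower is better.
#' @param config A [ga_config()].
#' @return Numeric vector of the same length: the next population.
#' @export
evolve_generation <- function(population, fitnesses, config) {
  if (length(population) != length(fitnesses))
    stop_invalid("`population` and `fitnesses` must have the same length")
  n <- length(population)
  lo <- config$bounds[1]; hi <- config$bounds[2]
  mut_sd <- 0.05 * (hi - lo)
  tournament <- function() {
    idx <- sample.int(n, min(3L, n))
    idx[which.min(fitnesses[idx])]
  }
  children <- numeric(n)
  children[1] <- population[which.min(fitnesses)]   # elite
  i <- 2L
  while (i <= n) {
    p1 <- population[tournament()]
    p2 <- population[tournament()]
    if (stats::runif(1) < config$p_crossover) {
      a <- stats::runif(1)
      c1 <- a * p1 + (1 - a) * p2
      c2 <- (1 - a) * p1 + a * p2
    } else {
      c1 <- p1; c2 <- p2
    }
    for (ch in c(c1, c2)) {
      if (i > n) break
      if (stats::runif(1) < config$p_mutation)
        ch <- ch + stats::rnorm(1, sd = mut_sd)
      children[i] <- min(hi, max(lo, ch))
      i <- i + 1L
    }
  }
  children
}

#' Optimize the GRNN smoothing factor by genetic search
#'
#' Minimizes `fitness(sigma)` (typically [loo_mse()]) over the configured
#' bounds. Stops at the generation cap, or earlier (under the default stop
#' rule) once the best fitness is at or below `fitness_threshold` and has
#' not improved for `stall_generations` generations.
#'
#' @param fitness Function sigma -> finite MSE.
#' @param config A [ga_config()].
#' @return A list of class `"ga_result"`: `best_sigma`, `best_fitness`,
#'   `history` (data frame with per-generation `best` and `mean` fitness),
#'   `generations_run`, `evaluations`.
#' @examples
#' r <- ga_optimize(function(s) (s - 0.5)^2,
#'                  ga_config(population = 30, max_generations = 40, seed = 2))
#' r$best_sigma
#' @export
ga_optimize <- function(fitness, config = ga_config()) {
  if (!inherits(config, "ga_config"))
    stop_invalid("`config` must be created by ga_config()")
  if (!is.function(fitness)) stop_invalid("`fitness` must be a function")
  cache <- new.env(parent = emptyenv())
  with_seed(config$seed, {
    lo <- config$bounds[1]; hi <- config$bounds[2]
    pop <- stats::runif(config$population, lo, hi)
    best_hist <- mean_hist <- numeric(config$max_generations)
    best_sigma <- NA_real_; best_fit <- Inf; stall <- 0L
    gen <- 0L
    for (gen in seq_len(config$max_generations)) {
      fits <- vapply(pop, function(s) eval_fitness(fitness, s, cache), numeric(1))
      gbest <- which.min(fits)
      if (fits[gbest] < best_fit - 1e-15) {
        best_fit <- fits[gbest]; best_sigma <- pop[gbest]; stall <- 0L
      } else {
        stall <- stall + 1L
      }
      best_hist[gen] <- best_fit
      mean_hist[gen] <- mean(fits)
      if (config$stop_rule == "threshold_stall" &&
          best_fit <= config$fitness_threshold &&
          stall >= config$stall_generations) break
      if (gen < config$max_generations)
        pop <- evolve_generation(pop, fits, config)
    }
    structure(list(best_sigma = best_sigma, best_fitness = best_fit,
                   history = data.frame(generation = seq_len(gen),
                                        best = best_hist[seq_len(gen)],
                                        mean = mean_hist[seq_len(gen)]),
                   generations_run = gen,
                   evaluations = length(ls(cache))),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result> best sigma:", format(x$best_sigma, digits = 6),
      "| best fitness (MSE):", format(x$best_fitness, digits = 6),
      "| generations:", x$generations_run, "\n")
  invisible(x)
}

#' Tune a GRNN on window samples with the genetic algorithm
#'
#' Convenience wrapper: precomputes the pairwise distance matrix once, runs
#' [ga_optimize()] on the leave-one-out MSE, and returns the fitted model.
#'
#' @param windows Window data frame from [make_windows()].
#' @param config A [ga_config()].
#' @param decision_threshold Classification cut for the returned model.
#' @return List with `model` ([grnn()]), `ga` (`ga_result`).
#' @export
train_ga_grnn <- function(windows, config = ga_config(),
                          decision_threshold = 0.5) {
  cols <- window_feature_cols(windows)
  patterns <- as.matrix(windows[cols])
  labels <- windows$label
  d2 <- pattern_sqdist(patterns)
  res <- ga_optimize(function(s) loo_mse(patterns, labels, s, d2 = d2), config)
  list(model = grnn(patterns, labels, res$best_sigma, decision_threshold),
       ga = res)
}
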