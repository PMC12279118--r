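#' Define a box-constrained search space
#'
#' All optimizers in this package search a `d`-dimensional box. The default
#' unit box `[0, 1]^d` is the domain used throughout for both continuous
#' benchmark problems and binary feature-selection encodings.
#'
#' @param dim Positive integer, the dimensionality `d`.
#' @param lower Lower bounds; scalar recycled to length `dim`, or a vector of
#'   length `dim`.
#' @param upper Upper bounds, recycled like `lower`. Must satisfy
#'   `lower[j] < upper[j]` for every dimension.
#' @return An object of class `"search_space"`: a list with elements `dim`,
#'   `lower` and `upper`.
#' @examples
#' sp <- search_space(8)
#' sp$upper
#' @export
search_space <- function(dim, lower = 0, upper = 1) {
  stopifnot(is.numeric(dim), length(dim) == 1, dim >= 1, dim == round(dim))
  dim <- as.integer(dim)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("search space bounds must be finite")
  if (any(lower >= upper))
    stop("every lower bound must be strictly below its upper bound")
  structure(list(dim = dim, lower = lower, upper = upper),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("<search_space> %d dimensions\n", x$dim))
  cat("  lower:", paste(signif(x$lower, 4), collapse = " "), "\n")
  cat("  upper:", paste(signif(x$upper, 4), collapse = " "), "\n")
  invisible(x)
}

#' Clamp a vector to the bounds of a search space
#'
#' Componentwise clipping: values below the lower bound are set to it, values
#' above the upper bound likewise. Idempotent. This is the bound-handling
#' rule applied after every position update in every optimizer here.
#'
#' @param v Numeric vector of length `space$dim`.
#' @param space A [search_space()].
#' @return The clipped vector.
#' @export
clip_to_bounds <- function(v, space) {
  if (length(v) != space$dim)
    stop("dimension mismatch: vector has length ", length(v),
         " but the space has ", space$dim, " dimensions")
  pmin(space$upper, pmax(space$lower, v))
}

# Matrix version used in the optimizer inner loops (rows = agents).
clip_rows <- function(P, space) {
  P <- sweep(P, 2, space$lower, pmax)
  sweep(P, 2, space$upper, pmin)
}

# Evaluate `seed` handling: run expr with a locally seeded RNG, restoring the
# caller's RNG state afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Derive a reproducible child seed
#'
#' Mixes a base seed with one or more labels (algorithm tag, run index, ...)
#' into an integer below 2^31, so independent experiment arms get
#' reproducible, distinct randomness from one base seed.
#'
#' @param seed Base integer seed.
#' @param ... Labels (coerced to character) identifying the arm.
#' @return An integer seed.
#' @examples
#' derive_seed(1, "dtoprs", 3)
#' @export
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), as.character))
  h <- as.double(seed %% 2147483647)
  for (p in parts) {
    for (ch in utf8ToInt(p)) h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Initialize a population of agents
#'
#' Positions are drawn i.i.d. uniform within the bounds; velocities start at
#' zero (the agents sit still until an update rule moves them, which avoids
#' initial overshoot in a unit box). Fitness is unset (`NA`).
#'
#' @param space A [search_space()].
#' @param n Number of agents, at least 2.
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return A list with `positions` (`n x d` matrix), `velocities` (`n x d`,
#'   all zero) and `fitness` (length-`n` vector of `NA`).
#' @export
init_population <- function(space, n, seed = NULL) {
  stopifnot(inherits(space, "search_space"))
  if (!is.numeric(n) || length(n) != 1 || n < 2)
    stop("population size n must be at least 2")
  n <- as.integer(n)
  d <- space$dim
  P <- with_seed(seed, {
    matrix(stats::runif(n * d), nrow = n, ncol = d)
  })
  P <- sweep(sweep(P, 2, space$upper - space$lower, `*`), 2, space$lower, `+`)
  list(positions = P,
       velocities = matrix(0, nrow = n, ncol = d),
       fitness = rep(NA_real_, n))
}

# Evaluate every row of P under `objective`; non-finite values become +Inf
# with a warning so a stochastic run survives a pathological agent.
eval_rows <- function(P, objective) {
  f <- vapply(seq_len(nrow(P)), function(i) {
    val <- tryCatch(objective(P[i, ]), error = function(e) NaN)
    as.numeric(val)[1]
  }, numeric(1))
  bad <- !is.finite(f)
  if (any(bad)) {
    warning(sum(bad), " agent(s) returned a non-finite objective value; ",
            "assigned +Inf fitness")
    f[bad] <- Inf
  }
  f
}

# Construct the standard optimizer result object shared by every algorithm.
new_opt_result <- function(algorithm, best_position, best_fitness, trace,
                           evaluations, seed = NULL, runtime = NA_real_,
                           population = NULL) {
  structure(list(algorithm = algorithm,
                 best_position = as.numeric(best_position),
                 best_fitness = as.numeric(best_fitness),
                 trace = data.frame(iteration = seq_along(trace) - 1L,
                                    best_fitness = as.numeric(trace)),
                 evaluations = as.integer(evaluations),
                 seed = seed,
                 runtime = runtime,
                 population = population),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("<opt_result> %s\n", x$algorithm))
  cat(sprintf("  best fitness: %.6g after %d evaluations (%d iterations)\n",
              x$best_fitness, x$evaluations, nrow(x$trace) - 1L))
  cat("  best position:", paste(signif(x$best_position, 4), collapse = " "),
      "\n")
  invisible(x)
}

#' Plot the convergence trace of an optimizer run
#'
#' @param x An `opt_result`.
#' @param log Axis specification passed to [graphics::plot()]; default draws
#'   the fitness axis on a log scale when all values are positive.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.opt_result <- function(x, log = if (all(x$trace$best_fitness > 0)) "y" else "", ...) {
  graphics::plot(x$trace$iteration, x$trace$best_fitness, type = "s",
                 xlab = "iteration", ylab = "best fitness so far", log = log,
                 main = x$algorithm, ...)
  invisible(x)
}

#' Uniform random search over a box (budget-matched reference)
#'
#' Draws `n * iters` uniform points and returns the best. Serves as the
#' equal-budget reference that any population optimizer should beat on the
#' benchmark functions; it is also the simplest member of the common
#' optimizer contract.
#'
#' @inheritParams dto_optimize
#' @return An `opt_result`.
#' @export
random_search <- function(objective, space, n = 30, iters = 100, seed = NULL) {
  with_seed(seed, {
    t0 <- proc.time()[["elapsed"]]
    evals <- 0L
    best_f <- Inf
    best_x <- rep(NA_real_, space$dim)
    trace <- numeric(iters + 1L)
    for (t in 0:iters) {
      P <- matrix(stats::runif(n * space$dim), nrow = n)
      P <- sweep(sweep(P, 2, space$upper - space$lower, `*`),
                 2, space$lower, `+`)
      f <- eval_rows(P, objective)
      evals <- evals + n
      i <- which.min(f)
      if (f[i] < best_f) { best_f <- f[i]; best_x <- P[i, ] }
      trace[t + 1L] <- best_f
    }
    new_opt_result("random_search", best_x, best_f, trace, evals, seed,
                   proc.time()[["elapsed"]] - t0)
  })
}

#' Benchmark objectives: sphere and Rastrigin
#'
#' Standard test functions on the unit box, both minimized at the lower
#' corner (the box is `[0,1]^d`, so the global optimum of each sits at the
#' origin corner). `rastrigin_fn` is the usual multimodal benchmark
#' `10 d + sum(x^2 - 10 cos(2 pi x))`.
#'
#' @param x Numeric vector.
#' @return Objective value (scalar).
#' @export
sphere_fn <- function(x) sum(x^2)

#' @rdname sphere_fn
#' @export
rastrigin_fn <- function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))
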