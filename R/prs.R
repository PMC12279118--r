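#' Polar Rose Search (PRS) primitives
#'
#' PRS diversifies a population by re-projecting a pair of coordinates to
#' polar form and replacing the radius with a point on a rhodonea (rose)
#' curve `r' = a cos(k theta + dtheta)`. The amplitude `a` controls the
#' petal radius, the angular frequency `k` the petal count (odd integer `k`
#' gives `k` petals, even gives `2k`), and the rotational offset `dtheta`
#' keeps successive perturbations from revisiting the same petal pattern.
#'
#' @name prs
NULL

#' Cartesian to polar coordinates
#'
#' `r = sqrt(u^2 + v^2)`, `theta = atan2(v, u)` in `(-pi, pi]`. The origin
#' maps to `(0, 0)` by convention.
#'
#' @param u,v Cartesian coordinates.
#' @return Named list with `r` and `theta`.
#' @export
to_polar <- function(u, v) {
  list(r = sqrt(u^2 + v^2), theta = atan2(v, u))
}

#' @rdname to_polar
#' @param r,theta Polar coordinates.
#' @export
from_polar <- function(r, theta) {
  list(u = r * cos(theta), v = r * sin(theta))
}

#' Rose-curve radius
#'
#' `r' = a cos(k theta + dtheta)`, in `[-a, a]`. Negative radii are
#' meaningful: the perturbed point flips through the origin.
#'
#' @param a Amplitude (> 0 for a non-degenerate curve).
#' @param k Angular frequency.
#' @param theta Polar angle.
#' @param dtheta Rotational offset.
#' @return The rose radius.
#' @export
rose_radius <- function(a, k, theta, dtheta = 0) {
  a * cos(k * theta + dtheta)
}

#' Petal count of a rose curve
#'
#' For integer `k >= 1`: odd `k` yields `k` petals, even `k` yields `2k`.
#'
#' @param k Positive integer angular frequency.
#' @return The number of petals.
#' @export
petal_count <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("petal_count is defined for integer k >= 1 ",
         "(non-integer k still defines a usable curve)")
  k <- as.integer(k)
  if (k %% 2L == 1L) k else 2L * k
}

#' Perturb a position along a rose curve
#'
#' Coordinates `j` and `j + 1` of `position` are taken as a plane, mapped to
#' polar form, the radius is replaced by [rose_radius()], and the pair is
#' mapped back (`x_j = r' cos theta`, `x_{j+1} = r' sin theta`). Only that
#' pair changes; the result is clipped to the bounds.
#'
#' @param position Numeric vector.
#' @param plane Index `j` of the first coordinate of the plane,
#'   `1 <= j <= d - 1`.
#' @param a,k,dtheta Rose parameters (see [rose_radius()]).
#' @param space A [search_space()].
#' @return The perturbed position vector.
#' @export
rose_perturb <- function(position, plane, a, k, dtheta, space) {
  d <- length(position)
  if (plane < 1 || plane > d - 1) stop("plane index out of range")
  pol <- to_polar(position[plane], position[plane + 1L])
  r2 <- rose_radius(a, k, pol$theta, dtheta)
  xy <- from_polar(r2, pol$theta)
  position[plane] <- xy$u
  position[plane + 1L] <- xy$v
  clip_to_bounds(position, space)
}

#' Population diversity (normalized positional entropy)
#'
#' The diversity trigger of the hybrid: the mean over dimensions of the
#' per-dimension population standard deviation (1/n convention), each
#' normalized by that dimension's range. Zero iff all agents coincide; two
#' agents at opposite corners of the unit box give 0.5.
#'
#' @param positions An `n x d` matrix of agent positions (n >= 2).
#' @param space A [search_space()].
#' @return A scalar >= 0.
#' @export
population_entropy <- function(positions, space) {
  if (nrow(positions) < 2) stop("entropy requires at least 2 agents")
  sds <- apply(positions, 2, function(x) sqrt(mean((x - mean(x))^2)))
  mean(sds / (space$upper - space$lower))
}

#' Hybrid DTO + PRS optimizer
#'
#' Each iteration runs one DTO step (exploitation), then decides whether to
#' fire a PRS diversification phase: it fires when the population entropy
#' falls below `entropy_threshold` OR a Bernoulli draw with probability
#' `prs_prob(t)` succeeds (either mechanism can be disabled by setting the
#' threshold to 0 / the probability to 0). In the PRS phase the elite
#' fraction of the population (best by fitness) is perturbed along a rose
#' curve on a cycling coordinate plane; a perturbed agent replaces its
#' original only if not worse (greedy acceptance), so the best-so-far trace
#' never worsens.
#'
#' Rose parameters adapt over the run: the amplitude anneals linearly from
#' `a0` to `a_end` (defaults: half resp. 5% of the mean dimension width),
#' `k` cycles through `k_cycle` across PRS invocations, and the rotational
#' offset advances as `dtheta(t) = 2 pi t / iters` (one full rotation over
#' the run).
#'
#' @inheritParams dto_optimize
#' @param entropy_threshold Fire PRS when entropy drops below this
#'   (default 0.05; 0 disables the entropy trigger).
#' @param elite_fraction Fraction of the population perturbed (default 0.2;
#'   at least one agent after ceiling).
#' @param prs_prob Function of `t` giving the probability of a scheduled PRS
#'   phase; default `0.3 * (1 - t / iters)` (annealing schedule). A number
#'   is accepted as a constant schedule.
#' @param a0,a_end Amplitude schedule endpoints; defaults scale with the
#'   mean dimension width.
#' @param k_cycle Angular frequencies cycled across PRS invocations
#'   (default `c(2, 3, 5, 7)`).
#' @param dtheta Function of `t` giving the rotational offset; default one
#'   full rotation over the run.
#' @return An `opt_result` (algorithm tag `"dtoprs"`).
#' @examples
#' res <- dtoprs_optimize(sphere_fn, search_space(4), n = 10, iters = 20, seed = 1)
#' res$best_fitness
#' @export
dtoprs_optimize <- function(objective, space, n = 30, iters = 100,
                            seed = NULL, C3 = 0.7, C4 = 2, C5 = 2,
                            entropy_threshold = 0.05, elite_fraction = 0.2,
                            prs_prob = NULL, a0 = NULL, a_end = NULL,
                            k_cycle = c(2, 3, 5, 7), dtheta = NULL,
                            init = NULL) {
  stopifnot(elite_fraction > 0, elite_fraction <= 1, entropy_threshold >= 0)
  width <- mean(space$upper - space$lower)
  if (is.null(a0)) a0 <- 0.5 * width
  if (is.null(a_end)) a_end <- 0.05 * width
  if (is.null(prs_prob)) prs_prob <- function(t) 0.3 * (1 - t / iters)
  if (is.numeric(prs_prob)) {
    p_const <- prs_prob
    prs_prob <- function(t) p_const
  }
  if (is.null(dtheta)) dtheta <- function(t) 2 * pi * t / iters

  with_seed(seed, {
    t0 <- proc.time()[["elapsed"]]
    pop <- init_population(space, n)
    pop <- inject_init(pop, init, space)
    pop$fitness <- eval_rows(pop$positions, objective)
    evals <- n
    ib <- which.min(pop$fitness)
    gbest <- list(position = pop$positions[ib, ], fitness = pop$fitness[ib])
    trace <- numeric(iters + 1L)
    trace[1L] <- gbest$fitness
    n_elite <- ceiling(elite_fraction * n)
    invocation <- 0L

    if (iters >= 1) {
      for (t in seq_len(iters)) {
        st <- dto_step(pop, space, objective, t, iters, C3, C4, C5, gbest)
        pop <- st$pop
        gbest <- st$gbest
        evals <- evals + n

        H <- population_entropy(pop$positions, space)
        p_t <- prs_prob(t)
        # the Bernoulli draw is skipped when its probability is zero so a
        # fully disabled PRS phase consumes no RNG and the trajectory is
        # bit-identical to plain DTO under the same seed
        fire <- (entropy_threshold > 0 && H < entropy_threshold) ||
          (p_t > 0 && stats::runif(1) < p_t)
        if (fire) {
          invocation <- invocation + 1L
          a_t <- a0 + (a_end - a0) * t / iters
          k_t <- k_cycle[((invocation - 1L) %% length(k_cycle)) + 1L]
          plane <- if (space$dim >= 2)
            ((invocation - 1L) %% (space$dim - 1L)) + 1L else NULL
          if (!is.null(plane)) {
            elite <- order(pop$fitness)[seq_len(n_elite)]
            for (i in elite) {
              cand <- rose_perturb(pop$positions[i, ], plane, a_t, k_t,
                                   dtheta(t), space)
              f <- eval_rows(rbind(cand), objective)
              evals <- evals + 1L
              if (f <= pop$fitness[i]) {
                pop$positions[i, ] <- cand
                pop$fitness[i] <- f
              }
            }
            ib <- which.min(pop$fitness)
            if (pop$fitness[ib] < gbest$fitness)
              gbest <- list(position = pop$positions[ib, ],
                            fitness = pop$fitness[ib])
          }
        }
        trace[t + 1L] <- gbest$fitness
      }
    }
    new_opt_result("dtoprs", gbest$position, gbest$fitness, trace, evals,
                   seed, proc.time()[["elapsed"]] - t0,
                   population = pop$positions)
  })
}
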