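#' Baseline swarm optimizers
#'
#' Canonical implementations of six population optimizers used as
#' comparators for the DTO + PRS hybrid, all behind the same contract
#' (objective, space, n, iters, seed -> `opt_result`): Grey Wolf Optimizer,
#' Particle Swarm Optimization, Bat Algorithm, Whale Optimization
#' Algorithm, Satin Bowerbird Optimizer and Firefly Algorithm. Constants
#' follow the common benchmarking configuration: population 30, 100
#' iterations, unit-box domain; algorithm-specific constants are noted per
#' function.
#'
#' @name baselines
NULL

#' Grey Wolf Optimizer
#'
#' The three best wolves (alpha, beta, delta) jointly steer every agent;
#' the control parameter `a` decreases linearly from 2 to 0 over the run.
#'
#' @inheritParams dto_optimize
#' @return An `opt_result`.
#' @export
gwo_optimize <- function(objective, space, n = 30, iters = 100, seed = NULL) {
  with_seed(seed, {
    t0 <- proc.time()[["elapsed"]]
    d <- space$dim
    pop <- init_population(space, n)
    P <- pop$positions
    f <- eval_rows(P, objective)
    evals <- n
    ord <- order(f)
    leaders <- P[ord[1:3], , drop = FALSE]
    gbest <- list(position = P[ord[1], ], fitness = f[ord[1]])
    trace <- numeric(iters + 1L)
    trace[1L] <- gbest$fitness
    for (t in seq_len(iters)) {
      a <- 2 - 2 * (t / iters)
      for (i in seq_len(n)) {
        X <- numeric(d)
        for (l in 1:3) {
          A <- 2 * a * stats::runif(d) - a
          C <- 2 * stats::runif(d)
          D <- abs(C * leaders[l, ] - P[i, ])
          X <- X + (leaders[l, ] - A * D)
        }
        P[i, ] <- clip_to_bounds(X / 3, space)
      }
      f <- eval_rows(P, objective)
      evals <- evals + n
      ord <- order(f)
      leaders <- P[ord[1:3], , drop = FALSE]
      if (f[ord[1]] < gbest$fitness)
        gbest <- list(position = P[ord[1], ], fitness = f[ord[1]])
      trace[t + 1L] <- gbest$fitness
    }
    new_opt_result("gwo", gbest$position, gbest$fitness, trace, evals, seed,
                   proc.time()[["elapsed"]] - t0)
  })
}

#' Particle Swarm Optimization
#'
#' Inertia weight annealed linearly from `w_max` to `w_min`; cognitive and
#' social constants both 2; velocities clamped to the domain width.
#'
#' @inheritParams dto_optimize
#' @param w_max,w_min Inertia schedule endpoints (defaults 0.9 and 0.6).
#' @param c1,c2 Cognitive and social acceleration constants (default 2).
#' @return An `opt_result`.
#' @export
pso_optimize <- function(objective, space, n = 30, iters = 100, seed = NULL,
                         w_max = 0.9, w_min = 0.6, c1 = 2, c2 = 2) {
  with_seed(seed, {
    t0 <- proc.time()[["elapsed"]]
    d <- space$dim
    width <- space$upper - space$lower
    pop <- init_population(space, n)
    P <- pop$positions
    V <- pop$velocities
    f <- eval_rows(P, objective)
    evals <- n
    pbest <- P
    pbest_f <- f
    ib <- which.min(f)
    gbest <- list(position = P[ib, ], fitness = f[ib])
    trace <- numeric(iters + 1L)
    trace[1L] <- gbest$fitness
    for (t in seq_len(iters)) {
      w <- w_max - (w_max - w_min) * (t / iters)
      for (i in seq_len(n)) {
        V[i, ] <- w * V[i, ] +
          c1 * stats::runif(d) * (pbest[i, ] - P[i, ]) +
          c2 * stats::runif(d) * (gbest$position - P[i, ])
        V[i, ] <- pmin(width, pmax(-width, V[i, ]))
        P[i, ] <- clip_to_bounds(P[i, ] + V[i, ], space)
      }
      f <- eval_rows(P, objective)
      evals <- evals + n
      imp <- f < pbest_f
      pbest[imp, ] <- P[imp, , drop = FALSE]
      pbest_f[imp] <- f[imp]
      ib <- which.min(pbest_f)
      if (pbest_f[ib] < gbest$fitness)
        gbest <- list(position = pbest[ib, ], fitness = pbest_f[ib])
      trace[t + 1L] <- gbest$fitness
    }
    new_opt_result("pso", gbest$position, gbest$fitness, trace, evals, seed,
                   proc.time()[["elapsed"]] - t0)
  })
}

#' Bat Algorithm
#'
#' Frequency-tuned velocity updates with loudness `A` and pulse rate `r`
#' evolving as `A <- a A`, `r <- r0 (1 - exp(-c t))`; local random walks
#' around the best solution scaled by the mean loudness. Constants follow
#' the common configuration: frequency range `[0, 100]`, `A0 = 1`,
#' `a = c = 0.9`, random-walk range `[-1, 1]`.
#'
#' @inheritParams dto_optimize
#' @param f_min,f_max Echolocation frequency range.
#' @param A0 Initial loudness.
#' @param r0 Initial pulse emission rate.
#' @param a_loud,c_pulse Loudness decay and pulse-rate growth constants.
#' @return An `opt_result`.
#' @export
ba_optimize <- function(objective, space, n = 30, iters = 100, seed = NULL,
                        f_min = 0, f_max = 100, A0 = 1, r0 = 0.5,
                        a_loud = 0.9, c_pulse = 0.9) {
  with_seed(seed, {
    t0 <- proc.time()[["elapsed"]]
    d <- space$dim
    width <- space$upper - space$lower
    pop <- init_population(space, n)
    P <- pop$positions
    V <- pop$velocities
    fit <- eval_rows(P, objective)
    evals <- n
    A <- rep(A0, n)
    r <- rep(0, n)
    ib <- which.min(fit)
    gbest <- list(position = P[ib, ], fitness = fit[ib])
    trace <- numeric(iters + 1L)
    trace[1L] <- gbest$fitness
    for (t in seq_len(iters)) {
      for (i in seq_len(n)) {
        Q <- f_min + (f_max - f_min) * stats::runif(1)
        V[i, ] <- V[i, ] + (P[i, ] - gbest$position) * Q
        V[i, ] <- pmin(width, pmax(-width, V[i, ]))
        cand <- P[i, ] + V[i, ]
        if (stats::runif(1) > r[i]) {
          # local walk around the incumbent, scaled by mean loudness
          cand <- gbest$position +
            stats::runif(d, -1, 1) * mean(A) * 0.01 * width
        }
        cand <- clip_to_bounds(cand, space)
        fc <- eval_rows(rbind(cand), objective)
        evals <- evals + 1L
        if (fc <= fit[i] && stats::runif(1) < A[i]) {
          P[i, ] <- cand
          fit[i] <- fc
          A[i] <- a_loud * A[i]
          r[i] <- r0 * (1 - exp(-c_pulse * t))
        }
        if (fc < gbest$fitness)
          gbest <- list(position = cand, fitness = fc)
      }
      trace[t + 1L] <- gbest$fitness
    }
    new_opt_result("ba", gbest$position, gbest$fitness, trace, evals, seed,
                   proc.time()[["elapsed"]] - t0)
  })
}

#' Whale Optimization Algorithm
#'
#' Encircling / random-search moves controlled by `a` annealed 2 -> 0, and
#' a logarithmic spiral move with constant pitch `b` (default 1) taken with
#' probability 0.5.
#'
#' @inheritParams dto_optimize
#' @param b Spiral pitch constant.
#' @return An `opt_result`.
#' @export
woa_optimize <- function(objective, space, n = 30, iters = 100, seed = NULL,
                         b = 1) {
  with_seed(seed, {
    t0 <- proc.time()[["elapsed"]]
    d <- space$dim
    pop <- init_population(space, n)
    P <- pop$positions
    f <- eval_rows(P, objective)
    evals <- n
    ib <- which.min(f)
    gbest <- list(position = P[ib, ], fitness = f[ib])
    trace <- numeric(iters + 1L)
    trace[1L] <- gbest$fitness
    for (t in seq_len(iters)) {
      a <- 2 - 2 * (t / iters)
      for (i in seq_len(n)) {
        p <- stats::runif(1)
        if (p < 0.5) {
          A <- 2 * a * stats::runif(d) - a
          C <- 2 * stats::runif(d)
          if (max(abs(A)) < 1) {
            D <- abs(C * gbest$position - P[i, ])
            P[i, ] <- gbest$position - A * D
          } else {
            j <- sample.int(n, 1)
            D <- abs(C * P[j, ] - P[i, ])
            P[i, ] <- P[j, ] - A * D
          }
        } else {
          l <- stats::runif(1, -1, 1)
          D <- abs(gbest$position - P[i, ])
          P[i, ] <- D * exp(b * l) * cos(2 * pi * l) + gbest$position
        }
        P[i, ] <- clip_to_bounds(P[i, ], space)
      }
      f <- eval_rows(P, objective)
      evals <- evals + n
      ib <- which.min(f)
      if (f[ib] < gbest$fitness)
        gbest <- list(position = P[ib, ], fitness = f[ib])
      trace[t + 1L] <- gbest$fitness
    }
    new_opt_result("woa", gbest$position, gbest$fitness, trace, evals, seed,
                   proc.time()[["elapsed"]] - t0)
  })
}

#' Satin Bowerbird Optimizer
#'
#' Roulette selection of a bower proportional to (transformed) fitness,
#' movement toward the mid-point of the selected bower and the elite, plus
#' Gaussian mutation of a small fraction of coordinates.
#'
#' @inheritParams dto_optimize
#' @param alpha Greatest step size (default 0.94).
#' @param p_mutate Per-coordinate mutation probability (default 0.05).
#' @param z Mutation spread as a fraction of the domain width (default 0.02).
#' @return An `opt_result`.
#' @export
sbo_optimize <- function(objective, space, n = 30, iters = 100, seed = NULL,
                         alpha = 0.94, p_mutate = 0.05, z = 0.02) {
  with_seed(seed, {
    t0 <- proc.time()[["elapsed"]]
    d <- space$dim
    width <- space$upper - space$lower
    pop <- init_population(space, n)
    P <- pop$positions
    f <- eval_rows(P, objective)
    evals <- n
    ib <- which.min(f)
    gbest <- list(position = P[ib, ], fitness = f[ib])
    trace <- numeric(iters + 1L)
    trace[1L] <- gbest$fitness
    for (t in seq_len(iters)) {
      # transformed fitness for roulette probabilities (minimization)
      fit01 <- ifelse(f >= 0, 1 / (1 + f), 1 + abs(f))
      prob <- fit01 / sum(fit01)
      for (i in seq_len(n)) {
        for (k in seq_len(d)) {
          j <- sample.int(n, 1, prob = prob)
          lambda <- alpha / (1 + prob[j])
          P[i, k] <- P[i, k] +
            lambda * ((P[j, k] + gbest$position[k]) / 2 - P[i, k])
          if (stats::runif(1) < p_mutate)
            P[i, k] <- P[i, k] + stats::rnorm(1, 0, z * width[k])
        }
        P[i, ] <- clip_to_bounds(P[i, ], space)
      }
      f <- eval_rows(P, objective)
      evals <- evals + n
      ib <- which.min(f)
      if (f[ib] < gbest$fitness)
        gbest <- list(position = P[ib, ], fitness = f[ib])
      trace[t + 1L] <- gbest$fitness
    }
    new_opt_result("sbo", gbest$position, gbest$fitness, trace, evals, seed,
                   proc.time()[["elapsed"]] - t0)
  })
}

#' Firefly Algorithm
#'
#' Every firefly moves toward each brighter one with attractiveness
#' `beta0 exp(-gamma r^2)` plus a random step of size `alpha` (default
#' 0.94, annealed); a long-jump (random restart) probability lets the worst
#' firefly escape to a fresh uniform position.
#'
#' @inheritParams dto_optimize
#' @param alpha Randomization step size (default 0.94, decays geometrically).
#' @param beta0 Attractiveness at distance zero.
#' @param gamma Light absorption coefficient.
#' @param p_jump Range of the long-jump (restart) probability, annealed
#'   linearly across the run (default `c(0.2, 1)` applied to the worst
#'   firefly only, so elitism is preserved).
#' @return An `opt_result`.
#' @export
fa_optimize <- function(objective, space, n = 30, iters = 100, seed = NULL,
                        alpha = 0.94, beta0 = 1, gamma = 1,
                        p_jump = c(0.2, 1)) {
  with_seed(seed, {
    t0 <- proc.time()[["elapsed"]]
    d <- space$dim
    width <- space$upper - space$lower
    pop <- init_population(space, n)
    P <- pop$positions
    f <- eval_rows(P, objective)
    evals <- n
    ib <- which.min(f)
    gbest <- list(position = P[ib, ], fitness = f[ib])
    trace <- numeric(iters + 1L)
    trace[1L] <- gbest$fitness
    alpha_t <- alpha
    for (t in seq_len(iters)) {
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (f[j] < f[i]) {
            r2 <- sum((P[i, ] - P[j, ])^2)
            beta <- beta0 * exp(-gamma * r2)
            P[i, ] <- P[i, ] + beta * (P[j, ] - P[i, ]) +
              alpha_t * (stats::runif(d) - 0.5) * width
          }
        }
        P[i, ] <- clip_to_bounds(P[i, ], space)
      }
      # long jump: the worst firefly restarts with annealed probability
      pj <- p_jump[1] + (p_jump[2] - p_jump[1]) * (t / iters)
      if (stats::runif(1) < pj) {
        iw <- which.max(f)
        P[iw, ] <- space$lower + stats::runif(d) * width
      }
      f <- eval_rows(P, objective)
      evals <- evals + n
      alpha_t <- alpha_t * 0.97
      ib <- which.min(f)
      if (f[ib] < gbest$fitness)
        gbest <- list(position = P[ib, ], fitness = f[ib])
      trace[t + 1L] <- gbest$fitness
    }
    new_opt_result("fa", gbest$position, gbest$fitness, trace, evals, seed,
                   proc.time()[["elapsed"]] - t0)
  })
}

#' Optimizer registry
#'
#' Maps algorithm tags to their optimizer functions (all share the common
#' contract `f(objective, space, n, iters, seed, ...)`). Binary wrapper
#' variants are formed by composing any of these with the sigmoid
#' transfer / thresholding of the feature-selection module and are referred
#' to by a "b" prefix (`bdto`, `bdtoprs`, `bgwo`, ...).
#'
#' @param tag Optional tag; when given, the matching function is returned
#'   (a "b" prefix is stripped, since binarization lives in the objective).
#' @return With no argument, a named list of optimizer functions; with a
#'   tag, a single function.
#' @export
optimizer_registry <- function(tag = NULL) {
  reg <- list(dto = dto_optimize, dtoprs = dtoprs_optimize,
              gwo = gwo_optimize, pso = pso_optimize, ba = ba_optimize,
              woa = woa_optimize, sbo = sbo_optimize, fa = fa_optimize,
              random = random_search)
  if (is.null(tag)) return(reg)
  key <- tolower(tag)
  if (!key %in% names(reg)) {
    # binary variants keep the continuous engine; binarization lives in the
    # objective ("ba" itself is a plain tag, so strip "b" only on no match)
    stripped <- sub("^b", "", key)
    if (stripped %in% names(reg)) key <- stripped
    else stop("unknown optimizer tag: ", tag)
  }
  reg[[key]]
}
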