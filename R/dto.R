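#' Dipper-Throated Optimization (DTO)
#'
#' DTO models the foraging of dipper birds: each agent either performs a
#' "swimming" move (a folded attraction toward the best solution) or a
#' "flying" move (a velocity update pulled toward both the current
#' population best and the best position ever seen). The branch is chosen
#' per agent per iteration by a uniform draw `R`: `R < 0.5` swims,
#' `R >= 0.5` flies.
#'
#' The swimming move is
#' `pos' = best - C1 * |C2 * best - pos|`
#' with annealed coefficients `C1 = 2 c r1 - c`, `C2 = 2 r1` and
#' `c = 2 (1 - (t / Tmax)^2)`, so the step shrinks from aggressive to
#' vanishing over the run. The flying move is the classical velocity rule
#' `vel' = C3 vel + C4 r2 (best - pos) + C5 r2 (gbest - pos)`,
#' `pos' = pos + vel'`.
#'
#' @name dto
NULL

#' Annealed DTO control coefficients
#'
#' Computes `c = 2 (1 - (t/Tmax)^2)` (decreasing from 2 at `t = 0` to 0 at
#' `t = Tmax`), `C1 = 2 c r1 - c` (in `[-c, c]`) and `C2 = 2 r1` (in
#' `[0, 2]`).
#'
#' @param t Iteration index, `0 <= t <= Tmax`.
#' @param Tmax Iteration budget.
#' @param r1 A uniform draw on `[0, 1]`.
#' @return Named list with `c`, `C1`, `C2`.
#' @export
dto_coefficients <- function(t, Tmax, r1) {
  if (t < 0 || t > Tmax) stop("iteration index t must lie in [0, Tmax]")
  cc <- 2 * (1 - (t / Tmax)^2)
  list(c = cc, C1 = 2 * cc * r1 - cc, C2 = 2 * r1)
}

#' DTO swimming update
#'
#' `pos' = clip(best - C1 * |C2 * best - pos|)`, the dipper's folded
#' attraction toward the best-known position.
#'
#' @param pos,best_pos Numeric vectors of equal length.
#' @param C1,C2 Control coefficients (see [dto_coefficients()]).
#' @param space A [search_space()] used for clipping.
#' @return Updated position vector.
#' @export
swim_update <- function(pos, best_pos, C1, C2, space) {
  if (length(pos) != length(best_pos))
    stop("dimension mismatch between pos and best_pos")
  clip_to_bounds(best_pos - C1 * abs(C2 * best_pos - pos), space)
}

#' DTO flying update
#'
#' Velocity rule `vel' = C3 vel + C4 r2 (best - pos) + C5 r2 (gbest - pos)`
#' followed by `pos' = clip(pos + vel')`. The velocity is clamped to the
#' domain width per dimension to prevent divergence.
#'
#' @param vel,pos,best_pos,gbest_pos Numeric vectors of equal length.
#' @param C3 Inertia coefficient.
#' @param C4,C5 Acceleration coefficients toward the population best and the
#'   incumbent (best-ever) position.
#' @param r2 A uniform draw on `[0, 1]`.
#' @param space A [search_space()].
#' @return List with `velocity` and `position`.
#' @export
fly_update <- function(vel, pos, best_pos, gbest_pos, C3, C4, C5, r2, space) {
  if (length(unique(c(length(vel), length(pos), length(best_pos),
                      length(gbest_pos)))) != 1L)
    stop("dimension mismatch among velocity/position vectors")
  v <- C3 * vel + C4 * r2 * (best_pos - pos) + C5 * r2 * (gbest_pos - pos)
  width <- space$upper - space$lower
  v <- pmin(width, pmax(-width, v))
  list(velocity = v, position = clip_to_bounds(pos + v, space))
}

#' One synchronous DTO iteration
#'
#' Updates every agent by exactly one branch (swim or fly), re-evaluates,
#' and re-identifies the best agent. Exposed mainly for inspection and
#' testing; [dto_optimize()] is the user-facing loop.
#'
#' @param pop Population list (`positions`, `velocities`, `fitness`) with
#'   fitness already set.
#' @param space A [search_space()].
#' @param objective Function mapping a position vector to a scalar
#'   (minimized).
#' @param t,iters Current iteration and budget (drive the `c` schedule).
#' @param C3,C4,C5 Flying-branch constants.
#' @param gbest Optional list `(position, fitness)` of the incumbent; when
#'   `NULL` the current population best is used.
#' @param draws Optional list with vectors `R`, `r1`, `r2` (one entry per
#'   agent) overriding the RNG; used for deterministic dissection of the
#'   branch logic.
#' @return List with the updated `pop`, the updated `gbest`, and `branches`
#'   (character vector, "swim"/"fly" per agent).
#' @export
dto_step <- function(pop, space, objective, t, iters,
                     C3 = 0.7, C4 = 2, C5 = 2, gbest = NULL, draws = NULL) {
  n <- nrow(pop$positions)
  if (anyNA(pop$fitness)) stop("population must be evaluated before a step")
  ib <- which.min(pop$fitness)
  best_pos <- pop$positions[ib, ]
  if (is.null(gbest) || pop$fitness[ib] < gbest$fitness)
    gbest <- list(position = best_pos, fitness = pop$fitness[ib])
  if (is.null(draws))
    draws <- list(R = stats::runif(n), r1 = stats::runif(n),
                  r2 = stats::runif(n))
  branches <- ifelse(draws$R < 0.5, "swim", "fly")
  for (i in seq_len(n)) {
    if (branches[i] == "swim") {
      k <- dto_coefficients(t, iters, draws$r1[i])
      pop$positions[i, ] <- swim_update(pop$positions[i, ], best_pos,
                                        k$C1, k$C2, space)
    } else {
      upd <- fly_update(pop$velocities[i, ], pop$positions[i, ], best_pos,
                        gbest$position, C3, C4, C5, draws$r2[i], space)
      pop$velocities[i, ] <- upd$velocity
      pop$positions[i, ] <- upd$position
    }
  }
  pop$fitness <- eval_rows(pop$positions, objective)
  ib <- which.min(pop$fitness)
  if (pop$fitness[ib] < gbest$fitness)
    gbest <- list(position = pop$positions[ib, ], fitness = pop$fitness[ib])
  list(pop = pop, gbest = gbest, branches = branches)
}

#' Run the DTO optimizer
#'
#' Minimizes `objective` over `space` with `n` agents for `iters`
#' iterations. The returned trace is the best-so-far fitness per iteration
#' (non-increasing by elitism).
#'
#' @param objective Function from a position vector to a scalar; minimized.
#'   Non-finite values are treated as `+Inf` with a warning.
#' @param space A [search_space()].
#' @param n Population size (default 30).
#' @param iters Iteration budget (default 100).
#' @param seed Optional integer seed for full reproducibility.
#' @param C3,C4,C5 Flying-branch constants; `C3` plays the inertia role and
#'   `C4`, `C5` the acceleration roles.
#' @param init Optional matrix of initial positions (rows) injected into the
#'   population before the first evaluation (a warm start); extra rows beyond
#'   `n` are ignored.
#' @return An object of class `opt_result`.
#' @examples
#' res <- dto_optimize(sphere_fn, search_space(4), n = 10, iters = 20, seed = 1)
#' res$best_fitness
#' @export
dto_optimize <- function(objective, space, n = 30, iters = 100, seed = NULL,
                         C3 = 0.7, C4 = 2, C5 = 2, init = NULL) {
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
    if (iters >= 1) {
      for (t in seq_len(iters)) {
        st <- dto_step(pop, space, objective, t, iters, C3, C4, C5, gbest)
        pop <- st$pop
        gbest <- st$gbest
        evals <- evals + n
        trace[t + 1L] <- gbest$fitness
      }
    }
    new_opt_result("dto", gbest$position, gbest$fitness, trace, evals, seed,
                   proc.time()[["elapsed"]] - t0, population = pop$positions)
  })
}

# Overwrite the first rows of a fresh population with user-supplied warm
# start positions (clipped to bounds).
inject_init <- function(pop, init, space) {
  if (is.null(init)) return(pop)
  init <- rbind(init)
  m <- min(nrow(init), nrow(pop$positions))
  for (i in seq_len(m))
    pop$positions[i, ] <- clip_to_bounds(as.numeric(init[i, ]), space)
  pop
}
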