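test_that("dto_coefficients follows the annealed schedule", {
  k <- dto_coefficients(0, 100, r1 = 1)
  expect_equal(k$c, 2)
  expect_equal(k$C1, 2)
  expect_equal(k$C2, 2)
  k <- dto_coefficients(100, 100, r1 = 0.3)
  expect_equal(k$c, 0)
  expect_equal(k$C1, 0)
  expect_equal(k$C2, 0.6)
  k <- dto_coefficients(50, 100, r1 = 0.5)
  expect_equal(k$c, 1.5)
  expect_equal(k$C1, 0)
  expect_equal(k$C2, 1)
  expect_error(dto_coefficients(101, 100, 0.5), "\\[0, Tmax\\]")
})

test_that("the c schedule decreases strictly from 2 to 0", {
  ts <- seq(0, 100, length.out = 11)
  cs <- vapply(ts, function(t) dto_coefficients(t, 100, 0.5)$c, numeric(1))
  expect_equal(cs[1], 2)
  expect_equal(cs[11], 0)
  expect_true(all(diff(cs) < 0))
})

test_that("swim_update matches the folded-attraction formula", {
  sp <- search_space(2)
  # C2 = 1 and pos = best is a fixed point
  expect_equal(swim_update(c(0.4, 0.6), c(0.4, 0.6), C1 = 0.7, C2 = 1, sp),
               c(0.4, 0.6))
  # 0.5 - 2*|2*0.5 - 0| = -1.5, clipped to 0
  sp1 <- search_space(1)
  expect_equal(swim_update(0, 0.5, C1 = 2, C2 = 2, sp1), 0)
  # C1 = 0 collapses onto the best position
  expect_equal(swim_update(c(0.1, 0.9), c(0.3, 0.3), C1 = 0, C2 = 1.7, sp),
               c(0.3, 0.3))
  expect_error(swim_update(c(0.1, 0.2), 0.3, 1, 1, sp), "dimension")
})

test_that("fly_update matches the velocity rule", {
  sp <- search_space(1)
  # fixed point when everything coincides and velocity is zero
  upd <- fly_update(0, 0.5, 0.5, 0.5, C3 = 0.7, C4 = 2, C5 = 2, r2 = 0.9, sp)
  expect_equal(upd$velocity, 0)
  expect_equal(upd$position, 0.5)
  # hand arithmetic: v' = 0 + 2*0.5*(0.4-0.2) + 2*0.5*(0.6-0.2) = 0.6
  upd <- fly_update(0, 0.2, 0.4, 0.6, C3 = 0.7, C4 = 2, C5 = 2, r2 = 0.5, sp)
  expect_equal(upd$velocity, 0.6)
  expect_equal(upd$position, 0.8)
  # pure inertial drift
  upd <- fly_update(0.1, 0.2, 0.9, 0.9, C3 = 1, C4 = 0, C5 = 0, r2 = 0.5, sp)
  expect_equal(upd$position, 0.3)
})

test_that("the R draw routes each agent to exactly one branch", {
  sp <- search_space(3)
  pop <- init_population(sp, 6, seed = 1)
  pop$fitness <- apply(pop$positions, 1, sphere_fn)
  n <- 6
  st <- dto_step(pop, sp, sphere_fn, t = 1, iters = 10,
                 draws = list(R = rep(0, n), r1 = rep(0.5, n), r2 = rep(0.5, n)))
  expect_true(all(st$branches == "swim"))
  st <- dto_step(pop, sp, sphere_fn, t = 1, iters = 10,
                 draws = list(R = rep(0.9, n), r1 = rep(0.5, n), r2 = rep(0.5, n)))
  expect_true(all(st$branches == "fly"))
})

test_that("branch selection is 50/50 within binomial tolerance", {
  sp <- search_space(2)
  pop <- init_population(sp, 40, seed = 5)
  pop$fitness <- apply(pop$positions, 1, sphere_fn)
  set.seed(11)
  n_swim <- 0
  total <- 0
  for (rep in 1:50) {
    st <- dto_step(pop, sp, sphere_fn, t = 1, iters = 10)
    n_swim <- n_swim + sum(st$branches == "swim")
    total <- total + length(st$branches)
  }
  expect_lt(abs(n_swim / total - 0.5), 3 * sqrt(0.25 / total))
})

test_that("dto_optimize honors the budget, elitism and seeding contracts", {
  sp <- search_space(8)
  r0 <- dto_optimize(sphere_fn, sp, n = 10, iters = 0, seed = 4)
  pop <- init_population(sp, 10, seed = 4)
  expect_equal(r0$best_fitness, min(apply(pop$positions, 1, sphere_fn)))

  ra <- dto_optimize(sphere_fn, sp, n = 15, iters = 40, seed = 7)
  rb <- dto_optimize(sphere_fn, sp, n = 15, iters = 40, seed = 7)
  expect_identical(ra$trace, rb$trace)
  expect_identical(ra$best_position, rb$best_position)
  expect_true(all(diff(ra$trace$best_fitness) <= 0))
  expect_true(all(ra$best_position >= 0 & ra$best_position <= 1))
  expect_equal(ra$evaluations, 15 * 41)
})

test_that("DTO beats equal-budget random search on sphere and Rastrigin", {
  sp <- search_space(8)
  for (fn in list(sphere_fn, rastrigin_fn)) {
    wins <- 0
    for (s in 1:10) {
      rd <- dto_optimize(fn, sp, n = 20, iters = 50, seed = s)
      rr <- random_search(fn, sp, n = 20, iters = 50, seed = 1000 + s)
      wins <- wins + (rd$best_fitness <= rr$best_fitness)
    }
    expect_gte(wins, 8)
  }
})
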