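# Moth-Flame Optimization engine: initialization, flame memory, schedule,
# spiral update, and the full optimize loop.

test_that("population initialization is the affine map of uniform draws", {
  space <- mfo_search_space(-1, 1, dims = 1)
  # with a known uniform draw, position = rand * (ub - lb) + lb
  withr::with_seed(1, u <- runif(1))
  withr::with_seed(1, pop <- mfo_init_population(space, 2))
  expect_equal(pop$positions[1, 1], u * 2 - 1)

  # all positions inside arbitrary bounds
  space2 <- mfo_search_space(c(-3, 0, 10), c(-1, 5, 11))
  withr::with_seed(7, pop2 <- mfo_init_population(space2, 25))
  expect_true(all(sweep(pop2$positions, 2, space2$lower, `>=`)))
  expect_true(all(sweep(pop2$positions, 2, space2$upper, `<=`)))
  expect_true(all(is.na(pop2$fitness)))
})

test_that("degenerate bounds are rejected", {
  expect_error(mfo_search_space(0, Inf, dims = 2), "finite")
  expect_error(mfo_search_space(1, 1, dims = 2), "strictly below")
})

test_that("flame count follows the shrinking schedule with half-away rounding", {
  expect_identical(mfo_flame_count(1, 10, 100), 10L)  # round(9.91)
  expect_identical(mfo_flame_count(50, 10, 100), 6L)  # round(5.5) away from 0
  expect_identical(mfo_flame_count(100, 10, 100), 1L)
  # endpoints and monotonicity for several (N, T)
  for (n in c(2, 5, 30)) {
    for (t_max in c(1, 7, 50)) {
      r <- vapply(seq_len(t_max), mfo_flame_count, integer(1),
                  n = n, t_max = t_max)
      expect_identical(r[t_max], 1L)
      expect_true(all(diff(r) <= 0))
      expect_true(all(r >= 1 & r <= n))
    }
  }
  expect_error(mfo_flame_count(0, 10, 100), "\\[1, t_max\\]")
  expect_error(mfo_flame_count(101, 10, 100), "\\[1, t_max\\]")
})

test_that("flame construction sorts at t=1 and merges elitistically later", {
  moths <- list(positions = matrix(c(31, 11, 21), ncol = 1),
                fitness = c(3, 1, 2))
  fl <- mfo_construct_flames(NULL, moths, t = 1)
  expect_equal(fl$flame_fitness, c(1, 2, 3))
  expect_equal(as.numeric(fl$flames), c(11, 21, 31))

  prev <- list(flames = matrix(c(101, 103), ncol = 1),
               flame_fitness = c(1, 3))
  moths2 <- list(positions = matrix(c(202, 204), ncol = 1),
                 fitness = c(2, 4))
  fl2 <- mfo_construct_flames(prev, moths2, t = 2)
  expect_equal(fl2$flame_fitness, c(1, 2))
  expect_equal(as.numeric(fl2$flames), c(101, 202))
  # elitism: best fitness never increases in the merge
  expect_lte(min(fl2$flame_fitness), min(prev$flame_fitness))

  moths_bad <- list(positions = matrix(1:2, ncol = 1), fitness = c(1, NaN))
  expect_error(mfo_construct_flames(prev, moths_bad, 2), "NaN")
})

test_that("spiral coefficients hit their endpoints", {
  terms <- withr::with_seed(1, mfo_spiral_terms(100, 100))
  expect_equal(terms$a, -2)
  # k = (a-1)*rand + 1 spans [a, 1]
  ks <- withr::with_seed(2, replicate(200, mfo_spiral_terms(40, 100)$k))
  a40 <- -1 + 40 * (-1 / 100)
  expect_true(all(ks <= 1 & ks >= a40))
})

test_that("spiral update has the zero-distance fixed point and D'=1 case", {
  space <- mfo_search_space(-100, 100, dims = 1)
  cfg <- mfo_config(n_moths = 2, max_iterations = 10, spiral_b = 1, seed = 1)
  flames <- list(flames = matrix(c(5, 7), ncol = 1), flame_fitness = c(1, 2))
  # moth exactly at its flame: distance 0, lands on the flame for any k
  moths <- list(positions = matrix(c(5, 7), ncol = 1), fitness = c(1, 2))
  upd <- withr::with_seed(3,
    mothflame:::mfo_update_positions(moths, flames, r = 2, t = 1, cfg, space))
  expect_equal(as.numeric(upd$positions), c(5, 7))
  # D'=1, k=0 (analytic): e^0 cos 0 = 1 so new position = F + 1;
  # reproduce by direct formula rather than forcing the RNG
  expect_equal(1 * exp(1 * 0) * cos(2 * pi * 0) + 5, 6)
  # clamping: any update stays inside tight bounds
  space_tight <- mfo_search_space(0, 1, dims = 3)
  cfgt <- mfo_config(4, 5, seed = 2)
  m <- list(positions = matrix(runif(12), 4, 3), fitness = 1:4)
  f <- mothflame:::mfo_construct_flames(NULL, m, 1)
  u <- withr::with_seed(4,
    mothflame:::mfo_update_positions(m, f, 2, 1, cfgt, space_tight))
  expect_true(all(u$positions >= 0 & u$positions <= 1))
})

test_that("optimize minimizes the sphere and keeps its contracts", {
  space <- mfo_search_space(-10, 10, dims = 5)
  res <- mfo_optimize(function(x) sum(x^2), space,
                      mfo_config(n_moths = 30, max_iterations = 120,
                                 seed = 99))
  expect_lt(res$best_fitness, 1e-2)
  expect_true(all(diff(res$trace) <= 0))         # elitism on the trace
  expect_equal(res$best_fitness, res$trace[120])
  expect_true(all(res$best_position >= -10 & res$best_position <= 10))

  # bit-identical determinism under the same seed
  res2 <- mfo_optimize(function(x) sum(x^2), space,
                       mfo_config(30, 120, seed = 99))
  expect_identical(res$trace, res2$trace)
  expect_identical(res$best_position, res2$best_position)

  # single-iteration contract: trace has length 1
  res1 <- mfo_optimize(function(x) sum(x^2),
                       mfo_search_space(-1, 1, dims = 2),
                       mfo_config(2, 1, seed = 5))
  expect_length(res1$trace, 1)

  # objective errors carry iteration context
  expect_error(
    mfo_optimize(function(x) stop("boom"), space, mfo_config(2, 2, seed = 1)),
    "iteration 1.*boom")
})

test_that("tidy/glance/autoplot methods work on mfo results", {
  res <- mfo_optimize(function(x) sum(x^2),
                      mfo_search_space(-1, 1, dims = 2),
                      mfo_config(5, 10, seed = 3))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("iteration", "best_fitness"))
  expect_equal(nrow(td), 10)
  gl <- glance(res)
  expect_equal(gl$best_fitness, res$best_fitness)
  expect_s3_class(autoplot(res), "ggplot")
})
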