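sphere <- function(x) sum(x^2)
box2 <- search_space(c(-5, -5), c(5, 5))

test_that("grey-wolf candidate arithmetic follows the encircling rules", {
  # A = 0 (a = 0) makes each X_k the leader itself: candidate is the mean
  cand <- gwo_candidate(c(9, 9), alpha = c(0, 0), beta = c(3, 0),
                        delta = c(0, 3), a = 0,
                        lambda1 = rep(list(c(0.3, 0.8)), 3),
                        lambda2 = rep(list(c(0.6, 0.1)), 3))
  expect_equal(cand, c(1, 1))

  # lambda1 = lambda2 = 0.5 gives A = 0, C = 1 for any a: X_k = leader
  cand2 <- gwo_candidate(c(2, -2), alpha = c(1, 1), beta = c(1, 1),
                         delta = c(1, 1), a = 1.4,
                         lambda1 = rep(list(c(0.5, 0.5)), 3),
                         lambda2 = rep(list(c(0.5, 0.5)), 3))
  expect_equal(cand2, c(1, 1))
})

test_that("particle-swarm velocity and position updates are exact", {
  # hand evaluation: 0.7*0 + 0.75*(1-0) + 0.75*(2-0) = 2.25
  up <- pso_update(x = 0, v = 0, pbest = 1, gbest = 2, omega = 0.7,
                   c1 = 1.5, c2 = 1.5, r1 = 0.5, r2 = 0.5)
  expect_equal(up$velocity, 2.25)
  expect_equal(up$position, 2.25)

  # no attraction: velocity decays geometrically
  up2 <- pso_update(x = 3, v = 1, pbest = 3, gbest = 3, omega = 0.5,
                    c1 = 1.5, c2 = 1.5, r1 = 0.9, r2 = 0.2)
  expect_equal(up2$velocity, 0.5)

  up3 <- pso_update(x = 0, v = 1, pbest = 5, gbest = 7, omega = 0.5,
                    c1 = 0, c2 = 0, r1 = 1, r2 = 1)
  expect_equal(up3$velocity, 0.5)
})

test_that("genetic selection and crossover follow the stated formulas", {
  expect_equal(ga_selection_prob(c(1, 3)), c(0.25, 0.75))
  expect_equal(ga_selection_prob(c(0, 0)), c(0.5, 0.5))
  expect_equal(ga_crossover(c(0, 0), c(2, 4), 0.5), c(1, 2))
  expect_equal(ga_crossover(c(1, 1), c(9, 9), 1), c(1, 1))
  expect_error(ga_selection_prob(c(-1, 2)), "non-negative")
})

test_that("zebra moves follow the foraging and defense rules", {
  expect_equal(zoa_forage(c(2, 2), pz = c(5, 1), r = c(1, 1), I = 1),
               c(5, 1))
  # vanishing defense step at the final iteration
  expect_equal(zoa_defense(c(2, 2), az = c(0, 0), r = c(0.3, 0.9), I = 2,
                           mode = 1, t = 30, t_max = 30), c(2, 2))
  expect_equal(zoa_defense(c(1, 1), az = c(3, 3), r = c(1, 1), I = 1,
                           mode = 2, t = 1, t_max = 30), c(3, 3))
})

test_that("optimizers are seeded, bounded, and monotone in best-so-far", {
  for (alg in c("gwo", "pso", "ga", "zoa")) {
    seen <- list()
    fit <- function(x) { seen[[length(seen) + 1]] <<- x; sphere(x) }
    r1 <- mh_optimize(alg, fit, box2, pop_size = 8, max_iter = 10, seed = 4)
    expect_length(r1$trace, 10)
    expect_true(all(diff(r1$trace) <= 0))
    expect_equal(r1$best_fitness, r1$trace[10])
    pos <- do.call(rbind, seen)
    expect_true(all(pos >= -5 & pos <= 5))
    expect_equal(nrow(pos), r1$evaluations)

    r2 <- mh_optimize(alg, sphere, box2, pop_size = 8, max_iter = 10,
                      seed = 4)
    expect_identical(r1$trace, r2$trace)
    expect_identical(r1$best_position, r2$best_position)
  }
})

test_that("evaluation counts match each algorithm's bookkeeping", {
  n <- 9; iters <- 7
  evals <- vapply(c("gwo", "pso", "ga", "zoa"), function(alg) {
    mh_optimize(alg, sphere, box2, pop_size = n, max_iter = iters,
                seed = 1)$evaluations
  }, numeric(1))
  expect_equal(unname(evals["gwo"]), n * (iters + 1))
  expect_equal(unname(evals["pso"]), n * (iters + 1))
  expect_equal(unname(evals["ga"]), n + (n - 1) * iters)  # elitism spares one
  expect_equal(unname(evals["zoa"]), n + 2 * n * iters)   # two phases
})

test_that("constant fitness leaves the trace flat at the initial best", {
  for (alg in c("gwo", "pso", "ga", "zoa")) {
    r <- mh_optimize(alg, function(x) 1, box2, pop_size = 5,
                     max_iter = 6, seed = 2)
    expect_equal(r$trace, rep(1, 6))
    expect_equal(r$best_fitness, 1)
  }
})

test_that("non-finite fitness aborts with the offending position", {
  expect_error(
    mh_optimize("gwo", function(x) NaN, box2, pop_size = 4, max_iter = 2,
                seed = 1),
    "non-finite fitness")
})

test_that("gwo beats random search on the sphere at equal budget", {
  budget <- 8 * 11
  gwo_best <- vapply(1:20, function(s) {
    mh_optimize("gwo", sphere, box2, pop_size = 8, max_iter = 10,
                seed = s)$best_fitness
  }, numeric(1))
  rand_best <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      P <- matrix(runif(budget * 2, -5, 5), budget, 2)
      min(rowSums(P^2))
    })
  }, numeric(1))
  expect_lt(median(gwo_best), median(rand_best))
})

test_that("a tiny genetic population without mutation stalls early", {
  r <- mh_optimize("ga", sphere, box2, pop_size = 4, max_iter = 40,
                   seed = 6, control = list(mutation_rate = 0))
  late <- r$trace[31:40]
  expect_equal(length(unique(late)), 1)   # premature convergence
  expect_gt(r$best_fitness, 0)            # stalled short of the optimum
})
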