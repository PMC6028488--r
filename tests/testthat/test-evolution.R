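one_round_linear_config <- function(generations, seed = NULL,
                                    lambda = 1, games = 1000) {
  evolution_config(
    game_config(2, 1, wealth = 1, alpha = 1,
                risk = risk_curve("linear", lambda)),
    n_pop = 100, mu = 0.03, sigma = 0.15,
    games_per_generation = games, generations = generations, seed = seed
  )
}

test_that("fitness is the exponential of payoff", {
  expect_equal(fitness(0), 1)
  expect_equal(fitness(1), exp(1))
  pis <- sort(runif(10, -2, 2))
  expect_true(all(diff(fitness(pis)) > 0))
})

test_that("a monomorphic population is unchanged without mutation", {
  set.seed(51)
  cfg <- one_round_linear_config(1, games = 100)
  cfg$mu <- 0
  pop <- matrix(rep(c(0.5, 0.3, 0.3), each = 100), 100)
  step <- generation_step(pop, cfg)
  expect_equal(step$population, pop)
  expect_length(step$pi, 100)
  expect_length(step$parents, 100)
  expect_true(all(step$parents %in% 1:100))
})

test_that("selection is neutral when all payoffs are equal", {
  set.seed(53)
  # alpha = 0 and identical strategies: every payoff identical
  cfg <- evolution_config(
    game_config(2, 1, wealth = 1, alpha = 0,
                risk = risk_curve("linear", 1)),
    n_pop = 20, mu = 0, sigma = 0.15,
    games_per_generation = 50, generations = 1, seed = NULL
  )
  pop <- matrix(rep(c(0.5, 0.2, 0.2), each = 20), 20)
  counts <- integer(20)
  for (k in 1:500) {
    step <- generation_step(pop, cfg)
    counts <- counts + tabulate(step$parents, 20)
  }
  chi <- stats::chisq.test(counts)
  expect_gt(chi$p.value, 0.01)
})

test_that("a payoff advantage of 5 fixes almost surely", {
  set.seed(59)
  # alpha = 0 so payoff is endowment minus own contribution: contributing 5
  # of 6 versus contributing 0 gives a payoff gap of exactly 5
  cfg <- evolution_config(
    game_config(2, 1, wealth = 6, alpha = 0,
                risk = risk_curve("linear", 1)),
    n_pop = 20, mu = 0, sigma = 0.15,
    games_per_generation = 200, generations = 1
  )
  fixed <- vapply(1:200, function(run) {
    pop <- rbind(matrix(rep(c(0, 5, 5), each = 10), 10),
                 matrix(rep(c(0, 0, 0), each = 10), 10))
    for (gen in 1:15) {
      pop <- generation_step(pop, cfg)$population
      if (all(pop[, 2] == 0) || all(pop[, 2] == 5)) break
    }
    all(pop[, 2] == 0)
  }, logical(1))
  expect_gt(mean(fixed), 0.99)
})

test_that("runs are bit-identical under the same seed", {
  cfg <- one_round_linear_config(50, seed = 61, games = 100)
  fit1 <- run_evolution(cfg)
  fit2 <- run_evolution(cfg)
  expect_identical(fit1$summary, fit2$summary)
  expect_identical(fit1$populations, fit2$populations)
  game <- game_config(2, 2, wealth = c(1, 1), alpha = 1,
                      risk = risk_curve("sigmoid", 10))
  cfg2 <- evolution_config(game, n_pop = 30, games_per_generation = 100,
                           generations = 40, seed = 67)
  expect_identical(run_two_populations(cfg2)$summary,
                   run_two_populations(cfg2)$summary)
})

test_that("population size is preserved and m > N is rejected", {
  cfg <- one_round_linear_config(5, seed = 71, games = 50)
  fit <- run_evolution(cfg)
  expect_equal(dim(fit$populations[[1]]), c(100L, 3L))
  cfg_small <- evolution_config(
    game_config(8, 1, wealth = 1, alpha = 1, risk = risk_curve("linear", 1)),
    n_pop = 4, games_per_generation = 10, generations = 2
  )
  expect_error(run_evolution(cfg_small), "exceed")
})

test_that("one-round linear-risk evolution recovers the algebraic equilibrium", {
  # symmetric one-round game: the closed-form stable contribution is
  # W_i,0 / 3 for every lambda that keeps the optimum interior
  for (lam in c(0.5, 1, 2)) {
    cfg <- one_round_linear_config(2500, seed = 100 + lam, lambda = lam)
    got <- glance(run_evolution(cfg))$mean_total_contribution
    expect_lt(abs(got - 1 / 3), 0.08)
  }
})

test_that("harmless losses select contributions down to mutation load", {
  # with alpha = 0 a contribution is pure cost; the stationary mean is the
  # balance between selection and the uniform mutation influx (~0.06 W at
  # mu = 0.03), far below both the neutral mean W/2 and the alpha = 1
  # equilibrium W/3
  cfg <- evolution_config(
    game_config(2, 2, wealth = 1, alpha = 0,
                risk = risk_curve("sigmoid", 10)),
    generations = 1500, games_per_generation = 1000, seed = 73
  )
  g <- glance(run_evolution(cfg))
  expect_lt(g$mean_total_contribution / 2, 0.1)
  expect_lt(g$mean_total_contribution / 2, (1 / 3) / 3)
})

test_that("neutral drift leaves contribution traits uniform", {
  # a single-generation snapshot is coalescent-correlated, so the uniform
  # stationary marginal is checked on the time average: populations pooled
  # over widely spaced snapshots of a selection-free run
  set.seed(79)
  cfg <- one_round_linear_config(2, games = 100)
  cfg$selection <- FALSE
  pop <- unclass(random_population(100, 1, 1, tau_max = 2))
  pool <- c()
  for (snap in 1:30) {
    for (j in 1:200) pop <- generation_step(pop, cfg)$population
    pool <- c(pool, pop[, 2])
  }
  ks <- suppressWarnings(stats::ks.test(pool, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
  expect_lt(abs(mean(pool) - 0.5), 0.05)
})

test_that("identical rich and poor conditions give symmetric outcomes", {
  game <- game_config(2, 2, wealth = c(1, 1), alpha = 1,
                      risk = risk_curve("sigmoid", 10))
  cfg <- evolution_config(game, generations = 2000,
                          games_per_generation = 1000, seed = 83)
  g <- glance(run_two_populations(cfg))
  expect_setequal(g$population, c("rich", "poor"))
  gap <- abs(diff(g$mean_total_contribution))
  expect_lt(gap, 0.05 * 2)  # within stochastic tolerance of 0.05 W per round
  # strategies never cross populations: both keep their own size
  fit <- run_two_populations(cfg)
  expect_equal(vapply(fit$populations, nrow, integer(1)), c(100L, 100L))
})

test_that("two-population configs must agree on shared parameters", {
  game <- game_config(2, 1, wealth = c(4, 1), alpha = 1,
                      risk = risk_curve("sigmoid", 10))
  a <- evolution_config(game, generations = 10, games_per_generation = 10)
  b <- evolution_config(game, generations = 20, games_per_generation = 10)
  expect_error(run_two_populations(a, b), "generations")
})
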