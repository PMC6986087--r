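test_that("graded fitness separates violations from feasible sets by sign", {
  d <- data.frame(y = rep(0:1, each = 250), X1 = rnorm(500), X2 = rnorm(500))
  m <- cost_model(c(X1 = 1, X2 = 1), budget = 1)
  expect_equal(fga_fitness(c("X1", "X2"), d, "y", m), 1 - 2 / 1) # double the budget
  f_empty <- fga_fitness(character(), d, "y", m)
  expect_equal(f_empty, 1 / (2 - 2 * 500 * log(0.5)), tolerance = 1e-6)
  # any feasible set outranks any violating set
  expect_gt(f_empty, fga_fitness(c("X1", "X2"), d, "y", m))
  m_eps <- cost_model(c(X1 = 1, X2 = 1), budget = 2 - 1e-6)
  expect_lt(fga_fitness(c("X1", "X2"), d, "y", m_eps), 0)
})

test_that("fGA initialisation hits the expected cost and clamps at full inclusion", {
  set.seed(1)
  m <- cost_model(toy_costs(500, rep(1, 500)), budget = 10)
  pop <- init_population_fga(m, 400)
  mean_cost <- mean(vapply(pop, function(s) total_cost(s, m), numeric(1)))
  # expected individual cost = min(c_max, sum c) = 10; se = sqrt(p q (1-q)) / sqrt(400)
  expect_lt(abs(mean_cost - 10), 3 * sqrt(500 * 0.02 * 0.98) / sqrt(400))
  m_rich <- cost_model(toy_costs(20, rep(1, 20)), budget = 100)
  expect_true(all(lengths(init_population_fga(m_rich, 5)) == 20))
})

test_that("random forward initialisation always lands inside the budget", {
  set.seed(2)
  m <- cost_model(toy_costs(30), budget = 2)
  sets <- replicate(400, init_individual_cga(m, 1 / 500), simplify = FALSE)
  expect_true(all(vapply(sets, within_budget, logical(1), model = m)))
  expect_gt(mean(lengths(sets)), 1) # small p_stop favours filled sets
  # immediate stop and an unaffordable pool both give the empty set
  expect_length(init_individual_cga(m, p_stop = 1), 0)
  m_tight <- cost_model(c(a = 0.5, b = 0.9), budget = 0.2)
  expect_length(init_individual_cga(m_tight), 0)
})

test_that("cost-constrained crossover preserves parents' shared features and the budget", {
  set.seed(3)
  m <- cost_model(toy_costs(20, rep(1, 20)), budget = 10)
  a <- paste0("X", 1:10); b <- paste0("X", 11:20) # disjoint, budget-filling
  for (i in 1:300) {
    kids <- cc_crossover(a, b, m)
    expect_true(within_budget(kids$child_a, m))
    expect_true(within_budget(kids$child_b, m))
  }
  same <- cc_crossover(a, a, m)
  expect_setequal(same$child_a, a)
  expect_setequal(same$child_b, a)
  from_one <- cc_crossover(character(), a, m)
  expect_true(all(c(from_one$child_a, from_one$child_b) %in% a))
  expect_error(cc_crossover(c(a, "X11"), b, m), "feasible")
})

test_that("cost-constrained mutation follows the add probability and stays feasible", {
  m <- cost_model(toy_costs(10, rep(0.1, 10)), budget = 0.5)
  # empty set: P(add) = 1
  set.seed(4)
  expect_true(all(replicate(50, length(cc_mutate(character(), m))) == 1))
  # full budget: P(add) = 0, a member is removed
  full <- paste0("X", 1:5)
  expect_true(all(replicate(50, length(cc_mutate(full, m))) == 4))
  # half budget: P(add) = 0.5 within 3 binomial SEs
  half <- paste0("X", 1:2) # cost 0.2... use 0.25 of 0.5: adjust to exactly half
  m2 <- cost_model(toy_costs(10, rep(0.1, 10)), budget = 0.4)
  n_trials <- 20000
  added <- replicate(n_trials, length(cc_mutate(half, m2)) == 3)
  expect_lt(abs(mean(added) - 0.5), 3 * sqrt(0.25 / n_trials))
  # feasibility closure under fuzzed costs/budgets
  set.seed(5)
  for (i in 1:200) {
    mm <- cost_model(toy_costs(8), budget = runif(1, 0.1, 3))
    s <- init_individual_cga(mm, 0.1)
    expect_true(within_budget(cc_mutate(s, mm), mm))
  }
})

test_that("linear-rank selection weights survivors by fitness rank only", {
  set.seed(6)
  expect_equal(rank_selection(5), 1)
  picks <- rank_selection(c(0.1, 0.9), size = 30000)
  expect_lt(abs(mean(picks == 2) - 2 / 3), 3 * sqrt(2 / 9 / 30000))
  # permutation invariance: distribution depends on fitness ranks, not order
  picks_rev <- rank_selection(c(0.9, 0.1), size = 30000)
  expect_lt(abs(mean(picks_rev == 1) - 2 / 3), 0.02)
  expect_error(rank_selection(c(1, NA)), "finite")
})

test_that("cGA evaluates only feasible individuals and runs deterministically", {
  d <- toy_data(n = 120, p = 8, p_informative = 2, beta = 1.2, seed = 7)
  m <- cost_model(toy_costs(8), budget = 1)
  r1 <- select_ga(d, "y", m, "cga", population_size = 30, max_iterations = 15, seed = 42)
  r2 <- select_ga(d, "y", m, "cga", population_size = 30, max_iterations = 15, seed = 42)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$trace, r2$trace)
  expect_true(within_budget(r1$selected, m))
  expect_true(all(diff(r1$trace$best_so_far) >= 0))
})

test_that("fGA reports an explicit infeasible result when nothing fits", {
  d <- toy_data(n = 60, p = 3, seed = 8)
  # budget below every single cost, so no feasible set other than {} exists;
  # force a start deep in the infeasible region and forbid emptying it
  m <- cost_model(toy_costs(3, c(0.5, 0.6, 0.7)), budget = 0.1)
  res <- suppressWarnings(
    select_ga(d, "y", m, "fga", population_size = 10, max_iterations = 3,
              mutation_rate = 0, crossover_rate = 0, init = "uniform", seed = 9)
  )
  # the empty set is feasible and reachable only via mutation; with mutation
  # off the run may never see it -> either a feasible empty set or the
  # explicit infeasible flag, never a silent budget violation
  expect_true(res$feasible || length(res$selected) == 0)
  expect_true(within_budget(res$selected, m))
})

test_that("best-so-far fitness is non-decreasing for both variants", {
  d <- toy_data(n = 100, p = 6, p_informative = 2, beta = 1, seed = 10)
  m <- cost_model(toy_costs(6), budget = 1)
  for (v in c("cga", "fga")) {
    res <- select_ga(d, "y", m, v, population_size = 20, max_iterations = 10,
                     seed = 11)
    expect_true(all(diff(res$trace$best_so_far) >= 0))
  }
})
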