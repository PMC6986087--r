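test_that("the preset grid reproduces the published parameter combinations", {
  grid <- setting_presets()
  expect_equal(nrow(grid), 11)
  a <- setting_spec("A")
  expect_equal(list(a$gamma, a$p, a$p_rel, a$beta), list(1/2, 30L, 18L, 0.3))
  c_ <- setting_spec("C")
  expect_equal(list(c_$gamma, c_$p, c_$p_rel, c_$beta), list(1/3, 300L, 30L, 0.5))
  e <- setting_spec("E")
  expect_equal(list(e$gamma, e$p, e$p_rel, e$beta), list(2, 1500L, 15L, 0.5))
  expect_equal(setting_spec("H")$cost_rule, "effect_dependent")
  expect_equal(setting_spec("G")$generation_model, "logistic")
  expect_equal(setting_spec("J")$cost_rule, "correlated")
  expect_equal(setting_spec("K")$distribution_rule, "heavy_tail_mixture")
  expect_equal(a$n_train, 500L)
  expect_equal(a$n_test, 10000L)
  expect_equal(a$n_replicates, 100L)
  expect_error(setting_spec("Z")) # non-preset label without parameters
})

test_that("effect vectors follow the constant and equidistant rules", {
  mu_d <- build_mu(setting_spec("D"))
  expect_length(mu_d, 300)
  expect_equal(mu_d[1:3], rep(0.5, 3))
  expect_true(all(mu_d[4:300] == 0))
  mu_i <- build_mu(setting_spec("I"))
  expect_equal(mu_i[1:30], (30:1) / 30)
  expect_equal(max(mu_i), 1)
  expect_true(all(mu_i[31:300] == 0))
  empty <- setting_spec("custom", gamma = 0, p = 5, p_rel = 0, beta = 0.5)
  expect_equal(build_mu(empty), rep(0, 5))
})

test_that("class-conditional generation shifts relevant features by beta", {
  set.seed(1)
  spec <- setting_spec("custom", gamma = 1, p = 4, p_rel = 2, beta = 0.7,
                       n_train = 10000)
  d <- generate_class_conditional(spec)
  expect_lt(abs(mean(d$y) - 0.5), 3 * 0.5 / sqrt(10000))
  diff_rel <- mean(d$X1[d$y == 1]) - mean(d$X1[d$y == 0])
  diff_noise <- mean(d$X4[d$y == 1]) - mean(d$X4[d$y == 0])
  se <- sqrt(4 / 10000)
  expect_lt(abs(diff_rel - 0.7), 3 * se)
  expect_lt(abs(diff_noise), 3 * se)
})

test_that("logistic generation balances classes at mu = 0 and recovers mu by refit", {
  set.seed(2)
  null_spec <- setting_spec("custom", gamma = 0, p = 3, p_rel = 0, beta = 0,
                            generation_model = "logistic", n_train = 8000)
  d0 <- generate_logistic(null_spec)
  expect_lt(abs(mean(d0$y) - 0.5), 3 * 0.5 / sqrt(8000))
  # features stay marginally standard normal regardless of y
  expect_lt(abs(mean(d0$X1)), 3 / sqrt(8000))
  expect_lt(abs(stats::sd(d0$X1) - 1), 0.05)

  spec <- setting_spec("custom", gamma = 1, p = 3, p_rel = 2, beta = 0.8,
                       generation_model = "logistic", n_train = 8000)
  d <- generate_logistic(spec)
  fit <- stats::glm(y ~ X1 + X2 + X3, binomial, data = d)
  ses <- sqrt(diag(stats::vcov(fit)))
  expect_lt(abs(stats::coef(fit)[["X1"]] - 0.8), 3 * ses[["X1"]])
  expect_lt(abs(stats::coef(fit)[["X3"]]), 3 * ses[["X3"]])
})

test_that("block-exchangeable covariance is positive definite and degenerates to identity", {
  expect_equal(make_correlated_covariance(6, block_size = 3, rho = 0),
               diag(6))
  expect_equal(make_correlated_covariance(6, block_size = 1, rho = 0.9),
               diag(6))
  sigma <- make_correlated_covariance(7, block_size = 3, rho = 0.7)
  expect_true(all(eigen(sigma, symmetric = TRUE)$values > 0))
  expect_equal(sigma[1, 2], 0.7)
  expect_equal(sigma[1, 4], 0) # across blocks
  expect_error(make_correlated_covariance(4, rho = 1), "rho")
  # correlated draws actually carry the block structure
  set.seed(3)
  x <- costsel:::rmvn(5000, 6, make_correlated_covariance(6, 3, 0.7))
  expect_gt(cor(x[, 1], x[, 2]), 0.6)
  expect_lt(abs(cor(x[, 1], x[, 4])), 0.06)
})

test_that("heavy-tail mixture keeps the mean and inflates variance and kurtosis", {
  set.seed(4)
  x <- sample_heavy_tail(c(0.5, 0), 40000)
  expect_lt(abs(mean(x[, 1]) - 0.5), 3 * sqrt(3.4 / 40000))
  expect_lt(abs(stats::var(x[, 2]) - 3.4), 0.15)
  z <- x[, 2]
  kurt <- mean((z - mean(z))^4) / stats::var(z)^2 - 3
  expect_gt(kurt, 1)
})

test_that("realised settings tie costs, budget and data together consistently", {
  set.seed(5)
  b_spec <- setting_spec("B", n_test = 200)
  inst <- realize_setting(b_spec)
  expect_equal(nrow(inst$train), 500)
  expect_equal(nrow(inst$test), 200)
  expect_equal(sum(inst$relevant), 3)
  # gamma = 2/3 on 3 relevant features: budget is the two cheapest
  rel_costs <- sort(inst$model$costs[inst$relevant])
  expect_equal(inst$model$budget, sum(rel_costs[1:2]))
  # gamma <= 1: budget never exceeds total relevant cost
  expect_lte(inst$model$budget, sum(inst$model$costs[inst$relevant]))
  # gamma > 1 (unconstrained): budget exceeds the total relevant cost
  set.seed(6)
  e_inst <- realize_setting(setting_spec("E", p = 60, p_rel = 15, n_test = 50,
                                         n_train = 50))
  expect_gt(e_inst$model$budget, sum(e_inst$model$costs[e_inst$relevant]))
  # Setting-H cost split: relevant mean 0.7, noise mean 0.4
  set.seed(7)
  h_inst <- realize_setting(setting_spec("H", p = 10000, p_rel = 5000,
                                         n_train = 5, n_test = 5))
  expect_lt(abs(mean(h_inst$model$costs[h_inst$relevant]) - 0.7), 0.01)
  expect_lt(abs(mean(h_inst$model$costs[!h_inst$relevant]) - 0.4), 0.01)
})

test_that("a fixed seed reproduces a realisation bitwise", {
  spec <- setting_spec("A", n_test = 100)
  set.seed(123); r1 <- realize_setting(spec)
  set.seed(123); r2 <- realize_setting(spec)
  expect_identical(r1$train, r2$train)
  expect_identical(r1$model$costs, r2$model$costs)
})

test_that("specs round-trip through serialization unchanged", {
  path <- tempfile(fileext = ".json")
  for (label in c("A", "G", "I", "K")) {
    spec <- setting_spec(label)
    write_setting(spec, path)
    expect_equal(read_setting(path), spec)
  }
  unlink(path)
})
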