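test_that("vectorised t-test matches stats::t.test per feature", {
  d <- toy_data(n = 60, p = 5, p_informative = 2, beta = 1, seed = 1)
  ranking <- score_ttest(d, "y")
  for (f in paste0("X", 1:5)) {
    ref <- stats::t.test(d[[f]][d$y == 1], d[[f]][d$y == 0])$p.value
    expect_equal(ranking$score[ranking$feature == f], ref, tolerance = 1e-10)
  }
  expect_identical(attr(ranking, "direction"), "lower")
})

test_that("t-test p-values are affine invariant and powered at a 1-sd shift", {
  d <- toy_data(n = 500, p = 2, p_informative = 1, beta = 1, seed = 2)
  p1 <- score_ttest(d, "y")$score[1]
  d$X1 <- 3 * d$X1 - 7
  expect_equal(score_ttest(d, "y")$score[1], p1, tolerance = 1e-9)
  expect_lt(p1, 1e-10) # group means 0 vs 1 at n = 500
  d$X2 <- 1 # constant in both groups
  expect_true(is.na(score_ttest(d, "y")$score[2]))
})

test_that("null t-test p-values are approximately uniform", {
  set.seed(3)
  pvals <- replicate(1000, {
    d <- data.frame(y = rep(0:1, each = 15), X1 = rnorm(30))
    score_ttest(d, "y")$score[1]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("symmetric uncertainty is symmetric, maximal for a copy, null for noise", {
  set.seed(4)
  y <- rbinom(400, 1, 0.5)
  d <- data.frame(y = y, copy = y + 0.001 * (seq_along(y) %% 2), indep = rnorm(400))
  su <- score_symmetric_uncertainty(d, "y", bins = 2)
  expect_gt(su$score[su$feature == "copy"], 0.95)
  expect_lt(su$score[su$feature == "indep"], 0.05)
  # symmetry SU(X;Y) = SU(Y;X): swap the roles of two exactly balanced
  # binary variables so the 2-bin discretisation is lossless in both
  x_bal <- rep(0:1, each = 200)
  y_bal <- x_bal
  y_bal[c(1:20, 201:220)] <- 1 - y_bal[c(1:20, 201:220)] # flip 40 symmetric
  su_xy <- score_symmetric_uncertainty(data.frame(y = y_bal, x = x_bal),
                                       "y", bins = 2)$score
  su_yx <- score_symmetric_uncertainty(data.frame(y = x_bal, x = y_bal),
                                       "y", bins = 2)$score
  expect_equal(su_xy, su_yx, tolerance = 1e-10)
  d$flat <- 1
  expect_equal(score_symmetric_uncertainty(d, "y")$score[3], 0)
})

test_that("the scorer adapter enforces its contract and preserves orderings", {
  d <- toy_data(n = 80, p = 4, p_informative = 2, beta = 1.2, seed = 5)
  m <- cost_model(toy_costs(4, rep(0.3, 4)), budget = 0.6)
  neg_p <- function(data, response) -score_ttest(data, response)$score
  adapted <- select_filter(d, "y", m, "external", scorer = neg_p, threshold = NA)
  direct <- select_filter(d, "y", m, "ttest", threshold = NA)
  expect_identical(adapted$selected, direct$selected)
  expect_error(score_adapter(d, "y", function(data, response) 1:2),
               "one value per feature")
  expect_error(score_adapter(d, "y", function(data, response) c(1, NaN, 3, 4)),
               "X2")
  const <- score_adapter(d, "y", function(data, response) rep(1, 4))
  expect_equal(filter_select_topdown(const, m), c("X1", "X2")) # index tie-break
})

test_that("a random-forest impurity scorer plugs in through the adapter", {
  skip_if_not_installed("ranger")
  d <- toy_data(n = 150, p = 5, p_informative = 1, beta = 1.5, seed = 8)
  m <- cost_model(toy_costs(5, rep(0.2, 5)), budget = 0.4)
  impurity <- function(data, response) {
    fit <- ranger::ranger(x = data[setdiff(names(data), response)],
                          y = factor(data[[response]]),
                          importance = "impurity", num.trees = 100, seed = 1)
    fit$variable.importance
  }
  res <- select_filter(d, "y", m, "external", scorer = impurity)
  expect_true("X1" %in% res$selected)
  expect_true(within_budget(res$selected, m))
})

test_that("top-down walk skips unaffordable features without blocking later ones", {
  ranking <- costsel:::new_importance_ranking(c("A", "B", "C"),
                                              c(3, 2, 1), "higher", "toy")
  m <- cost_model(c(A = 0.9, B = 0.5, C = 0.5), budget = 1)
  # A fits (0.9); B and C each exceed the remaining 0.1 -> {A}
  expect_equal(filter_select_topdown(ranking, m), "A")
  m2 <- cost_model(c(A = 1.1, B = 0.5, C = 0.5), budget = 1)
  # A never fits but must not block B and C
  expect_equal(filter_select_topdown(ranking, m2), c("B", "C"))
  expect_equal(filter_select_topdown(ranking, m2, stop_at_first_unaffordable = TRUE),
               character())
  expect_length(filter_select_topdown(ranking, cost_model(m$costs, 0)), 0)
})

test_that("equal costs reduce top-down selection to the top-k ranked features", {
  set.seed(6)
  for (i in 1:5) {
    p <- sample(5:12, 1)
    sc <- runif(p)
    ranking <- costsel:::new_importance_ranking(paste0("X", 1:p), sc, "higher", "toy")
    k <- sample(seq_len(p), 1)
    m <- cost_model(toy_costs(p, rep(0.2, p)), budget = 0.2 * k + 1e-12)
    expect_setequal(filter_select_topdown(ranking, m),
                    paste0("X", order(-sc)[seq_len(k)]))
  }
})

test_that("default thresholds stop the walk at uninformative features", {
  d <- toy_data(n = 400, p = 6, p_informative = 1, beta = 2, seed = 7)
  m <- cost_model(toy_costs(6, rep(0.1, 6)), budget = 10)
  res <- select_filter(d, "y", m, "ttest") # default threshold 0.05
  expect_true("X1" %in% res$selected)
  # noise p-values sit mostly above 0.05, so the walk stops well short of all 6
  expect_lt(length(res$selected), 6)
  all_in <- select_filter(d, "y", m, "ttest", threshold = NA)
  expect_equal(length(all_in$selected), 6)
  expect_true(within_budget(res$selected, m))
})
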