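#' Precision and recall of relevant-feature recovery
#'
#' Summarises the 2x2 contingency of relevance vs. selection: precision is
#' the share of selected features that are truly relevant ("what portion of
#' the selected features is actually relevant?"), recall the share of all
#' relevant features that were selected. An empty selection has recall 0 and
#' missing precision (excluded from averages rather than scored 0 or 1).
#'
#' @param selected Character vector of selected feature ids.
#' @param relevant Named logical vector over the full feature universe.
#' @return One-row tibble: `n_selected`, `n_relevant_selected`, `precision`,
#'   `recall`.
#' @examples
#' recovery_metrics(c("X1", "X4"), c(X1 = TRUE, X2 = TRUE, X3 = FALSE, X4 = FALSE))
#' @export
recovery_metrics <- function(selected, relevant) {
  if (is.null(names(relevant))) abort("relevant must be a named logical vector")
  unknown <- setdiff(selected, names(relevant))
  if (length(unknown) > 0) {
    abort(paste0("selected feature(s) outside the universe: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  n_sel <- length(selected)
  n_rel_sel <- sum(relevant[selected])
  p_rel <- sum(relevant)
  tibble(
    n_selected = n_sel,
    n_relevant_selected = n_rel_sel,
    precision = if (n_sel > 0) n_rel_sel / n_sel else NA_real_,
    recall = if (p_rel > 0) n_rel_sel / p_rel else 0
  )
}

#' Reference values for random feature selection
#'
#' Expected recovery metrics when features are selected uniformly at
#' random, from the hypergeometric distribution: a random subset of size `n`
#' contains `n * p_rel / p` relevant features in expectation, so the
#' expected precision is `p_rel / p` regardless of the subset size. For
#' recall the subset size matters; it is estimated as the average model size
#' a budget allows, `budget / mean_cost`, giving recall
#' `budget / (mean_cost * p)` (capped at 1).
#'
#' @param p Total number of features.
#' @param p_rel Number of relevant features.
#' @param budget Cost budget.
#' @param mean_cost Mean per-feature cost.
#' @return Expected precision / recall as a ratio in \\[0, 1\\].
#' @examples
#' random_precision(300, 30) # 0.1
#' @export
random_precision <- function(p, p_rel) {
  stopifnot(p >= 1, p_rel >= 0, p_rel <= p)
  p_rel / p
}

#' @rdname random_precision
#' @export
random_recall <- function(budget, mean_cost, p, p_rel) {
  stopifnot(mean_cost > 0, p >= 1)
  min(1, budget / (mean_cost * p))
}

#' Budget-violation probability of unconstrained uniform crossover
#'
#' For two budget-filling parents with `n_disjoint` non-shared unit-cost
#' features, a cost-agnostic uniform crossover assigns each non-shared
#' feature to a child by fair coin, so a child's size is
#' `Binomial(n_disjoint, 1/2)` and it violates the budget whenever that
#' count exceeds `budget / unit_cost`. With 20 disjoint features and budget
#' 10 the violation probability is `P(Bin(20, 1/2) >= 11) = 0.412` — the
#' motivation for the cost-constrained crossover, which violates in 0% of
#' cases by construction.
#'
#' @param n_disjoint Number of features present in exactly one parent.
#' @param budget Cost budget.
#' @param unit_cost Cost per feature (default 1).
#' @param mode `"analytic"` (exact binomial tail) or `"montecarlo"`.
#' @param n_trials Monte-Carlo trials.
#' @return Violation probability in \\[0, 1\\].
#' @export
crossover_violation_probability <- function(n_disjoint, budget, unit_cost = 1,
                                            mode = c("analytic", "montecarlo"),
                                            n_trials = 100000) {
  mode <- match.arg(mode)
  stopifnot(n_disjoint >= 0, unit_cost > 0)
  k_max <- floor(budget / unit_cost) # largest feasible child size
  if (mode == "analytic") {
    pbinom(k_max, n_disjoint, 0.5, lower.tail = FALSE)
  } else {
    mean(rbinom(n_trials, n_disjoint, 0.5) > k_max)
  }
}

#' Add probability of the cost-agnostic mutation
#'
#' The cost-agnostic mutation toggles a uniformly random feature, so it
#' adds (rather than removes) whenever the drawn feature is absent from the
#' current set: probability `(p - set_size) / p`. Near-exhausted budgets
#' with small sets in large pools make this almost always an addition
#' (0.98 at p = 500, set size 10), hence almost always a violation — the
#' motivation for the explicit add/remove decision of [cc_mutate()].
#'
#' @param p Total number of features.
#' @param set_size Current set size.
#' @return Probability in \\[0, 1\\].
#' @export
naive_mutation_add_probability <- function(p, set_size) {
  stopifnot(p >= 1, set_size >= 0, set_size <= p)
  (p - set_size) / p
}

#' Run one selector on a realised setting instance
#'
#' @param inst A [realize_setting()] result.
#' @param method One of `"fs"`, `"cfs"`, `"cfs_mean"`, `"cfs_max"`, `"fga"`,
#'   `"cga"`, `"filter_ttest"`, `"filter_symuncert"`.
#' @param ga_control Named list of overrides passed to [select_ga()]
#'   (e.g. `list(population_size = 100, max_iterations = 50)`).
#' @return A [selection_result].
#' @export
run_method <- function(inst, method, ga_control = list()) {
  d <- inst$train; m <- inst$model
  if (method %in% c("fs", "cfs", "cfs_mean", "cfs_max")) {
    select_forward(d, "y", m, strategy = method)
  } else if (method %in% c("fga", "cga")) {
    do.call(select_ga, c(list(d, "y", m, variant = method), ga_control))
  } else if (method == "filter_ttest") {
    select_filter(d, "y", m, method = "ttest")
  } else if (method == "filter_symuncert") {
    select_filter(d, "y", m, method = "symuncert")
  } else {
    abort(paste0("unknown method: ", method))
  }
}

#' Multi-setting benchmark of budgeted feature selectors
#'
#' For every setting, method and replicate: realises the setting (costs,
#' budget, train/test data), runs the selector, and records the test AUC of
#' the refit logistic model, the recovery metrics against the true
#' relevance mask, the model size and cost, and the wall time. Replicate
#' `b` re-seeds the generator with `master_seed + b`, so the whole table is
#' reproducible and each method within a replicate sees the identical
#' instance. A method failure on one replicate is recorded as a row with
#' missing metrics, not an error.
#'
#' @param specs List of [setting_spec()] objects (a single spec is
#'   accepted).
#' @param methods Character vector of method labels (see [run_method()]).
#' @param n_replicates Replicates per setting (defaults to each spec's
#'   `n_replicates`).
#' @param master_seed Integer master seed.
#' @param ga_control Passed to [run_method()] for the GA variants.
#' @return Tidy tibble: `setting`, `method`, `replicate`, `auc`,
#'   `precision`, `recall`, `n_selected`, `total_cost`, `budget`, `gamma`,
#'   `seconds`, `error`.
#' @seealso [benchmark_reference()] for the analytic reference rows,
#'   [plot_benchmark()] and [plot_recovery()] for display.
#' @export
run_benchmark <- function(specs, methods, n_replicates = NULL,
                          master_seed = 1, ga_control = list()) {
  if (inherits(specs, "setting_spec")) specs <- list(specs)
  rows <- purrr::map_dfr(specs, function(spec) {
    reps <- n_replicates %||% spec$n_replicates
    purrr::map_dfr(seq_len(reps), function(b) {
      set.seed(master_seed + b)
      inst <- realize_setting(spec)
      purrr::map_dfr(methods, function(method) {
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(run_method(inst, method, ga_control),
                        error = function(e) e)
        secs <- proc.time()[["elapsed"]] - t0
        if (inherits(res, "error")) {
          return(tibble(setting = spec$label, method = method, replicate = b,
                        auc = NA_real_, precision = NA_real_, recall = NA_real_,
                        n_selected = NA_integer_, total_cost = NA_real_,
                        budget = inst$model$budget, gamma = spec$gamma,
                        seconds = secs, error = conditionMessage(res)))
        }
        rec <- recovery_metrics(res$selected, inst$relevant)
        tibble(setting = spec$label, method = method, replicate = b,
               auc = evaluate_auc(res$fit, inst$test, "y"),
               precision = rec$precision, recall = rec$recall,
               n_selected = rec$n_selected, total_cost = res$total_cost,
               budget = inst$model$budget, gamma = spec$gamma,
               seconds = secs, error = NA_character_)
      })
    })
  })
  out <- rows
  if (nrow(out) == 0) {
    out <- tibble(setting = character(), method = character(),
                  replicate = integer(), auc = numeric(),
                  precision = numeric(), recall = numeric(),
                  n_selected = integer(), total_cost = numeric(),
                  budget = numeric(), gamma = numeric(),
                  seconds = numeric(), error = character())
  }
  out
}

#' Analytic reference rows for a benchmark
#'
#' Per-setting reference quantities that need no simulation: the hard
#' recall ceiling implied by the budget (`min(gamma, 1)` for the relative
#' budget definition) and the expected precision of random selection
#' (`p_rel / p`).
#'
#' @param specs List of [setting_spec()] objects (or a single spec).
#' @return Tibble: `setting`, `recall_cap`, `random_precision`.
#' @export
benchmark_reference <- function(specs) {
  if (inherits(specs, "setting_spec")) specs <- list(specs)
  dplyr::bind_rows(purrr::map(specs, function(spec) {
    tibble(setting = spec$label,
           recall_cap = min(spec$gamma, 1),
           random_precision = random_precision(spec$p, spec$p_rel))
  }))
}

#' Benchmark summary and plots
#'
#' `summarize_benchmark()` aggregates a [run_benchmark()] table per setting
#' and method: mean AUC with its 0.05/0.95 quantiles, mean precision
#' (missing precisions from empty selections excluded), mean recall and
#' mean model size. `plot_benchmark()` shows the AUC distributions as
#' boxplots per method, faceted by setting; `plot_recovery()` shows the
#' mean precision-recall positions with the budget recall ceiling and the
#' random-selection precision as reference lines.
#'
#' @param results Tibble from [run_benchmark()].
#' @return A tibble (`summarize_benchmark`) or a ggplot object.
#' @export
summarize_benchmark <- function(results) {
  results |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$setting, .data$method) |>
    dplyr::summarise(
      n = dplyr::n(),
      auc_mean = mean(.data$auc),
      auc_q05 = quantile(.data$auc, 0.05, names = FALSE),
      auc_q95 = quantile(.data$auc, 0.95, names = FALSE),
      precision_mean = mean(.data$precision, na.rm = TRUE),
      recall_mean = mean(.data$recall),
      size_mean = mean(.data$n_selected),
      .groups = "drop"
    )
}

#' @rdname summarize_benchmark
#' @export
plot_benchmark <- function(results) {
  ggplot2::ggplot(dplyr::filter(results, is.na(.data$error)),
                  ggplot2::aes(.data$method, .data$auc)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 2.5) +
    ggplot2::facet_wrap(~setting, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "test AUC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname summarize_benchmark
#' @export
plot_recovery <- function(results) {
  summ <- summarize_benchmark(results)
  ref <- results |>
    dplyr::distinct(.data$setting, .data$gamma)
  ggplot2::ggplot(summ, ggplot2::aes(.data$recall_mean, .data$precision_mean,
                                     label = .data$method)) +
    ggplot2::geom_vline(data = ref,
                        ggplot2::aes(xintercept = pmin(.data$gamma, 1)),
                        colour = "darkgreen", linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::facet_wrap(~setting) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall (relevant features found)",
                  y = "precision (selected features relevant)") +
    ggplot2::theme_minimal()
}
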