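#' Construct a cost model
#'
#' Bundles per-feature acquisition costs with the hard budget that a selected
#' feature set must satisfy: the sum of member costs may not exceed
#' `budget`. Costs are in abstract cost units (money, time, patient burden,
#' ...); the budget is in the same units.
#'
#' @param costs Named numeric vector of strictly positive per-feature costs,
#'   or a two-column data frame `(feature, cost)`.
#' @param budget Non-negative scalar cost limit.
#' @param gamma Optional non-negative ratio recording how the budget was
#'   derived relative to the total cost of relevant features (see
#'   [compute_budget()]); purely informational here.
#' @return An object of class `cost_model`: a list with elements `costs`
#'   (named numeric), `budget`, and `gamma`.
#' @examples
#' cost_model(c(X1 = 0.3, X2 = 0.7), budget = 1)
#' @export
cost_model <- function(costs, budget, gamma = NULL) {
  if (is.data.frame(costs)) {
    if (ncol(costs) < 2) abort("cost data frame needs columns (feature, cost)")
    costs <- setNames(as.numeric(costs[[2]]), as.character(costs[[1]]))
  }
  if (is.null(names(costs)) || anyDuplicated(names(costs))) {
    abort("costs must be uniquely named by feature id")
  }
  if (any(!is.finite(costs)) || any(costs <= 0)) {
    bad <- names(costs)[!is.finite(costs) | costs <= 0]
    abort(paste0("all feature costs must be strictly positive; offending: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (!is.numeric(budget) || length(budget) != 1 || budget < 0) {
    abort("budget must be a single non-negative number")
  }
  if (!is.null(gamma) && (!is.numeric(gamma) || gamma < 0)) {
    abort("gamma must be non-negative")
  }
  structure(list(costs = costs, budget = as.numeric(budget), gamma = gamma),
            class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat("<cost_model> ", length(x$costs), " features, budget ",
      format(x$budget, digits = 4),
      if (!is.null(x$gamma)) paste0(" (gamma = ", format(x$gamma, digits = 4), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Sample feature costs
#'
#' Cost-generating rules used by the simulation settings. `sample_costs_uniform()`
#' draws each cost from Uniform(0.1, 1), the regime where costs carry no
#' information about effects. `sample_costs_effect_dependent()` makes relevant
#' features more expensive on average (Uniform(0.4, 1), mean 0.7) than noise
#' features (Uniform(0.1, 0.7), mean 0.4). `sample_costs_correlated()` couples
#' each cost to the feature's effect size via Uniform(0.1 + mu/2, 0.5 + mu/2).
#'
#' @param p Number of features.
#' @param relevant Logical vector marking truly relevant features.
#' @param mu Non-negative effect-size vector, one entry per feature.
#' @return Numeric vector of positive costs (unnamed).
#' @seealso [cost_model()], [realize_setting()]
#' @export
sample_costs_uniform <- function(p) {
  stopifnot(p >= 0)
  runif(p, 0.1, 1)
}

#' @rdname sample_costs_uniform
#' @export
sample_costs_effect_dependent <- function(relevant) {
  stopifnot(is.logical(relevant))
  p <- length(relevant)
  out <- numeric(p)
  out[relevant] <- runif(sum(relevant), 0.4, 1)
  out[!relevant] <- runif(sum(!relevant), 0.1, 0.7)
  out
}

#' @rdname sample_costs_uniform
#' @export
sample_costs_correlated <- function(mu) {
  if (any(mu < 0)) abort("effect sizes must be non-negative")
  runif(length(mu), 0.1 + mu / 2, 0.5 + mu / 2)
}

#' Budget implied by a relative constraint ratio
#'
#' Derives the hard budget from the costs of the truly relevant features and
#' a ratio `gamma`. For `gamma <= 1` the budget is the summed cost of the
#' cheapest relevant features up to the `gamma`-quantile of the relevant cost
#' distribution, so at most a `gamma`-share of the relevant information fits.
#' For `gamma > 1` all relevant features fit, plus headroom of
#' `(gamma - 1) * p_rel` features at the overall mean cost:
#' `sum(relevant costs) + (gamma - 1) * mean(costs) * p_rel`.
#'
#' The quantile is the inclusive empirical quantile (order statistic at
#' `ceiling(gamma * p_rel)`), so `gamma = 0.5` admits exactly the cheapest
#' half of the relevant features for even counts; cost ties at the quantile
#' are all included.
#'
#' @param costs Positive cost vector for all `p` features.
#' @param relevant Logical vector (length `p`) marking relevant features.
#' @param gamma Non-negative ratio.
#' @return Scalar budget.
#' @examples
#' compute_budget(c(0.2, 0.5, 0.9), c(TRUE, TRUE, FALSE), gamma = 1) # 0.7
#' @export
compute_budget <- function(costs, relevant, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0) {
    abort("gamma must be a single non-negative number")
  }
  stopifnot(length(costs) == length(relevant))
  rel_costs <- costs[relevant]
  if (gamma > 0 && length(rel_costs) == 0) {
    abort("at least one relevant feature is required when gamma > 0")
  }
  if (gamma <= 1) {
    k <- ceiling(gamma * length(rel_costs))
    if (k == 0) return(0)
    q <- sort(rel_costs)[k]
    sum(rel_costs[rel_costs <= q])
  } else {
    sum(rel_costs) + (gamma - 1) * mean(costs) * length(rel_costs)
  }
}

#' Total cost and budget feasibility of a feature set
#'
#' @param members Character vector of feature ids.
#' @param model A [cost_model()].
#' @return `total_cost()`: the summed cost of the members. `within_budget()`:
#'   `TRUE` if that sum does not exceed the budget (within an absolute
#'   tolerance of 1e-9, so exactly-full sets count as feasible).
#' @export
total_cost <- function(members, model) {
  if (length(members) == 0) return(0)
  unknown <- setdiff(members, names(model$costs))
  if (length(unknown) > 0) {
    abort(paste0("unknown feature id(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  sum(model$costs[members])
}

#' @rdname total_cost
#' @export
within_budget <- function(members, model) {
  total_cost(members, model) <= model$budget + BUDGET_TOL
}
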