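#' Graded constraint-violation fitness
#'
#' Fitness of a candidate feature set for the fitness-adapted genetic
#' algorithm: sets that violate the budget score `1 - costs(s)/c_max`
#' (strictly negative, more negative for larger violations, so the search
#' can evolve towards the feasible region), while feasible sets score
#' `1 / AIC`. The sign therefore encodes feasibility exactly, provided the
#' AIC is positive; a non-positive AIC inside the budget breaks that
#' contract and is raised as an error.
#'
#' @param members Character vector of feature ids (the candidate set).
#' @param data Training data frame.
#' @param response Name of the 0/1 response column.
#' @param model A [cost_model()] with `budget > 0`.
#' @param fit_fun Optional AIC evaluator `function(members) -> scored_fit`
#'   (used internally to share a fit cache).
#' @return Scalar fitness (maximised).
#' @export
fga_fitness <- function(members, data, response, model, fit_fun = NULL) {
  if (model$budget <= 0) abort("fga fitness requires a positive budget")
  cost <- total_cost(members, model)
  if (cost > model$budget + BUDGET_TOL) return(1 - cost / model$budget)
  aic <- if (is.null(fit_fun)) fit_aic(data, response, members)$aic else fit_fun(members)$aic
  if (aic <= 0) {
    abort("AIC <= 0 inside the budget: negative fitness values are reserved for constraint violations")
  }
  1 / aic
}

#' Initial population for the fitness-adapted GA
#'
#' Each feature enters each individual independently with probability
#' `min(1, c_max / sum(costs))`, so the expected total cost of an individual
#' is `min(c_max, sum(costs))`: the population starts centred on the budget
#' boundary rather than deep in the infeasible region. An alternative
#' `inclusion_prob` (e.g. 0.5 for a plain random population) can be supplied
#' to reproduce unconstrained starting conditions.
#'
#' @param model A [cost_model()].
#' @param size Population size.
#' @param inclusion_prob Per-feature inclusion probability; defaults to the
#'   cost-scaled rule above.
#' @return List of `size` character vectors of feature ids.
#' @export
init_population_fga <- function(model, size, inclusion_prob = NULL) {
  stopifnot(size >= 1)
  ids <- names(model$costs)
  pr <- inclusion_prob %||% min(1, model$budget / sum(model$costs))
  lapply(seq_len(size), function(i) ids[runif(length(ids)) < pr])
}

#' Random forward initialisation of one budget-feasible individual
#'
#' Builds a candidate set by starting empty and repeatedly drawing a
#' uniformly random not-yet-tried feature: before each draw the current set
#' is returned with probability `p_stop`; a drawn feature is added if it
#' fits the remaining budget, otherwise the set is returned as is. Every
#' returned set is budget-feasible by construction, and any feasible set has
#' positive probability of occurring, so the initial population covers the
#' constrained subspace broadly. Small `p_stop` (default 1/500) favours
#' large, budget-filling sets.
#'
#' @param model A [cost_model()].
#' @param p_stop Per-step stop probability in (0, 1].
#' @return Character vector of feature ids, always within budget.
#' @export
init_individual_cga <- function(model, p_stop = 1 / 500) {
  stopifnot(p_stop > 0, p_stop <= 1)
  untried <- names(model$costs)
  members <- character()
  remaining <- model$budget
  repeat {
    if (length(untried) == 0 || runif(1) < p_stop) return(members)
    pick <- untried[sample.int(length(untried), 1)]
    untried <- setdiff(untried, pick)
    if (model$costs[[pick]] <= remaining + BUDGET_TOL) {
      members <- c(members, pick)
      remaining <- remaining - model$costs[[pick]]
    } else {
      return(members)
    }
  }
}

#' Cost-constrained crossover
#'
#' Recombines two budget-feasible parents into two budget-feasible children.
#' Features present in both parents are forwarded to both children; features
#' present in exactly one parent are visited in random order and assigned by
#' fair coin to one of the children, but added only if that child's
#' remaining budget allows it. The pass stops once every candidate has been
#' tried or no remaining candidate fits either child.
#'
#' @param parent_a,parent_b Character vectors of feature ids, each within
#'   budget.
#' @param model A [cost_model()].
#' @return List of two character vectors (`child_a`, `child_b`), both within
#'   budget.
#' @export
cc_crossover <- function(parent_a, parent_b, model) {
  if (!within_budget(parent_a, model) || !within_budget(parent_b, model)) {
    abort("cc_crossover requires budget-feasible parents")
  }
  shared <- intersect(parent_a, parent_b)
  children <- list(shared, shared)
  remaining <- model$budget - total_cost(shared, model) + BUDGET_TOL
  remaining <- c(remaining, remaining)
  candidates <- setdiff(union(parent_a, parent_b), shared)
  candidates <- candidates[sample.int(length(candidates))]
  for (f in candidates) {
    cost <- model$costs[[f]]
    if (cost > remaining[1] && cost > remaining[2]) next
    child <- sample.int(2, 1)
    if (cost <= remaining[child]) {
      children[[child]] <- c(children[[child]], f)
      remaining[child] <- remaining[child] - cost
    }
    if (min(model$costs[candidates]) > max(remaining)) break
  }
  names(children) <- c("child_a", "child_b")
  children
}

#' Cost-constrained mutation
#'
#' Explicitly decides in advance whether to add or remove a feature, with
#' `P(add) = 1 - costs(s)/c_max`: exploration adds features while the budget
#' has headroom and removes them once it is nearly exhausted. An "add"
#' decision picks uniformly among the absent features that fit the remaining
#' budget; if none fits, a random member is removed instead. A "remove"
#' decision drops a uniformly random member (an empty set is returned
#' unchanged). The result is always within budget.
#'
#' @param members Character vector of feature ids, within budget.
#' @param model A [cost_model()].
#' @return Mutated character vector of feature ids.
#' @export
cc_mutate <- function(members, model) {
  if (!within_budget(members, model)) {
    abort("cc_mutate requires a budget-feasible input set")
  }
  cost <- total_cost(members, model)
  p_add <- 1 - cost / model$budget
  if (runif(1) < p_add) {
    absent <- setdiff(names(model$costs), members)
    affordable <- absent[model$costs[absent] <= model$budget - cost + BUDGET_TOL]
    if (length(affordable) > 0) {
      return(c(members, affordable[sample.int(length(affordable), 1)]))
    }
    # add decided but nothing fits: remove a random member instead
  }
  if (length(members) == 0) return(members)
  members[-sample.int(length(members), 1)]
}

#' Linear-rank survivor selection
#'
#' Samples survivors with replacement with probability linear in fitness
#' rank: the worst individual has weight 1 and the best weight `m`
#' (normalised by `m(m+1)/2`). Depends on fitness only through its ranks,
#' so it is invariant to monotone rescaling and to the order of individuals.
#'
#' @param fitness Numeric vector of finite fitness values (larger is
#'   better).
#' @param size Number of survivors to draw (default: population size).
#' @return Integer vector of selected indices.
#' @export
rank_selection <- function(fitness, size = length(fitness)) {
  if (length(fitness) == 0 || any(!is.finite(fitness))) {
    abort("rank_selection requires a non-empty vector of finite fitnesses")
  }
  w <- rank(fitness, ties.method = "average")
  sample.int(length(fitness), size, replace = TRUE, prob = w)
}

# uniform crossover, cost-agnostic: shared features to both children, each
# exclusive feature assigned to one child by fair coin (the other child gets
# the complement)
uniform_crossover <- function(parent_a, parent_b) {
  shared <- intersect(parent_a, parent_b)
  diff <- setdiff(union(parent_a, parent_b), shared)
  to_a <- runif(length(diff)) < 0.5
  list(child_a = c(shared, diff[to_a]), child_b = c(shared, diff[!to_a]))
}

# random-alteration mutation, cost-agnostic: toggle one random feature
ra_mutation <- function(members, pool) {
  pick <- pool[sample.int(length(pool), 1)]
  if (pick %in% members) setdiff(members, pick) else c(members, pick)
}

#' Genetic-algorithm feature selection under a budget
#'
#' Runs a generational genetic algorithm over feature subsets with
#' linear-rank selection, crossover, mutation and 1-elitism, in one of two
#' budget-handling variants:
#' \describe{
#'   \item{`cga`}{cost-preserving GA — random forward initialisation
#'     ([init_individual_cga()]), cost-constrained crossover
#'     ([cc_crossover()]) and mutation ([cc_mutate()]) keep every evaluated
#'     individual budget-feasible; fitness is the negative AIC.}
#'   \item{`fga`}{fitness-adapted GA — cost-scaled random initialisation
#'     ([init_population_fga()]), plain uniform crossover and random-toggle
#'     mutation; the graded fitness [fga_fitness()] scores infeasible sets
#'     by their degree of violation and feasible sets by `1/AIC`.}
#' }
#' The run stops after `max_iterations` generations or once the best-so-far
#' fitness has not improved (absolute tolerance 1e-12) for `patience`
#' consecutive generations. The result is the best budget-feasible
#' individual ever evaluated; an `fga` run that never encounters a feasible
#' individual returns an explicit infeasible result (`feasible = FALSE`)
#' with an empty selection.
#'
#' @inheritParams select_forward
#' @param variant `"cga"` or `"fga"`.
#' @param population_size Number of individuals (default 500).
#' @param max_iterations Maximum generations (default 150).
#' @param patience Generations without best-fitness improvement before
#'   convergence is declared (default 10).
#' @param p_stop Stop probability of the cGA initialisation (default 1/500).
#' @param crossover_rate Fraction of selected pairs recombined (default 0.8).
#' @param mutation_rate Per-individual mutation probability (default 0.1).
#' @param init fGA initial-population rule: `"cost_scaled"` (default) or
#'   `"uniform"` (inclusion probability 0.5, the unconstrained random start).
#' @param seed Optional integer seed set before the run for exact
#'   repeatability.
#' @return A [selection_result]; `trace` has one row per generation
#'   (`generation`, `best_fitness`, `mean_fitness`, `best_so_far`).
#' @export
select_ga <- function(data, response, model, variant = c("cga", "fga"),
                      population_size = 500, max_iterations = 150,
                      patience = 10, p_stop = 1 / 500,
                      crossover_rate = 0.8, mutation_rate = 0.1,
                      init = c("cost_scaled", "uniform"), seed = NULL) {
  variant <- match.arg(variant)
  init <- match.arg(init)
  stopifnot(population_size >= 2, patience >= 1, max_iterations >= 1)
  if (model$budget <= 0) abort("select_ga requires a positive budget")
  if (!is.null(seed)) set.seed(seed)
  pool <- feature_pool(data, response, model)

  cache <- make_fit_cache(data, response)
  fitness_of <- if (variant == "cga") {
    function(members) -cache$fit(members)$aic
  } else {
    function(members) fga_fitness(members, data, response, model, fit_fun = cache$fit)
  }

  population <- if (variant == "cga") {
    lapply(seq_len(population_size), function(i) init_individual_cga(model, p_stop))
  } else {
    init_population_fga(model, population_size,
                        inclusion_prob = if (init == "uniform") 0.5)
  }

  best_feasible <- NULL   # list(members, aic)
  note_feasible <- function(members) {
    if (variant == "cga" || within_budget(members, model)) {
      aic <- cache$fit(members)$aic
      if (is.null(best_feasible) || aic < best_feasible$aic) {
        best_feasible <<- list(members = members, aic = aic)
      }
    }
  }

  evaluate <- function(pop) {
    fit <- vapply(pop, fitness_of, numeric(1))
    note_feasible(pop[[which.max(fit)]])
    fit
  }

  fitness <- evaluate(population)
  best_so_far <- max(fitness)
  best_individual <- population[[which.max(fitness)]]
  trace <- list(tibble(generation = 0L, best_fitness = max(fitness),
                       mean_fitness = mean(fitness), best_so_far = best_so_far))
  stall <- 0L

  for (gen in seq_len(max_iterations)) {
    idx <- rank_selection(fitness, population_size)
    pop <- population[idx]

    # pairwise crossover over the (already randomly ordered) survivors
    for (i in seq(1, population_size - 1, by = 2)) {
      if (runif(1) < crossover_rate) {
        kids <- if (variant == "cga") {
          cc_crossover(pop[[i]], pop[[i + 1]], model)
        } else {
          uniform_crossover(pop[[i]], pop[[i + 1]])
        }
        pop[[i]] <- kids$child_a
        pop[[i + 1]] <- kids$child_b
      }
    }

    mutate_idx <- which(runif(population_size) < mutation_rate)
    for (i in mutate_idx) {
      pop[[i]] <- if (variant == "cga") cc_mutate(pop[[i]], model)
                  else ra_mutation(pop[[i]], pool)
    }

    pop[[1]] <- best_individual # 1-elitism
    population <- pop
    fitness <- evaluate(population)

    gen_best <- max(fitness)
    if (gen_best > best_so_far + 1e-12) {
      best_so_far <- gen_best
      best_individual <- population[[which.max(fitness)]]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    trace <- c(trace, list(tibble(generation = gen, best_fitness = gen_best,
                                  mean_fitness = mean(fitness),
                                  best_so_far = best_so_far)))
    if (stall >= patience) break
  }

  if (is.null(best_feasible)) {
    warn("no budget-feasible individual was ever evaluated; returning an empty infeasible result")
    fit <- cache$fit(character())
    return(new_selection_result(variant, character(), model, fit,
                                dplyr::bind_rows(trace), cache$n_evaluations(),
                                feasible = FALSE,
                                extra = list(generations = length(trace) - 1L)))
  }
  fit <- cache$fit(best_feasible$members)
  new_selection_result(variant, sort_by_pool(best_feasible$members, pool),
                       model, fit, dplyr::bind_rows(trace),
                       cache$n_evaluations(),
                       extra = list(generations = length(trace) - 1L))
}

sort_by_pool <- function(members, pool) pool[pool %in% members]
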