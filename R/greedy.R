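#' Benefit-cost ratio of a candidate feature
#'
#' The selection criterion of cost-constrained forward selection:
#' `BCR = (AIC(current) - AIC(current + candidate)) / (cost + xi)`.
#' A positive value means the candidate improves the AIC; with `xi = 0`
#' the improvement is weighed fully against the candidate's cost, while
#' large `xi` shifts the ranking back towards the raw AIC gain.
#'
#' @param aic_current AIC of the current model.
#' @param aic_candidate AIC after adding the candidate.
#' @param cost Positive cost of the candidate.
#' @param xi Non-negative trade-off offset (cost units).
#' @return The benefit-cost ratio; `<= 0` iff the candidate does not improve
#'   the AIC.
#' @examples
#' bcr(100, 90, cost = 0.5) # 20
#' @export
bcr <- function(aic_current, aic_candidate, cost, xi = 0) {
  if (any(cost + xi <= 0)) abort("cost + xi must be positive")
  (aic_current - aic_candidate) / (cost + xi)
}

resolve_xi <- function(strategy, costs, xi = NULL) {
  switch(strategy,
    fs = 0,          # unused: FS ranks by raw AIC gain
    cfs = 0,
    cfs_mean = mean(costs),
    cfs_max = max(costs),
    cfs_custom = {
      if (is.null(xi) || !is.numeric(xi) || xi < 0) {
        abort("strategy 'cfs_custom' requires a non-negative numeric `xi`")
      }
      xi
    },
    abort(paste0("unknown strategy: ", strategy))
  )
}

#' Budget-limited greedy forward selection
#'
#' Starts from the empty set and iteratively adds the best affordable
#' candidate feature until no affordable candidate improves the AIC or the
#' budget admits no further candidate. Candidates whose individual cost
#' exceeds the remaining budget are skipped in every iteration (the budget
#' only shrinks, so a skipped candidate never becomes affordable again).
#'
#' Strategies differ only in the candidate ranking:
#' \describe{
#'   \item{`fs`}{naive forward selection — maximises the raw AIC decrease,
#'     ignoring costs except through the budget restriction;}
#'   \item{`cfs`}{maximises the benefit-cost ratio [bcr()] with `xi = 0`;}
#'   \item{`cfs_mean`, `cfs_max`}{trade-off variants with `xi` set to the
#'     mean / maximum of the full cost vector (evaluated once at start);}
#'   \item{`cfs_custom`}{user-supplied `xi`.}
#' }
#' Ties are broken by the lowest feature index (column order in `data`).
#'
#' @param data Training data frame with feature columns and the response.
#' @param response Name of the 0/1 response column.
#' @param model A [cost_model()] covering all candidate features.
#' @param strategy One of `"fs"`, `"cfs"`, `"cfs_mean"`, `"cfs_max"`,
#'   `"cfs_custom"`.
#' @param xi Trade-off offset for `strategy = "cfs_custom"`.
#' @param max_features Optional cap on the number of selected features.
#' @return A [selection_result] whose `trace` has one row per accepted step
#'   (`step`, `feature`, `aic`, `criterion`).
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(100), x2 = rnorm(100))
#' d$y <- rbinom(100, 1, plogis(2 * d$x1))
#' m <- cost_model(c(x1 = 0.3, x2 = 0.4), budget = 0.5)
#' select_forward(d, "y", m, strategy = "cfs")
#' @export
select_forward <- function(data, response, model,
                           strategy = c("cfs", "fs", "cfs_mean", "cfs_max", "cfs_custom"),
                           xi = NULL, max_features = NULL) {
  strategy <- match.arg(strategy)
  pool <- feature_pool(data, response, model)
  xi_val <- resolve_xi(strategy, model$costs[pool], xi)

  cache <- make_fit_cache(data, response)
  selected <- character()
  current <- cache$fit(selected)
  trace <- list(tibble(step = 0L, feature = NA_character_,
                       aic = current$aic, criterion = NA_real_))

  repeat {
    remaining <- model$budget - total_cost(selected, model)
    cand <- setdiff(pool, selected)
    cand <- cand[model$costs[cand] <= remaining + BUDGET_TOL]
    if (length(cand) == 0) break
    if (!is.null(max_features) && length(selected) >= max_features) break

    aics <- vapply(cand, function(f) cache$fit(c(selected, f))$aic, numeric(1))
    benefit <- current$aic - aics
    if (max(benefit) <= 0) break
    crit <- if (strategy == "fs") benefit else benefit / (model$costs[cand] + xi_val)
    best <- which.max(crit) # which.max takes the first (lowest index) on ties
    selected <- c(selected, cand[best])
    current <- cache$fit(selected)
    trace <- c(trace, list(tibble(step = length(selected),
                                  feature = cand[best],
                                  aic = current$aic,
                                  criterion = unname(crit[best]))))
  }

  new_selection_result(
    method = sub("_", ".", strategy), selected = selected, model = model,
    fit = current, trace = dplyr::bind_rows(trace),
    n_evaluations = cache$n_evaluations()
  )
}

# candidate features: columns present both in the data and the cost model
feature_pool <- function(data, response, model) {
  pool <- intersect(names(model$costs), setdiff(names(data), response))
  if (length(pool) < length(model$costs)) {
    missing <- setdiff(names(model$costs), pool)
    abort(paste0("cost model feature(s) not in data: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  # preserve data column order so index tie-breaks are well defined
  setdiff(names(data), response)[setdiff(names(data), response) %in% pool]
}
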