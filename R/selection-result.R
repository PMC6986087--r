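#' Selection result container
#'
#' All selectors ([select_forward()], [select_ga()], [select_filter()])
#' return a `selection_result`: the chosen feature subset, its total cost,
#' the final AIC of the logistic model on that subset, a per-step (or
#' per-generation) score trace, the number of model evaluations spent, and
#' the method label.
#'
#' @name selection_result
#' @keywords internal
NULL

new_selection_result <- function(method, selected, model, fit, trace,
                                 n_evaluations, feasible = TRUE, extra = list()) {
  structure(c(list(
    method = method,
    selected = selected,
    total_cost = total_cost(selected, model),
    budget = model$budget,
    aic = fit$aic,
    fit = fit,
    trace = trace,
    n_evaluations = n_evaluations,
    feasible = feasible,
    cost_lookup = model$costs
  ), extra), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> method ", x$method, "\n", sep = "")
  cat("  selected ", length(x$selected), " feature(s), cost ",
      format(x$total_cost, digits = 4), " / budget ",
      format(x$budget, digits = 4), "\n", sep = "")
  cat("  AIC ", format(x$aic, digits = 6),
      if (!x$feasible) "  [no feasible solution found]", "\n", sep = "")
  if (length(x$selected)) {
    cat("  members: ", paste(head(x$selected, 12), collapse = ", "),
        if (length(x$selected) > 12) ", ...", "\n", sep = "")
  }
  invisible(x)
}

#' @describeIn selection_result one row per selected feature, in selection
#'   order where the method defines one.
#' @param x A `selection_result`.
#' @param ... Unused.
#' @export
tidy.selection_result <- function(x, ...) {
  tibble(feature = x$selected,
         rank = seq_along(x$selected),
         cost = if (length(x$selected)) unname(x$cost_lookup[x$selected]) else numeric())
}

#' @describeIn selection_result one-row summary of the run.
#' @export
glance.selection_result <- function(x, ...) {
  tibble(method = x$method,
         n_selected = length(x$selected),
         total_cost = x$total_cost,
         budget = x$budget,
         aic = x$aic,
         n_evaluations = x$n_evaluations,
         feasible = x$feasible)
}

#' @describeIn selection_result score trace over steps/generations.
#' @param object A `selection_result`.
#' @export
autoplot.selection_result <- function(object, ...) {
  tr <- object$trace
  yvar <- if ("best_fitness" %in% names(tr)) "best_fitness" else "aic"
  xvar <- if ("generation" %in% names(tr)) "generation" else "step"
  ggplot2::ggplot(tr, ggplot2::aes(.data[[xvar]], .data[[yvar]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = xvar, y = yvar,
                  title = paste0(object$method, " score trace")) +
    ggplot2::theme_minimal()
}
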