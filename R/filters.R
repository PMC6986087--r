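#' Per-feature importance scores
#'
#' Filter scorers assign every feature an importance for discriminating the
#' two response classes. `score_ttest()` uses the two-sided p-value of a
#' Welch two-sample t-test (lower is better); `score_symmetric_uncertainty()`
#' computes the symmetric uncertainty `SU(X;Y) = 2 I(X;Y) / (H(X) + H(Y))`
#' after equal-frequency discretisation of the feature into `bins` bins
#' (higher is better); `score_adapter()` wraps any user-supplied importance
#' function, so external scorers (e.g. minimal-joint-mutual-information or
#' random-forest impurity rankings) plug into the same budgeted selection.
#'
#' Degenerate features are flagged rather than failing: a feature with zero
#' variance in both classes gets a missing t-test p-value (ranked last), and
#' a feature collapsing to a single bin gets symmetric uncertainty 0.
#'
#' @param data Data frame with feature columns and the response.
#' @param response Name of the 0/1 response column.
#' @param bins Number of equal-frequency bins (>= 2) for the discretisation.
#' @param scorer Function `(data, response) -> numeric` returning one finite
#'   importance per feature (named or in column order).
#' @param direction `"higher"` or `"lower"`: whether larger scorer values
#'   mean more important.
#' @param method_label Label stored on the ranking.
#' @return An `importance_ranking`: tibble with columns `feature`, `score`
#'   and attributes `direction`, `method_label`.
#' @examples
#' d <- data.frame(y = rep(0:1, each = 20), x = c(rnorm(20), rnorm(20, 2)))
#' score_ttest(d, "y")
#' @export
score_ttest <- function(data, response) {
  y <- response_vector(data, response)
  if (min(sum(y == 1), sum(y == 0)) < 2) {
    abort("both classes need at least 2 samples")
  }
  x <- as.matrix(data[setdiff(names(data), response)])
  m1 <- colMeans(x[y == 1, , drop = FALSE])
  m0 <- colMeans(x[y == 0, , drop = FALSE])
  v1 <- apply(x[y == 1, , drop = FALSE], 2, stats::var)
  v0 <- apply(x[y == 0, , drop = FALSE], 2, stats::var)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  se2 <- v1 / n1 + v0 / n0
  t_stat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  p[se2 == 0] <- NA_real_ # constant in both groups: no evidence either way
  new_importance_ranking(colnames(x), unname(p), "lower", "filter_ttest")
}

#' @rdname score_ttest
#' @export
score_symmetric_uncertainty <- function(data, response, bins = 10) {
  stopifnot(bins >= 2)
  y <- response_vector(data, response)
  x <- data[setdiff(names(data), response)]
  su <- vapply(x, function(col) su_single(col, y, bins), numeric(1))
  new_importance_ranking(names(x), unname(su), "higher", "filter_symuncert")
}

su_single <- function(x, y, bins) {
  breaks <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                            names = FALSE, type = 7))
  if (length(breaks) < 2) return(0) # degenerate feature: single bin
  xb <- cut(x, breaks, include.lowest = TRUE)
  tab <- table(xb, y)
  if (nrow(tab) < 2) return(0)
  pxy <- tab / sum(tab)
  px <- rowSums(pxy); py <- colSums(pxy)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx + hy == 0) return(0)
  mi <- sum(pxy[pxy > 0] * log(pxy[pxy > 0] / outer(px, py)[pxy > 0]))
  2 * mi / (hx + hy)
}

#' @rdname score_ttest
#' @export
score_adapter <- function(data, response, scorer, direction = "higher",
                          method_label = "filter_external") {
  features <- setdiff(names(data), response)
  scores <- scorer(data, response)
  if (!is.null(names(scores))) scores <- scores[features]
  if (length(scores) != length(features)) {
    abort("scorer must return one value per feature")
  }
  if (any(!is.finite(scores))) {
    abort(paste0("scorer returned a non-finite value for: ",
                 paste(head(features[!is.finite(scores)], 5), collapse = ", ")))
  }
  new_importance_ranking(features, unname(scores), direction, method_label)
}

new_importance_ranking <- function(features, scores, direction, method_label) {
  stopifnot(direction %in% c("higher", "lower"))
  out <- tibble(feature = features, score = scores)
  structure(out, direction = direction, method_label = method_label,
            class = c("importance_ranking", class(out)))
}

#' Budget-constrained top-down filter selection
#'
#' Walks the features in decreasing importance order and adds each feature
#' whose cost still fits the remaining budget; unaffordable features are
#' skipped and never block later affordable ones (set
#' `stop_at_first_unaffordable = TRUE` for the stricter reading that stops
#' at the first misfit). The walk also stops once the next feature's
#' importance crosses `threshold` (a p-value >= threshold for
#' lower-is-better scores, a score <= threshold otherwise); features with
#' missing scores rank last and are never selected when a threshold is set.
#' Rank ties are broken by feature order.
#'
#' @param ranking An `importance_ranking` from one of the scorers.
#' @param model A [cost_model()] covering all ranked features.
#' @param threshold Optional importance cutoff.
#' @param stop_at_first_unaffordable Stop instead of skipping (default
#'   `FALSE`).
#' @return Character vector of selected feature ids in rank order, always
#'   budget-feasible. [select_filter()] wraps this into a full
#'   [selection_result].
#' @export
filter_select_topdown <- function(ranking, model, threshold = NULL,
                                  stop_at_first_unaffordable = FALSE) {
  direction <- attr(ranking, "direction")
  score <- if (direction == "lower") ranking$score else -ranking$score
  ord <- order(score, seq_along(score), na.last = TRUE)
  selected <- character()
  remaining <- model$budget
  for (i in ord) {
    s <- ranking$score[i]
    if (!is.null(threshold)) {
      if (is.na(s)) break
      if (direction == "lower" && s >= threshold) break
      if (direction == "higher" && s <= threshold) break
    }
    cost <- model$costs[[ranking$feature[i]]]
    if (cost <= remaining + BUDGET_TOL) {
      selected <- c(selected, ranking$feature[i])
      remaining <- remaining - cost
    } else if (stop_at_first_unaffordable) {
      break
    }
  }
  selected
}

#' Filter-based feature selection under a budget
#'
#' Scores every feature, then applies the budget-constrained top-down walk
#' of [filter_select_topdown()] and refits the logistic model on the chosen
#' subset. Default thresholds follow the scorer: 0.05 for the t-test
#' p-value, 1e-6 for symmetric uncertainty, none for external scorers.
#'
#' @inheritParams select_forward
#' @param method `"ttest"`, `"symuncert"`, or `"external"`.
#' @param threshold Importance cutoff; `NULL` for the method default, `NA`
#'   to disable.
#' @param bins Bins for the symmetric-uncertainty discretisation.
#' @param scorer External importance function for `method = "external"`.
#' @param direction Score direction for `method = "external"`.
#' @param stop_at_first_unaffordable See [filter_select_topdown()].
#' @return A [selection_result].
#' @export
select_filter <- function(data, response, model,
                          method = c("ttest", "symuncert", "external"),
                          threshold = NULL, bins = 10, scorer = NULL,
                          direction = "higher",
                          stop_at_first_unaffordable = FALSE) {
  method <- match.arg(method)
  feature_pool(data, response, model) # validates coverage
  ranking <- switch(method,
    ttest = score_ttest(data, response),
    symuncert = score_symmetric_uncertainty(data, response, bins),
    external = {
      if (is.null(scorer)) abort("method = 'external' requires a scorer")
      score_adapter(data, response, scorer, direction)
    }
  )
  if (is.null(threshold)) {
    threshold <- switch(method, ttest = 0.05, symuncert = 1e-6, external = NULL)
  } else if (is.na(threshold)) {
    threshold <- NULL
  }
  selected <- filter_select_topdown(ranking, model, threshold,
                                    stop_at_first_unaffordable)
  fit <- fit_aic(data, response, selected)
  new_selection_result(
    method = attr(ranking, "method_label"), selected = selected,
    model = model, fit = fit,
    trace = tibble(step = seq_along(selected), feature = selected,
                   aic = NA_real_,
                   criterion = ranking$score[match(selected, ranking$feature)]),
    n_evaluations = 1L,
    extra = list(ranking = ranking)
  )
}
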