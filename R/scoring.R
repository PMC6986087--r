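#' Fit the scoring model on a candidate feature set
#'
#' Fits a logistic regression of the binary response on the given features
#' plus an intercept and returns its Akaike Information Criterion,
#' `AIC = 2k - 2 logLik` with `k = |features| + 1` counting the intercept.
#' Lower is better; the AIC is the selection criterion used by all wrapper
#' selectors in this package.
#'
#' The parameter count uses the requested number of features, not the fitted
#' rank, so adding a linearly dependent (e.g. duplicated) column can never
#' decrease the AIC. Fits that fail to converge within `maxit` IRLS
#' iterations, or that are rank deficient, are returned with
#' `converged = FALSE` rather than as errors: a greedy or evolutionary
#' search must not abort on one pathological candidate.
#'
#' @param data Data frame holding the feature columns and the response.
#' @param response Name of the 0/1 response column.
#' @param features Character vector of feature column names (may be empty
#'   for the intercept-only model).
#' @param maxit Maximum IRLS iterations (default 100).
#' @return An object of class `scored_fit`: list with `features`, `aic`,
#'   `loglik`, `coefficients` (named, intercept first; aliased coefficients
#'   are 0), `converged`, `n`.
#' @examples
#' d <- data.frame(y = rep(0:1, each = 5), x = rnorm(10))
#' fit_aic(d, "y", "x")
#' @export
fit_aic <- function(data, response, features = character(), maxit = 100) {
  y <- response_vector(data, response)
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    abort(paste0("feature(s) not in data: ", paste(head(missing, 5), collapse = ", ")))
  }
  n <- length(y)
  x <- cbind(`(Intercept)` = rep(1, n),
             if (length(features)) as.matrix(data[features]))
  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::binomial(),
                   control = list(maxit = maxit))
  )
  k <- length(features) + 1
  coefs <- fit$coefficients
  aliased <- !is.finite(coefs)
  coefs[aliased] <- 0
  loglik <- -fit$deviance / 2
  structure(list(
    features = features,
    aic = fit$deviance + 2 * k,
    loglik = loglik,
    coefficients = coefs,
    converged = isTRUE(fit$converged) && !any(aliased),
    n = n
  ), class = "scored_fit")
}

#' @export
print.scored_fit <- function(x, ...) {
  cat("<scored_fit> ", length(x$features), " feature(s), AIC ",
      format(x$aic, digits = 6),
      if (!x$converged) " [not converged]", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.scored_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
glance.scored_fit <- function(x, ...) {
  tibble(aic = x$aic, logLik = x$loglik, n_features = length(x$features),
         nobs = x$n, converged = x$converged)
}

#' Predictive AUC of a fitted model on held-out data
#'
#' Computes the area under the ROC curve of the fitted linear predictor
#' against the test labels, as the midrank Mann-Whitney statistic: tied
#' scores contribute 1/2.
#'
#' @param fit A [fit_aic()] result.
#' @param test Data frame with the member features and the response column.
#' @param response Name of the 0/1 response column.
#' @return AUC in \\[0, 1\\].
#' @export
evaluate_auc <- function(fit, test, response) {
  y <- response_vector(test, response)
  if (length(unique(y)) < 2) abort("test response must contain both classes")
  scores <- predict_lp(fit, test)
  auc_rank(scores, y)
}

# linear predictor of a scored_fit on new data
predict_lp <- function(fit, data) {
  missing <- setdiff(fit$features, names(data))
  if (length(missing) > 0) {
    abort(paste0("feature(s) not in data: ", paste(head(missing, 5), collapse = ", ")))
  }
  lp <- rep(fit$coefficients[["(Intercept)"]], nrow(data))
  if (length(fit$features)) {
    lp <- lp + as.matrix(data[fit$features]) %*% fit$coefficients[fit$features]
  }
  as.numeric(lp)
}

# midrank (Mann-Whitney) AUC
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# coerce and validate a 0/1 response column
response_vector <- function(data, response) {
  if (!response %in% names(data)) {
    abort(paste0("response column '", response, "' not found"))
  }
  y <- data[[response]]
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!all(y %in% c(0, 1))) abort("response must be binary 0/1")
  as.numeric(y)
}

# per-run memoised AIC evaluation keyed by the sorted member set; wrapper
# searches revisit the same subsets constantly (elitism, converged GA
# populations), and the fit is the dominant cost
make_fit_cache <- function(data, response) {
  cache <- new.env(parent = emptyenv())
  count <- 0L
  list(
    fit = function(features) {
      key <- paste(c(".", sort(features)), collapse = "\r")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      count <<- count + 1L
      out <- fit_aic(data, response, features)
      assign(key, out, envir = cache)
      out
    },
    n_evaluations = function() count
  )
}
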