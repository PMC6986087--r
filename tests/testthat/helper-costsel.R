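# shared fixtures and independent oracles, all generated in code

`%||%` <- function(x, y) if (is.null(x)) y else x

# small named cost vector X1..Xp
toy_costs <- function(p, values = NULL) {
  setNames(values %||% runif(p, 0.1, 1), paste0("X", seq_len(p)))
}

# balanced two-class dataset with `p_informative` strong features first
toy_data <- function(n = 100, p = 4, p_informative = 1, beta = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  if (p_informative > 0) {
    x[y == 1, seq_len(p_informative)] <- x[y == 1, seq_len(p_informative)] + beta
  }
  colnames(x) <- paste0("X", seq_len(p))
  cbind(data.frame(y = y), as.data.frame(x))
}

# brute-force AUC: average over all positive/negative pairs, ties count 1/2
auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# exhaustive search over all budget-feasible subsets (oracle for p <= 12)
exhaustive_best_aic <- function(data, model, response = "y") {
  ids <- names(model$costs)
  best <- list(aic = Inf, members = character())
  for (k in 0:length(ids)) {
    sets <- if (k == 0) list(character()) else asplit(utils::combn(ids, k), 2)
    for (s in sets) {
      s <- as.character(s)
      if (within_budget(s, model)) {
        a <- fit_aic(data, response, s)$aic
        if (a < best$aic) best <- list(aic = a, members = s)
      }
    }
  }
  best
}
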