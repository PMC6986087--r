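#' Simulation setting specifications
#'
#' A `setting_spec` defines one synthetic benchmark condition: the budget
#' ratio `gamma`, feature count `p`, number of truly relevant features
#' `p_rel`, effect size `beta` (in feature-standard-deviation units), the
#' cost-generating rule, the feature covariance rule, the feature
#' distribution and the response-generating model, plus the simulation sizes
#' (`n_train = 500`, `n_test = 10000`, `n_replicates = 100`).
#'
#' Eleven presets `"A"`–`"K"` cover the standard grid: small to
#' high-dimensional pools (p = 30 to 1500), effect sizes 0.3–1, and tight to
#' unconstrained budgets (gamma = 1/3 to 2). The specialised presets modify
#' one assumption each: `G` uses correlated features with a logistic
#' response model, `H` effect-dependent costs, `I` equidistant
#' (non-constant) effects, `J` equidistant effects with cost–effect
#' correlation, and `K` a heavy-tailed 0.9/0.1 normal scale mixture.
#'
#' @param label Preset letter `"A"`–`"K"`; any other name defines a custom
#'   setting whose parameters must be given in `...`.
#' @param ... Overrides for any spec field (e.g. `n_replicates = 10`,
#'   `p = 100`).
#' @return An object of class `setting_spec`.
#' @examples
#' setting_spec("C")
#' setting_spec("custom", gamma = 0.5, p = 20, p_rel = 4, beta = 0.8)
#' @export
setting_spec <- function(label = "custom", ...) {
  presets <- setting_presets()
  base <- list(
    label = label, gamma = NA_real_, p = NA_integer_, p_rel = NA_integer_,
    beta = NA_real_, effect_rule = "constant",
    n_train = 500L, n_test = 10000L, n_replicates = 100L,
    cost_rule = "uniform", covariance_rule = "identity",
    distribution_rule = "normal", generation_model = "class_conditional",
    block_size = 5L, rho = 0.7, tail_sd = 5, tail_prob = 0.1
  )
  if (label %in% presets$label) {
    row <- presets[presets$label == label, ]
    base[names(row)] <- as.list(row)
  }
  spec <- modifyList(base, list(...))
  validate_setting_spec(spec)
}

validate_setting_spec <- function(spec) {
  spec$p <- as.integer(spec$p)
  spec$p_rel <- as.integer(spec$p_rel)
  if (is.na(spec$p) || spec$p < 1) abort("p must be >= 1")
  if (spec$p_rel > spec$p || spec$p_rel < 0) abort("p_rel must be in [0, p]")
  if (is.na(spec$gamma) || spec$gamma < 0) abort("gamma must be >= 0")
  if (spec$effect_rule == "constant" && (is.na(spec$beta) || spec$beta < 0)) {
    abort("beta must be a non-negative effect size")
  }
  structure(spec, class = "setting_spec")
}

#' @export
print.setting_spec <- function(x, ...) {
  cat("<setting_spec ", x$label, "> gamma=", format(x$gamma, digits = 4),
      " p=", x$p, " p_rel=", x$p_rel,
      " beta=", if (x$effect_rule == "constant") format(x$beta) else x$effect_rule,
      " [", x$generation_model, ", ", x$cost_rule, " costs, ",
      x$covariance_rule, " cov, ", x$distribution_rule, "]\n", sep = "")
  invisible(x)
}

#' @describeIn setting_spec the preset table as a tibble (one row per
#'   setting letter).
#' @export
setting_presets <- function() {
  tibble(
    label   = LETTERS[1:11],
    gamma   = c(1/2, 2/3, 1/3, 2/3, 2, 1/2, 1/3, 1/3, 1/3, 1/3, 1/3),
    p       = c(30L, 30L, 300L, 300L, 1500L, 1500L, 300L, 300L, 300L, 300L, 300L),
    p_rel   = c(18L, 3L, 30L, 3L, 15L, 20L, 30L, 30L, 30L, 30L, 30L),
    beta    = c(0.3, 1, 0.5, 0.5, 0.5, 0.5, 0.3, 0.5, NA, NA, 0.5),
    effect_rule = c(rep("constant", 8), "equidistant", "equidistant", "constant"),
    cost_rule = c(rep("uniform", 7), "effect_dependent", "uniform", "correlated", "uniform"),
    covariance_rule = c(rep("identity", 6), "correlated", rep("identity", 4)),
    distribution_rule = c(rep("normal", 10), "heavy_tail_mixture"),
    generation_model = c(rep("class_conditional", 6), "logistic", rep("class_conditional", 4))
  )
}

#' Effect-size vector of a setting
#'
#' Constant-effect settings place `beta` on the first `p_rel` features and 0
#' elsewhere. Equidistant settings place the decreasing sequence
#' `p_rel/p_rel, ..., 2/p_rel, 1/p_rel` on the relevant features, covering
#' the interval (0, 1] from strong to weak.
#'
#' @param spec A [setting_spec()].
#' @return Numeric vector of length `p`.
#' @export
build_mu <- function(spec) {
  rel <- switch(spec$effect_rule,
    constant = rep(spec$beta, spec$p_rel),
    equidistant = rev(seq_len(spec$p_rel)) / spec$p_rel,
    abort(paste0("unknown effect rule: ", spec$effect_rule))
  )
  c(rel, rep(0, spec$p - spec$p_rel))
}

#' Block-exchangeable correlation matrix
#'
#' Builds a block-diagonal covariance with unit variances and exchangeable
#' within-block correlation `rho`: a synthetic stand-in for the strongly
#' correlated covariance structures of real metabolomic panels. Positive
#' definite for `-1/(block_size - 1) < rho < 1`.
#'
#' @param p Dimension.
#' @param block_size Features per correlated block (a trailing partial block
#'   is allowed); `1` gives the identity.
#' @param rho Within-block correlation, `|rho| < 1`.
#' @return `p` x `p` covariance matrix.
#' @export
make_correlated_covariance <- function(p, block_size = 5, rho = 0.7) {
  stopifnot(p >= 1, block_size >= 1)
  if (abs(rho) >= 1) abort("rho must satisfy |rho| < 1")
  sigma <- diag(p)
  if (block_size > 1 && rho != 0) {
    starts <- seq(1, p, by = block_size)
    for (s in starts) {
      idx <- s:min(s + block_size - 1, p)
      sigma[idx, idx] <- rho
      diag(sigma)[idx] <- 1
    }
  }
  sigma
}

#' Heavy-tailed feature draws
#'
#' Draws each cell from the 0.9/0.1 normal scale mixture
#' `0.9 N(mu_i, 1) + 0.1 N(mu_i, tail_sd^2)`: the minority component adds
#' extreme values while leaving the location (and hence the effect size)
#' unchanged. With the default `tail_sd = 5` the mixture variance is
#' `0.9 + 0.1 * 25 = 3.4` and the excess kurtosis is positive.
#'
#' @param mu Per-feature location vector.
#' @param n Number of rows.
#' @param tail_sd Standard deviation of the minority component.
#' @param tail_prob Minority-component probability (default 0.1).
#' @return `n` x `length(mu)` matrix.
#' @export
sample_heavy_tail <- function(mu, n, tail_sd = 5, tail_prob = 0.1) {
  stopifnot(n >= 1)
  p <- length(mu)
  sd_cell <- ifelse(runif(n * p) < tail_prob, tail_sd, 1)
  matrix(rnorm(n * p, sd = sd_cell), n, p) +
    matrix(mu, n, p, byrow = TRUE)
}

# Cholesky-based multivariate normal draw (identity short-circuited)
rmvn <- function(n, p, sigma = NULL) {
  z <- matrix(rnorm(n * p), n, p)
  if (is.null(sigma)) return(z)
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) abort("covariance matrix is not positive definite")
  z %*% chol(sigma)
}

setting_sigma <- function(spec) {
  if (spec$covariance_rule == "identity") NULL
  else make_correlated_covariance(spec$p, spec$block_size, spec$rho)
}

#' Generate one dataset under the class-conditional model
#'
#' Draws `y ~ Bernoulli(0.5)` and features from `p`-dimensional normals
#' whose mean is `mu` in class 1 and `0` in class 0 (shared covariance), so
#' each relevant feature separates the classes by its effect size in
#' standard-deviation units. Heavy-tailed settings replace the normal cells
#' by the scale mixture of [sample_heavy_tail()].
#'
#' @param spec A [setting_spec()].
#' @param n Number of samples (defaults to `spec$n_train`).
#' @return Tibble with columns `y` and `X1 ... Xp`.
#' @export
generate_class_conditional <- function(spec, n = spec$n_train) {
  mu <- build_mu(spec)
  y <- rbinom(n, 1, 0.5)
  x <- if (spec$distribution_rule == "heavy_tail_mixture") {
    sample_heavy_tail(rep(0, spec$p), n, spec$tail_sd, spec$tail_prob)
  } else {
    rmvn(n, spec$p, setting_sigma(spec))
  }
  if (any(y == 1)) {
    x[y == 1, ] <- x[y == 1, ] + matrix(mu, sum(y == 1), spec$p, byrow = TRUE)
  }
  as_dataset(x, y, spec$p)
}

#' Generate one dataset under the logistic model
#'
#' Draws marginally centred features `X ~ N_p(0, Sigma)` and the response
#' from `y_i ~ Bernoulli(plogis(x_i' mu))`: classes are defined through the
#' linear predictor of the relevant features rather than by a mean shift, so
#' correlated surrogate features can carry predictive information.
#'
#' @inheritParams generate_class_conditional
#' @export
generate_logistic <- function(spec, n = spec$n_train) {
  mu <- build_mu(spec)
  x <- rmvn(n, spec$p, setting_sigma(spec))
  y <- rbinom(n, 1, plogis(as.numeric(x %*% mu)))
  as_dataset(x, y, spec$p)
}

as_dataset <- function(x, y, p) {
  colnames(x) <- paste0("X", seq_len(p))
  dplyr::bind_cols(tibble(y = y), as_tibble(x))
}

#' Realise a full simulation instance of a setting
#'
#' Draws the per-feature costs according to the setting's cost rule, derives
#' the budget from `gamma` via [compute_budget()], and generates independent
#' training (`n_train = 500`) and test (`n_test = 10000`) datasets from the
#' same distribution and effect vector.
#'
#' @param spec A [setting_spec()].
#' @return A list of class `setting_realization`: `train`, `test` (tibbles
#'   with response column `y`), `model` (a [cost_model()]), `relevant`
#'   (named logical), `mu` (named numeric), `spec`.
#' @examples
#' set.seed(1)
#' inst <- realize_setting(setting_spec("B", n_test = 500))
#' inst$model$budget
#' @export
realize_setting <- function(spec) {
  mu <- build_mu(spec)
  relevant <- mu > 0
  costs <- switch(spec$cost_rule,
    uniform = sample_costs_uniform(spec$p),
    effect_dependent = sample_costs_effect_dependent(relevant),
    correlated = sample_costs_correlated(mu),
    abort(paste0("unknown cost rule: ", spec$cost_rule))
  )
  ids <- paste0("X", seq_len(spec$p))
  names(costs) <- names(mu) <- names(relevant) <- ids
  budget <- compute_budget(costs, relevant, spec$gamma)
  gen <- switch(spec$generation_model,
    class_conditional = generate_class_conditional,
    logistic = generate_logistic,
    abort(paste0("unknown generation model: ", spec$generation_model))
  )
  structure(list(
    train = gen(spec, spec$n_train),
    test = gen(spec, spec$n_test),
    model = cost_model(costs, budget, gamma = spec$gamma),
    relevant = relevant,
    mu = mu,
    spec = spec
  ), class = "setting_realization")
}

#' @export
print.setting_realization <- function(x, ...) {
  cat("<setting_realization ", x$spec$label, "> n_train=", nrow(x$train),
      " n_test=", nrow(x$test), " p=", x$spec$p,
      " budget=", format(x$model$budget, digits = 4), "\n", sep = "")
  invisible(x)
}
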