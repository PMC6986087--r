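---
title: "Cost-constrained feature selection: models, operators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-constrained feature selection: models, operators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costsel)
```

## The problem

Given a binary response, `p` candidate features with strictly positive
additive costs `c_i`, and a hard budget `c_max`, the task is to find the
feature subset `s` minimising the AIC of a logistic regression while
keeping the summed member costs within the budget. The budget is a *hard
margin*: a model violating it is inadmissible, not merely penalised. This
differs from cost-sensitive learning, where feature costs and
misclassification costs are traded off in a single soft objective; that
soft-margin family is out of scope here.

All selectors in `costsel` share one scoring model: a logistic regression
with intercept, scored by `AIC = 2k − 2·logLik` with `k = |s| + 1`.
Predictive quality is measured as the midrank Mann–Whitney AUC of the
fitted linear predictor on held-out data.

## Relative budgets

Rather than fixing `c_max` in absolute units, simulation settings derive it
from the costs of the truly relevant features through a ratio `γ`:

- `γ ≤ 1`: `c_max` is the summed cost of the cheapest relevant features up
  to the `γ`-quantile of the relevant cost distribution, so at most a
  `γ`-share of the relevant information fits. This makes `γ` itself a hard
  ceiling on the recall of *any* selector — a structural property the test
  suite exploits.
- `γ > 1`: all relevant features fit, plus headroom of `(γ − 1)·p_rel`
  features priced at the overall mean cost.

The quantile type is not dictated by the definition; `costsel` uses the
inclusive empirical quantile (order statistic at `ceiling(γ·p_rel)`), which
makes `γ = 0.5` admit exactly the cheapest half of an even number of
relevant features and lets both branches agree at `γ = 1`. Cost ties at the
quantile are all admitted, consistent with the indicator-sum form of the
definition.

## Greedy selection and the benefit-cost ratio

Forward selection starts from the empty set; in each iteration only
candidates whose individual cost fits the *remaining* budget are
considered, and the best candidate by the strategy's criterion is added:

- **FS** ranks by raw AIC decrease — costs enter only through the budget
  restriction;
- **cFS** ranks by the benefit-cost ratio
  `BCR = ΔAIC / c_i`, which favours cheap surrogates carrying similar
  information;
- **cFS.mean / cFS.max** use `BCR_ξ = ΔAIC / (c_i + ξ)` with `ξ` the mean
  or maximum of the full cost vector, shifting the ranking back towards
  raw benefit. `ξ` is evaluated once on the full cost vector at the start,
  not on the shrinking candidate pool, because it is defined over all
  `i ∈ {1, …, p}`. Quantile-based `ξ` rules can be supplied through
  `strategy = "cfs_custom"`; no default is imposed.

Since `ΔAIC ≤ 0 ⟺ BCR ≤ 0`, one stopping rule serves every strategy: stop
when no affordable candidate improves the AIC (or none is affordable).
Ties are broken by the lowest feature index, making runs deterministic.
Because the remaining budget only shrinks, a candidate skipped for cost is
effectively excluded for the rest of the run.

## Genetic algorithms

Both GA variants share linear-rank survivor selection (weight proportional
to fitness rank, sampled with replacement), generational replacement with
1-elitism, and a convergence rule of `patience` consecutive generations
(default 10) without best-fitness improvement beyond an absolute tolerance
of 1e-12, capped at `max_iterations` (default 150) with population size 500
by default.

**fGA** handles the constraint in the fitness:
infeasible sets score `1 − costs(s)/c_max` (strictly negative, more
negative for larger violations), feasible sets `1/AIC`. The sign encodes
feasibility exactly — which assumes `AIC > 0`; a non-positive AIC inside
the budget would break the reserved-sign contract and is raised as an
error rather than clamped. The initial population includes each feature
with probability `min(1, c_max/Σc_i)`, so the expected individual cost
equals `min(c_max, Σc_i)`. Crossover is plain uniform crossover (shared
features to both children, each exclusive feature to one child by fair
coin) and mutation toggles one random feature. The returned solution is
the best *feasible* individual ever evaluated; a run that never finds one
returns an explicit infeasible result.

**cGA** instead makes every operator closed under the budget:

- *Initialisation* draws random not-yet-tried features, stopping with
  probability `pStop` (default 1/500) before each draw or when a drawn
  feature no longer fits. Every feasible set is reachable, and small
  `pStop` favours budget-filling start sets. Draws are deliberately not
  restricted to affordable features, which would bias starts towards very
  cheap features.
- *Crossover* forwards shared features to both children, then visits the
  exclusive features in random order, assigning each by fair coin and
  adding it only if that child's remaining budget allows.
- *Mutation* decides add-vs-remove in advance with
  `P(add) = 1 − costs(s)/c_max`, picks uniformly among affordable absent
  features (falling back to removal if none fits), or removes a uniform
  member. A "remove" on an empty set returns it unchanged — a
  probability-zero event under the decision rule but reachable through
  configuration.

Fitness is the negative AIC; no violation handling is needed because no
violating candidate is ever constructed. Subset fitness evaluations are
memoised per run, since elitism and converged populations revisit the same
subsets constantly.

Why bother with closed operators? Two analytic facts, both exposed as
functions: for two disjoint budget-filling 10-feature parents with unit
costs and budget 10, unconstrained uniform crossover produces a violating
child with probability `P(Bin(20, ½) ≥ 11) ≈ 0.412`
(`crossover_violation_probability()`), and a cost-agnostic toggle mutation
of a 10-feature set in a 500-feature pool adds — and thus violates at a
full budget — with probability 0.98 (`naive_mutation_add_probability()`).

Crossover and mutation rates (0.8 per selected pair, 0.1 per individual)
are not part of the method definitions; they are exposed as configuration
with those common defaults. Elitism likewise: it is the default of widely
used GA implementations and gives the monotone best-so-far property the
tests assert.

## Filter baselines

Filters score each feature marginally — Welch t-test p-values
(lower is better) or symmetric uncertainty
`SU = 2·I(X;Y)/(H(X)+H(Y))` on 10 equal-frequency bins (higher is better);
any external scorer plugs in through `score_adapter()`. Selection walks
the ranking top-down, adding each feature that fits the remaining budget.
Two readings of "stop if the cost of any remaining feature would exceed
the budget" are possible; `costsel` skips unaffordable features and
continues until *no* remaining feature fits, which maximises budget use,
and offers `stop_at_first_unaffordable = TRUE` for the stricter reading.
Default importance thresholds are 0.05 for the t-test and 1e-6 for
symmetric uncertainty; external scorers get none.

## The synthetic framework

Settings `A`–`K` (see `setting_presets()`) define the study grid over
`γ ∈ {1/3, 1/2, 2/3, 2}`, `p ∈ {30, 300, 1500}`, `p_rel ∈ {3, 15, 18, 20, 30}`
and effect sizes `β ∈ {0.3, 0.5, 1}` (in feature-sd units), with
`n_train = 500`, `n_test = 10000` and 100 replicates as the reference
conditions. The main generator draws `y ~ Bernoulli(0.5)` and features
from `N_p(μ, I)` in class 1 vs `N_p(0, I)` in class 0, with `μ` carrying
`β` on the first `p_rel` coordinates. The specialised settings vary one
assumption each:

- `G`: correlated features with a logistic response
  (`X ~ N_p(0, Σ)`, `y_i ~ Bernoulli(plogis(x_i'μ))`). The covariance
  estimated from the real metabolomic panel that motivates this setting is
  not publicly available, so a clearly synthetic block-exchangeable
  substitute is used (blocks of 5 at ρ = 0.7, both configurable) — it
  mimics "groups of strongly correlated covariables", not the original
  matrix.
- `H`: effect-dependent costs — relevant features `U(0.4, 1)` (mean 0.7),
  noise `U(0.1, 0.7)` (mean 0.4).
- `I`: equidistant effects `p_rel/p_rel, …, 2/p_rel, 1/p_rel` spanning
  (0, 1].
- `J`: equidistant effects with cost–effect coupling
  `c_i ~ U(0.1 + μ_i/2, 0.5 + μ_i/2)`.
- `K`: heavy-tailed cells from `0.9·N(μ_i, 1) + 0.1·N(μ_i, 5²)`
  (mixture variance 3.4). The second mixture parameter is read as a
  standard deviation — the spread convention of the robustness literature
  this construction follows — and is configurable (`tail_sd`); no test
  depends on that reading.

What the generator does *not* emulate: real spectra or assay panels
(block-exchangeable correlation is a crude stand-in for empirical
covariance), measurement error in the costs themselves, non-additive or
group-structured costs, and class imbalance. Passing tests therefore
demonstrate correctness of the algorithms under the stated generative
conditions, not performance claims about any particular real data set.

## Numerical choices and degenerate inputs

- Budget comparisons use an absolute tolerance of 1e-9 so exactly-full
  sets are feasible; costs must be strictly positive (the BCR divides by
  `c_i`), enforced at construction.
- The AIC parameter count uses the *requested* member count, not the
  fitted rank, so a duplicated (rank-deficient) column can never lower the
  AIC; such fits, and fits hitting the IRLS iteration cap (100), are
  returned with `converged = FALSE` and treated as valid candidates — a
  greedy or evolutionary search must not abort on one pathological
  candidate.
- AUC ties contribute 1/2 (midrank convention).
- A t-test on a feature constant in both classes yields a missing score,
  ranked last; a feature collapsing to a single bin gets symmetric
  uncertainty 0.
- Replicate `b` of a benchmark re-seeds with `master_seed + b`, so every
  method within a replicate sees the identical instance and the whole
  table is reproducible bitwise.

## Scale of the shipped experiments

The test suite and the acceptance script run the framework at desk scale,
chosen so the full check completes in minutes on one core while leaving
the study conditions (effect sizes, `γ`, cost rules, `n_train = 500`)
untouched: recovery checks use 30 replicates of the small strong-effect
setting; the recall-ceiling check runs settings A–C with 2–3 replicates;
GA checks use populations of 80–200 with at most 150 generations; the
exhaustive oracle enumerates all feasible subsets at `p = 10`; the
feasibility-crossing demonstration uses the full 298-feature unit-cost
scenario. The `n_test` used for AUC evaluation is reduced from 10000 to
500–2000 where the quantity under test is a recovery rate rather than an
AUC. Population 500 × 150 generations — the reference configuration for
full-scale studies — remains the package default.

## Limitations

- The scoring model is fixed to AIC-scored logistic regression;
  cross-validated criteria and other learners would broaden applicability
  but change the evaluation-count economics of the wrappers.
- Greedy complexity scales with `p` per step; for `p` in the thousands the
  GA variants or filters are the practical choices.
- The external-scorer adapter deliberately does not reimplement published
  joint-mutual-information or random-forest-impurity filters
  bit-for-bit; it reproduces their role, not their implementations.
- `fGA` may legitimately end without a feasible solution on pathological
  budgets; callers must check the `feasible` flag.
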