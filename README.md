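# gges

Score-based causal discovery for clinical cohort tables in which some
variables are *outcomes* (disease recurrence, recurrence-free survival) and
must never be modeled as causes. `gges` learns a directed acyclic graph
(DAG) over the variables by a grouped greedy search, ranks the causal
influence of every variable on each outcome with IDA (intervention
do-calculus adjustment) estimates, and ships a synthetic clinical-cohort
generator with a known ground-truth model so the whole pipeline can be
validated end to end.

It is aimed at analysts of observational clinical datasets — for example
CT-derived body-composition features, demographics, and pathologic stage in
a lung-cancer surgical cohort — who want causal structure rather than pure
prediction.

## The method

Variables are partitioned into a causal group `Vc` and an outcome
(predicted) group `Vp`. The search maximizes a decomposable Gaussian BIC
score over DAGs subject to a background-knowledge constraint `C`:

```
max_G  f(G, D)    s.t.  G acyclic,  G |= C
C:  vi -> vj allowed   if vi in Vc
    vi -> vj forbidden if vi in Vp      (outcomes are sinks)
```

with `f(G, D) = sum_j [ loglik_j - (k_j / 2) log n ]`, where `loglik_j` is
the maximized Gaussian log-likelihood of the linear regression of variable
`j` on its parents in `G` (intercept included, ML variance) and
`k_j = |parents| + 2`. The search runs two phases from the empty graph:

1. **Greedy forward search** — repeatedly insert the admissible edge with
   the largest strictly positive score gain (acyclicity checked per
   candidate);
2. **Greedy backward search** — repeatedly delete the edge whose removal
   gives the largest strictly positive gain.

Variables left unconnected are pruned as non-significant. Causal influence
of `x` on outcome `y` is then quantified by the IDA estimate: the
coefficient of `x` in the regression of `y` on `x` plus the learned parents
of `x` (equivalence-class multisets with a min-|effect| summary are
available via `ida_multiset()`). On simulated ground truth, exact total
causal effects (`tce()`, the sum over directed paths of edge-weight
products) validate those estimates, and adjacency/arrowhead
precision-recall (`metric_report()`) plus k-fold cross-validation
(`cross_validate()`) measure structural accuracy and stability.

## Worked example

```r
library(gges)

sim <- simulate_cohort(cohort_spec(n = 2000, seed = 42))
fit <- fit_gges(sim$dataset, sim$roles)

metric_report(fit$graph, sim$sem$dag)
#> AP 0.960  AR 0.857  AHP 0.920  AHR 0.821

prune_isolated(fit)
#> gges_fit: 21 variables (3 pruned), 25 edges, score -56273.1224

head(ida_table(sim$dataset, fit$graph, "rec_free_survival",
               roles = sim$roles), 4)
#>                 variable   ida abs_ida rank
#> 1                t_stage -2.90    2.90    1
#> 2 mass_intermuscular_fat -2.43    2.43    2
#> 3              tnm_stage -2.29    2.29    3
#> 4                n_stage -2.15    2.15    4
```

The fitted graph recovers the generating skeleton with 96% precision and
86% recall at n = 2000, and the IDA ranking surfaces the stage and
body-composition variables that truly drive recurrence-free survival in
the generator (e.g. the exact total effect of `tnm_stage` is −3.0 months
per stage unit; the IDA estimate above is −2.29 on the learned graph).
Isolated variables (`race`, `smoke_hx_coded`, `histology` here) are pruned
as unconnected at this sample size.

A command-line wrapper with `fit`, `cv`, `simulate`, and `metrics`
subcommands is installed at
`system.file("cli", "gges", package = "gges")`.

## Package layout

- `R/graphs.R` — DAG/PDAG types, acyclicity, restricted CPDAGs, Meek-style
  orientation closure, consistent extensions, CSV/DOT export.
- `R/scoring.R` — decomposable Gaussian BIC local and graph scores with
  caching.
- `R/search.R` — grouped greedy forward/backward search and pruning.
- `R/effects.R` — IDA estimates (single-graph and equivalence-class
  multiset), exact total causal effects, ranked effect tables.
- `R/evaluation.R` — adjacency/arrowhead precision-recall and k-fold
  cross-validation with edge-stability reporting.
- `R/synthetic.R` — random constrained DAGs, linear-Gaussian SEM sampling,
  and the clinical-cohort emulator.
- `R/cli.R` — pipeline entry points (`run_fit`, `run_cv`, `run_simulate`,
  `run_metrics`) behind the command-line wrapper.

See `vignettes/gges-methods.Rmd` for the full methodological account.
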