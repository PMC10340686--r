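---
title: "Grouped greedy equivalence search: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grouped greedy equivalence search: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gges)
```

## The problem

Observational clinical cohorts mix demographic variables, imaging-derived
body-composition measurements, and pathologic staging with outcome
variables such as binary recurrence and recurrence-free survival (RFS, in
months). Regression and machine-learning models rank predictors but say
nothing about the web of dependencies *between* the predictors, which is
exactly what a clinician reasoning about intervention targets needs. `gges`
addresses this with score-based causal structure learning specialized to
the clinical setting, where one piece of prior knowledge is always
available: outcomes cannot cause anything.

## Model and score

Let `D` be an n x p complete numeric data matrix and `G` a DAG over its
columns. We model each variable as a linear function of its parents plus
Gaussian noise and score structures with the decomposable Gaussian BIC

$$ f(G, D) \;=\; \sum_{j=1}^{p} \Big[ \hat\ell_j(\mathrm{Pa}_G(j)) - \frac{k_j}{2}\log n \Big], \qquad k_j = |\mathrm{Pa}_G(j)| + 2, $$

where $\hat\ell_j$ is the maximized log-likelihood of the regression of
column `j` on its parents with intercept and ML (1/n) variance. The
parameter count includes the intercept and the residual variance, so even a
parentless node pays `(2/2) log n`. Larger scores are better. Because the
score decomposes over nodes, the gain of inserting or deleting a single
edge `x -> y` involves only the two local terms of `y`; `delta_insert()`
returns exactly `graph_score(g + x->y) - graph_score(g)`.

Two standard assumptions connect the score optimum to causal structure:
the Markov condition and faithfulness (the conditional independencies in
the data are exactly those implied by the true DAG). They are documented
preconditions of the method, not runtime checks — no finite sample can
verify them.

Integer-coded categorical variables (race, smoking, histology, ordinal
stage codes) are scored by the same Gaussian likelihood. This matches
common practice for cohort tables that are integer-encoded before analysis
and keeps the score decomposable; it is an approximation for genuinely
discrete variables and is listed under limitations.

## Group constraint

Variables are partitioned into a causal group and an outcome group. The
admissibility rule is evaluated edge-wise by `allowed_edge()`: an edge is
admissible exactly when its source is causal. Outcome-to-causal and
outcome-to-outcome edges are forbidden, so outcomes are sinks in every
graph the search ever visits, including intermediates. The constraint is
asserted again on the final graph, and the test suite replays every search
trace to confirm no intermediate violates it.

## Search procedure

The search operates in DAG space, mirroring the procedure it implements:
single edges are added or deleted on a directed graph under an acyclicity
check, rather than Chickering-style insert/delete operators on equivalence
classes.

1. **Forward phase.** Start from the empty graph. Each round evaluates the
   insertion gain of every absent admissible edge that keeps the graph
   acyclic and inserts the single best edge if its gain is strictly
   positive; otherwise the phase stops.
2. **Backward phase.** Each round evaluates the deletion gain of every
   existing edge and deletes the best strictly positive one; deletions can
   never create cycles or constraint violations.

The final score is recomputed from scratch and checked against the
incremental trace.

Numerical choices, each of which matters for reproducibility:

- **Stopping rule.** Strict improvement with no slack; deltas within 1e-9
  of zero are treated as zero. BIC already penalizes complexity, and any
  looser threshold would be an extra hyperparameter.
- **Tie-breaking.** Among equal-gain candidates the lexicographically
  first (source index, target index) pair in input column order wins, so
  outputs are deterministic functions of the input.
- **Score-equivalent orientations.** Within the all-causal block, the two
  orientations of a covered edge score identically; the tie-break then
  decides the reported direction. The honest summary of such edges is the
  equivalence class: `cpdag_of()` computes the restricted CPDAG (compelled
  edges directed, reversible edges undirected) under the outcome
  constraint treated as background knowledge.
- **Degenerate candidates.** A candidate whose parent set is collinear, or
  whose residual variance falls below `1e-12` times the child's variance,
  raises a degenerate-model error; during search such candidates are
  skipped with a warning rather than aborting the fit.
- **Single pass.** One forward phase followed by one backward phase. The
  backward phase rarely modifies a forward result on well-identified data,
  and the pair of phases is the procedure's definition here; iterating the
  phases to convergence is a possible extension, not implemented.

After the search, `prune_isolated()` removes degree-0 variables as
non-significant, keeping their marginal score terms separately so the
total score remains auditable.

## Orientation machinery

`meek_closure()` maximally orients a partially directed graph under the
group constraint: undirected edges incident to an outcome are oriented into
the outcome, Meek rules R1-R3 are applied to a fixpoint, and remaining
compelled orientations — including the configurations covered by rule R4,
which only arises under background knowledge — are found by an
extension-feasibility sweep (an orientation is compelled when the reverse
admits no consistent extension, tested with the Dor-Tarsi sink algorithm).
This closure is validated in the test suite against brute-force enumeration
of every DAG on up to four nodes: for each graph the package's restricted
CPDAG is compared with the orientation pattern shared by all
constraint-satisfying members of its equivalence class.
`consistent_extension()` picks the highest-index eligible sink at each
step, so an undirected edge `x -- y` between causal variables extends to
`x -> y` when `x` precedes `y` in column order.

## Effect estimation

For a fitted DAG, the IDA estimate of the effect of `x` on outcome `y` is
the coefficient of `x` in the least-squares regression of `y` on
`{x} ∪ Pa(x)`; when `y` is a parent of `x` the effect is zero by
definition. Ranked effect tables (`ida_table()`) sort by absolute estimate,
ties in input order. Three conventions follow the cited method's standard
use:

- a single score per variable is reported from the learned DAG's unique
  parent set; the equivalence-class multiset with the conservative
  minimum-absolute-value summary is available (`ida_multiset()`, or
  `--ida-aggregation min-abs` in the CLI) for analysts who prefer not to
  commit to one member of the class;
- signed values are reported and ranking uses the absolute value;
- effects are computed on raw columns (per-unit interpretation); a
  `standardize` flag enables z-scoring first.

On simulation ground truth, `tce()` computes the exact total causal
effect as the `(x, y)` entry of `(I - W)^{-1} - I` for the weight matrix
`W`, which equals the sum over directed paths of edge-weight products
because `W` is nilpotent on a DAG. The acceptance checks require the IDA
estimate to land within 10% relative error of the exact effect (for
effects of magnitude at least 0.5 at n = 10000) and within sampling noise
of zero for non-ancestor pairs.

## Structural evaluation and cross-validation

Adjacency precision/recall (AP, AR) compare skeletons; arrowhead
precision/recall (AHP, AHR) compare directed endpoints, counting an
estimated arrowhead correct only when the reference directs the same
ordered pair identically. Undirected edges contribute adjacencies but no
arrowheads, and a zero denominator yields an explicit `NA` ("undefined"),
never a silent 0 or 1.

For observational cohorts no ground-truth graph exists, so
`cross_validate()` evaluates each fold's graph against the full-data graph
and reports per-edge stability (the fraction of folds retaining each
edge). This is a *stability* harness: it measures sensitivity of the
learned structure to subsampling, not correctness, which is why the
package pairs it with the simulation-based recovery checks where truth is
known.

## The synthetic cohort

`simulate_cohort()` draws a 21-variable table emulating a lung-resection
cohort: demographics (age ~ N(68.3, 9.45²), 46.28% female, BMI ~
N(27.8, 5.98²), race and smoking codes), ordinal T/N/TNM stage, CT-derived
body-composition volumes, densities and masses, binary recurrence
(population rate 0.67) and recurrence-free survival in months. Design
choices a user should know:

- **Observed drivers, no latent factors.** Adiposity-related variables are
  driven by observed BMI and frame-size variables by observed height, so
  the generating DAG is causally sufficient and skeleton recovery against
  it is well-defined. Real cohorts have unmeasured confounders; passing
  recovery tests here does not certify behavior under latent confounding.
- **Mass consistency.** Tissue masses are generated from their volumes
  (mass ≈ volume × density-derived factor plus noise), reproducing the
  strong volume-mass dependencies of real body-composition tables.
- **Height and weight.** The emulator uses height ~ sex + noise (mean
  ≈ 170 cm, SD ≈ 10) and derives weight from BMI and height through the
  linearized `BMI × (height/100)²` relation, rather than generating the
  two independently — independent draws would be mutually inconsistent
  with the BMI marginal and can produce physically impossible values.
- **Outcome equations.** Recurrence is Bernoulli with a logistic link on
  stage, visceral-fat volume, and muscle density; its intercept is
  calibrated once per specification by Monte Carlo (fixed internal seed,
  20000 draws) so the population rate hits the target exactly in
  expectation. RFS is a censored-at-zero Gaussian whose latent mean (5.5)
  and noise SD (23.5) give an observed mean ≈ 12.5 and SD ≈ 16 months —
  the skew induced by censoring is the realistic feature, since
  recurrence-free time cannot be negative. Both outcomes depend on stage
  variables, which induces the outcome-outcome association seen in real
  cohorts without any outcome-to-outcome edge (outcomes must be sinks in
  the ground truth). The recorded SEM coefficients for these two nodes are
  their linear-predictor weights; the DAG itself is exact.
- **Values not fixed by the emulated summaries.** Smoking prevalence
  (0.85 for current/prior, typical of surgical lung-cancer cohorts) and
  histology proportions (0.6/0.3/0.1) are the package's own defaults,
  stated here and in `cohort_defs()`.
- **Deliberate non-realism.** Two binary-link and censored nodes violate
  the Gaussian-SEM assumption by design: they let the tests measure how
  the Gaussian BIC search degrades on realistic outcome encodings. The
  weak smoking-to-RFS signal (standardized effect ≈ 0.05) is genuinely
  below the BIC detection threshold at moderate n, so smoking is often
  pruned — mirroring the behavior of greedy search on marginal clinical
  signals.

`encode_variables()` applies the integer codebook (race: white 1, African
American 2, other 3; smoking: current/prior 1, never 2; histology:
adenocarcinoma 1, squamous 2, other 3) to string columns and drops
incomplete rows, so raw exports can be fed to the same pipeline.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` use: 50 seeded 4-variable
datasets (n = 500) for oracle agreement and single-edge local optimality;
all 3-node equivalence classes on 10 datasets for score equivalence; 20
seeded 10-variable SEMs (8 causal + 2 outcome, 10 edges, |coefficients| in
[0.8, 1.5], unit noise, n = 5000) for skeleton recovery; 20 seeded
6-variable SEMs at n = 10000 for IDA/TCE recovery; 10 cohort draws at the
study size n = 363 for marginal fidelity; and n = 5000 cohort draws for
end-to-end skeleton recall. These sizes were chosen so each property is
measured with comfortable statistical margin while the whole suite stays
quick to run.

## Known limitations

- Gaussian likelihood on coded categorical and binary variables is an
  approximation; a discrete or generalized score is out of scope.
- The greedy search returns a local optimum; the acceptance checks verify
  local (single-edge) optimality, not global optimality.
- No missing-data likelihood: rows with missing values are dropped at
  encoding.
- IDA assumes no unmeasured confounding of the adjusted pairs and linear
  effects; confidence intervals are not provided.
- Cross-validation stability is not a substitute for external validation
  on an independent cohort.
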