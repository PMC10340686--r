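test_that("allowed_edge implements the group constraint", {
  roles <- role_assignment(c("a", "b", "p", "q"), outcome = c("p", "q"))
  expect_true(allowed_edge("a", "b", roles))   # causal -> causal
  expect_true(allowed_edge("a", "p", roles))   # causal -> outcome
  expect_false(allowed_edge("p", "a", roles))  # outcome -> causal
  expect_false(allowed_edge("p", "q", roles))  # outcome -> outcome
  expect_error(allowed_edge("a", "zz", roles), "missing")
})

test_that("forward search keeps independent variables unconnected", {
  # with 10 variable pairs the BIC penalty leaves a small per-dataset
  # chance of one spurious edge, so assert the overwhelming tendency
  n_edges <- integer(10)
  for (seed in 1:10) {
    set.seed(seed)
    d <- matrix(rnorm(5000 * 5), 5000,
                dimnames = list(NULL, paste0("v", 1:5)))
    res <- greedy_forward(d, role_assignment(paste0("v", 1:5)))
    n_edges[seed] <- nrow(edge_list(res$graph))
    expect_equal(nrow(res$trace), n_edges[seed])
  }
  expect_gte(sum(n_edges == 0L), 9L)
})

test_that("forward search links a strongly dependent pair", {
  set.seed(7)
  x <- rnorm(1000)
  d <- cbind(x = x, y = 2 * x + rnorm(1000, sd = 0.1))
  # both causal: exactly one edge, either orientation
  res <- greedy_forward(d, role_assignment(c("x", "y")))
  e <- edge_list(res$graph)
  expect_equal(nrow(e), 1L)
  # y declared outcome: the single admissible direction
  res2 <- greedy_forward(d, role_assignment(c("x", "y"), outcome = "y"))
  e2 <- edge_list(res2$graph)
  expect_identical(e2$from, "x")
  expect_identical(e2$to, "y")
})

test_that("backward search deletes spurious edges and keeps faithful ones", {
  roles <- role_assignment(c("u", "v"))
  # nothing to delete
  set.seed(8)
  d0 <- as_gges_dataset(matrix(rnorm(100 * 2), 100,
                               dimnames = list(NULL, c("u", "v"))))
  res <- greedy_backward(d0, dag(c("u", "v")), roles)
  expect_equal(nrow(edge_list(res$graph)), 0L)
  expect_equal(nrow(res$trace), 0L)
  # independent pair with a forced edge: deletion recovers the penalty
  for (seed in 1:5) {
    set.seed(seed)
    d <- matrix(rnorm(5000 * 2), 5000, dimnames = list(NULL, c("u", "v")))
    g <- dag(c("u", "v"), data.frame(from = "u", to = "v"))
    res <- greedy_backward(d, g, roles)
    expect_equal(nrow(edge_list(res$graph)), 0L)
  }
  # forward-phase graphs on well-identified data are mostly untouched by
  # the backward phase (later insertions can occasionally make an earlier
  # edge redundant, so the pass-through is a tendency, not an identity)
  unchanged <- 0L
  for (seed in 20:24) {
    sim <- random_sem_dataset(5, 1, 0.4, 2000, seed = seed)
    fwd <- greedy_forward(sim$data, sim$roles)
    bwd <- greedy_backward(sim$data, fwd$graph, sim$roles)
    expect_gt(bwd$score - fwd$score, -1e-9)
    if (identical(bwd$graph$amat, fwd$graph$amat)) unchanged <- unchanged + 1L
  }
  expect_gte(unchanged, 4L)
})

test_that("fit_gges output satisfies score and constraint invariants", {
  sim <- random_sem_dataset(4, 1, 0.5, 800, seed = 5)
  fit <- fit_gges(sim$data, sim$roles)
  expect_s3_class(fit, "gges_fit")
  expect_true(is_acyclic(fit$graph))
  out_nodes <- sim$roles$name[sim$roles$role == "outcome"]
  expect_false(any(fit$graph$amat[out_nodes, ]))
  # reported score equals a from-scratch recomputation
  expect_equal(fit$score, graph_score(sim$data, fit$graph),
               tolerance = 1e-9)
  # trace is strictly increasing across both phases
  if (nrow(fit$trace) > 1L) {
    expect_true(all(diff(fit$trace$score_after) > 0))
  }
  # single outcome driven by a single cause
  set.seed(12)
  x <- rnorm(800)
  d <- cbind(cause = x, eff = 3 * x + rnorm(800, sd = 0.2))
  fit2 <- fit_gges(d, role_assignment(c("cause", "eff"), outcome = "eff"))
  expect_identical(edge_list(fit2$graph)$from, "cause")
  expect_identical(edge_list(fit2$graph)$to, "eff")
})

test_that("every intermediate graph of the search is valid", {
  for (seed in 1:5) {
    sim <- random_sem_dataset(5, 2, 0.4, 600, seed = seed)
    fit <- fit_gges(sim$data, sim$roles)
    out_nodes <- sim$roles$name[sim$roles$role == "outcome"]
    for (amat in replay_trace_graphs(fit$graph$nodes, fit$trace)) {
      expect_true(is_acyclic(amat))
      expect_false(any(amat[out_nodes, , drop = FALSE]))
    }
  }
})

test_that("prune_isolated removes exactly the degree-0 variables", {
  set.seed(30)
  x <- rnorm(600)
  vals <- cbind(a = x, b = 2 * x + rnorm(600, sd = 0.2), c = rnorm(600))
  fit <- fit_gges(vals, role_assignment(c("a", "b", "c")))
  expect_setequal(edge_list(fit$graph)$from, "a")
  pruned <- prune_isolated(fit)
  expect_identical(pruned$pruned_variables, "c")
  expect_setequal(pruned$retained_variables, c("a", "b"))
  expect_named(pruned$pruned_score_terms, "c")
  expect_equal(pruned$score, graph_score(pruned$dataset, pruned$graph),
               tolerance = 1e-9)
  # dropped marginal term accounts for the full score difference
  expect_equal(fit$score, pruned$score + pruned$pruned_score_terms[["c"]],
               tolerance = 1e-9)
  # identity when nothing is isolated
  expect_identical(prune_isolated(pruned)$pruned_variables, "c")
  # empty graph: everything is pruned
  d0 <- matrix(rnorm(500 * 3), 500, dimnames = list(NULL, c("p", "q", "r")))
  fit0 <- fit_gges(d0, role_assignment(c("p", "q", "r")))
  pr0 <- prune_isolated(fit0)
  expect_setequal(pr0$pruned_variables, c("p", "q", "r"))
  expect_length(pr0$retained_variables, 0L)
})

test_that("roles files load with causal defaults for unlisted variables", {
  f <- tempfile(fileext = ".yml")
  writeLines(c("rfs: outcome", "age: causal"), f)
  expect_warning(r <- read_roles(f, c("age", "bmi", "rfs")), "default to causal")
  expect_identical(role_of(r, c("age", "bmi", "rfs")),
                   c("causal", "causal", "outcome"))
  fj <- tempfile(fileext = ".json")
  writeLines('{"rfs": "outcome", "age": "causal", "bmi": "causal"}', fj)
  rj <- read_roles(fj, c("age", "bmi", "rfs"))
  expect_identical(role_of(rj, "rfs"), "outcome")
  writeLines(c("zz: outcome"), f)
  expect_error(read_roles(f, c("age")), "unknown variable")
})
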