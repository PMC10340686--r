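test_that("dag construction enforces structural invariants", {
  expect_s3_class(dag(c("a", "b"), data.frame(from = "a", to = "b")),
                  "gges_dag")
  expect_error(dag(c("a", "b"), data.frame(from = "a", to = "z")),
               "unknown node")
  expect_error(dag(c("a", "b"), data.frame(from = "a", to = "a")),
               "self-loop")
  expect_error(dag(c("a", "b"), data.frame(from = c("a", "b"),
                                           to = c("b", "a"))),
               "cycle")
  expect_error(dag(c("a", "a")), "duplicate")
})

test_that("is_acyclic matches igraph on hand cases and random graphs", {
  expect_true(is_acyclic(dag(c("a", "b", "c"))))
  amat2 <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2,
                  dimnames = list(c("a", "b"), c("a", "b")))
  expect_false(is_acyclic(amat2))
  tri <- dag(c("a", "b", "c"),
             data.frame(from = c("a", "b", "a"), to = c("b", "c", "c")))
  expect_true(is_acyclic(tri))
  # random directed graphs (cyclic or not) vs igraph oracle
  set.seed(42)
  for (rep in 1:30) {
    p <- sample(3:6, 1)
    nodes <- paste0("v", seq_len(p))
    amat <- matrix(stats::runif(p * p) < 0.3, p, p,
                   dimnames = list(nodes, nodes))
    diag(amat) <- FALSE
    ig <- igraph::graph_from_adjacency_matrix(amat * 1, mode = "directed")
    expect_identical(is_acyclic(amat), igraph::is_dag(ig))
  }
})

test_that("cpdag_of reproduces the stated small-graph classes", {
  all_causal <- role_assignment(c("x", "y", "z"))
  chain <- dag(c("x", "y", "z"),
               data.frame(from = c("x", "y"), to = c("y", "z")))
  p <- cpdag_of(chain, all_causal)
  expect_equal(sum(p$damat), 0L)
  expect_true(p$uamat["x", "y"] && p$uamat["y", "z"])
  collider <- dag(c("x", "y", "z"),
                  data.frame(from = c("x", "z"), to = c("y", "y")))
  p <- cpdag_of(collider, all_causal)
  expect_true(p$damat["x", "y"] && p$damat["z", "y"])
  expect_equal(sum(p$uamat), 0L)
  # an edge into an outcome node stays directed even without a collider
  g <- dag(c("x", "y"), data.frame(from = "x", to = "y"))
  p <- cpdag_of(g, role_assignment(c("x", "y"), outcome = "y"))
  expect_true(p$damat["x", "y"])
  expect_equal(sum(p$uamat), 0L)
})

test_that("cpdag_of is class-invariant and exact on all graphs up to 4 nodes", {
  for (setup in list(list(nodes = c("a", "b", "c"), out = character()),
                     list(nodes = c("a", "b", "c"), out = "c"),
                     list(nodes = c("a", "b", "c", "d"), out = character()),
                     list(nodes = c("a", "b", "c", "d"), out = "d"))) {
    roles <- role_assignment(setup$nodes, outcome = setup$out)
    out_idx <- match(setup$out, setup$nodes)
    gs <- Filter(function(g) !any(g$amat[out_idx, , drop = FALSE]),
                 all_dags(setup$nodes))
    sigs <- vapply(gs, dag_class_signature, "")
    for (i in seq_along(gs)) {
      cls <- gs[sigs == sigs[i]]
      # ground truth: an edge is compelled iff oriented the same way in
      # every class member satisfying the constraint
      dmat <- Reduce(`&`, lapply(cls, `[[`, "amat"))
      skel <- dmat | t(dmat) |
        Reduce(`|`, lapply(cls, function(h) h$amat | t(h$amat)))
      umat <- skel & !(dmat | t(dmat))
      got <- cpdag_of(gs[[i]], roles)
      expect_identical(unname(got$damat), unname(dmat))
      expect_identical(unname(got$uamat), unname(umat))
    }
  }
})

test_that("meek_closure fires R1, respects roles, and is idempotent", {
  roles <- role_assignment(c("a", "b", "c"))
  # R1: a -> b, b -- c, a and c nonadjacent
  p <- pdag(c("a", "b", "c"), directed = data.frame(from = "a", to = "b"),
            undirected = data.frame(from = "b", to = "c"))
  q <- meek_closure(p, roles)
  expect_true(q$damat["b", "c"])
  # fully undirected triangle: no rule fires
  tri <- pdag(c("a", "b", "c"),
              undirected = data.frame(from = c("a", "b", "c"),
                                      to = c("b", "c", "a")))
  q <- meek_closure(tri, roles)
  expect_equal(sum(q$damat), 0L)
  expect_equal(sum(q$uamat) / 2L, 3L)
  # background knowledge: a -- b with b an outcome orients a -> b
  p <- pdag(c("a", "b"), undirected = data.frame(from = "a", to = "b"))
  q <- meek_closure(p, role_assignment(c("a", "b"), outcome = "b"))
  expect_true(q$damat["a", "b"])
  # idempotence on assorted inputs
  for (p0 in list(tri, p)) {
    r <- role_assignment(p0$nodes)
    once <- meek_closure(p0, r)
    expect_identical(meek_closure(once, r), once)
  }
})

test_that("consistent_extension is deterministic, valid, and errors when stuck", {
  roles2 <- role_assignment(c("x", "y"))
  p <- pdag(c("x", "y"), undirected = data.frame(from = "x", to = "y"))
  g <- consistent_extension(p, roles2)
  expect_true(g$amat["x", "y"])   # node-order tie-break
  # already directed input passes through unchanged
  p2 <- pdag(c("x", "y", "z"),
             directed = data.frame(from = c("x", "y"), to = c("y", "z")))
  g2 <- consistent_extension(p2, role_assignment(c("x", "y", "z")))
  expect_identical(g2$amat, p2$damat)
  # directed 3-cycle cannot be built as a pdag at all
  expect_error(pdag(c("a", "b", "c"),
                    directed = data.frame(from = c("a", "b", "c"),
                                          to = c("b", "c", "a"))),
               "cycle")
  # extensions of random CPDAGs are acyclic, constraint-safe, and preserve
  # the equivalence class
  for (seed in 1:15) {
    g <- random_constrained_dag(4, 1, 0.5, seed = seed)
    roles <- role_assignment(g$nodes, outcome = "y1")
    p <- cpdag_of(g, roles)
    ext <- consistent_extension(p, roles)
    expect_true(is_acyclic(ext))
    expect_false(any(ext$amat["y1", ]))
    expect_identical(dag_class_signature(ext), dag_class_signature(g))
  }
})

test_that("graph CSV and DOT round-trips preserve structure", {
  g <- dag(c("a", "b", "c"),
           data.frame(from = c("a", "b"), to = c("b", "c")))
  f <- tempfile(fileext = ".csv")
  write_graph_csv(g, f)
  g2 <- read_graph_csv(f, nodes = g$nodes)
  expect_identical(g2$amat, g$amat)
  p <- pdag(c("a", "b", "c"), directed = data.frame(from = "a", to = "b"),
            undirected = data.frame(from = "b", to = "c"))
  write_graph_csv(p, f)
  p2 <- read_graph_csv(f, nodes = p$nodes)
  expect_identical(p2$damat, p$damat)
  expect_identical(p2$uamat, p$uamat)
  dotf <- tempfile(fileext = ".dot")
  write_dot(p, dotf)
  txt <- readLines(dotf)
  expect_true(any(grepl("\"a\" -> \"b\";", txt)))
  expect_true(any(grepl("dir=none", txt)))
})
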