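# Independent oracles used across the suite. These deliberately avoid the
# package's scoring/search code paths: local scores go through stats::lm +
# stats::BIC, acyclicity through igraph, and the greedy oracle rescores the
# whole graph at every step.

oracle_local <- function(df, child, parents) {
  f <- if (length(parents)) {
    stats::reformulate(sprintf("`%s`", parents), sprintf("`%s`", child))
  } else {
    stats::as.formula(sprintf("`%s` ~ 1", child))
  }
  -stats::BIC(stats::lm(f, data = df)) / 2
}

oracle_graph_score <- function(df, edges, nodes) {
  s <- 0
  for (v in nodes) s <- s + oracle_local(df, v, edges$from[edges$to == v])
  s
}

oracle_acyclic <- function(edges, nodes) {
  if (nrow(edges) == 0L) return(TRUE)
  igraph::is_dag(igraph::graph_from_data_frame(edges, vertices = nodes))
}

# naive grouped greedy search: forward then backward, full rescore per step
oracle_gges <- function(df, nodes, outcome = character()) {
  edges <- data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE)
  score <- oracle_graph_score(df, edges, nodes)
  repeat {
    best <- NULL
    for (x in setdiff(nodes, outcome)) for (y in nodes) {
      if (x == y || any(edges$from == x & edges$to == y)) next
      cand <- rbind(edges, data.frame(from = x, to = y))
      if (!oracle_acyclic(cand, nodes)) next
      s <- oracle_graph_score(df, cand, nodes)
      if (s > score + 1e-9 && (is.null(best) || s > best$s + 1e-9)) {
        best <- list(e = cand, s = s)
      }
    }
    if (is.null(best)) break
    edges <- best$e; score <- best$s
  }
  repeat {
    best <- NULL
    for (k in seq_len(nrow(edges))) {
      cand <- edges[-k, , drop = FALSE]
      s <- oracle_graph_score(df, cand, nodes)
      if (s > score + 1e-9 && (is.null(best) || s > best$s + 1e-9)) {
        best <- list(e = cand, s = s)
      }
    }
    if (is.null(best)) break
    edges <- best$e; score <- best$s
  }
  list(edges = edges, score = score)
}

# all DAGs on a (small) node set: each unordered pair absent/forward/reverse
all_dags <- function(nodes) {
  pr <- t(utils::combn(nodes, 2))
  states <- expand.grid(rep(list(0:2), nrow(pr)))
  out <- list()
  for (r in seq_len(nrow(states))) {
    st <- unlist(states[r, ])
    from <- character(); to <- character()
    for (k in seq_len(nrow(pr))) {
      if (st[k] == 1L) { from <- c(from, pr[k, 1]); to <- c(to, pr[k, 2]) }
      if (st[k] == 2L) { from <- c(from, pr[k, 2]); to <- c(to, pr[k, 1]) }
    }
    g <- tryCatch(dag(nodes, cbind(from = from, to = to)),
                  error = function(e) NULL)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  out
}

# skeleton + collider-triple signature identifying the Markov class
dag_class_signature <- function(g) {
  e <- edge_list(g)
  sk <- if (nrow(e)) {
    apply(cbind(pmin(e$from, e$to), pmax(e$from, e$to)), 1L,
          paste, collapse = "~")
  } else character()
  amat <- g$amat; skel <- amat | t(amat)
  trip <- character()
  for (y in g$nodes) {
    pa <- g$nodes[amat[, y]]
    if (length(pa) >= 2L) {
      for (i in seq_len(length(pa) - 1L)) for (j in seq(i + 1L, length(pa))) {
        if (!skel[pa[i], pa[j]]) {
          trip <- c(trip, paste(c(sort(c(pa[i], pa[j])), y), collapse = "|"))
        }
      }
    }
  }
  paste(paste(sort(sk), collapse = ";"), paste(sort(trip), collapse = ";"),
        sep = "#")
}

# random linear SEM on a role-constrained random DAG, with its dataset
random_sem_dataset <- function(n_causal, n_outcome, edge_prob, n, seed,
                               beta_range = c(0.5, 1.5)) {
  g <- random_constrained_dag(n_causal, n_outcome, edge_prob,
                              seed = seed + 1000L)
  e <- edge_list(g)
  set.seed(seed)
  wt <- if (nrow(e)) {
    sample(c(-1, 1), nrow(e), replace = TRUE) *
      stats::runif(nrow(e), beta_range[1], beta_range[2])
  } else numeric()
  sem <- sem_spec(g, data.frame(from = e$from, to = e$to, weight = wt),
                  noise_sd = 1)
  list(graph = g, sem = sem, data = sample_linear_sem(sem, n, seed = seed),
       roles = role_assignment(
         g$nodes,
         outcome = grep("^y", g$nodes, value = TRUE)))
}

# random DAG with exactly `n_edges` edges (resamples until hit)
random_dag_fixed_edges <- function(n_causal, n_outcome, n_edges, seed) {
  p_pairs <- n_causal * (n_causal - 1) / 2 + n_causal * n_outcome
  tries <- 0L
  repeat {
    tries <- tries + 1L
    g <- random_constrained_dag(n_causal, n_outcome, n_edges / p_pairs,
                                seed = seed * 1000L + tries)
    if (nrow(edge_list(g)) == n_edges) return(g)
  }
}

# replay a search trace, asserting validity of each intermediate graph
replay_trace_graphs <- function(nodes, trace) {
  amat <- matrix(FALSE, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  out <- list()
  for (k in seq_len(nrow(trace))) {
    if (trace$action[k] == "insert") {
      stopifnot(!amat[trace$from[k], trace$to[k]])
      amat[trace$from[k], trace$to[k]] <- TRUE
    } else {
      stopifnot(amat[trace$from[k], trace$to[k]])
      amat[trace$from[k], trace$to[k]] <- FALSE
    }
    out[[k]] <- amat
  }
  out
}
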