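# Directed and partially directed graph structures used throughout the
# package. Graphs are stored as logical adjacency matrices with a stable,
# user-supplied node order; that order is the universal tie-breaker so all
# outputs are deterministic.

#' Construct a directed acyclic graph
#'
#' A `gges_dag` holds an ordered node set and a set of directed edges stored
#' as a logical adjacency matrix (`amat[i, j]` is `TRUE` for the edge
#' `i -> j`). Self-loops, duplicate edges and directed cycles are rejected.
#'
#' @param nodes Character vector of unique node names; the order is kept and
#'   used as the deterministic tie-break throughout the package.
#' @param edges Two-column matrix or data frame of edges (`from`, `to`), or
#'   `NULL` for an edgeless graph.
#' @return An object of class `gges_dag` with elements `nodes` and `amat`.
#' @examples
#' g <- dag(c("a", "b", "c"), data.frame(from = "a", to = "b"))
#' is_acyclic(g)
#' @export
dag <- function(nodes, edges = NULL) {
  stopifnot(is.character(nodes))
  if (anyDuplicated(nodes)) stop("duplicate node names", call. = FALSE)
  p <- length(nodes)
  amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(edges) <- "character"
    bad <- !(edges %in% nodes)
    if (any(bad)) {
      stop("edge references unknown node(s): ",
           paste(unique(edges[bad]), collapse = ", "), call. = FALSE)
    }
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loop not allowed", call. = FALSE)
    amat[edges] <- TRUE
  }
  g <- structure(list(nodes = nodes, amat = amat), class = "gges_dag")
  if (!is_acyclic(g)) stop("edge set contains a directed cycle", call. = FALSE)
  g
}

#' Test whether a directed graph is acyclic
#'
#' Pure check by repeated removal of in-degree-zero nodes (Kahn's algorithm);
#' the input is never modified.
#'
#' @param g A `gges_dag`, or anything with a logical adjacency matrix in
#'   `$amat`.
#' @return `TRUE` if no directed cycle exists.
#' @export
is_acyclic <- function(g) {
  amat <- if (is.matrix(g)) g else g$amat
  if (!is.matrix(amat) || nrow(amat) != ncol(amat)) {
    stop("malformed adjacency matrix", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(amat))
  repeat {
    indeg <- colSums(amat[keep, keep, drop = FALSE])
    src <- which(indeg == 0L)
    if (length(src) == 0L) break
    keep[which(keep)[src]] <- FALSE
    if (!any(keep)) break
  }
  !any(keep)
}

#' Construct a partially directed graph
#'
#' A `gges_pdag` carries a directed part and an undirected part; a node pair
#' may appear in at most one of the two, and the directed part must be
#' acyclic.
#'
#' @param nodes Character vector of node names (order preserved).
#' @param directed Two-column matrix/data frame of directed edges, or `NULL`.
#' @param undirected Two-column matrix/data frame of undirected edges
#'   (stored symmetrically), or `NULL`.
#' @return An object of class `gges_pdag`.
#' @export
pdag <- function(nodes, directed = NULL, undirected = NULL) {
  gd <- dag(nodes, directed) # validates directed part incl. acyclicity
  p <- length(nodes)
  uamat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (!is.null(undirected) && NROW(undirected) > 0L) {
    ue <- as.matrix(undirected)[, 1:2, drop = FALSE]
    storage.mode(ue) <- "character"
    bad <- !(ue %in% nodes)
    if (any(bad)) {
      stop("edge references unknown node(s): ",
           paste(unique(ue[bad]), collapse = ", "), call. = FALSE)
    }
    if (any(ue[, 1L] == ue[, 2L])) stop("self-loop not allowed", call. = FALSE)
    uamat[ue] <- TRUE
    uamat[ue[, 2:1, drop = FALSE]] <- TRUE
  }
  both <- (gd$amat | t(gd$amat)) & uamat
  if (any(both)) {
    stop("node pair present in both directed and undirected edge sets",
         call. = FALSE)
  }
  structure(list(nodes = nodes, damat = gd$amat, uamat = uamat),
            class = "gges_pdag")
}

#' @export
print.gges_dag <- function(x, ...) {
  e <- edge_list(x)
  cat(sprintf("gges_dag: %d nodes, %d directed edges\n",
              length(x$nodes), nrow(e)))
  if (nrow(e)) {
    cat(paste0("  ", e$from, " -> ", e$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
print.gges_pdag <- function(x, ...) {
  e <- edge_list(x)
  cat(sprintf("gges_pdag: %d nodes, %d directed, %d undirected edges\n",
              length(x$nodes), sum(e$type == "directed"),
              sum(e$type == "undirected")))
  if (nrow(e)) {
    arrow <- ifelse(e$type == "directed", " -> ", " -- ")
    cat(paste0("  ", e$from, arrow, e$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Edge list of a graph
#'
#' @param g A `gges_dag` or `gges_pdag`.
#' @return Data frame with columns `from`, `to`, `type`
#'   (`"directed"`/`"undirected"`); undirected edges are listed once with
#'   `from` earlier in node order. Rows are in deterministic node order.
#' @export
edge_list <- function(g) {
  if (inherits(g, "gges_dag")) {
    idx <- which(g$amat, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    return(data.frame(from = g$nodes[idx[, 1L]], to = g$nodes[idx[, 2L]],
                      type = rep("directed", nrow(idx)),
                      stringsAsFactors = FALSE))
  }
  stopifnot(inherits(g, "gges_pdag"))
  di <- which(g$damat, arr.ind = TRUE)
  di <- di[order(di[, 1L], di[, 2L]), , drop = FALSE]
  ui <- which(g$uamat & upper.tri(g$uamat), arr.ind = TRUE)
  ui <- ui[order(ui[, 1L], ui[, 2L]), , drop = FALSE]
  data.frame(
    from = c(g$nodes[di[, 1L]], g$nodes[ui[, 1L]]),
    to = c(g$nodes[di[, 2L]], g$nodes[ui[, 2L]]),
    type = c(rep("directed", nrow(di)), rep("undirected", nrow(ui))),
    stringsAsFactors = FALSE)
}

# parents of `node` in a dag, as a character vector in node order
dag_parents <- function(g, node) g$nodes[g$amat[, node]]

# TRUE if a directed path from -> to exists (DFS on the adjacency matrix)
has_directed_path <- function(amat, from, to) {
  if (from == to) return(TRUE)
  p <- nrow(amat)
  seen <- rep(FALSE, p)
  stack <- from
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    nxt <- which(amat[v, ] & !seen)
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    stack <- c(stack, nxt)
  }
  FALSE
}

# skeleton (symmetric logical) of a dag or pdag
skeleton_amat <- function(g) {
  if (inherits(g, "gges_dag")) g$amat | t(g$amat)
  else g$damat | t(g$damat) | g$uamat
}

# v-structure edge matrix of a dag: logical amat containing exactly the
# edges that take part in some collider x -> y <- z with x, z nonadjacent
vstructure_amat <- function(g) {
  amat <- g$amat
  p <- nrow(amat)
  skel <- amat | t(amat)
  out <- matrix(FALSE, p, p, dimnames = dimnames(amat))
  for (y in seq_len(p)) {
    pa <- which(amat[, y])
    if (length(pa) < 2L) next
    for (i in seq_along(pa)[-length(pa)]) {
      for (j in seq((i + 1L), length(pa))) {
        if (!skel[pa[i], pa[j]]) {
          out[pa[i], y] <- TRUE
          out[pa[j], y] <- TRUE
        }
      }
    }
  }
  out
}

#' Restricted CPDAG of a DAG under the outcome-group constraint
#'
#' Computes the completed partially directed graph of the Markov equivalence
#' class of `g`, restricted by the background knowledge that edges into
#' outcome variables cannot be reversed: v-structure edges and edges into
#' outcome nodes stay directed, further compelled edges are found by the
#' orientation closure of [meek_closure()], and the remaining edges are
#' reported undirected.
#'
#' @param g A `gges_dag` (must be acyclic by construction).
#' @param roles A [role_assignment()] covering all nodes of `g`.
#' @return A `gges_pdag`.
#' @export
cpdag_of <- function(g, roles) {
  stopifnot(inherits(g, "gges_dag"))
  check_roles_cover(roles, g$nodes)
  vs <- vstructure_amat(g)
  forced <- g$amat & matrix(role_of(roles, g$nodes) == "outcome",
                            nrow(g$amat), ncol(g$amat), byrow = TRUE)
  dmat <- vs | forced
  umat <- (g$amat | t(g$amat)) & !(dmat | t(dmat))
  p0 <- structure(list(nodes = g$nodes, damat = dmat, uamat = umat),
                  class = "gges_pdag")
  meek_closure(p0, roles)
}

# orient u -> v inside the closure loop, catching conflicts
orient_edge <- function(p, u, v) {
  if (p$damat[v, u]) {
    stop(sprintf("orientation conflict on edge %s -- %s",
                 p$nodes[u], p$nodes[v]), call. = FALSE)
  }
  p$damat[u, v] <- TRUE
  p$uamat[u, v] <- FALSE
  p$uamat[v, u] <- FALSE
  p
}

#' Orientation closure of a partially directed graph
#'
#' Applies, to a fixpoint, the standard orientation rules for maximally
#' orienting a PDAG under background knowledge: any undirected edge with an
#' outcome endpoint is oriented into the outcome (outcome variables cannot
#' cause anything), Meek rules R1-R3 are applied directly, and remaining
#' compelled orientations (including rule-R4 configurations) are found by an
#' extension-feasibility sweep: if only one orientation of an undirected edge
#' admits a consistent extension, that orientation is compelled. The result
#' extends the directed part of the input and the operation is idempotent.
#'
#' @param p A `gges_pdag`.
#' @param roles A [role_assignment()] covering all nodes.
#' @return A `gges_pdag` with all compelled edges directed.
#' @export
meek_closure <- function(p, roles) {
  stopifnot(inherits(p, "gges_pdag"))
  check_roles_cover(roles, p$nodes)
  is_out <- role_of(roles, p$nodes) == "outcome"
  n <- length(p$nodes)

  # background knowledge: undirected edge with an outcome endpoint
  ue <- which(p$uamat & upper.tri(p$uamat), arr.ind = TRUE)
  for (k in seq_len(nrow(ue))) {
    a <- ue[k, 1L]; b <- ue[k, 2L]
    if (is_out[a] && is_out[b]) {
      stop(sprintf("orientation conflict on edge %s -- %s: both endpoints are outcomes",
                   p$nodes[a], p$nodes[b]), call. = FALSE)
    }
    if (is_out[b]) p <- orient_edge(p, a, b)
    else if (is_out[a]) p <- orient_edge(p, b, a)
  }

  repeat {
    changed <- FALSE
    skel <- p$damat | t(p$damat) | p$uamat
    ue <- which(p$uamat & upper.tri(p$uamat), arr.ind = TRUE)
    for (k in seq_len(nrow(ue))) {
      for (pair in list(c(ue[k, 1L], ue[k, 2L]), c(ue[k, 2L], ue[k, 1L]))) {
        a <- pair[1L]; b <- pair[2L]
        if (!p$uamat[a, b]) next
        # R1: c -> a, c and b nonadjacent  =>  a -> b
        r1 <- any(p$damat[, a] & !skel[, b] & seq_len(n) != b)
        # R2: a -> c -> b  =>  a -> b
        r2 <- any(p$damat[a, ] & p$damat[, b])
        # R3: a -- c -> b, a -- d -> b, c and d nonadjacent  =>  a -> b
        r3 <- FALSE
        cand <- which(p$uamat[a, ] & p$damat[, b])
        if (length(cand) >= 2L) {
          for (i in seq_along(cand)[-length(cand)]) {
            if (any(!skel[cand[i], cand[seq(i + 1L, length(cand))]])) {
              r3 <- TRUE; break
            }
          }
        }
        if (r1 || r2 || r3) {
          p <- orient_edge(p, a, b)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  # completion sweep: orientation compelled when the reverse admits no
  # consistent extension (covers Meek R4 and background-knowledge residue)
  repeat {
    changed <- FALSE
    ue <- which(p$uamat & upper.tri(p$uamat), arr.ind = TRUE)
    for (k in seq_len(nrow(ue))) {
      a <- ue[k, 1L]; b <- ue[k, 2L]
      if (!p$uamat[a, b]) next
      ok_ab <- extendable(orient_edge(p, a, b))
      ok_ba <- extendable(orient_edge(p, b, a))
      if (!ok_ab && !ok_ba) {
        stop(sprintf("orientation conflict on edge %s -- %s: no consistent extension either way",
                     p$nodes[a], p$nodes[b]), call. = FALSE)
      }
      if (xor(ok_ab, ok_ba)) {
        p <- if (ok_ab) orient_edge(p, a, b) else orient_edge(p, b, a)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p
}

# Dor & Tarsi feasibility: TRUE iff the pdag admits an acyclic extension
# that creates no new v-structures
extendable <- function(p) {
  dmat <- p$damat
  umat <- p$uamat
  alive <- rep(TRUE, length(p$nodes))
  repeat {
    if (!any(alive)) return(TRUE)
    found <- FALSE
    for (x in which(alive)) {
      if (any(dmat[x, alive])) next          # x has an out-edge, not a sink
      nb_un <- which(umat[x, ] & alive)
      nb_all <- which((dmat[, x] | umat[x, ]) & alive)
      ok <- TRUE
      for (u in nb_un) {
        others <- setdiff(nb_all, u)
        if (length(others) &&
            !all(dmat[u, others] | dmat[others, u] | umat[u, others])) {
          ok <- FALSE; break
        }
      }
      if (ok) {
        alive[x] <- FALSE
        found <- TRUE
        break
      }
    }
    if (!found) return(FALSE)
  }
}

#' Consistent DAG extension of a partially directed graph
#'
#' Orients all undirected edges so that the result is acyclic, introduces no
#' new v-structures, and respects the outcome-group constraint. The
#' extension is deterministic given the node order: at each step the
#' highest-index eligible sink is consumed, so an undirected edge `x -- y`
#' on two causal nodes extends to `x -> y` when `x` precedes `y`.
#'
#' @param p A `gges_pdag`.
#' @param roles A [role_assignment()] covering all nodes.
#' @return A `gges_dag` extending `p`'s directed part.
#' @export
consistent_extension <- function(p, roles) {
  stopifnot(inherits(p, "gges_pdag"))
  check_roles_cover(roles, p$nodes)
  # orient role-forced edges first so the extension cannot violate the group
  # constraint
  is_out <- role_of(roles, p$nodes) == "outcome"
  ue <- which(p$uamat & upper.tri(p$uamat), arr.ind = TRUE)
  for (k in seq_len(nrow(ue))) {
    a <- ue[k, 1L]; b <- ue[k, 2L]
    if (is_out[a] && is_out[b]) {
      stop("no consistent extension: undirected edge between two outcome nodes",
           call. = FALSE)
    }
    if (is_out[b]) p <- orient_edge(p, a, b)
    else if (is_out[a]) p <- orient_edge(p, b, a)
  }
  dmat <- p$damat
  umat <- p$uamat
  res <- p$damat
  alive <- rep(TRUE, length(p$nodes))
  while (any(alive)) {
    sink <- NA_integer_
    for (x in rev(which(alive))) {       # highest index first: see docs
      if (any(dmat[x, alive])) next
      nb_un <- which(umat[x, ] & alive)
      nb_all <- which((dmat[, x] | umat[x, ]) & alive)
      ok <- TRUE
      for (u in nb_un) {
        others <- setdiff(nb_all, u)
        if (length(others) &&
            !all(dmat[u, others] | dmat[others, u] | umat[u, others])) {
          ok <- FALSE; break
        }
      }
      if (ok) { sink <- x; break }
    }
    if (is.na(sink)) {
      stop("no consistent extension exists for this partially directed graph",
           call. = FALSE)
    }
    for (u in which(umat[sink, ] & alive)) res[u, sink] <- TRUE
    alive[sink] <- FALSE
  }
  dag(p$nodes, which_edges(res, p$nodes))
}

# logical amat -> two-column character matrix of edges
which_edges <- function(amat, nodes) {
  idx <- which(amat, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  cbind(from = nodes[idx[, 1L]], to = nodes[idx[, 2L]])
}

#' Write a graph as an edge-list CSV
#'
#' Columns are `source`, `target`, `type` (`directed`/`undirected`), matching
#' [read_graph_csv()].
#'
#' @param g A `gges_dag` or `gges_pdag`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_csv <- function(g, path) {
  e <- edge_list(g)
  utils::write.csv(
    data.frame(source = e$from, target = e$to, type = e$type),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a graph from an edge-list CSV
#'
#' @param path File written by [write_graph_csv()].
#' @param nodes Node set (ordered). Defaults to the nodes appearing in the
#'   file, in order of first appearance.
#' @return A `gges_dag` when all edges are directed, otherwise a `gges_pdag`.
#' @export
read_graph_csv <- function(path, nodes = NULL) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "type") %in% names(e)))
  if (is.null(nodes)) nodes <- unique(c(rbind(e$source, e$target)))
  if (all(e$type == "directed")) {
    dag(nodes, e[, c("source", "target")])
  } else {
    pdag(nodes,
         e[e$type == "directed", c("source", "target")],
         e[e$type == "undirected", c("source", "target")])
  }
}

#' Export a graph in Graphviz DOT format
#'
#' @param g A `gges_dag` or `gges_pdag`.
#' @param path Output file path.
#' @param name Graph name in the DOT header.
#' @return `path`, invisibly.
#' @export
write_dot <- function(g, path, name = "gges") {
  e <- edge_list(g)
  lines <- c(sprintf("digraph %s {", name),
             sprintf("  \"%s\";", g$nodes))
  if (nrow(e)) {
    attr_ <- ifelse(e$type == "undirected", " [dir=none]", "")
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\"%s;", e$from, e$to, attr_))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
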