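# The GGES search: variables are grouped into causal and outcome sets,
# outcome variables are forbidden from causing anything, and the graph is
# grown from the empty graph by greedy single-edge insertions (forward
# phase) followed by greedy single-edge deletions (backward phase), both
# maximizing the decomposable Gaussian BIC score under an acyclicity check.
# Deltas within 1e-9 of zero are treated as zero so the stopping rule is
# strict improvement; ties are broken lexicographically by (source index,
# target index) in input column order.

DELTA_EPS <- 1e-9

empty_trace <- function() {
  data.frame(phase = character(), from = character(), to = character(),
             action = character(), score_after = numeric(),
             stringsAsFactors = FALSE)
}

# shared engine for both phases. `moves` enumerates candidates each round.
greedy_phase <- function(d, amat, roles, cache, phase, score0, verbose) {
  nodes <- d$variables[d$variables %in% rownames(amat)]
  is_causal <- role_of(roles, rownames(amat)) == "causal"
  trace <- empty_trace()
  score <- score0
  repeat {
    best <- NULL
    p <- nrow(amat)
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (i == j) next
        if (phase == "forward") {
          if (amat[i, j] || !is_causal[i]) next
          if (has_directed_path(amat, j, i)) next  # insertion would cycle
        } else {
          if (!amat[i, j]) next
        }
        delta <- tryCatch(
          {
            pa <- rownames(amat)[amat[, j]]
            child <- rownames(amat)[j]
            new_pa <- if (phase == "forward") c(pa, rownames(amat)[i])
                      else setdiff(pa, rownames(amat)[i])
            local_score(d, child, new_pa, cache) -
              local_score(d, child, pa, cache)
          },
          error = function(e) {
            warning(sprintf("[%s] skipping %s -> %s: %s", toupper(phase),
                            rownames(amat)[i], rownames(amat)[j],
                            conditionMessage(e)), call. = FALSE)
            NA_real_
          })
        if (is.na(delta) || delta <= DELTA_EPS) next
        if (is.null(best) || delta > best$delta + DELTA_EPS) {
          best <- list(i = i, j = j, delta = delta)
        }
        # ties (within DELTA_EPS) keep the earlier (i, j): loop order is
        # already lexicographic
      }
    }
    if (is.null(best)) break
    if (phase == "forward") amat[best$i, best$j] <- TRUE
    else amat[best$i, best$j] <- FALSE
    score <- score + best$delta
    if (verbose) {
      message(sprintf("[%s] %s %s -> %s (score %.4f)", toupper(phase),
                      if (phase == "forward") "insert" else "delete",
                      rownames(amat)[best$i], rownames(amat)[best$j], score))
    }
    trace <- rbind(trace, data.frame(
      phase = phase, from = rownames(amat)[best$i],
      to = rownames(amat)[best$j],
      action = if (phase == "forward") "insert" else "delete",
      score_after = score, stringsAsFactors = FALSE))
  }
  list(amat = amat, trace = trace, score = score)
}

#' Greedy forward search
#'
#' Starting from the empty graph, repeatedly inserts the admissible edge
#' (causal source, acyclicity preserved) with the largest strictly positive
#' score gain, until no insertion improves the score.
#'
#' @param d Dataset ([as_gges_dataset()]).
#' @param roles [role_assignment()] covering all columns of `d`.
#' @param cache Optional [score_cache()].
#' @param verbose Log each accepted move.
#' @return List with `graph` (`gges_dag`) and `trace` (data frame of moves
#'   with strictly increasing `score_after`).
#' @export
greedy_forward <- function(d, roles, cache = score_cache(), verbose = FALSE) {
  d <- as_gges_dataset(d)
  check_roles_cover(roles, d$variables)
  g0 <- dag(d$variables)
  s0 <- graph_score(d, g0, cache)
  res <- greedy_phase(d, g0$amat, roles, cache, "forward", s0, verbose)
  list(graph = dag(d$variables, which_edges(res$amat, d$variables)),
       trace = res$trace, score = res$score)
}

#' Greedy backward search
#'
#' Repeatedly deletes the edge whose removal gives the largest strictly
#' positive score gain, until no deletion improves the score. Deletions can
#' never violate the group constraint or create cycles.
#'
#' @param d Dataset.
#' @param g Starting `gges_dag` (typically the forward-phase result).
#' @param roles [role_assignment()].
#' @param cache Optional [score_cache()].
#' @param verbose Log each accepted move.
#' @return List with `graph` and `trace` as in [greedy_forward()].
#' @export
greedy_backward <- function(d, g, roles, cache = score_cache(),
                            verbose = FALSE) {
  d <- as_gges_dataset(d)
  stopifnot(inherits(g, "gges_dag"))
  check_roles_cover(roles, g$nodes)
  s0 <- graph_score(d, g, cache)
  res <- greedy_phase(d, g$amat, roles, cache, "backward", s0, verbose)
  list(graph = dag(g$nodes, which_edges(res$amat, g$nodes)),
       trace = res$trace, score = res$score)
}

#' Fit a grouped greedy equivalence search model
#'
#' Runs the full search: role validation, greedy forward insertion phase,
#' then greedy backward deletion phase. The final score is recomputed from
#' scratch (fresh cache) and checked against the trace, and the result is
#' asserted to be acyclic with no edge out of an outcome variable.
#'
#' @param d Dataset (matrix, data frame, or [as_gges_dataset()] result).
#' @param roles [role_assignment()] covering all columns of `d`.
#' @param verbose Log accepted moves.
#' @return An object of class `gges_fit`: list with `graph` (`gges_dag`),
#'   `score`, `trace`, `retained_variables`, `pruned_variables` (empty until
#'   [prune_isolated()]), `pruned_score_terms`, `roles`, and `dataset`.
#' @examples
#' set.seed(1)
#' x <- rnorm(200); y <- 2 * x + rnorm(200, sd = 0.3)
#' d <- cbind(x = x, y = y)
#' fit <- fit_gges(d, role_assignment(c("x", "y"), outcome = "y"))
#' edge_list(fit$graph)
#' @export
fit_gges <- function(d, roles, verbose = FALSE) {
  d <- as_gges_dataset(d)
  check_roles_cover(roles, d$variables)
  cache <- score_cache()
  fwd <- greedy_forward(d, roles, cache, verbose)
  bwd <- greedy_backward(d, fwd$graph, roles, cache, verbose)
  g <- bwd$graph
  final_score <- graph_score(d, g, score_cache())  # from scratch
  stopifnot(abs(final_score - bwd$score) < 1e-6)
  empty_score <- graph_score(d, dag(d$variables), cache)
  stopifnot(final_score >= bwd$score - 1e-9,
            bwd$score >= fwd$score - 1e-9,
            fwd$score >= empty_score - 1e-9)
  assert_constraint(g, roles)
  trace <- rbind(fwd$trace, bwd$trace)
  structure(list(graph = g, score = final_score, trace = trace,
                 retained_variables = g$nodes,
                 pruned_variables = character(),
                 pruned_score_terms = numeric(),
                 roles = roles, dataset = d),
            class = "gges_fit")
}

# stop unless g is acyclic and no edge leaves an outcome node
assert_constraint <- function(g, roles) {
  if (!is_acyclic(g)) stop("result graph is cyclic", call. = FALSE)
  is_out <- role_of(roles, g$nodes) == "outcome"
  if (any(g$amat[is_out, ])) {
    stop("constraint violation: edge out of an outcome variable",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.gges_fit <- function(x, ...) {
  cat(sprintf("gges_fit: %d variables (%d pruned), %d edges, score %.4f\n",
              length(x$retained_variables) + length(x$pruned_variables),
              length(x$pruned_variables), nrow(edge_list(x$graph)), x$score))
  invisible(x)
}

#' Remove variables unconnected to the rest of the graph
#'
#' Degree-0 nodes are treated as non-significant and dropped from the fitted
#' graph. The reported score is recomputed over the retained variables only;
#' the dropped marginal score terms are kept in `pruned_score_terms`.
#'
#' @param r A `gges_fit`.
#' @return A `gges_fit` on the retained variables, with `pruned_variables`
#'   extended.
#' @export
prune_isolated <- function(r) {
  stopifnot(inherits(r, "gges_fit"))
  deg <- rowSums(r$graph$amat) + colSums(r$graph$amat)
  iso <- r$graph$nodes[deg == 0]
  if (!length(iso)) return(r)
  keep <- setdiff(r$graph$nodes, iso)
  cache <- score_cache()
  dropped <- vapply(iso, function(v) local_score(r$dataset, v, cache = cache),
                    numeric(1L))
  r$pruned_variables <- c(r$pruned_variables, iso)
  r$pruned_score_terms <- c(r$pruned_score_terms, dropped)
  r$retained_variables <- keep
  e <- edge_list(r$graph)
  r$graph <- dag(keep, e[, c("from", "to")])
  r$score <- if (length(keep)) graph_score(r$dataset, r$graph, cache) else 0
  r
}
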