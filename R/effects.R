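# Causal-effect quantification. IDA estimates the total causal effect of a
# unit intervention on x upon y by least-squares adjustment for x's graph
# parents; on an equivalence class it enumerates the locally valid parent
# sets and summarizes by minimum absolute value. On a weighted ground-truth
# DAG the total causal effect is exact: the sum over directed paths of the
# products of edge coefficients.

#' Specify a linear structural equation model
#'
#' Ground-truth weighted DAG with Gaussian noise, used for simulation and as
#' the reference for effect-recovery checks.
#'
#' @param dag A `gges_dag`.
#' @param weights Data frame with columns `from`, `to`, `weight`; the
#'   `(from, to)` pairs must be exactly the edges of `dag`.
#' @param noise_sd Named numeric vector of positive noise standard
#'   deviations, one per node (a single unnamed value is recycled).
#' @param intercepts Named numeric vector of intercepts (default all 0; a
#'   single unnamed value is recycled).
#' @return An object of class `gges_sem`.
#' @export
sem_spec <- function(dag, weights, noise_sd = 1, intercepts = 0) {
  stopifnot(inherits(dag, "gges_dag"))
  e <- edge_list(dag)
  if (nrow(e) == 0L) {
    weights <- data.frame(from = character(), to = character(),
                          weight = numeric())
  }
  stopifnot(all(c("from", "to", "weight") %in% names(weights)))
  key_g <- paste(e$from, e$to, sep = "\r")
  key_w <- paste(weights$from, weights$to, sep = "\r")
  if (!setequal(key_g, key_w) || anyDuplicated(key_w)) {
    stop("weights must be keyed exactly by the DAG's edges", call. = FALSE)
  }
  expand <- function(v, default_name) {
    if (length(v) == 1L && is.null(names(v))) {
      v <- stats::setNames(rep(v, length(dag$nodes)), dag$nodes)
    }
    if (!setequal(names(v), dag$nodes)) {
      stop(default_name, " must be named by the DAG's nodes", call. = FALSE)
    }
    v[dag$nodes]
  }
  noise_sd <- expand(noise_sd, "noise_sd")
  if (any(noise_sd <= 0)) stop("noise_sd must be positive", call. = FALSE)
  intercepts <- expand(intercepts, "intercepts")
  structure(list(dag = dag, weights = weights, noise_sd = noise_sd,
                 intercepts = intercepts),
            class = "gges_sem")
}

# node x node weight matrix W with W[i, j] = coefficient of i -> j
weight_matrix <- function(spec) {
  nodes <- spec$dag$nodes
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(spec$weights)) {
    W[cbind(spec$weights$from, spec$weights$to)] <- spec$weights$weight
  }
  W
}

#' Exact total causal effect in a linear SEM
#'
#' Sum over all directed paths from `x` to `y` of the product of edge
#' weights along each path; 0 when no directed path exists. Computed in
#' closed form as the `(x, y)` entry of `(I - W)^{-1} - I`, which equals the
#' path-product sum because `W` is nilpotent on a DAG.
#'
#' @param spec A [sem_spec()].
#' @param x,y Node names in `spec$dag`.
#' @return Numeric scalar.
#' @examples
#' g <- dag(c("x", "m", "y"),
#'          data.frame(from = c("x", "m", "x"), to = c("m", "y", "y")))
#' w <- data.frame(from = c("x", "m", "x"), to = c("m", "y", "y"),
#'                 weight = c(0.5, 0.4, 0.1))
#' tce(sem_spec(g, w), "x", "y")  # 0.5*0.4 + 0.1 = 0.3
#' @export
tce <- function(spec, x, y) {
  stopifnot(inherits(spec, "gges_sem"))
  miss <- setdiff(c(x, y), spec$dag$nodes)
  if (length(miss)) {
    stop("unknown node(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  W <- weight_matrix(spec)
  Tm <- solve(diag(nrow(W)) - W) - diag(nrow(W))
  unname(Tm[x, y])
}

effect_estimate <- function(source, target, ida, n_equivalent, aggregation) {
  structure(list(source = source, target = target, ida = ida,
                 n_equivalent = n_equivalent, aggregation = aggregation),
            class = "gges_effect")
}

#' @export
print.gges_effect <- function(x, ...) {
  cat(sprintf("IDA effect %s -> %s: %.6g (%d parent set%s, %s)\n",
              x$source, x$target, x$ida, x$n_equivalent,
              if (x$n_equivalent == 1L) "" else "s", x$aggregation))
  invisible(x)
}

# adjustment estimate: coefficient of x in lm(y ~ x + adjust); 0 when y is
# in the adjustment set (y is then a non-descendant of x)
adjust_coef <- function(d, x, y, adjust) {
  if (y %in% adjust) return(0)
  X <- cbind(1, d$values[, c(x, adjust), drop = FALSE])
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    stop(sprintf("degenerate model: collinear adjustment set for %s", x),
         call. = FALSE)
  }
  unname(qr.coef(qr_, d$values[, y])[2L])
}

#' IDA effect estimate on a directed graph
#'
#' The parent-adjustment estimate of the total causal effect of a unit
#' intervention on `x` upon `y`: the coefficient of `x` in the least-squares
#' regression of `y` on `x` and the graph parents of `x`. When `y` is a
#' parent of `x` (a non-descendant) the effect is 0 by definition.
#'
#' @param d Dataset.
#' @param g A `gges_dag` containing `x` and `y`.
#' @param x,y Source and target variable names, `x != y`.
#' @param standardize Z-score all columns before regressing (default FALSE:
#'   effects are per raw unit of `x`).
#' @return A `gges_effect` with `n_equivalent = 1`, `aggregation =
#'   "single"`.
#' @export
ida <- function(d, g, x, y, standardize = FALSE) {
  d <- as_gges_dataset(d)
  stopifnot(inherits(g, "gges_dag"), x != y)
  miss <- setdiff(c(x, y), intersect(g$nodes, d$variables))
  if (length(miss)) {
    stop("unknown variable(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (standardize) d <- as_gges_dataset(scale(d$values))
  est <- adjust_coef(d, x, y, dag_parents(g, x))
  effect_estimate(x, y, est, 1L, "single")
}

#' IDA multiset estimate on an equivalence class
#'
#' Enumerates the locally valid parent sets of `x` consistent with the
#' restricted CPDAG `p` (each subset of the undirected neighbours of `x`
#' that creates no new collider at `x`), computes the adjustment estimate
#' for each, and aggregates by minimum absolute value.
#'
#' @param d Dataset.
#' @param p A `gges_pdag` (e.g. from [cpdag_of()]).
#' @param x,y Source and target variable names.
#' @param standardize Z-score columns first.
#' @return A `gges_effect`; `n_equivalent` is the number of parent sets
#'   considered and `aggregation` is `"single"` when that number is 1,
#'   `"min_abs"` otherwise.
#' @export
ida_multiset <- function(d, p, x, y, standardize = FALSE) {
  d <- as_gges_dataset(d)
  stopifnot(inherits(p, "gges_pdag"), x != y)
  miss <- setdiff(c(x, y), intersect(p$nodes, d$variables))
  if (length(miss)) {
    stop("unknown variable(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (standardize) d <- as_gges_dataset(scale(d$values))
  skel <- skeleton_amat(p)
  definite <- p$nodes[p$damat[, x]]
  sibs <- p$nodes[p$uamat[x, ]]
  subsets <- list(character())
  for (s in sibs) subsets <- c(subsets, lapply(subsets, c, s))
  ests <- numeric()
  for (S in subsets) {
    # locally valid: orienting S -> x adds no collider at x, i.e. every
    # member of S is adjacent to every other member and to every definite
    # parent of x
    others <- c(S, definite)
    ok <- TRUE
    for (s in S) {
      rest <- setdiff(others, s)
      if (length(rest) && !all(skel[s, rest])) { ok <- FALSE; break }
    }
    if (!ok) next
    ests <- c(ests, adjust_coef(d, x, y, c(definite, S)))
  }
  n_eq <- length(ests)
  est <- ests[which.min(abs(ests))]
  effect_estimate(x, y, est, n_eq,
                  if (n_eq == 1L) "single" else "min_abs")
}

#' Ranked IDA effect table for one outcome
#'
#' One row per retained non-outcome variable of the fitted graph, sorted by
#' decreasing `|ida|` (ties keep input column order), mirroring the ranked
#' effect tables reported for clinical cohort models.
#'
#' @param d Dataset.
#' @param g A `gges_dag` (fitted graph).
#' @param outcome Outcome variable name (a node of `g`).
#' @param roles Optional [role_assignment()]; when given, all outcome-role
#'   variables (not just `outcome`) are excluded from the rows.
#' @param standardize Z-score columns first.
#' @return Data frame with columns `variable`, `ida`, `abs_ida`, `rank`.
#' @export
ida_table <- function(d, g, outcome, roles = NULL, standardize = FALSE) {
  d <- as_gges_dataset(d)
  stopifnot(inherits(g, "gges_dag"), outcome %in% g$nodes)
  drop <- outcome
  if (!is.null(roles)) {
    drop <- union(drop, roles$name[roles$role == "outcome"])
  }
  vars <- setdiff(g$nodes, drop)
  est <- vapply(vars, function(v) ida(d, g, v, outcome,
                                      standardize = standardize)$ida,
                numeric(1L))
  tab <- data.frame(variable = vars, ida = unname(est),
                    abs_ida = abs(unname(est)), stringsAsFactors = FALSE)
  ord <- order(-tab$abs_ida, seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Write an IDA effect table as CSV
#'
#' @param tab Result of [ida_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ida_csv <- function(tab, path) {
  utils::write.csv(tab[, c("variable", "ida", "abs_ida", "rank")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
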