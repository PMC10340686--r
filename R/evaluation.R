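# Structural accuracy metrics. Adjacency metrics compare skeletons (edges
# ignoring direction); arrowhead metrics compare directed endpoints, where
# an estimated arrowhead x -> y is correct only if the reference directs the
# same ordered pair the same way. Undirected edges contribute adjacencies
# but no arrowheads. Precision with a zero denominator is reported as NA
# ("undefined"), never silently 0 or 1.

skeleton_pairs <- function(g) {
  s <- skeleton_amat(g)
  idx <- which(s & upper.tri(s), arr.ind = TRUE)
  paste(rownames(s)[idx[, 1L]], colnames(s)[idx[, 2L]], sep = "\r")
}

arrowhead_pairs <- function(g) {
  amat <- if (inherits(g, "gges_dag")) g$amat else g$damat
  idx <- which(amat, arr.ind = TRUE)
  paste(rownames(amat)[idx[, 1L]], colnames(amat)[idx[, 2L]], sep = "\r")
}

check_same_nodes <- function(est, ref) {
  if (!setequal(est$nodes, ref$nodes)) {
    stop("estimated and reference graphs have different node sets",
         call. = FALSE)
  }
}

#' Adjacency precision and recall
#'
#' Compares the skeletons of an estimated and a reference graph.
#' `ap = TP / (TP + FP)` over estimated adjacencies (NA when the estimate
#' has no edges), `ar = TP / (TP + FN)` over reference adjacencies.
#'
#' @param est,ref `gges_dag` or `gges_pdag` objects on the same node set.
#' @return List with `ap`, `ar`, and `counts = c(tp, fp, fn)`.
#' @export
adjacency_metrics <- function(est, ref) {
  check_same_nodes(est, ref)
  e <- skeleton_pairs(est)
  r <- skeleton_pairs(ref)
  tp <- length(intersect(e, r))
  fp <- length(setdiff(e, r))
  fn <- length(setdiff(r, e))
  list(ap = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
       ar = if (tp + fn == 0L) NA_real_ else tp / (tp + fn),
       counts = c(tp = tp, fp = fp, fn = fn))
}

#' Arrowhead precision and recall
#'
#' An arrowhead is a directed endpoint `x -> y`; it is counted correct only
#' when the other graph directs the same ordered pair identically.
#' `ahp` is over estimated arrowheads (NA when there are none), `ahr` over
#' reference arrowheads.
#'
#' @param est,ref `gges_dag` or `gges_pdag` objects on the same node set.
#' @return List with `ahp`, `ahr`, and `counts = c(tp, fp, fn)`.
#' @export
arrowhead_metrics <- function(est, ref) {
  check_same_nodes(est, ref)
  e <- arrowhead_pairs(est)
  r <- arrowhead_pairs(ref)
  tp <- length(intersect(e, r))
  fp <- length(setdiff(e, r))
  fn <- length(setdiff(r, e))
  list(ahp = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
       ahr = if (tp + fn == 0L) NA_real_ else tp / (tp + fn),
       counts = c(tp = tp, fp = fp, fn = fn))
}

#' Combined structural metric report
#'
#' @param est,ref Graphs on the same node set.
#' @return List of class `gges_metrics` with `ap`, `ar`, `ahp`, `ahr`,
#'   `adjacency_counts`, `arrowhead_counts`.
#' @export
metric_report <- function(est, ref) {
  a <- adjacency_metrics(est, ref)
  h <- arrowhead_metrics(est, ref)
  structure(list(ap = a$ap, ar = a$ar, ahp = h$ahp, ahr = h$ahr,
                 adjacency_counts = a$counts, arrowhead_counts = h$counts),
            class = "gges_metrics")
}

#' @export
print.gges_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat(sprintf("AP %s  AR %s  AHP %s  AHR %s\n",
              fmt(x$ap), fmt(x$ar), fmt(x$ahp), fmt(x$ahr)))
  invisible(x)
}

#' k-fold cross-validation of the structure search
#'
#' Splits the rows into `k` seeded folds, refits the search on each training
#' fold, and evaluates every fold graph against the full-data graph with
#' both adjacency and arrowhead metrics. No ground truth exists for
#' observational cohorts, so the full-data graph is the reference and the
#' per-edge stability (fraction of folds retaining each directed edge) is
#' the headline stability summary.
#'
#' @param d Dataset.
#' @param roles [role_assignment()].
#' @param k Number of folds (>= 2), default 10.
#' @param seed Integer seed for the fold split.
#' @param verbose Log per-fold progress.
#' @return An object of class `gges_cv`: `fold_reports` (list of
#'   `gges_metrics`), `edge_stability` (data frame `from`, `to`,
#'   `fraction`), `full_graph`, `k`, `seed`.
#' @export
cross_validate <- function(d, roles, k = 10L, seed = 1L, verbose = FALSE) {
  d <- as_gges_dataset(d)
  check_roles_cover(roles, d$variables)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (d$n < k) stop("more folds than rows", call. = FALSE)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), d$n)))
  full <- fit_gges(d, roles)
  reports <- vector("list", k)
  edge_count <- new.env(parent = emptyenv())
  for (f in seq_len(k)) {
    train <- d$values[folds != f, , drop = FALSE]
    if (nrow(train) < 3L) {
      stop(sprintf("fold %d leaves fewer than 3 training rows", f),
           call. = FALSE)
    }
    if (nrow(train) <= ncol(train)) {
      warning(sprintf("fold %d: training rows <= variables", f),
              call. = FALSE)
    }
    fit_f <- fit_gges(train, roles)
    if (verbose) message(sprintf("[CV] fold %d/%d: %d edges", f, k,
                                 nrow(edge_list(fit_f$graph))))
    reports[[f]] <- metric_report(fit_f$graph, full$graph)
    e <- edge_list(fit_f$graph)
    for (key in paste(e$from, e$to, sep = "\r")) {
      assign(key, (get0(key, envir = edge_count) %||% 0L) + 1L,
             envir = edge_count)
    }
  }
  keys <- sort(ls(edge_count))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  stability <- data.frame(
    from = vapply(parts, `[`, "", 1L),
    to = vapply(parts, `[`, "", 2L),
    fraction = vapply(keys, function(k_) get(k_, envir = edge_count), 0L) / k,
    stringsAsFactors = FALSE)
  rownames(stability) <- NULL
  structure(list(fold_reports = reports, edge_stability = stability,
                 full_graph = full$graph, k = k, seed = as.integer(seed)),
            class = "gges_cv")
}

#' @export
print.gges_cv <- function(x, ...) {
  ar <- vapply(x$fold_reports, function(r) r$ar, numeric(1L))
  cat(sprintf("gges_cv: k = %d, mean fold AR vs full-data graph %.3f\n",
              x$k, mean(ar, na.rm = TRUE)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds the random number generator, evaluates `expr`, and restores the
#' caller's RNG state afterwards, so seeded draws never perturb surrounding
#' randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
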