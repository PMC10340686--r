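# Decomposable Gaussian BIC scoring. Each node contributes a local score:
# the maximized log-likelihood of the linear regression of the node on its
# parents (with intercept, ML variance) minus (k/2) log n, k = |parents| + 2
# (regression coefficients + intercept + residual variance). Larger is
# better, and a graph's score is the sum of its local scores, so single-edge
# score differences reduce to two local terms.

#' Construct a scoring dataset
#'
#' Validates and wraps an n x p numeric matrix (or data frame) for use with
#' the BIC score and the search. All values must be finite, every column
#' must have positive variance, and n >= 3; n < p is allowed with a warning.
#'
#' @param x Numeric matrix or all-numeric data frame with column names.
#' @return An object of class `gges_dataset` with elements `values` (matrix),
#'   `n`, `p`, `variables` (column names).
#' @export
as_gges_dataset <- function(x) {
  if (inherits(x, "gges_dataset")) return(x)
  if (is.data.frame(x)) {
    if (!all(vapply(x, is.numeric, logical(1L)))) {
      stop("all columns must be numeric (encode categorical variables first)",
           call. = FALSE)
    }
    x <- as.matrix(x)
  }
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    stop("dataset needs unique column names", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("dataset contains missing or non-finite values", call. = FALSE)
  }
  n <- nrow(x); p <- ncol(x)
  if (n < 3L) stop("at least 3 rows are required", call. = FALSE)
  v <- apply(x, 2L, stats::var)
  if (any(v <= 0)) {
    stop("constant column(s): ", paste(colnames(x)[v <= 0], collapse = ", "),
         call. = FALSE)
  }
  if (n < p) warning("fewer rows than columns (n < p)", call. = FALSE)
  structure(list(values = x, n = n, p = p, variables = colnames(x)),
            class = "gges_dataset")
}

#' @export
print.gges_dataset <- function(x, ...) {
  cat(sprintf("gges_dataset: %d rows x %d variables\n", x$n, x$p))
  invisible(x)
}

#' Create a local-score cache
#'
#' Maps `(child, sorted parent set)` to the local score; a cache hit returns
#' the identical stored value. One cache must only ever be used with the
#' dataset it was created for.
#'
#' @return An environment of class `gges_score_cache`.
#' @export
score_cache <- function() {
  structure(new.env(parent = emptyenv()), class = "gges_score_cache")
}

cache_key <- function(child, parents) {
  paste0(child, "|", paste(sort(parents), collapse = ","))
}

#' Gaussian BIC local score of one node given a parent set
#'
#' Fits the linear regression of `child` on `parents` plus an intercept with
#' maximum likelihood (variance estimated with 1/n) and returns
#' `loglik - (k/2) log n`, `k = |parents| + 2`. Deterministic; invariant to
#' the order of `parents` and to row permutations of the data.
#'
#' @param d A [as_gges_dataset()] dataset.
#' @param child Column name of the node being scored.
#' @param parents Character vector of parent column names (may be empty).
#' @param cache Optional [score_cache()].
#' @return Numeric scalar (larger is better).
#' @export
local_score <- function(d, child, parents = character(), cache = NULL) {
  d <- as_gges_dataset(d)
  parents <- as.character(parents)
  if (child %in% parents) stop("child cannot be its own parent", call. = FALSE)
  miss <- setdiff(c(child, parents), d$variables)
  if (length(miss)) {
    stop("unknown variable(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.null(cache)) {
    key <- cache_key(child, parents)
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
  }
  n <- d$n
  y <- d$values[, child]
  X <- cbind(`(Intercept)` = 1, d$values[, parents, drop = FALSE])
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    stop(sprintf("degenerate model for %s: collinear parent set {%s}",
                 child, paste(parents, collapse = ", ")), call. = FALSE)
  }
  rss <- sum(qr.resid(qr_, y)^2)
  sigma2 <- rss / n
  vy <- sum((y - mean(y))^2) / n
  if (sigma2 < 1e-12 * vy) {
    stop(sprintf("degenerate model for %s: zero residual variance", child),
         call. = FALSE)
  }
  ll <- -(n / 2) * (log(2 * pi * sigma2) + 1)
  k <- length(parents) + 2
  s <- ll - (k / 2) * log(n)
  if (!is.null(cache)) assign(key, s, envir = cache)
  s
}

#' Total BIC score of a graph
#'
#' Sum over all nodes of the local score given the node's parents in `g`
#' (decomposability). Scoring errors are annotated with the offending node.
#'
#' @param d Dataset.
#' @param g A `gges_dag` whose nodes are columns of `d`.
#' @param cache Optional [score_cache()].
#' @return Numeric scalar.
#' @export
graph_score <- function(d, g, cache = NULL) {
  d <- as_gges_dataset(d)
  stopifnot(inherits(g, "gges_dag"))
  miss <- setdiff(g$nodes, d$variables)
  if (length(miss)) {
    stop("graph node(s) not in dataset: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  total <- 0
  for (v in g$nodes) {
    total <- total + tryCatch(
      local_score(d, v, dag_parents(g, v), cache),
      error = function(e) stop(sprintf("scoring node %s: %s", v,
                                       conditionMessage(e)), call. = FALSE))
  }
  total
}

#' Score change from inserting one edge
#'
#' Returns `graph_score(g + x->y) - graph_score(g)` using decomposability:
#' only the local term of `y` changes.
#'
#' @param d Dataset.
#' @param g Current `gges_dag`.
#' @param x,y Edge to insert (`x -> y` must be absent from `g`).
#' @param cache Optional [score_cache()].
#' @return Numeric scalar delta (positive = improvement).
#' @export
delta_insert <- function(d, g, x, y, cache = NULL) {
  stopifnot(inherits(g, "gges_dag"))
  if (g$amat[x, y]) stop("edge already present", call. = FALSE)
  pa <- dag_parents(g, y)
  local_score(d, y, c(pa, x), cache) - local_score(d, y, pa, cache)
}

# score change from deleting an existing edge x -> y
delta_delete <- function(d, g, x, y, cache = NULL) {
  stopifnot(inherits(g, "gges_dag"))
  if (!g$amat[x, y]) stop("edge not present", call. = FALSE)
  pa <- dag_parents(g, y)
  local_score(d, y, setdiff(pa, x), cache) - local_score(d, y, pa, cache)
}
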