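# Ground-truth generators: random role-constrained DAGs, linear-Gaussian
# SEM sampling, and a clinical-cohort emulator. The emulator reproduces the
# marginal structure of a lung-resection cohort (n = 363): age 68.3 +/-
# 9.45, BMI 27.8 +/- 5.98, 46.28% female, a ~0.67 recurrence rate, ordinal
# T/N stage codes, and CT-derived body-composition volumes/densities/masses
# driven by observed BMI (adiposity) and height (frame size). The full
# generating model is returned alongside the data so structure and effect
# recovery are checkable.

#' Random DAG honoring the outcome-group constraint
#'
#' Samples a DAG from a uniformly random topological order over the causal
#' nodes with independent Bernoulli(`edge_prob`) edges, plus
#' Bernoulli(`edge_prob`) edges from each causal node to each outcome node.
#' Outcome nodes always have out-degree 0.
#'
#' @param n_causal,n_outcome Numbers of causal (`x1..`) and outcome (`y1..`)
#'   nodes.
#' @param edge_prob Edge inclusion probability in `[0, 1]`.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A `gges_dag`.
#' @export
random_constrained_dag <- function(n_causal, n_outcome = 0L,
                                   edge_prob = 0.3, seed = 1L) {
  stopifnot(n_causal >= 1L, n_outcome >= 0L,
            edge_prob >= 0, edge_prob <= 1)
  causal <- paste0("x", seq_len(n_causal))
  outcome <- if (n_outcome > 0L) paste0("y", seq_len(n_outcome)) else character()
  nodes <- c(causal, outcome)
  with_seed(seed, {
    ord <- sample(causal)
    from <- character(); to <- character()
    if (n_causal >= 2L) {
      for (i in seq_len(n_causal - 1L)) {
        for (j in seq(i + 1L, n_causal)) {
          if (stats::runif(1) < edge_prob) {
            from <- c(from, ord[i]); to <- c(to, ord[j])
          }
        }
      }
    }
    for (x in causal) {
      for (y in outcome) {
        if (stats::runif(1) < edge_prob) {
          from <- c(from, x); to <- c(to, y)
        }
      }
    }
    dag(nodes, cbind(from = from, to = to))
  })
}

#' Sample data from a linear-Gaussian structural equation model
#'
#' Each node equals its intercept plus the weighted sum of its parents plus
#' independent Gaussian noise, evaluated in topological order.
#'
#' @param spec A [sem_spec()].
#' @param n Number of rows.
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return A `gges_dataset` with columns in the spec's node order.
#' @export
sample_linear_sem <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "gges_sem"), n >= 1L)
  nodes <- spec$dag$nodes
  p <- length(nodes)
  W <- weight_matrix(spec)
  eps <- with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  eps <- sweep(eps, 2L, spec$noise_sd, `*`)
  X <- matrix(0, n, p, dimnames = list(NULL, nodes))
  for (v in topo_order(spec$dag)) {
    pa <- nodes[spec$dag$amat[, v]]
    X[, v] <- spec$intercepts[[v]] + eps[, match(v, nodes)] +
      if (length(pa)) X[, pa, drop = FALSE] %*% W[pa, v] else 0
  }
  as_gges_dataset(X)
}

# deterministic topological order (ties broken by node order)
topo_order <- function(g) {
  amat <- g$amat
  nodes <- g$nodes
  alive <- rep(TRUE, length(nodes))
  out <- character()
  while (any(alive)) {
    indeg <- colSums(amat[alive, alive, drop = FALSE])
    nxt <- which(alive)[which(indeg == 0L)[1L]]
    if (is.na(nxt)) stop("graph is cyclic", call. = FALSE)
    out <- c(out, nodes[nxt])
    alive[nxt] <- FALSE
  }
  out
}

# --- clinical cohort emulator ------------------------------------------------

# internal: ordered node definitions; declaration order is topological
cohort_defs <- function(par) {
  list(
    age = list(type = "normal", mean = par$age_mean, sd = par$age_sd),
    sex = list(type = "bernoulli", p = par$p_female),
    race = list(type = "categorical", codes = 1:3,
                probs = c(0.8981, 0.0937, 0.0082)),
    smoke_hx_coded = list(type = "categorical", codes = 1:2,
                          probs = c(par$p_smoker, 1 - par$p_smoker)),
    histology = list(type = "categorical", codes = 1:3,
                     probs = c(0.60, 0.30, 0.10)),
    bmi = list(type = "normal", mean = par$bmi_mean, sd = par$bmi_sd),
    t_stage = list(type = "categorical", codes = 0:4,
                   probs = c(0.0165, 0.3802, 0.4325, 0.1295, 0.0413)),
    n_stage = list(type = "categorical", codes = 0:2,
                   probs = c(0.6942, 0.1873, 0.1185)),
    height = list(type = "linear", intercept = 176,
                  weights = c(sex = -12), sd = 8),
    weight = list(type = "linear", intercept = -160.6,
                  weights = c(bmi = 2.89, height = 0.945), sd = 2),
    volume_subcutaneous_fat = list(type = "linear", intercept = -4,
                                   weights = c(bmi = 0.30, sex = 1.5),
                                   sd = 1.2),
    volume_visceral_fat = list(type = "linear", intercept = -3,
                               weights = c(bmi = 0.25, sex = -1.2,
                                           age = 0.04), sd = 1.0),
    volume_muscle = list(type = "linear", intercept = 0,
                         weights = c(height = 0.12, sex = -3), sd = 1.0),
    volume_bone = list(type = "linear", intercept = -3,
                       weights = c(height = 0.06), sd = 0.5),
    density_muscle = list(type = "linear", intercept = 55,
                          weights = c(age = -0.2, bmi = -0.3), sd = 3),
    mass_subcutaneous_fat = list(type = "linear", intercept = 0.5,
                                 weights = c(volume_subcutaneous_fat = 0.9),
                                 sd = 0.3),
    mass_intermuscular_fat = list(type = "linear", intercept = -2,
                                  weights = c(volume_muscle = 0.15,
                                              bmi = 0.05), sd = 0.2),
    mass_bone = list(type = "linear", intercept = 0.5,
                     weights = c(volume_bone = 1.3), sd = 0.2),
    tnm_stage = list(type = "linear", intercept = 0,
                     weights = c(t_stage = 0.8, n_stage = 1.0), sd = 0.3),
    recur = list(type = "logistic", intercept = NA_real_,
                 weights = c(tnm_stage = 0.8, volume_visceral_fat = 0.3,
                             density_muscle = -0.1),
                 target_rate = par$recurrence_rate),
    rec_free_survival = list(type = "tobit", intercept = NA_real_,
                             weights = c(tnm_stage = -3, smoke_hx_coded = -3,
                                         height = 0.15,
                                         mass_intermuscular_fat = -2,
                                         t_stage = -2,
                                         volume_visceral_fat = -0.4),
                             sd = par$rfs_noise_sd,
                             latent_mean = par$rfs_latent_mean))
}

# sample all columns of `defs` up to (excluding) `stop_at`; RNG must
# already be set by the caller
cohort_engine <- function(defs, n, stop_at = NULL) {
  X <- matrix(0, n, 0L)
  for (v in names(defs)) {
    if (!is.null(stop_at) && v == stop_at) break
    def <- defs[[v]]
    col <- switch(def$type,
      normal = stats::rnorm(n, def$mean, def$sd),
      bernoulli = stats::rbinom(n, 1L, def$p),
      categorical = sample(def$codes, n, replace = TRUE, prob = def$probs),
      linear = def$intercept +
        X[, names(def$weights), drop = FALSE] %*% def$weights +
        stats::rnorm(n, 0, def$sd),
      logistic = stats::rbinom(n, 1L, stats::plogis(
        def$intercept +
          X[, names(def$weights), drop = FALSE] %*% def$weights)),
      tobit = pmax(0, def$intercept +
        X[, names(def$weights), drop = FALSE] %*% def$weights +
        stats::rnorm(n, 0, def$sd)),
      stop("unknown node type: ", def$type))
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- v
  }
  X
}

# analytic node means, propagated in declaration order; logistic nodes use
# their calibrated target rate, tobit nodes their latent mean
cohort_means <- function(defs) {
  m <- numeric()
  for (v in names(defs)) {
    def <- defs[[v]]
    m[[v]] <- switch(def$type,
      normal = def$mean,
      bernoulli = def$p,
      categorical = sum(def$codes * def$probs),
      linear = def$intercept + sum(def$weights * m[names(def$weights)]),
      logistic = def$target_rate,
      tobit = def$latent_mean)
  }
  m
}

#' Specify the synthetic clinical cohort
#'
#' Fixes the marginal parameters of the cohort emulator and calibrates the
#' two outcome equations: the recurrence logit intercept is solved once by
#' Monte Carlo (fixed internal seed, 20000 draws) so the population
#' recurrence rate equals `recurrence_rate`, and the recurrence-free
#' survival intercept is solved analytically from the propagated node means
#' so the latent (pre-truncation) mean equals `rfs_latent_mean`.
#'
#' @param n Cohort size (default 363).
#' @param seed Default seed used by [simulate_cohort()].
#' @param age_mean,age_sd,bmi_mean,bmi_sd Demographic marginals.
#' @param p_female Probability that `sex = 1`.
#' @param p_smoker Probability of smoking code 1 (current/prior smoker).
#' @param recurrence_rate Target population recurrence probability.
#' @param rfs_latent_mean,rfs_noise_sd Latent mean and noise SD of the
#'   censored-at-zero recurrence-free-survival equation (months). The
#'   defaults give an observed mean/SD close to 12.5/16 months.
#' @return An object of class `gges_cohort_spec`.
#' @export
cohort_spec <- function(n = 363L, seed = 1L,
                        age_mean = 68.3, age_sd = 9.45,
                        bmi_mean = 27.8, bmi_sd = 5.98,
                        p_female = 0.4628, p_smoker = 0.85,
                        recurrence_rate = 0.67,
                        rfs_latent_mean = 5.5, rfs_noise_sd = 23.5) {
  stopifnot(n >= 1L, age_sd > 0, bmi_sd > 0, rfs_noise_sd > 0,
            p_female > 0, p_female < 1, p_smoker > 0, p_smoker < 1,
            recurrence_rate > 0, recurrence_rate < 1)
  par <- list(age_mean = age_mean, age_sd = age_sd, bmi_mean = bmi_mean,
              bmi_sd = bmi_sd, p_female = p_female, p_smoker = p_smoker,
              recurrence_rate = recurrence_rate,
              rfs_latent_mean = rfs_latent_mean,
              rfs_noise_sd = rfs_noise_sd)
  defs <- cohort_defs(par)
  for (def in defs) {
    if (def$type %in% c("categorical")) {
      stopifnot(abs(sum(def$probs) - 1) < 1e-6, all(def$probs >= 0))
    }
  }
  # calibrate the recurrence intercept by Monte Carlo on the linear
  # predictor (internal fixed seed, independent of the simulation seed)
  w <- defs$recur$weights
  eta0 <- with_seed(104729L, {
    Xc <- cohort_engine(defs, 20000L, stop_at = "recur")
    drop(Xc[, names(w), drop = FALSE] %*% w)
  })
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta0)) -
                         recurrence_rate,
                       c(-60, 60), tol = 1e-10)$root
  defs$recur$intercept <- b0
  # recurrence-free survival intercept from propagated means
  m <- cohort_means(defs)
  wr <- defs$rec_free_survival$weights
  defs$rec_free_survival$intercept <-
    rfs_latent_mean - sum(wr * m[names(wr)])
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 parameters = par, defs = defs),
            class = "gges_cohort_spec")
}

#' @export
print.gges_cohort_spec <- function(x, ...) {
  cat(sprintf("gges_cohort_spec: n = %d, %d variables, seed %d\n",
              x$n, length(x$defs), x$seed))
  invisible(x)
}

# nominal node SD used in the exported ground-truth SEM record
cohort_noise_sd <- function(def) {
  switch(def$type,
    normal = def$sd,
    bernoulli = sqrt(def$p * (1 - def$p)),
    categorical = {
      mu <- sum(def$codes * def$probs)
      sqrt(sum(def$probs * (def$codes - mu)^2))
    },
    linear = def$sd,
    logistic = sqrt(def$target_rate * (1 - def$target_rate)),
    tobit = def$sd)
}

#' Simulate the synthetic clinical cohort
#'
#' Draws a cohort-like table from the generating model fixed by
#' [cohort_spec()] and returns it together with the exact generating
#' structure: the ground-truth DAG (outcomes are sinks), the edge
#' coefficients, and nominal noise scales. The recurrence node is binary
#' (logistic link on its linear predictor) and recurrence-free survival is
#' censored at zero; for those two nodes the recorded SEM coefficients are
#' the linear-predictor weights.
#'
#' @param spec A [cohort_spec()].
#' @param n Rows to draw (defaults to `spec$n`).
#' @param seed Seed (defaults to `spec$seed`).
#' @return List with `dataset` (a `gges_dataset`), `sem` (a [sem_spec()]
#'   recording the ground truth), `roles` (the matching
#'   [role_assignment()]), and `spec`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n = 363, seed = 7))
#' colMeans(cohort$dataset$values[, c("age", "bmi", "recur")])
#' @export
simulate_cohort <- function(spec = cohort_spec(), n = spec$n,
                            seed = spec$seed) {
  stopifnot(inherits(spec, "gges_cohort_spec"))
  X <- with_seed(seed, cohort_engine(spec$defs, n))
  from <- character(); to <- character(); wt <- numeric()
  for (v in names(spec$defs)) {
    w <- spec$defs[[v]]$weights
    if (!is.null(w)) {
      from <- c(from, names(w)); to <- c(to, rep(v, length(w)))
      wt <- c(wt, unname(w))
    }
  }
  g <- dag(names(spec$defs), cbind(from = from, to = to))
  sem <- sem_spec(
    g, data.frame(from = from, to = to, weight = wt),
    noise_sd = vapply(spec$defs, cohort_noise_sd, numeric(1L)),
    intercepts = vapply(spec$defs, function(d_)
      if (is.null(d_$intercept)) 0 else d_$intercept, numeric(1L)))
  list(dataset = as_gges_dataset(X), sem = sem,
       roles = cohort_roles(), spec = spec)
}

#' Role assignment of the synthetic cohort
#'
#' All cohort variables are causal except the two outcomes (`recur`,
#' `rec_free_survival`).
#'
#' @return A `gges_roles` object.
#' @export
cohort_roles <- function() {
  defs <- cohort_defs(list(age_mean = 0, age_sd = 1, bmi_mean = 0,
                           bmi_sd = 1, p_female = 0.5, p_smoker = 0.5,
                           recurrence_rate = 0.5, rfs_latent_mean = 0,
                           rfs_noise_sd = 1))
  role_assignment(names(defs),
                  outcome = c("recur", "rec_free_survival"))
}

#' Write a cohort specification to YAML
#'
#' Serializes the free marginal parameters plus `n` and `seed`, together
#' with the ground-truth edge list implied by them. The structural recipe
#' (which edges exist, their coefficients) is versioned in
#' `cohort_defs()`; the YAML records the tunable parameters and, for
#' reference, the resulting edges.
#'
#' @param spec A [cohort_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "gges_cohort_spec"))
  edges <- list()
  for (v in names(spec$defs)) {
    w <- spec$defs[[v]]$weights
    for (u in names(w)) {
      edges[[length(edges) + 1L]] <-
        list(from = u, to = v, weight = unname(w[[u]]))
    }
  }
  yaml::write_yaml(list(n = spec$n, seed = spec$seed,
                        parameters = spec$parameters,
                        ground_truth_edges = edges), path)
  invisible(path)
}

#' Read a cohort specification from YAML
#'
#' Rebuilds the specification (including intercept calibration) from the
#' parameters stored by [write_cohort_spec()].
#'
#' @param path YAML file path.
#' @return A `gges_cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(cohort_spec, c(list(n = y$n, seed = y$seed), y$parameters))
}

# --- categorical encoding ----------------------------------------------------

#' Default clinical codebook
#'
#' Integer coding for the cohort's string variables: race (white = 1,
#' African American/Black = 2, other = 3), smoking (current/prior = 1,
#' never = 2), histology (adenocarcinoma = 1, squamous cell carcinoma = 2,
#' other = 3). Matching is case-insensitive.
#'
#' @return Named list mapping column name to a named integer vector.
#' @export
default_codebook <- function() {
  list(
    race = c("white" = 1L, "african american" = 2L, "black" = 2L,
             "asian" = 3L, "other" = 3L),
    smoking = c("current" = 1L, "prior" = 1L, "current and prior" = 1L,
                "never" = 2L, "no smoking history" = 2L),
    histology = c("adenocarcinoma" = 1L, "squamous cell carcinoma" = 2L,
                  "squamous" = 2L, "other" = 3L))
}

#' Encode string variables with an integer codebook
#'
#' String columns are mapped through the codebook (case-insensitively,
#' after trimming); numeric columns pass through unchanged. Rows containing
#' missing values are dropped with a message.
#'
#' @param raw Data frame with numeric and/or character/factor columns.
#' @param codebook Named list mapping column names to named integer vectors
#'   (see [default_codebook()]).
#' @return A `gges_dataset` of the encoded complete cases.
#' @export
encode_variables <- function(raw, codebook = default_codebook()) {
  stopifnot(is.data.frame(raw))
  out <- raw
  for (col in names(out)) {
    if (is.factor(out[[col]])) out[[col]] <- as.character(out[[col]])
    if (is.character(out[[col]])) {
      if (!col %in% names(codebook)) {
        stop(sprintf("no codebook entry for string column '%s'", col),
             call. = FALSE)
      }
      map <- codebook[[col]]
      names(map) <- tolower(trimws(names(map)))
      key <- tolower(trimws(out[[col]]))
      hit <- map[key]
      unmapped <- !is.na(key) & is.na(hit)
      if (any(unmapped)) {
        stop(sprintf("column '%s': value '%s' not in codebook", col,
                     out[[col]][which(unmapped)[1L]]), call. = FALSE)
      }
      out[[col]] <- as.numeric(unname(hit))
    } else if (!is.numeric(out[[col]])) {
      stop(sprintf("column '%s' is neither numeric nor encodable", col),
           call. = FALSE)
    }
  }
  cc <- stats::complete.cases(out)
  if (any(!cc)) {
    message(sprintf("dropping %d row(s) with missing values", sum(!cc)))
    out <- out[cc, , drop = FALSE]
  }
  as_gges_dataset(out)
}
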