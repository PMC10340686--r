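# Variable role assignment: every variable is either a potential cause
# ("causal") or an outcome ("outcome"). Outcome variables may be influenced
# but can never influence anything, so they are sinks in every admissible
# graph.

#' Assign causal/outcome roles to variables
#'
#' @param variables Character vector of variable names (order preserved; it
#'   is the deterministic tie-break order everywhere).
#' @param outcome Character vector naming the outcome variables (a subset of
#'   `variables`); everything else is causal.
#' @param kind Optional character vector (recycled) in
#'   `c("continuous", "coded-categorical")` describing each variable.
#' @return A data frame of class `gges_roles` with columns `name`, `role`,
#'   `kind`.
#' @examples
#' role_assignment(c("age", "bmi", "recur"), outcome = "recur")
#' @export
role_assignment <- function(variables, outcome = character(),
                            kind = "continuous") {
  stopifnot(is.character(variables), length(variables) >= 1L)
  if (anyDuplicated(variables)) stop("duplicate variable names", call. = FALSE)
  missing_out <- setdiff(outcome, variables)
  if (length(missing_out)) {
    stop("outcome variable(s) not in variable list: ",
         paste(missing_out, collapse = ", "), call. = FALSE)
  }
  role <- ifelse(variables %in% outcome, "outcome", "causal")
  if (!any(role == "causal")) {
    stop("at least one causal variable is required", call. = FALSE)
  }
  kind <- rep_len(match.arg(kind, c("continuous", "coded-categorical"),
                            several.ok = TRUE), length(variables))
  structure(data.frame(name = variables, role = role, kind = kind,
                       stringsAsFactors = FALSE),
            class = c("gges_roles", "data.frame"))
}

# role ("causal"/"outcome") of each of `vars`, erroring on unknown names
role_of <- function(roles, vars) {
  idx <- match(vars, roles$name)
  if (anyNA(idx)) {
    stop("variable(s) missing from role assignment: ",
         paste(vars[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  roles$role[idx]
}

check_roles_cover <- function(roles, vars) {
  stopifnot(inherits(roles, "gges_roles"))
  invisible(role_of(roles, vars))
}

#' Is a directed edge admissible under the group constraint?
#'
#' An edge `x -> y` is admissible exactly when `x` is a causal variable:
#' causal variables may point at causal or outcome variables, while outcome
#' variables may not point at anything.
#'
#' @param x,y Variable names, `x != y`.
#' @param roles A [role_assignment()] containing both.
#' @return Logical scalar.
#' @export
allowed_edge <- function(x, y, roles) {
  stopifnot(x != y)
  r <- role_of(roles, c(x, y))
  r[1L] == "causal"
}

#' Read a role assignment from a YAML or JSON file
#'
#' The file maps variable names to `"causal"` or `"outcome"`. Variables
#' present in `variables` but absent from the file default to causal with a
#' warning.
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON file.
#' @param variables Full ordered variable list the assignment must cover.
#' @return A `gges_roles` object.
#' @export
read_roles <- function(path, variables) {
  if (!file.exists(path)) stop("roles file not found: ", path, call. = FALSE)
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  spec <- unlist(spec)
  bad <- setdiff(names(spec), variables)
  if (length(bad)) {
    stop("roles file names unknown variable(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  badrole <- setdiff(unique(spec), c("causal", "outcome"))
  if (length(badrole)) {
    stop("invalid role value(s): ", paste(badrole, collapse = ", "),
         call. = FALSE)
  }
  unlisted <- setdiff(variables, names(spec))
  if (length(unlisted)) {
    warning("variable(s) not in roles file default to causal: ",
            paste(unlisted, collapse = ", "), call. = FALSE)
  }
  role_assignment(variables,
                  outcome = names(spec)[spec == "outcome"])
}
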