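#' Specify a linear-Gaussian structural equation model
#'
#' Couples a causal graph with known standardized path coefficients, giving
#' a generator with analytically known behaviour for validating the fitting
#' machinery.
#'
#' @param model a [parse_model()] result (directed part used; correlated
#'   errors are ignored by the generator).
#' @param coefficients named numeric vector of path coefficients; names are
#'   `"from->to"` and must match the model's edges exactly (every edge needs
#'   a coefficient).
#' @param error_sd named numeric vector of residual SDs per endogenous node.
#'   `NULL` (default) chooses each residual SD so the node has unit variance
#'   given its parents' implied covariance — i.e. a fully standardized SEM.
#' @param exogenous optional named list of `c(mean, sd)` per exogenous node;
#'   default standard normal.
#' @return object of class `linear_sem_spec`.
#' @export
#' @examples
#' m <- parse_model("z ~ x\ny ~ z")
#' spec <- linear_sem_spec(m, c("x->z" = 0.5, "z->y" = 0.5))
#' head(sample_linear_sem(spec, n = 5, seed = 1))
linear_sem_spec <- function(model, coefficients, error_sd = NULL,
                            exogenous = NULL) {
  stopifnot(inherits(model, "causal_model"))
  edge_keys <- paste0(model$edges[, "from"], "->", model$edges[, "to"])
  extra <- setdiff(names(coefficients), edge_keys)
  if (length(extra)) stop("coefficients for non-edges: ",
                          paste(extra, collapse = ", "))
  missing_c <- setdiff(edge_keys, names(coefficients))
  if (length(missing_c)) stop("missing coefficient for edge(s): ",
                              paste(missing_c, collapse = ", "))
  endo <- setdiff(model$nodes, model$exogenous)
  if (!is.null(error_sd)) {
    if (!all(endo %in% names(error_sd))) {
      stop("error_sd must cover all endogenous nodes")
    }
    if (any(error_sd <= 0)) stop("error_sd must be strictly positive")
  }
  exo_par <- stats::setNames(
    rep(list(c(mean = 0, sd = 1)), length(model$exogenous)), model$exogenous)
  if (!is.null(exogenous)) {
    for (v in names(exogenous)) {
      if (!v %in% model$exogenous) stop("'", v, "' is not an exogenous node")
      exo_par[[v]] <- c(mean = exogenous[[v]][1], sd = exogenous[[v]][2])
      if (exo_par[[v]]["sd"] <= 0) stop("exogenous sd must be positive")
    }
  }
  spec <- structure(
    list(model = model, coefficients = coefficients, error_sd = error_sd,
         exogenous = exo_par),
    class = "linear_sem_spec"
  )
  if (is.null(error_sd)) {
    spec$error_sd <- standardized_error_sd(spec)
  }
  spec
}

# coefficient matrix B[from, to] of the spec
spec_B <- function(spec) {
  nodes <- spec$model$nodes
  B <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  e <- spec$model$edges
  for (i in seq_len(nrow(e))) {
    B[e[i, "from"], e[i, "to"]] <-
      spec$coefficients[paste0(e[i, "from"], "->", e[i, "to"])]
  }
  B
}

# residual SDs giving every endogenous node unit variance
standardized_error_sd <- function(spec) {
  Sigma <- implied_covariance(spec, unit_endogenous = TRUE)
  model <- spec$model
  endo <- setdiff(model$nodes, model$exogenous)
  B <- spec_B(spec)
  out <- numeric(0)
  for (y in endo) {
    pa <- parents(model, y)
    expl <- as.numeric(t(B[pa, y]) %*% Sigma[pa, pa] %*% B[pa, y])
    if (expl >= 1) {
      stop("explained variance of '", y, "' is ", signif(expl, 4),
           " >= 1: coefficients are not jointly standardizable")
    }
    out[y] <- sqrt(1 - expl)
  }
  out
}

#' Implied covariance of a linear SEM specification
#'
#' Propagates covariances through the graph in topological order. With
#' `unit_endogenous = TRUE` every endogenous node is taken to have unit
#' variance (the standardized convention); otherwise the spec's residual SDs
#' determine the variances.
#'
#' @param spec a [linear_sem_spec()].
#' @param unit_endogenous force unit endogenous variances (used when deriving
#'   standardizing residual SDs).
#' @return covariance matrix over the model nodes.
#' @export
implied_covariance <- function(spec, unit_endogenous = FALSE) {
  model <- spec$model
  nodes <- model$nodes
  B <- spec_B(spec)
  Sigma <- matrix(0, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
  for (v in model$order) {
    pa <- parents(model, v)
    if (!length(pa)) {
      Sigma[v, v] <- spec$exogenous[[v]]["sd"]^2
      next
    }
    b <- B[pa, v]
    # cov with previously generated nodes
    done <- model$order[seq_len(which(model$order == v) - 1)]
    Sigma[v, done] <- Sigma[done, v] <- as.numeric(Sigma[done, pa, drop = FALSE] %*% b)
    expl <- as.numeric(t(b) %*% Sigma[pa, pa] %*% b)
    Sigma[v, v] <- if (unit_endogenous) 1 else
      expl + spec$error_sd[v]^2
  }
  Sigma
}

#' Sample from a linear-Gaussian SEM
#'
#' Generates `n` rows by drawing exogenous nodes from their Gaussian
#' distributions and each endogenous node, in topological order, as the
#' linear combination of its parents plus Gaussian noise.
#'
#' @param spec a [linear_sem_spec()].
#' @param n number of rows (at least 3).
#' @param seed RNG seed; fixed seed gives bit-identical tables.
#' @return data.frame with one column per node.
#' @export
sample_linear_sem <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "linear_sem_spec"))
  if (n < 3) stop("n must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  model <- spec$model
  out <- as.data.frame(
    matrix(NA_real_, n, length(model$nodes),
           dimnames = list(NULL, model$nodes)))
  for (v in model$order) {
    pa <- parents(model, v)
    if (!length(pa)) {
      par <- spec$exogenous[[v]]
      out[[v]] <- stats::rnorm(n, par["mean"], par["sd"])
    } else {
      b <- spec$coefficients[paste0(pa, "->", v)]
      mu <- as.matrix(out[, pa, drop = FALSE]) %*% b
      out[[v]] <- as.numeric(mu) + stats::rnorm(n, 0, spec$error_sd[v])
    }
  }
  out
}
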