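#' Enumerate directed paths between two nodes
#'
#' All simple directed paths from `x` to `y` in the causal model, in
#' lexicographic order of their node sequences.
#'
#' @param model a [parse_model()] result.
#' @param x,y source and target node names.
#' @return list of character vectors, each a path `c(x, ..., y)`.
#' @export
enumerate_paths <- function(model, x, y) {
  stopifnot(inherits(model, "causal_model"))
  if (!all(c(x, y) %in% model$nodes)) stop("x and y must be model nodes")
  if (identical(x, y)) stop("x and y must differ")
  paths <- list()
  walk <- function(node, trail) {
    if (identical(node, y)) {
      paths[[length(paths) + 1]] <<- trail
      return(invisible())
    }
    for (k in sort(children(model, node))) {
      if (!(k %in% trail)) walk(k, c(trail, k))
    }
  }
  walk(x, x)
  paths
}

path_product <- function(B, path) {
  prod(B[cbind(path[-length(path)], path[-1])])
}

#' Direct, indirect and total effects between two nodes
#'
#' Standardized effect decomposition by path tracing: the direct effect is
#' the coefficient on the edge `x -> y` (zero if absent); each indirect path
#' contributes the product of its edge coefficients; the indirect effect is
#' the sum over paths of length two or more; the total effect is their sum.
#'
#' @param fitted a [fit_sem()] result (or a list with elements `model` and a
#'   coefficient matrix `B`).
#' @param x,y source and target node names.
#' @return list: `direct`, `indirect`, `total`, `paths` (data.frame of path
#'   strings and their products).
#' @export
path_effects <- function(fitted, x, y) {
  B <- if (is.matrix(fitted)) fitted else coef_matrix(fitted)
  model <- if (is.matrix(fitted)) attr(fitted, "model") else fitted$model
  if (!all(c(x, y) %in% rownames(B))) stop("node not in model: ",
                                           paste(setdiff(c(x, y), rownames(B)),
                                                 collapse = ", "))
  paths <- enumerate_paths(model, x, y)
  eff <- vapply(paths, function(p) path_product(B, p), numeric(1))
  len <- vapply(paths, length, integer(1))
  direct <- if (any(len == 2)) sum(eff[len == 2]) else 0
  indirect <- if (any(len > 2)) sum(eff[len > 2]) else 0
  list(direct = direct, indirect = indirect, total = direct + indirect,
       paths = data.frame(
         path = vapply(paths, paste, character(1), collapse = "->"),
         effect = eff, stringsAsFactors = FALSE))
}

#' Mediator-specific effect
#'
#' The summed product of coefficients over every directed path from `x` to
#' `y` whose node sequence passes through the mediator `z`. This is the
#' effect of a land-use mediator on a stability driver in the sense of the
#' bar plots accompanying each SEM: how much of the influence of `x` on `y`
#' travels through `z`.
#'
#' @param fitted a [fit_sem()] result.
#' @param x,y source and target nodes.
#' @param mediator intermediate node (distinct from both).
#' @return scalar.
#' @export
mediator_effect <- function(fitted, x, y, mediator) {
  B <- coef_matrix(fitted)
  model <- fitted$model
  if (!mediator %in% model$nodes) stop("mediator not a model node: ", mediator)
  if (mediator %in% c(x, y)) stop("mediator must differ from x and y")
  paths <- enumerate_paths(model, x, y)
  through <- vapply(paths, function(p) mediator %in% p, logical(1))
  if (!any(through)) return(0)
  sum(vapply(paths[through], function(p) path_product(B, p), numeric(1)))
}

#' Total-effect matrix in closed form
#'
#' For a linear SEM with coefficient matrix `B` (`B[from, to]`), the matrix
#' of total effects is `(I - B)^-1 - I`; its `[x, y]` entry equals the sum
#' over all directed paths from `x` to `y` of the path products. Used as an
#' algebraic cross-check of [path_effects()].
#'
#' @param B square coefficient matrix with `B[from, to]` convention.
#' @return matrix of total effects.
#' @export
total_effect_matrix <- function(B) {
  I <- diag(nrow(B))
  out <- solve(I - B) - I
  dimnames(out) <- dimnames(B)
  out
}

#' Bootstrap confidence intervals for SEM effects
#'
#' Nonparametric bootstrap of standardized effects: rows are resampled with
#' replacement; each replicate is re-standardized and every structural
#' equation refitted with the (fixed, already selected) model structure;
#' the queried effects are recomputed per replicate. Point estimates come
#' from the full-data fit; intervals are bias-corrected percentile intervals
#' by default. Term selection is never repeated inside replicates.
#'
#' @param model a [parse_model()] result (the final structure).
#' @param data raw (unstandardized) data.
#' @param queries list of effect queries, each a list with `source`,
#'   `target`, `type` in `c("direct", "indirect", "total", "mediator")` and,
#'   for mediator queries, `mediator`.
#' @param n_boot number of bootstrap replicates (at least 200).
#' @param seed RNG seed (integer) for reproducibility.
#' @param ci_level confidence level (default 0.95).
#' @param interval `"bc"` bias-corrected percentile (default) or
#'   `"percentile"`.
#' @return data.frame of class `effect_estimates`: one row per query with
#'   `source`, `target`, `type`, `mediator`, `estimate`, `lower`, `upper`,
#'   `level`, `n_boot`, `n_failed`, `significant`.
#' @export
bootstrap_effects <- function(model, data, queries, n_boot = 2000, seed = 1,
                              ci_level = 0.95,
                              interval = c("bc", "percentile")) {
  interval <- match.arg(interval)
  if (n_boot < 200) stop("n_boot must be at least 200")
  stopifnot(inherits(model, "causal_model"))
  d0 <- as.data.frame(data)[, model$nodes, drop = FALSE]
  d0 <- d0[stats::complete.cases(d0), , drop = FALSE]

  # paths are fixed by the structure; only coefficients change per replicate
  qpaths <- lapply(queries, function(q) {
    if (!q$type %in% c("direct", "indirect", "total", "mediator")) {
      stop("unknown effect type: ", q$type)
    }
    if (q$type == "mediator") {
      if (is.null(q$mediator) || !q$mediator %in% model$nodes) {
        stop("mediator query needs a valid `mediator` node")
      }
      if (q$mediator %in% c(q$source, q$target)) {
        stop("mediator must differ from source and target")
      }
    }
    paths <- enumerate_paths(model, q$source, q$target)
    len <- vapply(paths, length, integer(1))
    keep <- switch(q$type,
      direct = len == 2,
      indirect = len > 2,
      total = rep(TRUE, length(paths)),
      mediator = vapply(paths, function(p) q$mediator %in% p, logical(1)))
    paths[keep]
  })
  eval_queries <- function(B) {
    vapply(qpaths, function(ps) {
      if (!length(ps)) return(0)
      sum(vapply(ps, function(p) path_product(B, p), numeric(1)))
    }, numeric(1))
  }
  # matrix fast path: per replicate, re-standardize and solve each equation
  # by least squares on the resampled rows
  nodes <- model$nodes
  M0 <- as.matrix(d0)
  eqs <- lapply(nodes, function(v) parents(model, v))
  names(eqs) <- nodes
  eqs <- eqs[vapply(eqs, length, integer(1)) > 0]
  boot_B <- function(M) {
    Z <- scale(M)
    if (any(attr(Z, "scaled:scale") == 0)) stop("constant column in replicate")
    B <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    for (y in names(eqs)) {
      pa <- eqs[[y]]
      X <- cbind(1, Z[, pa, drop = FALSE])
      cf <- stats::lm.fit(X, Z[, y])
      if (cf$rank < ncol(X)) stop("rank-deficient replicate for '", y, "'")
      B[pa, y] <- cf$coefficients[-1]
    }
    B
  }
  est <- eval_queries(boot_B(M0))

  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, length(queries))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(M0), replace = TRUE)
    B <- tryCatch(boot_B(M0[idx, , drop = FALSE]), error = function(e) NULL)
    if (is.null(B)) { n_failed <- n_failed + 1L; next }
    reps[b, ] <- eval_queries(B)
  }
  if (n_failed > 0.1 * n_boot) {
    stop("more than 10% of bootstrap replicates failed (", n_failed, "/",
         n_boot, ")")
  }
  alpha <- 1 - ci_level
  ci <- t(vapply(seq_along(queries), function(j) {
    th <- reps[, j]
    th <- th[!is.na(th)]
    if (interval == "bc") {
      prop <- mean(th < est[j]) + 0.5 * mean(th == est[j])
      prop <- min(max(prop, 1 / (length(th) + 1)), length(th) / (length(th) + 1))
      z0 <- stats::qnorm(prop)
      lo <- stats::pnorm(2 * z0 + stats::qnorm(alpha / 2))
      hi <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha / 2))
      stats::quantile(th, c(lo, hi), names = FALSE, type = 6)
    } else {
      stats::quantile(th, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 6)
    }
  }, numeric(2)))

  out <- data.frame(
    source = vapply(queries, `[[`, character(1), "source"),
    target = vapply(queries, `[[`, character(1), "target"),
    type = vapply(queries, `[[`, character(1), "type"),
    mediator = vapply(queries, function(q)
      if (is.null(q$mediator)) NA_character_ else q$mediator, character(1)),
    estimate = est, lower = ci[, 1], upper = ci[, 2],
    level = ci_level, n_boot = n_boot, n_failed = n_failed,
    significant = ci[, 1] > 0 | ci[, 2] < 0,
    stringsAsFactors = FALSE
  )
  class(out) <- c("effect_estimates", class(out))
  out
}
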