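#' Standardise a data table to zero mean, unit SD
#'
#' Mean-centres and scales every column to sample SD one, so that regression
#' slopes fitted downstream are directly comparable standardized effects.
#' The scaling record allows back-transformation.
#'
#' @param data data.frame of numeric columns.
#' @return list: `data` (standardized data.frame), `center`, `scale`
#'   (named vectors).
#' @export
standardize <- function(data) {
  data <- as.data.frame(data)
  num <- vapply(data, is.numeric, logical(1))
  if (!all(num)) stop("non-numeric columns: ",
                      paste(names(data)[!num], collapse = ", "))
  ctr <- vapply(data, mean, numeric(1))
  scl <- vapply(data, stats::sd, numeric(1))
  if (any(scl == 0)) {
    stop("constant columns cannot be standardized: ",
         paste(names(data)[scl == 0], collapse = ", "))
  }
  z <- as.data.frame(mapply(function(x, m, s) (x - m) / s, data, ctr, scl,
                            SIMPLIFY = FALSE))
  list(data = z, center = ctr, scale = scl)
}

# Fast OLS on a prebuilt design matrix (intercept in column 1).
# Returns the pieces every caller needs; avoids lm()'s formula overhead in
# the Monte-Carlo-heavy paths (all-subsets selection, bootstrap).
ols <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  n <- length(y)
  p <- fit$rank
  if (p < ncol(X)) {
    bad <- colnames(X)[fit$qr$pivot[seq(p + 1, ncol(X))]]
    stop("rank-deficient design: collinear term(s) ",
         paste(bad, collapse = ", "))
  }
  r <- fit$residuals
  rss <- sum(r^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(fit$qr))
  piv <- fit$qr$pivot
  se <- numeric(p)
  se[piv] <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(X)
  est <- fit$coefficients
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  tss <- sum((y - mean(y))^2)
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  list(estimate = est, se = se, t = tval, p = pval,
       r2 = 1 - rss / tss, residuals = r, fitted = fit$fitted.values,
       rss = rss, n = n, rank = p,
       aic = -2 * loglik + 2 * (p + 1))  # +1: residual variance
}

design_matrix <- function(data, terms) {
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, terms, drop = FALSE]))
  X
}

#' Fit the local linear models of a piecewise SEM
#'
#' One ordinary least-squares regression per endogenous node, of the node on
#' its parents in the causal model. On standardized data the slopes are
#' standardized path coefficients.
#'
#' @param model a [parse_model()] result.
#' @param data data.frame (typically standardized) containing every model node.
#' @return list: `equations` (per endogenous node: `coefficients` data.frame
#'   with term/estimate/se/t/p, `r2`, `residuals`, `fit` the `lm` object),
#'   `n` rows used, `n_dropped` incomplete rows removed.
#' @export
fit_local <- function(model, data) {
  stopifnot(inherits(model, "causal_model"))
  miss <- setdiff(model$nodes, names(data))
  if (length(miss)) stop("data lacks model variables: ",
                         paste(miss, collapse = ", "))
  d <- data[, model$nodes, drop = FALSE]
  cc <- stats::complete.cases(d)
  n_dropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  responses <- model$order[vapply(model$order,
                                  function(v) length(parents(model, v)) > 0,
                                  logical(1))]
  max_par <- if (length(responses)) {
    max(vapply(responses, function(v) length(parents(model, v)), numeric(1)))
  } else 0
  if (nrow(d) <= max_par + 2) {
    stop("too few complete rows (", nrow(d), ") for the largest equation")
  }
  equations <- list()
  for (y in responses) {
    pa <- parents(model, y)
    fit <- tryCatch(ols(d[[y]], design_matrix(d, pa)), error = function(e) {
      stop("equation for '", y, "': ", conditionMessage(e), call. = FALSE)
    })
    if (fit$rss < 1e-12) {
      warning("zero residual variance in equation for '", y, "'")
    }
    coefs <- data.frame(
      response = y,
      term = names(fit$estimate),
      estimate = unname(fit$estimate),
      se = unname(fit$se),
      t = unname(fit$t),
      p = unname(fit$p),
      row.names = NULL, stringsAsFactors = FALSE
    )
    equations[[y]] <- list(coefficients = coefs, r2 = fit$r2,
                           residuals = fit$residuals, terms = pa)
  }
  list(equations = equations, n = nrow(d), n_dropped = n_dropped, data = d)
}

#' Directed-separation tests for a basis set
#'
#' Tests each independence claim by regressing the claim's response on its
#' conditioning set plus the other member of the pair; the claim's p-value is
#' the two-sided t-test of that member's partial slope.
#'
#' @param claims output of [basis_set()].
#' @param data data.frame with all involved variables (standardized or not;
#'   p-values are invariant to linear scaling).
#' @return data.frame: `response`, `other`, `conditioning`, `estimate`, `p`.
#' @export
dsep_tests <- function(claims, data) {
  if (!length(claims)) {
    return(data.frame(response = character(0), other = character(0),
                      conditioning = character(0), estimate = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE))
  }
  out <- lapply(claims, function(cl) {
    rhs <- c(cl$conditioning, cl$other)
    fit <- ols(data[[cl$response]], design_matrix(data, rhs))
    est <- fit$estimate[[cl$other]]
    p <- fit$p[[cl$other]]
    if (p <= 0) {  # guard against underflow before Fisher's C
      p <- .Machine$double.xmin
    }
    data.frame(response = cl$response, other = cl$other,
               conditioning = paste(cl$conditioning, collapse = "+"),
               estimate = est, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fisher's C statistic and global goodness-of-fit p-value
#'
#' Combines the basis-set p-values into `C = -2 * sum(log p_i)`, chi-square
#' distributed with `2k` degrees of freedom when the causal model is correct.
#' A global p-value above 0.05 indicates the data are consistent with the
#' hypothesised structure. An empty basis set (saturated model) returns
#' `C = 0`, `df = 0`, `p = 1`.
#'
#' @param p_values numeric vector of claim p-values, each in (0, 1].
#' @return list: `C`, `df`, `p_value`, `k`.
#' @export
#' @examples
#' fishers_c(c(0.5, 0.12, 0.9))
fishers_c <- function(p_values) {
  if (length(p_values) == 0) {
    return(list(C = 0, df = 0L, p_value = 1, k = 0L, saturated = TRUE))
  }
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("claim p-values must lie in (0, 1]")
  }
  C <- -2 * sum(log(p_values))
  k <- length(p_values)
  df <- 2L * k
  list(C = C, df = df,
       p_value = stats::pchisq(C, df = df, lower.tail = FALSE),
       k = k, saturated = FALSE)
}

#' Convert a Fisher's C statistic to its global p-value
#'
#' The analytic chi-square conversion: the upper-tail probability of a
#' chi-square variate with `df` degrees of freedom at `C`. Useful for
#' recomputing the global goodness-of-fit probability from a reported
#' (C, df) pair.
#'
#' @param C Fisher's C statistic (nonnegative).
#' @param df degrees of freedom (twice the number of claims; even).
#' @return p-value in `[0, 1]`; vectorised over `C` and `df`.
#' @export
#' @examples
#' fisher_c_pvalue(32.064, 26)
fisher_c_pvalue <- function(C, df) {
  if (any(C < 0) || any(df < 0)) stop("C and df must be nonnegative")
  ifelse(df == 0, 1, stats::pchisq(C, df = df, lower.tail = FALSE))
}

#' Whole-model AICc for a fitted piecewise SEM
#'
#' Information criterion on the Fisher's C scale: `AIC = C + 2K` and
#' `AICc = C + 2K * n / (n - K - 1)`, where `K` counts every estimated
#' parameter across the local models (one slope per edge, one intercept and
#' one residual variance per equation) plus one per correlated-error pair.
#'
#' @param C Fisher's C statistic.
#' @param K total number of estimated parameters.
#' @param n number of rows the model was fitted on.
#' @return list: `AIC`, `AICc`, `K`, `n`.
#' @export
sem_aicc <- function(C, K, n) {
  if (n <= K + 1) stop("n must exceed K + 1 for AICc (n = ", n, ", K = ", K, ")")
  list(AIC = C + 2 * K, AICc = C + 2 * K * n / (n - K - 1), K = K, n = n)
}

count_parameters <- function(model) {
  n_edges <- nrow(model$edges)
  n_eq <- length(unique(model$edges[, "to"]))
  # slopes + intercept & residual variance per equation + covariances
  n_edges + 2 * n_eq + nrow(model$correlated_errors)
}

#' All-subsets term selection with the evidence-ratio rule
#'
#' Fits every submodel (all `2^p` subsets of the candidate terms, intercept
#' always included) by OLS, scores each with the per-equation small-sample
#' AICc, converts to Akaike weights, and sums the weights of the submodels
#' containing each term. A term's evidence ratio is the odds of that summed
#' weight, `ER = s / (1 - s)`; terms with `ER` above the threshold
#' (default 2.72, roughly e, "a likely effect") are retained.
#'
#' @param response name of the response variable.
#' @param terms character vector of candidate predictor terms (at most 20).
#' @param data data.frame containing response and terms.
#' @param threshold evidence-ratio retention threshold (default 2.72).
#' @return list of class `selection_table`: `terms` (data.frame with
#'   `term`, `sum_weight`, `evidence_ratio`, `retained`), `submodels`
#'   (data.frame with `terms`, `K`, `aicc`, `delta`, `weight`), `retained`
#'   (character vector), `response`, `threshold`.
#' @export
select_terms <- function(response, terms, data, threshold = 2.72) {
  p <- length(terms)
  if (p > 20) stop("more than 20 candidate terms (2^p submodels): reduce manually")
  if (p < 1) stop("no candidate terms")
  cc <- stats::complete.cases(data[, c(response, terms), drop = FALSE])
  d <- data[cc, , drop = FALSE]
  n <- nrow(d)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  m <- nrow(subsets)
  aicc <- numeric(m)
  labels <- character(m)
  Xfull <- design_matrix(d, terms)
  yv <- d[[response]]
  for (i in seq_len(m)) {
    inc <- terms[subsets[i, ]]
    fit <- ols(yv, Xfull[, c(TRUE, subsets[i, ]), drop = FALSE])
    K <- length(inc) + 2  # slopes + intercept + residual variance
    aicc[i] <- fit$aic + 2 * K * (K + 1) / (n - K - 1)
    labels[i] <- if (length(inc)) paste(inc, collapse = "+") else "(intercept)"
  }
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  s <- vapply(seq_len(p), function(j) sum(w[unlist(subsets[, j])]), numeric(1))
  er <- s / (1 - s)
  tab <- data.frame(term = terms, sum_weight = s, evidence_ratio = er,
                    retained = er > threshold, stringsAsFactors = FALSE)
  structure(
    list(terms = tab,
         submodels = data.frame(terms = labels,
                                K = rowSums(subsets) + 2,
                                aicc = aicc, delta = delta, weight = w,
                                stringsAsFactors = FALSE),
         retained = terms[er > threshold],
         response = response, threshold = threshold, n = n),
    class = "selection_table"
  )
}

#' @export
print.selection_table <- function(x, ...) {
  cat("<selection_table> response:", x$response, "- retained:",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)",
      "\n")
  print(x$terms, row.names = FALSE)
  invisible(x)
}

# rebuild a causal_model from explicit parts (used when reducing)
causal_model_from_parts <- function(nodes, edges, correlated_errors) {
  ord <- topological_order(nodes, edges)
  exo <- setdiff(nodes, unique(edges[, "to"]))
  structure(
    list(nodes = nodes, edges = edges, correlated_errors = correlated_errors,
         exogenous = exo, order = ord),
    class = "causal_model"
  )
}

#' Fit a piecewise structural equation model
#'
#' The full piecewise-SEM workflow: standardize the data, optionally reduce
#' each structural equation by all-subsets selection ([select_terms()]), fit
#' the local OLS models, enumerate and test the basis set of independence
#' claims, combine them into Fisher's C, and compute the whole-model AICc.
#' Declared correlated-error pairs are quantified as the Pearson correlation
#' of the two variables' equation residuals (an exogenous member enters as
#' its raw values), with a t-test p-value; such pairs are never tested as
#' independence claims.
#'
#' Independence claims rejected at the 0.05 level are listed in
#' `missing_paths` as candidate omitted links; they are reported, never
#' auto-added — whether a suggested path is causal is a modelling decision.
#'
#' @param model a [parse_model()] result.
#' @param data data.frame with one row per plot and one column per node.
#' @param reduce if `TRUE`, run term selection per equation and fit the
#'   reduced structure (the a-priori fit is returned alongside).
#' @param er_threshold evidence-ratio threshold passed to [select_terms()].
#' @param standardize_data standardize before fitting (default `TRUE`).
#' @param diagnostics if `TRUE`, run residual-normality (Shapiro-Wilk),
#'   heteroscedasticity (Breusch-Pagan, if \pkg{lmtest} is installed) and
#'   multicollinearity (VIF, if \pkg{car} is installed) checks and report
#'   failures as warnings; the fit is never gated on them.
#' @return object of class `fitted_sem`: `model`, `coefficients` (long
#'   data.frame over equations), `r2` (named), `basis` (claims with
#'   p-values), `C`, `df`, `p_value`, `saturated`, `AIC`, `AICc`, `K`, `n`,
#'   `correlated_errors` (data.frame with partial r and p), `missing_paths`,
#'   `scaling`, and when `reduce = TRUE`: `selection` (per-equation
#'   [select_terms()] tables), `apriori` (the unreduced `fitted_sem`).
#' @export
fit_sem <- function(model, data, reduce = FALSE, er_threshold = 2.72,
                    standardize_data = TRUE, diagnostics = FALSE) {
  stopifnot(inherits(model, "causal_model"))
  d0 <- as.data.frame(data)[, model$nodes, drop = FALSE]
  cc <- stats::complete.cases(d0)
  d0 <- d0[cc, , drop = FALSE]
  scaling <- NULL
  if (standardize_data) {
    std <- standardize(d0)
    d <- std$data
    scaling <- std[c("center", "scale")]
  } else {
    d <- d0
  }

  selection <- NULL
  apriori <- NULL
  if (reduce) {
    apriori <- fit_sem(model, d, reduce = FALSE, standardize_data = FALSE,
                       diagnostics = FALSE)
    apriori$scaling <- scaling
    selection <- list()
    keep <- matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to")))
    for (y in model$order) {
      pa <- parents(model, y)
      if (!length(pa)) next
      sel <- select_terms(y, pa, d, threshold = er_threshold)
      selection[[y]] <- sel
      if (length(sel$retained)) {
        keep <- rbind(keep, cbind(from = sel$retained, to = y))
      }
    }
    model <- causal_model_from_parts(model$nodes, keep, model$correlated_errors)
  }

  lf <- fit_local(model, d)
  claims <- basis_set(model)
  bs <- dsep_tests(claims, lf$data)
  fc <- fishers_c(bs$p)
  K <- count_parameters(model)
  ic <- sem_aicc(fc$C, K, lf$n)

  ce <- correlated_error_estimates(model, lf)
  coefs <- do.call(rbind, c(lapply(lf$equations, `[[`, "coefficients"),
                            list(make.row.names = FALSE)))
  r2 <- vapply(lf$equations, `[[`, numeric(1), "r2")
  missing_paths <- bs[bs$p < 0.05, , drop = FALSE]

  if (diagnostics) run_diagnostics(lf)

  structure(
    list(model = model, coefficients = coefs, r2 = r2, basis = bs,
         C = fc$C, df = fc$df, p_value = fc$p_value, saturated = fc$saturated,
         AIC = ic$AIC, AICc = ic$AICc, K = K, n = lf$n,
         n_dropped = sum(!cc) + lf$n_dropped,
         correlated_errors = ce, missing_paths = missing_paths,
         scaling = scaling, selection = selection, apriori = apriori,
         equations = lf$equations),
    class = "fitted_sem"
  )
}

correlated_error_estimates <- function(model, lf) {
  ce <- model$correlated_errors
  if (!nrow(ce)) {
    return(data.frame(a = character(0), b = character(0), r = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE))
  }
  resid_of <- function(v) {
    if (v %in% names(lf$equations)) lf$equations[[v]]$residuals
    else lf$data[[v]]  # exogenous or parentless: raw variable
  }
  out <- apply(ce, 1, function(pr) {
    ra <- resid_of(pr[1]); rb <- resid_of(pr[2])
    r <- stats::cor(ra, rb)
    n <- length(ra)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    data.frame(a = pr[1], b = pr[2], r = r,
               p = 2 * stats::pt(-abs(tstat), df = n - 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Koenker/studentized-free Breusch-Pagan: LM = n * R^2 of the auxiliary
# regression of squared residuals on the equation's predictors.
breusch_pagan <- function(residuals, data, terms) {
  u <- residuals^2
  aux <- ols(u, design_matrix(data, terms))
  lm_stat <- length(u) * aux$r2
  stats::pchisq(lm_stat, df = length(terms), lower.tail = FALSE)
}

# classical VIF: 1 / (1 - R^2) of each predictor on the remaining ones
vif_values <- function(data, terms) {
  vapply(terms, function(tj) {
    r2 <- ols(data[[tj]], design_matrix(data, setdiff(terms, tj)))$r2
    1 / (1 - r2)
  }, numeric(1))
}

run_diagnostics <- function(lf) {
  for (y in names(lf$equations)) {
    eq <- lf$equations[[y]]
    res <- eq$residuals
    if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 0) {
      swp <- stats::shapiro.test(res)$p.value
      if (swp < 0.05) warning("equation '", y,
                              "': residuals deviate from normality (Shapiro-Wilk p = ",
                              signif(swp, 3), ")", call. = FALSE)
      bpp <- breusch_pagan(res, lf$data, eq$terms)
      if (bpp < 0.05) warning("equation '", y,
                              "': heteroscedastic residuals (Breusch-Pagan p = ",
                              signif(bpp, 3), ")", call. = FALSE)
    }
    if (length(eq$terms) > 1) {
      v <- vif_values(lf$data, eq$terms)
      if (any(v > 5)) {
        warning("equation '", y, "': high variance inflation (max VIF = ",
                signif(max(v), 3), ")", call. = FALSE)
      }
    }
  }
}

#' @export
print.fitted_sem <- function(x, ...) {
  cat("<fitted_sem>", length(x$model$nodes), "nodes,", nrow(x$model$edges),
      "edges, n =", x$n, "\n")
  if (x$saturated) {
    cat("  saturated model (empty basis set)\n")
  } else {
    cat(sprintf("  Fisher's C = %.3f, df = %d, P = %.3f\n",
                x$C, x$df, x$p_value))
  }
  cat(sprintf("  AICc = %.2f (K = %d)\n", x$AICc, x$K))
  invisible(x)
}

#' Extract the standardized path-coefficient matrix
#'
#' @param fitted a [fit_sem()] result.
#' @return square matrix `B` over model nodes with `B[from, to]` the
#'   standardized coefficient of `from` in `to`'s equation (0 where no edge).
#' @export
coef_matrix <- function(fitted) {
  stopifnot(inherits(fitted, "fitted_sem"))
  nodes <- fitted$model$nodes
  B <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  cf <- fitted$coefficients
  cf <- cf[cf$term != "(Intercept)", , drop = FALSE]
  for (i in seq_len(nrow(cf))) {
    B[cf$term[i], cf$response[i]] <- cf$estimate[i]
  }
  B
}
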