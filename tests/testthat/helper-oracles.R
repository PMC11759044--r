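# Literal-formula reference implementations, written as plain double loops so
# they stay independent of the vectorised package code they check.

oracle_stability <- function(A) {
  tot <- numeric(ncol(A))
  for (t in seq_len(ncol(A))) {
    s <- 0
    for (i in seq_len(nrow(A))) s <- s + A[i, t]
    tot[t] <- s
  }
  m <- sum(tot) / length(tot)
  v <- 0
  for (t in seq_along(tot)) v <- v + (tot[t] - m)^2
  m / sqrt(v / (length(tot) - 1))
}

oracle_mean_richness <- function(A) {
  acc <- 0
  for (t in seq_len(ncol(A))) {
    for (i in seq_len(nrow(A))) if (A[i, t] > 0) acc <- acc + 1
  }
  acc / ncol(A)
}

oracle_mean_total_abundance <- function(A) {
  sum(A) / ncol(A)
}

oracle_eta_w <- function(A) {
  pres <- which(apply(A, 1, function(x) any(x > 0)))
  A <- A[pres, , drop = FALSE]
  tot <- colSums(A)
  r <- w <- rep(NA_real_, nrow(A))
  for (i in seq_len(nrow(A))) {
    rest <- tot - A[i, ]
    if (sd(A[i, ]) > 0 && sd(rest) > 0) {
      r[i] <- cor(A[i, ], rest)
      w[i] <- sum(A[i, ])
    }
  }
  ok <- !is.na(r)
  sum((w[ok] / sum(w[ok])) * r[ok])
}

oracle_wapv <- function(A) {
  pres <- which(apply(A, 1, function(x) any(x > 0)))
  A <- A[pres, , drop = FALSE]
  tot <- colSums(A)
  out <- 0
  for (i in seq_len(nrow(A))) {
    mu <- mean(A[i, ])
    if (mu <= 0) next
    cv <- sd(A[i, ]) / mu
    shares <- A[i, tot > 0] / tot[tot > 0]
    out <- out + mean(shares) * cv
  }
  out
}

oracle_pool <- function(A) {
  pres <- which(apply(A, 1, function(x) any(x > 0)))
  A <- A[pres, , drop = FALSE]
  tot <- colSums(A)
  p <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    p[i] <- mean(A[i, tot > 0] / tot[tot > 0])
  }
  p / sum(p)
}

oracle_rao <- function(p, D) {
  q <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) q <- q + p[i] * p[j] * D[i, j]
  }
  q
}

oracle_cwm <- function(p, tr) {
  s <- 0
  for (i in seq_along(p)) s <- s + p[i] * tr[i]
  s
}

# random community matrix: lognormal abundances, some structural zeros
random_community <- function(S, T, zero_prob = 0.15) {
  A <- matrix(rlnorm(S * T, meanlog = 1, sdlog = 0.8), S, T)
  A[runif(S * T) < zero_prob] <- 0
  rownames(A) <- paste0("sp", seq_len(S))
  colnames(A) <- 2000 + seq_len(T)
  A
}

# random DAG over n nodes (edges respect the ordering v1 < v2 < ...)
random_dag <- function(n_nodes, p_edge = 0.4) {
  nodes <- paste0("v", seq_len(n_nodes))
  edges <- matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to")))
  for (i in seq_len(n_nodes - 1)) {
    for (j in seq(i + 1, n_nodes)) {
      if (runif(1) < p_edge) {
        edges <- rbind(edges, c(nodes[i], nodes[j]))
      }
    }
  }
  lines <- character(0)
  for (v in nodes) {
    pa <- edges[edges[, "to"] == v, "from"]
    if (length(pa)) lines <- c(lines, paste(v, "~", paste(pa, collapse = " + ")))
  }
  if (!length(lines)) lines <- paste(nodes[2], "~", nodes[1])
  parse_model(paste(lines, collapse = "\n"))
}

# random standardized linear SEM spec on a DAG (coefficients shrunk until
# every endogenous node is standardizable)
random_spec <- function(model, max_coef = 0.6) {
  keys <- paste0(model$edges[, "from"], "->", model$edges[, "to"])
  beta <- runif(length(keys), 0.1, max_coef) * sample(c(-1, 1), length(keys),
                                                     replace = TRUE)
  names(beta) <- keys
  repeat {
    spec <- tryCatch(linear_sem_spec(model, beta), error = function(e) NULL)
    if (!is.null(spec)) return(spec)
    beta <- beta * 0.7
  }
}

# coefficient matrix -> minimal fitted_sem-shaped object for path algebra
fake_fitted <- function(model, B) {
  e <- model$edges
  coefs <- data.frame(
    response = e[, "to"], term = e[, "from"],
    estimate = B[cbind(e[, "from"], e[, "to"])],
    stringsAsFactors = FALSE)
  structure(list(model = model, coefficients = coefs), class = "fitted_sem")
}

# brute-force DFS path enumeration, independent of enumerate_paths()
oracle_paths <- function(model, x, y) {
  out <- list()
  stack <- list(x)
  while (length(stack)) {
    trail <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- trail[length(trail)]
    if (node == y) { out[[length(out) + 1]] <- trail; next }
    kids <- model$edges[model$edges[, "from"] == node, "to"]
    for (k in kids) {
      if (!(k %in% trail)) stack[[length(stack) + 1]] <- c(trail, k)
    }
  }
  out
}

small_landscape <- function(seed, n_plots = 40, coupling = NULL) {
  args <- list(n_plots = n_plots, n_years = 9, n_plant_species = 15,
               n_herbivore_species = 12, n_carnivore_species = 8, seed = seed)
  if (!is.null(coupling)) args$coupling <- coupling
  simulate_multitrophic(do.call(landscape_config, args))
}
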