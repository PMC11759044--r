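#' Parse a causal-model specification
#'
#' The model syntax is one statement per line: `y ~ x1 + x2` declares
#' directed edges `x1 -> y` and `x2 -> y`; `a ~~ b` declares a correlated
#' error (free covariance) between `a` and `b`; `#` starts a comment.
#' Duplicate edges collapse silently; the directed part must be acyclic.
#'
#' @param text model syntax, either a single string (possibly multi-line) or
#'   a character vector of lines.
#' @return object of class `causal_model`: `nodes`, `edges` (two-column
#'   matrix `from`/`to`), `correlated_errors` (two-column matrix),
#'   `exogenous` (nodes with no incoming edge), `order` (a topological order
#'   respecting declaration order among incomparable nodes).
#' @export
#' @examples
#' m <- parse_model("stability ~ synchrony + wapv
#'                   synchrony ~ lui")
#' m$exogenous
parse_model <- function(text) {
  if (length(text) == 1) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- sub("#.*$", "", text)
  text <- trimws(text)
  lines <- which(nzchar(text))
  edges <- matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to")))
  cerr <- matrix(character(0), 0, 2)
  nodes <- character(0)
  tok_ok <- function(x) grepl("^[A-Za-z.][A-Za-z0-9._]*$", x)
  for (ln in lines) {
    line <- text[ln]
    is_ce <- grepl("~~", line, fixed = TRUE)
    parts <- strsplit(line, if (is_ce) "~~" else "~", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop("cannot parse line ", ln, ": '", line, "'")
    }
    lhs <- trimws(parts[1])
    rhs <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
    bad <- c(lhs, rhs)[!tok_ok(c(lhs, rhs))]
    if (length(bad)) {
      stop("unknown token '", bad[1], "' on line ", ln)
    }
    nodes <- union(nodes, c(lhs, rhs))
    if (is_ce) {
      if (length(rhs) != 1) stop("correlated-error line ", ln,
                                 " must name exactly two variables")
      cerr <- rbind(cerr, sort(c(lhs, rhs[1])))
    } else {
      edges <- rbind(edges, cbind(from = rhs, to = lhs))
    }
  }
  if (!length(nodes)) stop("empty model text")
  edges <- unique(edges)
  cerr <- unique(cerr)
  if (nrow(cerr)) {
    both <- apply(cerr, 1, function(p) {
      any(edges[, 1] == p[1] & edges[, 2] == p[2]) ||
        any(edges[, 1] == p[2] & edges[, 2] == p[1])
    })
    if (any(both)) {
      stop("correlated-error pair also declared as a directed edge: ",
           paste(cerr[both, 1], cerr[both, 2], sep = "~~", collapse = ", "))
    }
  }
  ord <- topological_order(nodes, edges)  # errors on cycles
  exo <- setdiff(nodes, unique(edges[, "to"]))
  structure(
    list(nodes = nodes, edges = edges, correlated_errors = cerr,
         exogenous = exo, order = ord),
    class = "causal_model"
  )
}

# Kahn's algorithm; ties broken by declaration order in `nodes`.
topological_order <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (v in edges[, "to"]) indeg[v] <- indeg[v] + 1L
  out <- character(0)
  avail <- nodes[indeg[nodes] == 0]
  indeg_work <- indeg
  edges_work <- edges
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    out <- c(out, v)
    kids <- edges_work[edges_work[, "from"] == v, "to"]
    edges_work <- edges_work[edges_work[, "from"] != v, , drop = FALSE]
    for (k in kids) {
      indeg_work[k] <- indeg_work[k] - 1L
      if (indeg_work[k] == 0) {
        avail <- c(avail, k)
        avail <- avail[order(match(avail, nodes))]
      }
    }
  }
  if (length(out) != length(nodes)) {
    stop("model contains a cycle involving: ",
         paste(setdiff(nodes, out), collapse = ", "))
  }
  out
}

#' Serialise a causal model back to model syntax
#'
#' @param model a [parse_model()] result.
#' @return single string in the same dialect; `parse_model(serialize_model(m))`
#'   reproduces the graph.
#' @export
serialize_model <- function(model) {
  stopifnot(inherits(model, "causal_model"))
  lines <- character(0)
  for (y in model$order) {
    pa <- parents(model, y)
    if (length(pa)) lines <- c(lines, paste(y, "~", paste(pa, collapse = " + ")))
  }
  if (nrow(model$correlated_errors)) {
    lines <- c(lines, apply(model$correlated_errors, 1,
                            function(p) paste(p[1], "~~", p[2])))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.causal_model <- function(x, ...) {
  cat("<causal_model>", length(x$nodes), "nodes,", nrow(x$edges), "edges,",
      nrow(x$correlated_errors), "correlated-error pair(s)\n")
  invisible(x)
}

parents <- function(model, node) {
  model$edges[model$edges[, "to"] == node, "from"]
}

children <- function(model, node) {
  model$edges[model$edges[, "from"] == node, "to"]
}

is_adjacent <- function(model, a, b) {
  any(model$edges[, 1] == a & model$edges[, 2] == b) ||
    any(model$edges[, 1] == b & model$edges[, 2] == a)
}

has_correlated_error <- function(model, a, b) {
  if (!nrow(model$correlated_errors)) return(FALSE)
  p <- sort(c(a, b))
  any(model$correlated_errors[, 1] == p[1] & model$correlated_errors[, 2] == p[2])
}

#' Basis set of independence claims
#'
#' Enumerates the directed-separation claims a piecewise SEM must test: one
#' claim per unordered pair of non-adjacent nodes, excluding pairs declared
#' as correlated errors and pairs of two exogenous nodes. The claim's
#' response is the pair member later in the topological order (necessarily
#' endogenous), and the conditioning set is the union of both members'
#' parents, minus the pair itself.
#'
#' @param model a [parse_model()] result.
#' @return list of claims, each a list with `response`, `other`,
#'   `conditioning`.
#' @export
basis_set <- function(model) {
  stopifnot(inherits(model, "causal_model"))
  ord <- model$order
  claims <- list()
  n <- length(ord)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- ord[i]; b <- ord[j]
      if (is_adjacent(model, a, b)) next
      if (has_correlated_error(model, a, b)) next
      if (a %in% model$exogenous && b %in% model$exogenous) next
      # b is later in topological order; if b is exogenous the pair is
      # (endogenous a, exogenous b) — impossible since exogenous nodes have
      # no parents and sort before their descendants, but a could still be
      # endogenous with b exogenous when they are incomparable: then swap.
      resp <- b; other <- a
      if (resp %in% model$exogenous) { resp <- a; other <- b }
      cond <- setdiff(union(parents(model, a), parents(model, b)), c(a, b))
      claims[[length(claims) + 1]] <-
        list(response = resp, other = other, conditioning = cond)
    }
  }
  claims
}
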