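#' Prepare a species x trait table from raw records
#'
#' Collapses possibly repeated trait records to one row per species:
#' quantitative traits are averaged within species, categorical traits take
#' the modal category (a tie is an error naming the species), and traits
#' flagged for log transformation in the metadata are log-transformed after
#' averaging (values must be strictly positive).
#'
#' @param records data.frame with columns `species_id`, `trait`, `value`
#'   (character or numeric; categorical levels as character).
#' @param metadata data.frame with columns `trait`, `type`
#'   (`"quantitative"`, `"ordinal"` or `"categorical"`) and `transform`
#'   (`"none"` or `"log"`). Optional columns `group` (trait group used for
#'   Gower balancing) and `metric_role` (`"fd"`, `"cwm_pca"` or `"both"`)
#'   are carried through as attributes.
#' @return data.frame, one row per species (`species_id` column first),
#'   one column per trait; attribute `metadata` holds the metadata.
#' @export
prepare_traits <- function(records, metadata) {
  need <- c("species_id", "trait", "value")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(c("trait", "type", "transform") %in% names(metadata))) {
    stop("metadata must have columns: trait, type, transform")
  }
  unknown <- setdiff(unique(records$trait), metadata$trait)
  if (length(unknown)) {
    stop("records contain traits missing from metadata: ",
         paste(unknown, collapse = ", "))
  }
  bad_type <- setdiff(metadata$type, c("quantitative", "ordinal", "categorical"))
  if (length(bad_type)) stop("unknown trait type: ", paste(bad_type, collapse = ", "))

  species <- sort(unique(records$species_id))
  out <- data.frame(species_id = species, stringsAsFactors = FALSE)
  for (tr in metadata$trait) {
    meta <- metadata[metadata$trait == tr, ]
    rec <- records[records$trait == tr, ]
    col <- rep(NA, length(species))
    if (meta$type %in% c("quantitative", "ordinal")) {
      v <- tapply(as.numeric(rec$value), rec$species_id, mean)
      if (identical(meta$transform, "log")) {
        bad <- names(v)[!is.na(v) & v <= 0]
        if (length(bad)) {
          stop("nonpositive value under log transform for trait '", tr,
               "', species: ", paste(bad, collapse = ", "))
        }
        v <- log(v)
      }
      col <- as.numeric(v[match(species, names(v))])
    } else {
      v <- tapply(as.character(rec$value), rec$species_id, function(x) {
        tab <- sort(table(x), decreasing = TRUE)
        if (length(tab) > 1 && tab[1] == tab[2]) NA_character_ else names(tab)[1]
      })
      tied <- names(v)[is.na(v) & names(v) %in% unique(rec$species_id)]
      # distinguish genuine ties from species simply lacking records
      has_rec <- unique(rec$species_id)
      tied <- intersect(tied, has_rec)
      if (length(tied)) {
        stop("tied modal category for trait '", tr, "', species: ",
             paste(tied, collapse = ", "))
      }
      col <- as.character(v[match(species, names(v))])
    }
    out[[tr]] <- col
  }
  attr(out, "metadata") <- metadata
  out
}

trait_metadata <- function(traits) {
  md <- attr(traits, "metadata")
  if (is.null(md)) {
    # infer: numeric columns quantitative, character categorical
    cols <- setdiff(names(traits), "species_id")
    md <- data.frame(
      trait = cols,
      type = ifelse(vapply(traits[cols], is.numeric, logical(1)),
                    "quantitative", "categorical"),
      transform = "none", stringsAsFactors = FALSE
    )
  }
  md
}

#' Gower trait dissimilarity with balanced trait contributions
#'
#' Computes pairwise species dissimilarity over mixed trait types.
#' Per-trait distances are the usual Gower components: range-normalised
#' absolute differences for quantitative/ordinal traits; for a categorical
#' trait with L levels, the per-category membership mismatches are averaged
#' within the trait (so a plain mismatch contributes 2/L), keeping every
#' trait in `[0, 1]`. The overall dissimilarity is the weighted mean
#' `sum_k w_k d_k` with `sum w_k = 1`.
#'
#' With `weights_mode = "equal"` all traits get the same weight. With
#' `"balanced"` the weights are chosen analytically as
#' `w_k proportional to 1/mean(d_k)` so that every trait's mean contribution
#' `w_k * mean(d_k)` to the overall dissimilarity is identical — the
#' balancing goal of unequal-contribution-corrected Gower distances.
#'
#' @param traits output of [prepare_traits()] (or a compatible data.frame
#'   with a `species_id` column).
#' @param weights_mode `"balanced"` (default) or `"equal"`.
#' @param traits_use optional character vector restricting which traits enter.
#' @return list of class `trait_dissimilarity`: `d` (symmetric species x
#'   species matrix in `[0,1]`), `weights` (per trait), `mean_contribution`
#'   (per trait, `w_k * mean(d_k)`), `dropped` (constant traits removed).
#' @export
gower_balanced <- function(traits, weights_mode = c("balanced", "equal"),
                           traits_use = NULL) {
  weights_mode <- match.arg(weights_mode)
  md <- trait_metadata(traits)
  if (!is.null(traits_use)) md <- md[md$trait %in% traits_use, , drop = FALSE]
  species <- traits$species_id
  n <- length(species)
  if (n < 2) stop("need at least 2 species")

  dk <- list()
  dropped <- character(0)
  for (k in seq_len(nrow(md))) {
    tr <- md$trait[k]
    type <- md$type[k]
    v <- traits[[tr]]
    if (type %in% c("quantitative", "ordinal")) {
      v <- as.numeric(v)
      rng <- diff(range(v, na.rm = TRUE))
      if (!is.finite(rng) || rng == 0) { dropped <- c(dropped, tr); next }
      d <- abs(outer(v, v, "-")) / rng
    } else {
      v <- as.character(v)
      lev <- sort(unique(v[!is.na(v)]))
      if (length(lev) < 2) { dropped <- c(dropped, tr); next }
      acc <- matrix(0, n, n)
      for (lv in lev) {
        m <- as.numeric(v == lv)
        acc <- acc + abs(outer(m, m, "-"))
      }
      d <- acc / length(lev)
      d[is.na(outer(v, v, paste))] <- NA  # propagate missing categories
    }
    # pairwise-missing entries excluded later via weight renormalisation
    dk[[tr]] <- d
  }
  if (length(dropped)) {
    warning("constant traits dropped: ", paste(dropped, collapse = ", "))
  }
  if (!length(dk)) stop("all traits constant: no dissimilarity defined")

  off <- upper.tri(matrix(0, n, n))
  mean_d <- vapply(dk, function(d) mean(d[off], na.rm = TRUE), numeric(1))
  if (weights_mode == "balanced") {
    if (any(mean_d == 0)) {
      # a trait identical across species pairs would get infinite weight
      zero <- names(mean_d)[mean_d == 0]
      warning("traits with zero mean distance dropped from balancing: ",
              paste(zero, collapse = ", "))
      dk <- dk[mean_d > 0]; mean_d <- mean_d[mean_d > 0]
      if (!length(dk)) stop("all traits constant: no dissimilarity defined")
    }
    w <- (1 / mean_d) / sum(1 / mean_d)
  } else {
    w <- rep(1 / length(dk), length(dk))
    names(w) <- names(dk)
  }

  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (tr in names(dk)) {
    d <- dk[[tr]]
    ok <- !is.na(d)
    num[ok] <- num[ok] + w[tr] * d[ok]
    den[ok] <- den[ok] + w[tr]
  }
  D <- num / den
  D[den == 0] <- NA
  diag(D) <- 0
  dimnames(D) <- list(species, species)
  structure(
    list(d = D, weights = w,
         mean_contribution = w * mean_d[names(w)],
         per_trait_mean_distance = mean_d,
         dropped = dropped, mode = weights_mode),
    class = "trait_dissimilarity"
  )
}

#' @export
print.trait_dissimilarity <- function(x, ...) {
  cat("<trait_dissimilarity>", nrow(x$d), "species,", length(x$weights),
      "traits, mode =", x$mode, "\n")
  invisible(x)
}

#' Community-weighted means
#'
#' Abundance-weighted mean trait values of a pooled community: for a
#' quantitative trait `sum_i p_i t_i`; for a categorical trait, one entry per
#' category holding the summed relative abundance of the species in that
#' category (the proportion of the community in the category). Species
#' lacking a value for some trait are dropped for that trait only, with the
#' abundances renormalised over the covered species.
#'
#' @param p named relative-abundance vector (e.g.
#'   [pool_mean_relative_abundance()]); names are species ids.
#' @param traits output of [prepare_traits()].
#' @param traits_use optional restriction to a subset of traits.
#' @return named numeric vector; categorical entries are named
#'   `<trait>.<category>`.
#' @export
cwm <- function(p, traits, traits_use = NULL) {
  md <- trait_metadata(traits)
  if (!is.null(traits_use)) md <- md[md$trait %in% traits_use, , drop = FALSE]
  common <- intersect(names(p), traits$species_id)
  if (!length(common)) stop("no species shared between abundances and traits")
  out <- numeric(0)
  for (k in seq_len(nrow(md))) {
    tr <- md$trait[k]
    v <- traits[[tr]][match(common, traits$species_id)]
    ok <- !is.na(v)
    if (!any(ok)) stop("no trait coverage for '", tr, "'")
    pk <- p[common][ok]
    pk <- pk / sum(pk)
    if (md$type[k] %in% c("quantitative", "ordinal")) {
      out[tr] <- sum(pk * as.numeric(v[ok]))
    } else {
      vv <- as.character(v[ok])
      for (lv in sort(unique(vv))) {
        out[paste(tr, lv, sep = ".")] <- sum(pk[vv == lv])
      }
    }
  }
  out
}

#' Rao's quadratic entropy
#'
#' The expected trait dissimilarity between two individuals drawn at random
#' (with replacement) from the community: `Q = sum_ij p_i p_j d_ij`.
#'
#' @param p relative-abundance vector summing to 1 (named by species).
#' @param D a [gower_balanced()] result or a plain symmetric dissimilarity
#'   matrix with matching species.
#' @return scalar >= 0.
#' @export
rao_q <- function(p, D) {
  if (inherits(D, "trait_dissimilarity")) D <- D$d
  if (!is.null(names(p)) && !is.null(rownames(D))) {
    common <- intersect(names(p), rownames(D))
    if (!length(common)) stop("no species shared between p and D")
    p <- p[common]
    D <- D[common, common, drop = FALSE]
  }
  if (length(p) != nrow(D)) stop("dimension mismatch between p and D")
  p <- p / sum(p)
  as.numeric(p %*% D %*% p)
}

#' Dominant-trait axes: PCA on the plot x CWM table
#'
#' Runs a correlation-matrix principal components analysis on plot-level CWM
#' values and returns the first `n_axes` axes. The axis scores summarise the
#' traits of the dominant species in each plot (for plants, PC1 typically
#' tracks the leaf-economics spectrum from acquisitive to conservative
#' strategies). Eigenvector signs being arbitrary, each axis is oriented so
#' that the anchor trait loads positively: the named `anchor` trait for the
#' axis on which it loads most strongly, and otherwise the trait with the
#' largest absolute loading on that axis.
#'
#' @param cwm_table numeric matrix or data.frame, plots x CWM variables.
#' @param n_axes number of axes to keep (default 2).
#' @param anchor optional trait (column) name to anchor the sign convention.
#' @return list of class `dominant_trait_axes`: `loadings` (trait x axis,
#'   orthonormal), `scores` (plot x axis, mean zero), `explained` (proportion
#'   of variance per axis), `eigenvalues`, `anchors` (trait used to fix each
#'   axis sign), `dropped` (constant columns removed).
#' @export
dominant_trait_axes <- function(cwm_table, n_axes = 2, anchor = NULL) {
  X <- as.matrix(cwm_table)
  if (nrow(X) < 3) stop("need at least 3 plots")
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    X <- X[, sds > 0, drop = FALSE]
    message("constant CWM columns dropped: ", paste(dropped, collapse = ", "))
  }
  Z <- scale(X)
  R <- stats::cor(X)
  ev <- eigen(R, symmetric = TRUE)
  rank <- sum(ev$values > 1e-10)
  if (n_axes > rank) stop("requested ", n_axes, " axes but rank is ", rank)
  L <- ev$vectors[, seq_len(n_axes), drop = FALSE]
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("PC", seq_len(n_axes))
  anchors <- character(n_axes)
  for (a in seq_len(n_axes)) {
    tr <- if (!is.null(anchor) && anchor %in% rownames(L)) {
      anchor
    } else {
      rownames(L)[which.max(abs(L[, a]))]
    }
    anchors[a] <- tr
    if (L[tr, a] < 0) L[, a] <- -L[, a]
  }
  scores <- Z %*% L
  structure(
    list(loadings = L, scores = scores,
         explained = ev$values[seq_len(n_axes)] / sum(ev$values),
         eigenvalues = ev$values, anchors = anchors, dropped = dropped),
    class = "dominant_trait_axes"
  )
}

#' @export
print.dominant_trait_axes <- function(x, ...) {
  cat("<dominant_trait_axes>", ncol(x$loadings), "axes,",
      nrow(x$loadings), "traits; explained:",
      paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}
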