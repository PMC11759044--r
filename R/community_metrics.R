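#' Temporal community stability (inverse coefficient of variation)
#'
#' Stability is the constancy of total community abundance over time,
#' mu/sigma of the yearly totals, i.e. the inverse of the coefficient of
#' variation. The standard deviation is the sample SD (denominator T - 1).
#' A community whose totals do not vary has no defined CV; this is reported
#' as `NA` with an attribute rather than `Inf`.
#'
#' @param ts a [community_ts()].
#' @return positive scalar, or `NA` (with attribute `undefined = "zero-variance"`)
#'   when the yearly totals are constant.
#' @export
temporal_stability <- function(ts) {
  stopifnot(inherits(ts, "community_ts"))
  x <- yearly_totals(ts)
  if (length(x) < 3) stop("temporal stability needs at least 3 survey years")
  if (all(x == 0)) stop("all yearly totals are zero: stability undefined")
  s <- stats::sd(x)
  if (s == 0) {
    return(structure(NA_real_, undefined = "zero-variance"))
  }
  mean(x) / s
}

#' Mean species richness over the time series
#'
#' The average, over survey years, of the number of species with positive
#' abundance in that year. This is the usual proxy for the portfolio effect.
#'
#' @param ts a [community_ts()].
#' @return scalar >= 0.
#' @export
mean_richness <- function(ts) {
  stopifnot(inherits(ts, "community_ts"))
  if (length(ts$years) < 1 || length(ts$species) < 1) {
    stop("empty abundance matrix")
  }
  mean(colSums(ts$abundance > 0))
}

#' Mean total abundance over the time series
#'
#' The average over years of the yearly community total (summed percent cover
#' for plants, summed counts for arthropods). Enters the stability ratio as
#' its numerator, so it is carried as its own community feature.
#'
#' @param ts a [community_ts()].
#' @return scalar >= 0.
#' @export
mean_total_abundance <- function(ts) {
  stopifnot(inherits(ts, "community_ts"))
  if (length(ts$years) < 1 || length(ts$species) < 1) {
    stop("empty abundance matrix")
  }
  mean(yearly_totals(ts))
}

#' Weighted species synchrony (eta_w)
#'
#' The abundance-weighted mean Pearson correlation between each species'
#' yearly abundance series and the aggregated abundance of the rest of the
#' community. Weights are species' shares of the community grand total over
#' all years, renormalised over the species that actually enter the sum.
#' Species whose own series, or whose community remainder, has zero temporal
#' variance carry no defined correlation and are excluded (weights
#' renormalised); the excluded species are recorded in the `excluded`
#' attribute.
#'
#' Low synchrony indicates compensatory dynamics: fluctuations of some
#' species offset by others.
#'
#' @param ts a [community_ts()].
#' @return scalar in `[-1, 1]`, or `NA` (attribute `undefined`) when fewer
#'   than two variance-bearing species remain.
#' @export
synchrony_eta_w <- function(ts) {
  stopifnot(inherits(ts, "community_ts"))
  if (length(ts$years) < 3) stop("synchrony needs at least 3 survey years")
  A <- ts$abundance[present_species(ts), , drop = FALSE]
  if (nrow(A) < 2) {
    return(structure(NA_real_, undefined = "fewer than 2 present species"))
  }
  tot <- colSums(A)
  sp_tot <- rowSums(A)
  r <- rep(NA_real_, nrow(A))
  for (i in seq_len(nrow(A))) {
    xi <- A[i, ]
    rest <- tot - xi
    if (stats::sd(xi) > 0 && stats::sd(rest) > 0) {
      r[i] <- stats::cor(xi, rest)
    }
  }
  ok <- !is.na(r)
  if (sum(ok) < 2) {
    return(structure(NA_real_, undefined = "fewer than 2 variance-bearing species"))
  }
  w <- sp_tot[ok] / sum(sp_tot[ok])
  structure(sum(w * r[ok]),
            excluded = rownames(A)[!ok])
}

#' Weighted average population variability (wAPV)
#'
#' The community-weighted mean of species-level coefficients of variation:
#' `sum_i p_i * CV_i`, where `CV_i` is the sample CV of species i's yearly
#' abundances and `p_i` its mean relative abundance over the time series
#' (mean over years, with zero-total years skipped, of `x_it / X_t`). High
#' wAPV means the community is dominated by temporally variable populations.
#'
#' @param ts a [community_ts()].
#' @param weights `"mean_share"` (default) weights each species by the mean of
#'   its yearly relative abundances; `"total"` weights by its share of the
#'   community grand total over all years.
#' @return scalar >= 0.
#' @export
wapv <- function(ts, weights = c("mean_share", "total")) {
  stopifnot(inherits(ts, "community_ts"))
  weights <- match.arg(weights)
  if (length(ts$years) < 3) stop("wAPV needs at least 3 survey years")
  A <- ts$abundance[present_species(ts), , drop = FALSE]
  if (nrow(A) < 1) stop("no present species")
  tot <- colSums(A)
  if (all(tot == 0)) stop("all yearly totals are zero")
  mu <- rowMeans(A)
  keep <- mu > 0
  A <- A[keep, , drop = FALSE]
  mu <- mu[keep]
  cv <- apply(A, 1, stats::sd) / mu
  if (weights == "mean_share") {
    pos <- tot > 0
    p <- rowMeans(sweep(A[, pos, drop = FALSE], 2, tot[pos], "/"))
  } else {
    p <- rowSums(A) / sum(A)
  }
  sum(p * cv)
}

#' Pooled community: mean relative abundances
#'
#' Collapses a time series into one static community in which each species
#' carries the mean relative abundance it showed across the series: the mean
#' over years (with positive totals) of `x_it / X_t`, renormalised to sum to
#' one over the present species. This pooled vector is the abundance input to
#' the trait-based features (CWM and Rao's Q).
#'
#' @param ts a [community_ts()].
#' @return named numeric vector over present species, summing to 1.
#' @export
pool_mean_relative_abundance <- function(ts) {
  stopifnot(inherits(ts, "community_ts"))
  A <- ts$abundance[present_species(ts), , drop = FALSE]
  tot <- colSums(A)
  if (!any(tot > 0)) stop("no year with positive total abundance")
  pos <- tot > 0
  p <- rowMeans(sweep(A[, pos, drop = FALSE], 2, tot[pos], "/"))
  p / sum(p)
}

#' Filter plots by minimum years of presence
#'
#' Retains plots in which at least one species is present (abundance > 0) in
#' at least `min_years` survey years. Mirrors the screening of plots with
#' near-empty herbaceous layers before stability can be computed.
#'
#' @param ts_list list of [community_ts()] objects.
#' @param min_years minimum number of years with any species present.
#' @return list with elements `retained` (the surviving subset), `dropped`
#'   (character vector of dropped plot ids) and `presence_years` (named count
#'   per plot).
#' @export
filter_min_presence <- function(ts_list, min_years) {
  stopifnot(min_years >= 1)
  ny <- vapply(ts_list, function(ts) sum(colSums(ts$abundance) > 0), numeric(1))
  ids <- vapply(ts_list, function(ts) as.character(ts$plot_id), character(1))
  names(ny) <- ids
  names(ts_list) <- ids
  keep <- ny >= min_years
  if (!any(keep)) warning("no plot satisfies the presence filter")
  list(retained = ts_list[keep], dropped = ids[!keep], presence_years = ny)
}
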