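#' Community time series
#'
#' A `community_ts` holds the species-by-year abundance matrix of one plot:
#' percent cover for plants, individual counts for arthropods. Rows are
#' species, columns are ordered survey years. A species is considered present
#' if its abundance is positive in at least one year; years with no survey are
#' simply absent from the matrix (they are never imputed as zeros).
#'
#' @param abundance numeric matrix, species x years, nonnegative. Row names
#'   are species identifiers, column names the survey years.
#' @param plot_id plot identifier (scalar).
#' @param years optional numeric vector of survey years; defaults to the
#'   column names of `abundance`.
#' @param species optional character vector of species ids; defaults to the
#'   row names of `abundance`.
#'
#' @return an object of class `community_ts` with elements `plot_id`,
#'   `years`, `species` and `abundance`.
#' @export
#' @examples
#' m <- rbind(sp1 = c(3, 4, 5), sp2 = c(1, 0, 2))
#' colnames(m) <- 2008:2010
#' ts <- community_ts(m, plot_id = "P1")
#' temporal_stability(ts)
community_ts <- function(abundance, plot_id, years = NULL, species = NULL) {
  abundance <- as.matrix(abundance)
  if (!is.numeric(abundance)) {
    stop("`abundance` must be a numeric matrix (species x years)")
  }
  if (anyNA(abundance)) stop("`abundance` contains missing values")
  if (any(abundance < 0)) stop("`abundance` must be nonnegative")
  if (is.null(species)) species <- rownames(abundance)
  if (is.null(species)) species <- paste0("sp", seq_len(nrow(abundance)))
  if (is.null(years)) years <- colnames(abundance)
  if (is.null(years)) years <- seq_len(ncol(abundance))
  years <- as.numeric(years)
  if (length(species) != nrow(abundance) || length(years) != ncol(abundance)) {
    stop("dimensions of `abundance` do not match `species`/`years`")
  }
  if (anyDuplicated(species)) stop("duplicate species identifiers")
  if (anyDuplicated(years)) stop("duplicate years")
  ord <- order(years)
  abundance <- abundance[, ord, drop = FALSE]
  years <- years[ord]
  dimnames(abundance) <- list(species, years)
  structure(
    list(plot_id = plot_id, years = years, species = species,
         abundance = abundance),
    class = "community_ts"
  )
}

#' @export
print.community_ts <- function(x, ...) {
  cat("<community_ts> plot", x$plot_id, "-", length(x$species), "species x",
      length(x$years), "years\n")
  invisible(x)
}

yearly_totals <- function(ts) colSums(ts$abundance)

present_species <- function(ts) {
  rowSums(ts$abundance > 0) > 0
}
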