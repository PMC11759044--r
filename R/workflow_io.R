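#' Read a long-format abundance table
#'
#' Expects a CSV with columns `plot_id`, `year`, `species_id`, `abundance`.
#' Within a plot, the surveyed years are those appearing for that plot;
#' species without a record in a surveyed year are zeros. Duplicate
#' (plot, year, species) cells and negative abundances are errors.
#'
#' @param path CSV file path.
#' @return named list of [community_ts()], one per plot.
#' @export
read_abundance <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "year", "species_id", "abundance")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("abundance table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$abundance < 0)) stop("negative abundance values present")
  key <- paste(df$plot_id, df$year, df$species_id)
  if (anyDuplicated(key)) {
    stop("duplicate (plot, year, species) cells: ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  }
  out <- lapply(split(df, df$plot_id), function(d) {
    years <- sort(unique(d$year))
    species <- sort(unique(d$species_id))
    m <- matrix(0, length(species), length(years),
                dimnames = list(species, years))
    m[cbind(match(d$species_id, species), match(d$year, years))] <- d$abundance
    community_ts(m, plot_id = d$plot_id[1], years = years, species = species)
  })
  out[order(names(out))]
}

#' Write community time series as a long-format CSV
#'
#' Inverse of [read_abundance()]: one row per (plot, year, species) with
#' positive abundance; zero cells are implicit within surveyed years, and
#' each surveyed year is guaranteed at least one row per plot (an all-zero
#' year writes a zero row for the first species so the survey is recorded).
#'
#' @param ts_list list of [community_ts()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_abundance <- function(ts_list, path) {
  rows <- lapply(ts_list, function(ts) {
    A <- ts$abundance
    idx <- which(A > 0, arr.ind = TRUE)
    d <- data.frame(plot_id = ts$plot_id,
                    year = ts$years[idx[, 2]],
                    species_id = ts$species[idx[, 1]],
                    abundance = A[idx], stringsAsFactors = FALSE)
    empty <- setdiff(ts$years, d$year)
    if (length(empty)) {
      d <- rbind(d, data.frame(plot_id = ts$plot_id, year = empty,
                               species_id = ts$species[1], abundance = 0,
                               stringsAsFactors = FALSE))
    }
    d
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$plot_id, df$year, df$species_id), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trait table plus its metadata
#'
#' @param path trait CSV: `species_id` plus one column per trait.
#' @param meta_path metadata CSV: columns `trait`, `type`, `transform` and
#'   optionally `group`, `metric_role`.
#' @return trait data.frame with the metadata attached (as used by
#'   [gower_balanced()] and [cwm()]).
#' @export
read_traits <- function(path, meta_path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  md <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  if (!"species_id" %in% names(tr)) stop("trait table needs `species_id`")
  if (!all(c("trait", "type", "transform") %in% names(md))) {
    stop("trait metadata needs columns trait, type, transform")
  }
  unknown <- setdiff(md$trait, names(tr))
  if (length(unknown)) stop("metadata names unknown trait(s): ",
                            paste(unknown, collapse = ", "))
  attr(tr, "metadata") <- md
  tr
}

#' Assemble the per-plot feature table of one trophic group
#'
#' Runs the community time-series metrics and the trait-based features for
#' every plot and joins them with the land-use covariate into the analysis
#' table the SEM consumes: `lui`, `stability`, `mean_richness`,
#' `mean_total_abundance`, `synchrony`, `wapv`, `fd`, `pc1`, `pc2`.
#'
#' @param ts_list list of [community_ts()].
#' @param traits trait table (with metadata) for the group's species.
#' @param lui data.frame `plot_id`, `lui` (and any extra covariate columns,
#'   carried through).
#' @param min_presence_years drop plots with fewer years of any presence
#'   (`NULL` to skip the filter).
#' @param fd_traits,pca_traits optional trait-name subsets for the
#'   functional-diversity and dominant-trait computations; default uses the
#'   metadata's `metric_role` column when present, else all traits for both.
#' @param anchor sign-anchor trait for the dominant-trait PCA.
#' @param n_axes number of dominant-trait axes (default 2).
#' @return data.frame, one row per retained plot; attributes `axes` (the
#'   [dominant_trait_axes()] object), `dropped_plots`, `dissimilarity`.
#' @export
plot_features <- function(ts_list, traits, lui, min_presence_years = NULL,
                          fd_traits = NULL, pca_traits = NULL, anchor = NULL,
                          n_axes = 2) {
  dropped <- character(0)
  if (!is.null(min_presence_years)) {
    flt <- filter_min_presence(ts_list, min_presence_years)
    ts_list <- flt$retained
    dropped <- flt$dropped
  }
  md <- trait_metadata(traits)
  if (is.null(fd_traits) && "metric_role" %in% names(md)) {
    fd_traits <- md$trait[md$metric_role %in% c("fd", "both")]
  }
  if (is.null(pca_traits) && "metric_role" %in% names(md)) {
    pca_traits <- md$trait[md$metric_role %in% c("cwm_pca", "both")]
  }
  D <- gower_balanced(traits, traits_use = fd_traits)

  feats <- lapply(ts_list, function(ts) {
    p <- pool_mean_relative_abundance(ts)
    data.frame(
      plot_id = as.character(ts$plot_id),
      stability = as.numeric(temporal_stability(ts)),
      mean_richness = mean_richness(ts),
      mean_total_abundance = mean_total_abundance(ts),
      synchrony = as.numeric(synchrony_eta_w(ts)),
      wapv = wapv(ts),
      fd = rao_q(p, D),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(feats, list(make.row.names = FALSE)))

  cwm_list <- lapply(ts_list, function(ts) {
    cwm(pool_mean_relative_abundance(ts), traits, traits_use = pca_traits)
  })
  vars <- unique(unlist(lapply(cwm_list, names)))
  cwms <- matrix(0, length(cwm_list), length(vars),
                 dimnames = list(NULL, vars))  # absent category = share 0
  for (i in seq_along(cwm_list)) cwms[i, names(cwm_list[[i]])] <- cwm_list[[i]]
  axes <- dominant_trait_axes(cwms, n_axes = n_axes, anchor = anchor)
  for (a in seq_len(n_axes)) out[[paste0("pc", a)]] <- axes$scores[, a]

  out <- merge(out, lui, by = "plot_id", sort = TRUE)
  attr(out, "axes") <- axes
  attr(out, "dropped_plots") <- dropped
  attr(out, "cwm_table") <- cwms
  attr(out, "dissimilarity") <- D
  out
}

#' Built-in causal meta-model templates
#'
#' Text model syntax for the two experiment templates. `"h1"` is the
#' within-group meta-model: LUI acts on the functional features (dominant
#' trait axes `pc1`/`pc2`, functional diversity `fd`), on the acknowledged
#' stability drivers (mean richness, synchrony, weighted average population
#' variability) and on mean total abundance, with nearly saturated links
#' from features to drivers and from everything to stability. `"h2"` is the
#' cross-trophic variant for an arthropod group: the plant features
#' (`fd_plant`, `pc1_plant`, `pc2_plant`) respond to LUI and act as upstream
#' mediators of the arthropod features and drivers.
#'
#' @param hypothesis `"h1"` or `"h2"`.
#' @param correlated `"plant"` adds the free covariances between functional
#'   diversity and the dominant-trait axes; `"arthropod"` adds the free
#'   covariance between functional diversity and mean richness.
#' @return model syntax string (parse with [parse_model()]).
#' @export
model_template <- function(hypothesis = c("h1", "h2"),
                           correlated = c("plant", "arthropod")) {
  hypothesis <- match.arg(hypothesis)
  correlated <- match.arg(correlated)
  ce <- if (correlated == "plant") {
    "fd ~~ pc1\nfd ~~ pc2"
  } else {
    "fd ~~ mean_richness"
  }
  # the free covariance between fd and richness replaces the directed link
  rich_fd <- if (correlated == "plant") " + fd" else ""
  if (hypothesis == "h1") {
    paste(
      "pc1 ~ lui",
      "pc2 ~ lui",
      "fd ~ lui",
      paste0("mean_richness ~ lui + pc1 + pc2", rich_fd),
      "mean_total_abundance ~ lui + pc1 + pc2 + fd + mean_richness",
      "synchrony ~ lui + pc1 + pc2 + fd + mean_richness",
      "wapv ~ lui + pc1 + pc2 + fd + mean_richness + mean_total_abundance + synchrony",
      "stability ~ lui + pc1 + pc2 + fd + mean_richness + mean_total_abundance + synchrony + wapv",
      ce, sep = "\n")
  } else {
    paste(
      "pc1_plant ~ lui",
      "pc2_plant ~ lui",
      "fd_plant ~ lui",
      "pc1 ~ lui + pc1_plant + pc2_plant + fd_plant",
      "pc2 ~ lui + pc1_plant + pc2_plant + fd_plant",
      "fd ~ lui + pc1_plant + pc2_plant + fd_plant",
      paste0("mean_richness ~ lui + pc1_plant + pc2_plant + fd_plant + pc1 + pc2",
             rich_fd),
      "mean_total_abundance ~ lui + pc1 + pc2 + fd + mean_richness",
      "synchrony ~ lui + pc1_plant + pc2_plant + fd_plant + pc1 + pc2 + fd + mean_richness",
      "wapv ~ lui + pc1 + pc2 + fd + mean_richness + mean_total_abundance + synchrony",
      "stability ~ lui + pc1_plant + pc2_plant + fd_plant + pc1 + pc2 + fd + mean_richness + mean_total_abundance + synchrony + wapv",
      "fd_plant ~~ pc1_plant\nfd_plant ~~ pc2_plant",
      ce, sep = "\n")
  }
}

default_effect_queries <- function(model, source = "lui",
                                   targets = c("mean_richness", "synchrony",
                                               "wapv", "mean_total_abundance"),
                                   extra_total = "stability") {
  targets <- intersect(targets, model$nodes)
  queries <- list()
  for (tg in targets) {
    mediators <- setdiff(model$nodes, c(source, tg, model$exogenous))
    for (md in mediators) {
      paths <- enumerate_paths(model, source, tg)
      if (any(vapply(paths, function(p) md %in% p, logical(1)))) {
        queries[[length(queries) + 1]] <-
          list(source = source, target = tg, type = "mediator", mediator = md)
      }
    }
    queries[[length(queries) + 1]] <-
      list(source = source, target = tg, type = "total")
  }
  if (!is.null(extra_total) && extra_total %in% model$nodes) {
    queries[[length(queries) + 1]] <-
      list(source = source, target = extra_total, type = "total")
  }
  queries
}

run_pipeline <- function(features, model_text, correlated, er_threshold,
                         n_boot, seed, ci_level, out_dir, label) {
  model <- parse_model(model_text)
  miss <- setdiff(model$nodes, names(features))
  if (length(miss)) stop("feature table lacks model variable(s): ",
                         paste(miss, collapse = ", "))
  fit <- fit_sem(model, features, reduce = TRUE, er_threshold = er_threshold)
  queries <- default_effect_queries(fit$model)
  effects <- bootstrap_effects(fit$model, features, queries,
                               n_boot = n_boot, seed = seed,
                               ci_level = ci_level)
  result <- list(label = label, features = features, model = model,
                 fit = fit, effects = effects, seed = seed)
  class(result) <- "stability_run"
  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

#' Run the within-group (H1) analysis on a landscape
#'
#' End-to-end pipeline for one trophic group of a simulated (or file-loaded)
#' landscape: community metrics, trait features, feature-table assembly,
#' a-priori SEM fit, evidence-ratio reduction, and bootstrapped effect
#' decomposition.
#'
#' @param landscape a [simulate_multitrophic()] result (or a compatible list
#'   with `plants`/`herbivores`/`carnivores`, `traits`, `lui`).
#' @param group `"plants"`, `"herbivores"` or `"carnivores"`.
#' @param model_text model syntax; default [model_template()] for the group.
#' @param min_presence_years presence filter (default `NULL`: keep all).
#' @param er_threshold evidence-ratio threshold (default 2.72).
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param ci_level confidence level (default 0.95).
#' @param out_dir optional output directory; when given, coefficient, basis
#'   set, fit-statistic and effect tables are written as CSV/JSON along with
#'   a manifest.
#' @return list of class `stability_run`: `features`, `model`, `fit`
#'   (a [fit_sem()] result with selection tables), `effects`
#'   (bootstrapped [bootstrap_effects()] table).
#' @export
run_h1 <- function(landscape, group = c("plants", "herbivores", "carnivores"),
                   model_text = NULL, min_presence_years = NULL,
                   er_threshold = 2.72, n_boot = 2000, seed = 1,
                   ci_level = 0.95, out_dir = NULL) {
  group <- match.arg(group)
  features <- plot_features(landscape[[group]], landscape$traits[[group]],
                            landscape$lui,
                            min_presence_years = min_presence_years,
                            anchor = if (group == "plants") "sla" else NULL)
  if (is.null(model_text)) {
    model_text <- model_template("h1", correlated =
                                   if (group == "plants") "plant" else "arthropod")
  }
  run_pipeline(features, model_text,
               correlated = if (group == "plants") "plant" else "arthropod",
               er_threshold, n_boot, seed, ci_level, out_dir,
               label = paste0("h1_", group))
}

#' Run the cross-trophic (H2) analysis on a landscape
#'
#' As [run_h1()], but the arthropod feature table is inner-joined with the
#' plant-derived functional features (`fd_plant`, `pc1_plant`, `pc2_plant`)
#' of the same plots, which enter the SEM as upstream mediators between LUI
#' and the arthropod community.
#'
#' @inheritParams run_h1
#' @param group `"herbivores"` or `"carnivores"` (or `"plants"` is refused).
#' @return list of class `stability_run`; the feature table contains both
#'   trophic levels' features.
#' @export
run_h2 <- function(landscape, group = c("herbivores", "carnivores"),
                   model_text = NULL, min_presence_years = NULL,
                   er_threshold = 2.72, n_boot = 2000, seed = 1,
                   ci_level = 0.95, out_dir = NULL) {
  group <- match.arg(group)
  plant_feats <- plot_features(landscape$plants, landscape$traits$plants,
                               landscape$lui,
                               min_presence_years = min_presence_years,
                               anchor = "sla")
  arth_feats <- plot_features(landscape[[group]], landscape$traits[[group]],
                              landscape$lui,
                              min_presence_years = min_presence_years)
  pf <- plant_feats[, c("plot_id", "fd", "pc1", "pc2")]
  names(pf) <- c("plot_id", "fd_plant", "pc1_plant", "pc2_plant")
  n_before <- nrow(arth_feats)
  features <- merge(arth_feats, pf, by = "plot_id", sort = TRUE)
  if (!nrow(features)) stop("no plots shared between plant and ", group,
                            " feature tables")
  if (nrow(features) < n_before) {
    message(n_before - nrow(features), " plot(s) dropped in cross-trophic join")
  }
  if (is.null(model_text)) model_text <- model_template("h2", "arthropod")
  run_pipeline(features, model_text, correlated = "arthropod",
               er_threshold, n_boot, seed, ci_level, out_dir,
               label = paste0("h2_", group))
}

#' @export
print.stability_run <- function(x, ...) {
  cat("<stability_run>", x$label, "- n =", x$fit$n, "plots\n")
  print(x$fit)
  sig <- x$effects[x$effects$significant & x$effects$type == "mediator", ]
  cat("  significant mediator effects:", nrow(sig), "of",
      sum(x$effects$type == "mediator"), "\n")
  invisible(x)
}

config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f)  # scratch only; never part of the deliverable
  unname(tools::md5sum(f))
}

write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(list(model = serialize_model(result$model),
                           seed = result$seed))
  stamp <- function(df) { df$config_hash <- hash; df }
  utils::write.csv(stamp(result$fit$coefficients),
                   file.path(out_dir, paste0(result$label, "_coefficients.csv")),
                   row.names = FALSE)
  utils::write.csv(stamp(result$fit$basis),
                   file.path(out_dir, paste0(result$label, "_basis_set.csv")),
                   row.names = FALSE)
  utils::write.csv(stamp(as.data.frame(result$effects)),
                   file.path(out_dir, paste0(result$label, "_effects.csv")),
                   row.names = FALSE)
  fitstats <- list(
    label = result$label, C = result$fit$C, df = result$fit$df,
    p_value = result$fit$p_value, AICc = result$fit$AICc, K = result$fit$K,
    n = result$fit$n, r2 = as.list(result$fit$r2), config_hash = hash)
  jsonlite::write_json(fitstats,
                       file.path(out_dir, paste0(result$label, "_fit.json")),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "stabsem",
    version = as.character(utils::packageVersion("stabsem")),
    label = result$label, seed = result$seed,
    model = serialize_model(result$model),
    n_plots = result$fit$n, config_hash = hash,
    created = "run manifest")
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(result$label, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
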