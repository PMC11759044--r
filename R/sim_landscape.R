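#' Configuration for the multi-trophic landscape generator
#'
#' Defines a synthetic landscape of plots along a land-use-intensity (LUI)
#' gradient, each carrying plant, arthropod-herbivore and arthropod-carnivore
#' communities observed yearly. The generative mechanism builds in the causal
#' structure the downstream analysis is meant to recover:
#'
#' * each plant species carries a leaf-economics score (acquisitive high,
#'   conservative low) that shapes its traits (high SLA / low LDMC at the
#'   acquisitive end); higher LUI tilts community composition toward
#'   high-score species, so the community-weighted mean of the axis rises
#'   with LUI by construction;
#' * yearly abundances fluctuate lognormally around a species-by-plot mean,
#'   driven by species-specific loadings on one shared yearly environmental
#'   deviate per plot — the more similar the loadings, the higher the
#'   realized synchrony;
#' * herbivore community composition responds to the plant trait CWM, and
#'   carnivore composition to the herbivore CWM, creating a nonzero
#'   cross-trophic mediation path whose strength is the `coupling` setting;
#' * species occupancy is a LUI-dependent logistic, so richness declines
#'   with land use.
#'
#' @param n_plots number of plots (default 150).
#' @param n_years number of survey years (default 13).
#' @param n_plant_species,n_herbivore_species,n_carnivore_species species
#'   pool sizes (defaults 40, 30, 20).
#' @param lui_range numeric length-2 interval of LUI values (default
#'   `c(0.5, 3)`), sampled uniformly per plot.
#' @param env_loading list with `mean` and `sd` of species' loadings on the
#'   shared yearly environmental deviate (defaults 0.25 and 0.15; `sd = 0`
#'   makes all species respond identically, pushing synchrony toward its
#'   maximum), and `trait_cor` (default 0.6), the correlation between a
#'   species' loading and its trait score: acquisitive (fast) species
#'   respond more strongly to interannual environmental fluctuation, so
#'   communities tilted toward them have more variable populations (higher
#'   wAPV) and higher synchrony by construction.
#' @param trait_archetypes list controlling trait generation:
#'   `sla_slope`, `ldmc_slope` (loadings of the plant leaf-economics score
#'   on log SLA and log LDMC), `arthropod_slope` (loading of the arthropod
#'   morphometric score on log body size), `noise` (independent lognormal
#'   trait noise SD).
#' @param coupling list of causal strengths: `lui_trait` (LUI -> plant
#'   community trait score), `plant_herbivore` (plant CWM -> herbivore
#'   composition), `herbivore_carnivore` (herbivore CWM -> carnivore
#'   composition), `lui_abundance` (direct LUI effect on arthropod
#'   abundance).
#' @param occupancy list: `base` (mean logit of species presence),
#'   `lui_slope` (change in logit per unit of centred LUI; negative makes
#'   richness decline with LUI).
#' @param assembly_sd SD of the plot-level assembly deviate added to the
#'   trait-sorting direction (default 0.5): plots differ in trait
#'   composition for reasons unrelated to the modelled drivers (soil,
#'   history, dispersal limitation), so community-weighted means are
#'   correlated with, but not determined by, land use.
#' @param resid_sd residual lognormal SD of yearly abundances (default 0.4).
#' @param seed RNG seed.
#' @return validated list of class `landscape_config`.
#' @export
landscape_config <- function(n_plots = 150, n_years = 13,
                             n_plant_species = 40, n_herbivore_species = 30,
                             n_carnivore_species = 20,
                             lui_range = c(0.5, 3),
                             env_loading = list(mean = 0.25, sd = 0.15,
                                                trait_cor = 0.6),
                             trait_archetypes = list(sla_slope = 0.35,
                                                     ldmc_slope = -0.3,
                                                     arthropod_slope = 0.4,
                                                     noise = 0.15),
                             coupling = list(lui_trait = 0.8,
                                             plant_herbivore = 0.7,
                                             herbivore_carnivore = 0.7,
                                             lui_abundance = -0.15),
                             occupancy = list(base = 1.3, lui_slope = -0.7),
                             assembly_sd = 0.5,
                             resid_sd = 0.4,
                             seed = 1) {
  cfg <- list(n_plots = n_plots, n_years = n_years,
              n_plant_species = n_plant_species,
              n_herbivore_species = n_herbivore_species,
              n_carnivore_species = n_carnivore_species,
              lui_range = lui_range, env_loading = env_loading,
              trait_archetypes = trait_archetypes, coupling = coupling,
              occupancy = occupancy, assembly_sd = assembly_sd,
              resid_sd = resid_sd, seed = seed)
  counts <- c("n_plots", "n_years", "n_plant_species", "n_herbivore_species",
              "n_carnivore_species")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 2 || v != round(v)) {
      stop("invalid config field `", f, "`: must be an integer count >= 2")
    }
  }
  if (!is.numeric(lui_range) || length(lui_range) != 2 ||
      diff(lui_range) <= 0) {
    stop("invalid config field `lui_range`: must be a nondegenerate interval")
  }
  if (!is.list(env_loading) || is.null(env_loading$mean) ||
      is.null(env_loading$sd) || env_loading$sd < 0) {
    stop("invalid config field `env_loading`: needs mean and sd >= 0")
  }
  if (is.null(env_loading$trait_cor)) cfg$env_loading$trait_cor <- 0.6
  if (abs(cfg$env_loading$trait_cor) > 1) {
    stop("invalid config field `env_loading$trait_cor`: must lie in [-1, 1]")
  }
  for (f in c("lui_trait", "plant_herbivore", "herbivore_carnivore",
              "lui_abundance")) {
    if (is.null(coupling[[f]]) || !is.numeric(coupling[[f]])) {
      stop("invalid config field `coupling$", f, "`: must be numeric")
    }
  }
  if (!is.numeric(resid_sd) || resid_sd <= 0) {
    stop("invalid config field `resid_sd`: must be positive")
  }
  if (!is.numeric(assembly_sd) || assembly_sd < 0) {
    stop("invalid config field `assembly_sd`: must be nonnegative")
  }
  structure(cfg, class = "landscape_config")
}

#' Simulate a multi-trophic landscape
#'
#' Generates plant (percent cover), herbivore and carnivore (counts)
#' community time series for every plot of a [landscape_config()], together
#' with species trait tables, the per-plot LUI table and a ground-truth
#' record of every generating parameter (for recovery tests).
#'
#' Plant cover is lognormal and capped at 100 percent per species; arthropod
#' counts are Poisson-lognormal (a Poisson draw around a lognormal
#' intensity), strictly nonnegative integers.
#'
#' @param config a [landscape_config()].
#' @return list of class `landscape`: `plants`, `herbivores`, `carnivores`
#'   (lists of [community_ts()]), `traits` (list of trait data.frames with
#'   metadata, one per group), `lui` (data.frame `plot_id`, `lui`),
#'   `truth` (generating parameters: species scores, loadings, occupancy
#'   draws, couplings, plot-level trait CWMs of the latent scores), and
#'   `config`.
#' @export
simulate_multitrophic <- function(config) {
  if (!inherits(config, "landscape_config")) {
    config <- do.call(landscape_config, as.list(config))
  }
  set.seed(config$seed)
  np <- config$n_plots; ny <- config$n_years
  years <- seq(2008, length.out = ny)
  plot_ids <- sprintf("plot%03d", seq_len(np))
  ta <- config$trait_archetypes
  cpl <- config$coupling

  lui <- stats::runif(np, config$lui_range[1], config$lui_range[2])
  l <- (lui - mean(config$lui_range)) / (diff(config$lui_range) / 2)

  # shared yearly environmental deviate, one per plot-year
  E <- matrix(stats::rnorm(np * ny), np, ny)

  # loadings correlate with the trait score: fast species track the
  # environment more closely
  draw_loadings <- function(score) {
    rho <- config$env_loading$trait_cor
    z <- rho * score + sqrt(1 - rho^2) * stats::rnorm(length(score))
    config$env_loading$mean + config$env_loading$sd * z
  }

  ## ---- plants ----------------------------------------------------------
  Sp <- config$n_plant_species
  e_score <- stats::rnorm(Sp)                      # leaf-economics score
  plant_traits <- data.frame(
    species_id = sprintf("plant%03d", seq_len(Sp)),
    height = round(exp(-0.7 + 0.5 * stats::rnorm(Sp)), 4),
    sla = round(exp(2.8 + ta$sla_slope * e_score + ta$noise * stats::rnorm(Sp)), 4),
    ldmc = round(exp(5.4 + ta$ldmc_slope * e_score + ta$noise * stats::rnorm(Sp)), 4),
    seed_mass = round(exp(0.2 + 0.9 * stats::rnorm(Sp)), 4),
    leaf_n = round(exp(3.0 + 0.3 * e_score + ta$noise * stats::rnorm(Sp)), 4),
    leaf_p = round(exp(0.6 + 0.25 * e_score + ta$noise * stats::rnorm(Sp)), 4),
    stringsAsFactors = FALSE
  )
  attr(plant_traits, "metadata") <- data.frame(
    trait = c("height", "sla", "ldmc", "seed_mass", "leaf_n", "leaf_p"),
    type = "quantitative", transform = "none",
    group = c("size", "leaf", "leaf", "size", "leaf", "leaf"),
    metric_role = "both", stringsAsFactors = FALSE
  )
  occ_base_p <- config$occupancy$base + 0.5 * stats::rnorm(Sp)
  lam_p <- draw_loadings(e_score)
  base_p <- 0.9 + 0.5 * stats::rnorm(Sp)

  plant_out <- sim_group_cover(
    plot_ids, years, plant_traits$species_id, base_p, e_score,
    driver = l, trait_coupling = cpl$lui_trait,
    occ_base = occ_base_p, occ_slope = config$occupancy$lui_slope,
    lui_centred = l, loadings = lam_p, E = E, resid_sd = config$resid_sd,
    counts = FALSE, assembly_sd = config$assembly_sd)

  ## ---- herbivores ------------------------------------------------------
  Sh <- config$n_herbivore_species
  a_score <- stats::rnorm(Sh)                      # morphometric score
  herb_traits <- arthropod_trait_table("herb", Sh, a_score, ta,
                                       guilds = c("herbivore", "omnivore"))
  occ_base_h <- config$occupancy$base + 0.5 * stats::rnorm(Sh)
  lam_h <- draw_loadings(a_score)
  base_h <- 1.4 + 0.5 * stats::rnorm(Sh)
  plant_cwm <- plant_out$cwm_score                 # per plot, standardized

  herb_out <- sim_group_cover(
    plot_ids, years, herb_traits$species_id, base_h, a_score,
    driver = plant_cwm, trait_coupling = cpl$plant_herbivore,
    occ_base = occ_base_h, occ_slope = config$occupancy$lui_slope,
    lui_centred = l, loadings = lam_h, E = E, resid_sd = config$resid_sd,
    counts = TRUE, lui_abundance = cpl$lui_abundance,
    assembly_sd = config$assembly_sd)

  ## ---- carnivores ------------------------------------------------------
  Sc <- config$n_carnivore_species
  c_score <- stats::rnorm(Sc)
  carn_traits <- arthropod_trait_table("carn", Sc, c_score, ta,
                                       guilds = c("predator", "omnivore"))
  occ_base_c <- config$occupancy$base + 0.5 * stats::rnorm(Sc)
  lam_c <- draw_loadings(c_score)
  base_c <- 1.1 + 0.5 * stats::rnorm(Sc)
  herb_cwm <- herb_out$cwm_score

  carn_out <- sim_group_cover(
    plot_ids, years, carn_traits$species_id, base_c, c_score,
    driver = herb_cwm, trait_coupling = cpl$herbivore_carnivore,
    occ_base = occ_base_c, occ_slope = config$occupancy$lui_slope,
    lui_centred = l, loadings = lam_c, E = E, resid_sd = config$resid_sd,
    counts = TRUE, lui_abundance = cpl$lui_abundance,
    assembly_sd = config$assembly_sd)

  structure(
    list(
      plants = plant_out$ts, herbivores = herb_out$ts,
      carnivores = carn_out$ts,
      traits = list(plants = plant_traits, herbivores = herb_traits,
                    carnivores = carn_traits),
      lui = data.frame(plot_id = plot_ids, lui = lui,
                       stringsAsFactors = FALSE),
      truth = list(
        plant_score = e_score, herbivore_score = a_score,
        carnivore_score = c_score,
        env_loadings = list(plants = lam_p, herbivores = lam_h,
                            carnivores = lam_c),
        coupling = cpl, occupancy = config$occupancy,
        lui_centred = l,
        cwm_score = list(plants = plant_out$cwm_score,
                         herbivores = herb_out$cwm_score,
                         carnivores = carn_out$cwm_score)),
      config = config),
    class = "landscape"
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape>", length(x$plants), "plots x", x$config$n_years, "years;",
      x$config$n_plant_species, "plant /", x$config$n_herbivore_species,
      "herbivore /", x$config$n_carnivore_species, "carnivore species\n")
  invisible(x)
}

# one trophic group: species x plots x years abundances.
# driver: per-plot signal (centred LUI for plants, upstream CWM for others);
# trait_coupling * driver_p * score_i shifts composition toward high-score
# species where the driver is high.
sim_group_cover <- function(plot_ids, years, species, base, score, driver,
                            trait_coupling, occ_base, occ_slope, lui_centred,
                            loadings, E, resid_sd, counts,
                            lui_abundance = 0, assembly_sd = 0) {
  S <- length(species); np <- length(plot_ids); ny <- length(years)
  driver[is.na(driver)] <- mean(driver, na.rm = TRUE)
  drv <- if (stats::sd(driver) > 0) as.numeric(scale(driver)) else driver * 0
  # presence: logistic occupancy declining with LUI
  logit_occ <- outer(occ_base, occ_slope * lui_centred, "+")
  present <- matrix(stats::rbinom(S * np, 1, stats::plogis(logit_occ)), S, np)
  # trait sorting: the modelled driver plus plot-level assembly variation
  # that no measured covariate explains
  tilt <- trait_coupling * drv + stats::rnorm(np, 0, assembly_sd)
  # species-by-plot mean log abundance
  mu <- matrix(base, S, np) +
    outer(score, tilt) +
    matrix(lui_abundance * lui_centred, S, np, byrow = TRUE)
  ts <- vector("list", np)
  cwm_score <- numeric(np)
  for (p in seq_len(np)) {
    logx <- mu[, p] + outer(loadings, E[p, ]) +
      matrix(stats::rnorm(S * ny, 0, resid_sd), S, ny)
    x <- exp(logx) * present[, p]
    if (counts) {
      x[] <- stats::rpois(length(x), x)
    } else {
      x <- pmin(x, 100)   # percent cover bound
    }
    dimnames(x) <- list(species, years)
    ts[[p]] <- community_ts(x, plot_id = plot_ids[p], years = years,
                            species = species)
    mean_ab <- rowMeans(x)
    cwm_score[p] <- if (sum(mean_ab) > 0) {
      sum(mean_ab * score) / sum(mean_ab)
    } else NA_real_
  }
  names(ts) <- plot_ids
  list(ts = ts, cwm_score = cwm_score, present = present)
}

arthropod_trait_table <- function(prefix, S, score, ta, guilds) {
  modes <- c("chewing", "sucking", "extraintestinal")
  strata <- c("herb_layer", "ground", "shrub_tree", "unspecific")
  df <- data.frame(
    species_id = sprintf("%s%03d", prefix, seq_len(S)),
    body_size = round(exp(1.3 + ta$arthropod_slope * score +
                            ta$noise * stats::rnorm(S)), 4),
    body_size_var = round(exp(2.2 + 0.3 * stats::rnorm(S)), 4),
    dispersal = sample(seq(0, 1, 0.25), S, replace = TRUE),
    feeding_guild = sample(guilds, S, replace = TRUE),
    feeding_mode = modes[1 + (stats::plogis(score) > stats::runif(S)) +
                           (stats::plogis(-score) > stats::runif(S))],
    stratum = sample(strata, S, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)),
    stringsAsFactors = FALSE
  )
  attr(df, "metadata") <- data.frame(
    trait = c("body_size", "body_size_var", "dispersal", "feeding_guild",
              "feeding_mode", "stratum"),
    type = c("quantitative", "quantitative", "ordinal", "categorical",
             "categorical", "categorical"),
    transform = "none",
    group = c("morpho", "morpho", "morpho", "ecology", "ecology", "ecology"),
    metric_role = c("fd", "fd", "fd", "cwm_pca", "cwm_pca", "cwm_pca"),
    stringsAsFactors = FALSE
  )
  df
}
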