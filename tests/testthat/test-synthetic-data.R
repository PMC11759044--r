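test_that("sample_linear_sem recovers the generating slope on a chain", {
  m <- parse_model("z ~ x\ny ~ z")
  spec <- linear_sem_spec(m, c("x->z" = 0.5, "z->y" = 0.5))
  d <- sample_linear_sem(spec, 1e5, seed = 71)
  b <- coef(lm(scale(z) ~ scale(x), d))[2]
  expect_lt(abs(unname(b) - 0.5), 0.01)
})

test_that("zero coefficients give mutually independent columns", {
  m <- parse_model("z ~ x\ny ~ z")
  spec <- linear_sem_spec(m, c("x->z" = 0, "z->y" = 0))
  d <- sample_linear_sem(spec, 2e4, seed = 72)
  cors <- cor(d)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.03)
})

test_that("sampling is deterministic under a fixed seed", {
  m <- parse_model("z ~ x\ny ~ z + x")
  spec <- linear_sem_spec(m, c("x->z" = 0.4, "z->y" = 0.3, "x->y" = 0.2))
  expect_identical(sample_linear_sem(spec, 500, seed = 73),
                   sample_linear_sem(spec, 500, seed = 73))
})

test_that("spec validation names the offence", {
  m <- parse_model("z ~ x\ny ~ z")
  expect_error(linear_sem_spec(m, c("x->z" = 0.5)), "missing coefficient")
  expect_error(linear_sem_spec(m, c("x->z" = 0.5, "z->y" = 0.5,
                                    "x->y" = 0.1)), "non-edges")
  expect_error(linear_sem_spec(m, c("x->z" = 0.5, "z->y" = 0.5),
                               error_sd = c(z = 1, y = -1)), "positive")
  expect_error(linear_sem_spec(m, c("x->z" = 1.2, "z->y" = 0.5)),
               "standardizable")
})

test_that("empirical variances match the path-tracing covariance", {
  set.seed(77)
  m <- random_dag(5, p_edge = 0.5)
  spec <- random_spec(m)
  d <- sample_linear_sem(spec, 1e5, seed = 78)
  Sigma <- implied_covariance(spec)
  v_emp <- apply(d, 2, var)
  for (v in m$nodes) {
    expect_equal(unname(v_emp[v]), Sigma[v, v], tolerance = 0.05)
  }
  # every endogenous node is standardized to unit variance by construction
  endo <- setdiff(m$nodes, m$exogenous)
  expect_equal(unname(diag(Sigma)[endo]), rep(1, length(endo)))
})

test_that("the landscape has the configured shape and respects bounds", {
  cfg <- landscape_config(n_plots = 150, n_years = 13, seed = 81)
  L <- simulate_multitrophic(cfg)
  expect_length(L$plants, 150)
  expect_length(L$herbivores, 150)
  expect_length(L$carnivores, 150)
  expect_equal(length(L$plants[[1]]$years), 13)
  expect_equal(nrow(L$traits$plants), 40)

  covers <- vapply(L$plants, function(ts) max(ts$abundance), numeric(1))
  expect_true(all(covers >= 0 & covers <= 100))
  counts <- unlist(lapply(L$herbivores, function(ts) ts$abundance))
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
  expect_equal(nrow(L$lui), 150)
  expect_true(all(L$lui$lui >= 0.5 & L$lui$lui <= 3))
})

test_that("the landscape generator is deterministic and flags bad configs", {
  a <- small_landscape(seed = 83)
  b <- small_landscape(seed = 83)
  expect_identical(a$plants[[5]]$abundance, b$plants[[5]]$abundance)
  expect_identical(a$traits$herbivores, b$traits$herbivores)

  expect_error(landscape_config(n_plots = 1), "n_plots")
  expect_error(landscape_config(lui_range = c(2, 2)), "lui_range")
  expect_error(landscape_config(resid_sd = 0), "resid_sd")
  expect_error(landscape_config(coupling = list(lui_trait = 1)),
               "coupling")
})

test_that("identical environmental loadings push synchrony to its ceiling", {
  cfg <- landscape_config(n_plots = 30, n_years = 12, n_plant_species = 15,
                          n_herbivore_species = 8, n_carnivore_species = 6,
                          env_loading = list(mean = 0.8, sd = 0),
                          seed = 87)
  L <- simulate_multitrophic(cfg)
  eta <- vapply(L$plants, function(ts) as.numeric(synchrony_eta_w(ts)),
                numeric(1))
  expect_gt(median(eta, na.rm = TRUE), 0.8)
})

test_that("LUI shifts plant composition toward acquisitive species", {
  L <- small_landscape(seed = 89)
  slope <- coef(lm(scale(L$truth$cwm_score$plants) ~ scale(L$lui$lui)))[2]
  expect_gt(unname(slope), 0.5)
})

test_that("zero trophic coupling decouples herbivore from plant composition", {
  set.seed(91)
  null_cpl <- list(lui_trait = 0.8, plant_herbivore = 0,
                   herbivore_carnivore = 0, lui_abundance = 0)
  pvals <- vapply(1:100, function(i) {
    L <- small_landscape(seed = 9000 + i, n_plots = 30, coupling = null_cpl)
    d <- data.frame(h = L$truth$cwm_score$herbivores,
                    p = L$truth$cwm_score$plants)
    summary(lm(h ~ p, d))$coefficients["p", "Pr(>|t|)"]
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("stronger LUI-trait coupling strictly raises the recovered slope", {
  levels <- c(0.2, 0.5, 0.8)
  mean_slope <- vapply(levels, function(cp) {
    slopes <- vapply(1:50, function(i) {
      L <- small_landscape(seed = 7000 + i, n_plots = 25,
                           coupling = list(lui_trait = cp, plant_herbivore = 0.5,
                                           herbivore_carnivore = 0.5,
                                           lui_abundance = -0.15))
      unname(coef(lm(scale(L$truth$cwm_score$plants) ~ scale(L$lui$lui)))[2])
    }, numeric(1))
    mean(slopes)
  }, numeric(1))
  expect_true(mean_slope[1] < mean_slope[2] && mean_slope[2] < mean_slope[3])
})
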