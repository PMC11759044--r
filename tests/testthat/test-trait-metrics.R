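simple_meta <- function(traits, types, transforms = "none") {
  data.frame(trait = traits, type = types,
             transform = rep(transforms, length.out = length(traits)),
             stringsAsFactors = FALSE)
}

test_that("prepare_traits averages records, takes modes, applies log", {
  rec <- data.frame(
    species_id = c("s1", "s1", "s2", "s1", "s2", "s2"),
    trait = c("sla", "sla", "sla", "guild", "guild", "guild"),
    value = c("20", "30", "10", "herbivore", "predator", "predator"),
    stringsAsFactors = FALSE)
  md <- simple_meta(c("sla", "guild"), c("quantitative", "categorical"))
  tt <- prepare_traits(rec, md)
  expect_equal(tt$sla, c(25, 10))
  expect_equal(tt$guild, c("herbivore", "predator"))

  md_log <- simple_meta("x", "quantitative", "log")
  expect_error(
    prepare_traits(data.frame(species_id = "s1", trait = "x", value = "0"),
                   md_log),
    "nonpositive")
  expect_equal(
    prepare_traits(data.frame(species_id = "s1", trait = "x", value = "10"),
                   md_log)$x, log(10))

  tie <- data.frame(species_id = c("s1", "s1"), trait = "guild",
                    value = c("a", "b"), stringsAsFactors = FALSE)
  expect_error(prepare_traits(tie, simple_meta("guild", "categorical")),
               "tied modal")
})

test_that("prepare_traits equals a groupwise-mean oracle on random records", {
  set.seed(21)
  rec <- data.frame(
    species_id = sample(paste0("s", 1:6), 40, replace = TRUE),
    trait = sample(c("a", "b"), 40, replace = TRUE),
    value = as.character(round(runif(40, 1, 9), 3)),
    stringsAsFactors = FALSE)
  tt <- prepare_traits(rec, simple_meta(c("a", "b"),
                                        c("quantitative", "quantitative")))
  for (sp in tt$species_id) {
    for (tr in c("a", "b")) {
      sub <- rec[rec$species_id == sp & rec$trait == tr, ]
      expected <- if (nrow(sub)) mean(as.numeric(sub$value)) else NA_real_
      expect_equal(tt[tt$species_id == sp, tr], expected)
    }
  }
})

test_that("gower distances hit their endpoints", {
  tt <- data.frame(species_id = c("s1", "s2", "s3"),
                   x = c(1, 1, 5), y = c(2, 2, 7), stringsAsFactors = FALSE)
  attr(tt, "metadata") <- simple_meta(c("x", "y"),
                                      c("quantitative", "quantitative"))
  D <- gower_balanced(tt)
  expect_equal(D$d["s1", "s2"], 0)
  expect_equal(D$d["s1", "s3"], 1)  # both traits at range endpoints
  expect_true(all(abs(D$d - t(D$d)) < 1e-15))
  expect_equal(unname(diag(D$d)), rep(0, 3))
})

test_that("balanced mode equalises per-trait mean contributions", {
  set.seed(31)
  tt <- data.frame(species_id = paste0("s", 1:6),
                   a = rnorm(6), b = 10 * rnorm(6),
                   g = sample(c("u", "v", "w"), 6, replace = TRUE),
                   stringsAsFactors = FALSE)
  attr(tt, "metadata") <- simple_meta(c("a", "b", "g"),
                                      c("quantitative", "quantitative",
                                        "categorical"))
  D <- gower_balanced(tt, "balanced")
  expect_equal(max(D$mean_contribution) - min(D$mean_contribution), 0,
               tolerance = 1e-10)
  # direct recomputation of the contributions from the output
  expect_equal(sum(D$weights), 1, tolerance = 1e-12)
})

test_that("equal-weight quantitative Gower matches cluster::daisy", {
  skip_if_not_installed("cluster")
  set.seed(8)
  tt <- data.frame(species_id = paste0("s", 1:7),
                   a = rnorm(7), b = rexp(7), c = runif(7),
                   stringsAsFactors = FALSE)
  attr(tt, "metadata") <- simple_meta(c("a", "b", "c"),
                                      rep("quantitative", 3))
  D <- gower_balanced(tt, "equal")
  ref <- as.matrix(cluster::daisy(tt[, c("a", "b", "c")], metric = "gower"))
  expect_equal(unname(D$d), unname(ref), tolerance = 1e-10)
})

test_that("cwm matches the weighted-mean oracle and handles categories", {
  tt <- data.frame(species_id = c("s1", "s2"), sla = c(20, 40),
                   guild = c("herbivore", "predator"), stringsAsFactors = FALSE)
  attr(tt, "metadata") <- simple_meta(c("sla", "guild"),
                                      c("quantitative", "categorical"))
  out <- cwm(c(s1 = 1, s2 = 0), tt)
  expect_equal(out[["sla"]], 20)
  out2 <- cwm(c(s1 = 0.5, s2 = 0.5), tt)
  expect_equal(out2[["guild.herbivore"]], 0.5)
  expect_equal(out2[["guild.predator"]], 0.5)
  expect_equal(out2[["guild.herbivore"]] + out2[["guild.predator"]], 1)

  set.seed(13)
  p <- runif(8); p <- p / sum(p); names(p) <- paste0("s", 1:8)
  tr <- rnorm(8)
  tt2 <- data.frame(species_id = names(p), val = tr, stringsAsFactors = FALSE)
  attr(tt2, "metadata") <- simple_meta("val", "quantitative")
  expect_equal(unname(cwm(p, tt2)["val"]), unname(oracle_cwm(p, tr)),
               tolerance = 1e-12)
})

test_that("rao_q matches its double-loop oracle and its bounds", {
  expect_equal(rao_q(c(0.5, 0.5), matrix(c(0, 1, 1, 0), 2)), 0.5)
  expect_equal(rao_q(c(0.3, 0.7), matrix(0, 2, 2)), 0)

  set.seed(17)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    p <- runif(n); p <- p / sum(p)
    D <- matrix(runif(n * n), n, n); D <- (D + t(D)) / 2; diag(D) <- 0
    expect_equal(rao_q(p, D), oracle_rao(p, D), tolerance = 1e-12)
    expect_lte(rao_q(p, D), max(D))
    perm <- sample(n)
    expect_equal(rao_q(p[perm], D[perm, perm]), rao_q(p, D), tolerance = 1e-12)
  }
  expect_error(rao_q(c(0.5, 0.5), matrix(0, 3, 3)), "mismatch")
})

test_that("dominant-trait PCA diagonalises the correlation matrix", {
  set.seed(23)
  X <- matrix(rnorm(150 * 6), 150, 6)
  X[, 2] <- X[, 1] * 0.5 + rnorm(150, sd = 0.4)
  colnames(X) <- paste0("t", 1:6)
  ax <- dominant_trait_axes(X, n_axes = 6)
  R <- cor(X)
  # loadings diagonalize R with the eigenvalues on the diagonal
  Dg <- t(ax$loadings) %*% R %*% ax$loadings
  expect_equal(unname(Dg), diag(ax$eigenvalues), tolerance = 1e-10)
  expect_equal(unname(colMeans(ax$scores)), rep(0, 6), tolerance = 1e-12)
  # score covariance is diagonal with the eigenvalues
  expect_equal(unname(cov(ax$scores)), diag(ax$eigenvalues), tolerance = 1e-10)
  # explained variance agrees with prcomp on standardized data
  pr <- prcomp(X, scale. = TRUE)
  expect_equal(ax$explained,
               (pr$sdev^2 / sum(pr$sdev^2))[1:6], tolerance = 1e-10)
})

test_that("degenerate PCA geometries give the expected explained variance", {
  z <- rnorm(20)
  X <- cbind(a = z, b = 2 * z + 1)
  ax <- dominant_trait_axes(X, n_axes = 1)
  expect_equal(ax$explained, 1, tolerance = 1e-12)
  expect_error(dominant_trait_axes(X, n_axes = 2), "rank")

  th <- seq(0, 2 * pi, length.out = 9)[-9]
  Y <- cbind(a = cos(th), b = sin(th))  # exactly uncorrelated columns
  ax2 <- dominant_trait_axes(Y, n_axes = 2)
  expect_equal(ax2$explained, c(0.5, 0.5), tolerance = 1e-10)
})

test_that("the sign anchor orients loadings deterministically", {
  set.seed(29)
  X <- matrix(rnorm(60 * 4), 60, 4)
  colnames(X) <- c("sla", "ldmc", "height", "seed_mass")
  ax <- dominant_trait_axes(X, n_axes = 2, anchor = "sla")
  expect_true(all(ax$loadings["sla", ] >= 0))
  ax2 <- dominant_trait_axes(X, n_axes = 2)
  for (a in 1:2) {
    top <- which.max(abs(ax2$loadings[, a]))
    expect_gte(ax2$loadings[top, a], 0)
  }
})
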