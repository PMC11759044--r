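test_that("path enumeration covers chains, diamonds and random DAGs", {
  chain <- parse_model("z ~ x\ny ~ z")
  expect_equal(enumerate_paths(chain, "x", "y"), list(c("x", "z", "y")))

  diamond <- parse_model("a ~ x\nb ~ x\ny ~ a + b")
  paths <- enumerate_paths(diamond, "x", "y")
  expect_length(paths, 2)
  expect_equal(paths[[1]], c("x", "a", "y"))  # lexicographic order

  expect_error(enumerate_paths(chain, "x", "x"), "differ")

  set.seed(41)
  for (rep in 1:40) {
    m <- random_dag(sample(4:8, 1), p_edge = 0.5)
    x <- m$nodes[1]; y <- m$nodes[length(m$nodes)]
    got <- enumerate_paths(m, x, y)
    want <- oracle_paths(m, x, y)
    expect_setequal(vapply(got, paste, "", collapse = ">"),
                    vapply(want, paste, "", collapse = ">"))
  }
})

test_that("direct/indirect/total effects follow the product-and-sum rules", {
  m <- parse_model("z ~ x\ny ~ z")
  B <- matrix(0, 3, 3, dimnames = list(c("x", "z", "y"), c("x", "z", "y")))
  B["x", "z"] <- 0.5; B["z", "y"] <- 0.4
  f <- fake_fitted(m, B)
  pe <- path_effects(f, "x", "y")
  expect_equal(pe$direct, 0)
  expect_equal(pe$indirect, 0.2)
  expect_equal(pe$total, 0.2)

  m2 <- parse_model("y ~ x")
  B2 <- matrix(c(0, 0, 0.3, 0), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  pe2 <- path_effects(fake_fitted(m2, B2), "x", "y")
  expect_equal(pe2$direct, 0.3)
  expect_equal(pe2$total, 0.3)
})

test_that("totals agree with the (I - B)^-1 closed form on random SEMs", {
  set.seed(47)
  for (rep in 1:40) {
    m <- random_dag(sample(4:10, 1), p_edge = 0.4)
    B <- matrix(0, length(m$nodes), length(m$nodes),
                dimnames = list(m$nodes, m$nodes))
    for (i in seq_len(nrow(m$edges))) {
      B[m$edges[i, 1], m$edges[i, 2]] <- runif(1, -0.8, 0.8)
    }
    f <- fake_fitted(m, B)
    Tm <- total_effect_matrix(B)
    for (x in m$nodes) {
      for (y in setdiff(m$nodes, x)) {
        expect_equal(path_effects(f, x, y)$total, Tm[x, y], tolerance = 1e-10)
      }
    }
  }
})

test_that("mediator effects partition the indirect effect", {
  m <- parse_model("z ~ x\ny ~ z")
  B <- matrix(0, 3, 3, dimnames = list(c("x", "z", "y"), c("x", "z", "y")))
  B["x", "z"] <- 0.5; B["z", "y"] <- 0.4
  f <- fake_fitted(m, B)
  expect_equal(mediator_effect(f, "x", "y", "z"),
               path_effects(f, "x", "y")$indirect)

  dia <- parse_model("a ~ x\nb ~ x\ny ~ a + b")
  Bd <- matrix(0, 4, 4, dimnames = list(c("x", "a", "b", "y"),
                                        c("x", "a", "b", "y")))
  Bd["x", "a"] <- 0.5; Bd["x", "b"] <- -0.3
  Bd["a", "y"] <- 0.4; Bd["b", "y"] <- 0.6
  fd <- fake_fitted(dia, Bd)
  expect_equal(mediator_effect(fd, "x", "y", "a") +
                 mediator_effect(fd, "x", "y", "b"),
               path_effects(fd, "x", "y")$indirect, tolerance = 1e-12)
  expect_error(mediator_effect(fd, "x", "y", "nope"), "not a model node")

  # membership oracle on random DAGs
  set.seed(53)
  for (rep in 1:20) {
    m <- random_dag(6, p_edge = 0.5)
    k <- length(m$nodes)
    if (k < 3) next
    B <- matrix(0, k, k, dimnames = list(m$nodes, m$nodes))
    for (i in seq_len(nrow(m$edges))) {
      B[m$edges[i, 1], m$edges[i, 2]] <- runif(1, -0.7, 0.7)
    }
    f <- fake_fitted(m, B)
    x <- m$nodes[1]; y <- m$nodes[k]; z <- m$nodes[ceiling(k / 2)]
    if (z %in% c(x, y)) next
    want <- 0
    for (p in oracle_paths(m, x, y)) {
      if (z %in% p) {
        prod <- 1
        for (k in seq_len(length(p) - 1)) prod <- prod * B[p[k], p[k + 1]]
        want <- want + prod
      }
    }
    expect_equal(mediator_effect(f, x, y, z), want, tolerance = 1e-12)
  }
})

test_that("effects of a node on its ancestors are zero", {
  m <- parse_model("z ~ x\ny ~ z")
  B <- matrix(0, 3, 3, dimnames = list(c("x", "z", "y"), c("x", "z", "y")))
  B["x", "z"] <- 0.5; B["z", "y"] <- 0.4
  f <- fake_fitted(m, B)
  expect_equal(path_effects(f, "y", "x")$total, 0)
  expect_equal(path_effects(f, "z", "x")$total, 0)
})

test_that("bootstrap effects are reproducible and respect their contract", {
  set.seed(59)
  m <- parse_model("z ~ x\ny ~ z")
  spec <- linear_sem_spec(m, c("x->z" = 0.5, "z->y" = 0.5))
  d <- sample_linear_sem(spec, 400)
  q <- list(list(source = "x", target = "y", type = "indirect"))
  e1 <- bootstrap_effects(m, d, q, n_boot = 300, seed = 7)
  e2 <- bootstrap_effects(m, d, q, n_boot = 300, seed = 7)
  expect_identical(e1, e2)
  e3 <- bootstrap_effects(m, d, q, n_boot = 300, seed = 8)
  expect_false(identical(e1$lower, e3$lower))

  expect_true(e1$lower <= e1$estimate && e1$estimate <= e1$upper)
  expect_true(e1$lower < 0.25 && 0.25 < e1$upper)  # covers the truth here
  expect_error(bootstrap_effects(m, d, q, n_boot = 100), "at least 200")

  ep <- bootstrap_effects(m, d, q, n_boot = 300, seed = 7,
                          interval = "percentile")
  expect_true(ep$lower <= ep$estimate && ep$estimate <= ep$upper)
})

test_that("bootstrap CI width shrinks roughly like 1/sqrt(n)", {
  set.seed(61)
  m <- parse_model("z ~ x\ny ~ z")
  spec <- linear_sem_spec(m, c("x->z" = 0.5, "z->y" = 0.5))
  q <- list(list(source = "x", target = "y", type = "indirect"))
  widths <- vapply(c(250, 1000, 4000), function(n) {
    d <- sample_linear_sem(spec, n)
    e <- bootstrap_effects(m, d, q, n_boot = 250, seed = 5)
    e$upper - e$lower
  }, numeric(1))
  expect_true(widths[1] > widths[2] && widths[2] > widths[3])
  expect_equal(widths[1] / widths[3], 4, tolerance = 0.5)
})
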