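test_that("standardize centres and scales, and is idempotent on z-scores", {
  s <- standardize(data.frame(x = c(1, 2, 3)))
  expect_equal(mean(s$data$x), 0)
  expect_equal(sd(s$data$x), 1)

  set.seed(2)
  d <- data.frame(a = rnorm(50), b = rexp(50))
  z <- standardize(d)$data
  z2 <- standardize(z)$data
  expect_equal(z2, z, tolerance = 1e-12)

  expect_error(standardize(data.frame(ok = 1:3, k = c(2, 2, 2))), "constant")
  expect_error(standardize(data.frame(ch = letters[1:3])), "non-numeric")
})

test_that("fit_local recovers generating coefficients and flags degeneracies", {
  m <- parse_model("y ~ x")
  set.seed(4)
  x <- rnorm(1e4)
  d <- data.frame(x = x, y = 0.7 * x + rnorm(1e4, sd = 0.1))
  lf <- fit_local(m, standardize(d)$data)
  cf <- lf$equations$y$coefficients
  slope <- cf[cf$term == "x", ]
  expect_lt(abs(slope$estimate - 0.7 * sd(d$x) / sd(d$y)), 3 * slope$se)

  # parentless nodes yield no equation
  expect_named(lf$equations, "y")

  # perfect fit warns about zero residual variance
  d2 <- data.frame(x = rnorm(20))
  d2$y <- d2$x
  expect_warning(fit_local(m, d2), "zero residual variance")

  # collinear parents are named
  m3 <- parse_model("y ~ a + b")
  d3 <- data.frame(a = rnorm(30))
  d3$b <- 2 * d3$a
  d3$y <- d3$a + rnorm(30)
  expect_error(fit_local(m3, d3), "collinear")
})

test_that("slopes on pre-standardized data equal classical standardized betas", {
  set.seed(6)
  d <- data.frame(x = rexp(200), w = runif(200))
  d$y <- 1.5 * d$x - 2 * d$w + rnorm(200)
  m <- parse_model("y ~ x + w")
  std_fit <- fit_local(m, standardize(d)$data)$equations$y$coefficients
  raw_fit <- fit_local(m, d)$equations$y$coefficients
  for (term in c("x", "w")) {
    beta_raw <- raw_fit$estimate[raw_fit$term == term]
    expect_equal(std_fit$estimate[std_fit$term == term],
                 beta_raw * sd(d[[term]]) / sd(d$y), tolerance = 1e-10)
  }
})

test_that("d-separation p-value equals the textbook partial t-test", {
  set.seed(9)
  n <- 40
  z <- rnorm(n); x <- rnorm(n)
  y <- 0.5 * z + rnorm(n)
  d <- data.frame(x = x, z = z, y = y)
  claims <- basis_set(parse_model("z ~ x\ny ~ z"))
  res <- dsep_tests(claims, d)
  # hand-rolled: t-test of x's coefficient in lm(y ~ z + x)
  X <- cbind(1, z, x)
  b <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% b
  s2 <- sum(r^2) / (n - 3)
  se <- sqrt(s2 * solve(t(X) %*% X)[3, 3])
  t_stat <- b[3] / se
  expect_equal(res$p, 2 * pt(-abs(t_stat), df = n - 3), tolerance = 1e-10)
})

test_that("d-sep p-values are uniform when the model is true", {
  set.seed(14)
  m <- parse_model("z ~ x\nw ~ z\ny ~ w")
  spec <- linear_sem_spec(m, c("x->z" = 0.5, "z->w" = 0.5, "w->y" = 0.5))
  claims <- basis_set(m)
  pvals <- replicate(70, {
    d <- sample_linear_sem(spec, 150)
    dsep_tests(claims, d)$p
  })
  ks <- ks.test(as.numeric(pvals), "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("Fisher's C has its closed-form special cases", {
  expect_equal(fishers_c(numeric(0))$p_value, 1)
  expect_equal(fishers_c(numeric(0))$C, 0)
  fc <- fishers_c(rep(1, 4))
  expect_equal(fc$C, 0)
  expect_equal(fc$p_value, 1)
  fc2 <- fishers_c(exp(-1))
  expect_equal(fc2$C, 2)
  expect_equal(fc2$df, 2)
  expect_equal(fc2$p_value, exp(-1), tolerance = 1e-12)
  expect_error(fishers_c(c(0.5, 0)), "0, 1")
})

test_that("whole-model AICc follows the C + 2K n/(n-K-1) convention", {
  ic <- sem_aicc(C = 10, K = 5, n = 100)
  expect_equal(ic$AIC, 20)
  expect_equal(ic$AICc, 10 + 2 * 5 * 100 / 94)
  big <- sem_aicc(C = 10, K = 5, n = 1e9)
  expect_equal(big$AICc, big$AIC, tolerance = 1e-6)
  expect_error(sem_aicc(10, 5, 6), "exceed")
})

test_that("select_terms enumerates submodels and applies the odds rule", {
  set.seed(16)
  n <- 120
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$y <- 0.6 * d$a + rnorm(n)
  sel <- select_terms("y", c("a", "b", "c"), d)
  expect_equal(nrow(sel$submodels), 8)
  expect_equal(sum(sel$submodels$weight), 1, tolerance = 1e-12)
  expect_equal(sel$terms$evidence_ratio,
               sel$terms$sum_weight / (1 - sel$terms$sum_weight))
  expect_identical(sel$terms$retained, sel$terms$evidence_ratio > 2.72)
  expect_true("a" %in% sel$retained)

  # hand enumeration with lm/AIC as an independent oracle
  terms <- c("a", "b", "c")
  aicc_hand <- numeric(8)
  combos <- expand.grid(a = c(FALSE, TRUE), b = c(FALSE, TRUE),
                        c = c(FALSE, TRUE))
  for (i in 1:8) {
    inc <- terms[unlist(combos[i, ])]
    f <- if (length(inc)) reformulate(inc, "y") else y ~ 1
    K <- length(inc) + 2
    aicc_hand[i] <- AIC(lm(f, d)) + 2 * K * (K + 1) / (n - K - 1)
  }
  w_hand <- exp(-(aicc_hand - min(aicc_hand)) / 2)
  w_hand <- w_hand / sum(w_hand)
  s_hand <- vapply(1:3, function(j) sum(w_hand[combos[[j]]]), numeric(1))
  expect_equal(sel$terms$sum_weight, s_hand, tolerance = 1e-8)
  expect_error(select_terms("y", paste0("t", 1:21), d), "20")
})

test_that("fit_sem assembles coefficients, fit statistics and covariances", {
  set.seed(18)
  m <- parse_model("z ~ x\nw ~ z\ny ~ w + z")
  spec <- linear_sem_spec(m, c("x->z" = 0.6, "z->w" = 0.5, "w->y" = 0.4,
                               "z->y" = 0.3))
  d <- sample_linear_sem(spec, 400)
  f <- fit_sem(m, d)
  expect_s3_class(f, "fitted_sem")
  expect_equal(f$df, 2 * nrow(f$basis))
  expect_equal(f$df %% 2, 0)
  expect_true(f$p_value >= 0 && f$p_value <= 1)
  expect_true(all(f$r2 >= 0 & f$r2 <= 1))
  expect_equal(f$K, 4 + 2 * 3)  # 4 slopes, 3 equations
  expect_equal(f$AICc, f$C + 2 * f$K * f$n / (f$n - f$K - 1))

  # declaring no correlated errors must not change anything
  m_ce <- parse_model(paste(serialize_model(m), "", sep = "\n"))
  f2 <- fit_sem(m_ce, d)
  expect_equal(f2$C, f$C)
  expect_equal(f2$coefficients$estimate, f$coefficients$estimate)

  # correlated-error pair: partial correlation of residuals reported, claim dropped
  m3 <- parse_model("z ~ x\ny ~ z\nx ~~ y")
  f3 <- fit_sem(m3, d)
  expect_equal(nrow(f3$basis), 0)
  expect_true(f3$saturated)
  expect_equal(nrow(f3$correlated_errors), 1)
  expect_true(abs(f3$correlated_errors$r) <= 1)
})

test_that("reduction drops noise edges and the reduced fit is reported", {
  set.seed(26)
  n <- 500
  d <- data.frame(lui = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  d$mid <- 0.6 * d$lui + rnorm(n, sd = 0.8)
  d$out <- 0.7 * d$mid + rnorm(n, sd = 0.7)
  m <- parse_model("mid ~ lui + noise1\nout ~ mid + noise2 + lui")
  f <- fit_sem(m, d, reduce = TRUE)
  expect_false(is.null(f$selection))
  expect_false(is.null(f$apriori))
  kept <- paste(f$model$edges[, 1], f$model$edges[, 2])
  expect_true("lui mid" %in% kept)
  expect_true("mid out" %in% kept)
  expect_false("noise1 mid" %in% kept)
})

test_that("hand-rolled Breusch-Pagan and VIF agree with lmtest and car", {
  skip_if_not_installed("lmtest")
  skip_if_not_installed("car")
  set.seed(33)
  n <- 150
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- d$x1 + d$x2 + rnorm(n, sd = abs(d$x1) + 0.3)
  fit <- lm(y ~ x1 + x2, d)
  expect_equal(stabsem:::breusch_pagan(residuals(fit), d, c("x1", "x2")),
               unname(lmtest::bptest(fit)$p.value), tolerance = 1e-8)
  expect_equal(unname(stabsem:::vif_values(d, c("x1", "x2"))),
               unname(car::vif(fit)), tolerance = 1e-8)
})
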