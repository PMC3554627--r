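# Univariate association tests and composite-score / multivariate
# comparators.

test_that("linear test equals the correlation t test", {
  set.seed(1)
  g <- rbinom(300, 2, .5)
  y <- .2 * g + rnorm(300)
  res <- linear_test(y, g)
  ct <- cor.test(y, g)        # independent route
  expect_equal(res$p, ct$p.value, tolerance = 1e-10)
  expect_equal(res$df, unname(ct$parameter))

  perfect <- linear_test(as.numeric(g), g)
  expect_equal(perfect$estimate, 1)
  expect_lt(perfect$p, 1e-200)

  expect_error(linear_test(y, rep(1, 300)), "monomorphic")
  expect_error(linear_test(y[1:2], g[1:2]), "at least 3")
})

test_that("null linear p-values are uniform", {
  set.seed(2)
  n <- 200; n_sim <- 10000
  Y <- matrix(rnorm(n * n_sim), n, n_sim)
  g <- rbinom(n, 2, .5)
  p <- tates:::linear_pvalues(Y, g)$p
  expect_gt(ks.test(p, "punif")$p.value, .01)
})

test_that("logistic Wald test matches glm and is calibrated under the null", {
  set.seed(3)
  g <- rbinom(2000, 2, .5)
  # complete separation is a hard error, not a tiny p-value
  expect_error(suppressWarnings(logistic_test(as.numeric(g >= 1), g)),
               "converge")
  y <- rbinom(2000, 1, plogis(-2 + 3 * g))
  expect_lt(logistic_test(y, g)$p, 1e-50)

  y2 <- rbinom(2000, 1, .5)
  res <- logistic_test(y2, g)
  fit <- glm(y2 ~ g, family = binomial())   # formula interface as oracle
  want <- summary(fit)$coefficients["g", "Pr(>|z|)"]
  expect_equal(res$p, want, tolerance = 1e-8)

  set.seed(4)
  n_sim <- 2000
  p <- replicate(n_sim, {
    gg <- rbinom(300, 2, .5)
    logistic_test(rbinom(300, 1, .5), gg)$p
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, .01)
})

test_that("proportional-odds fit matches the reference ML implementation", {
  skip_if_not_installed("MASS")
  set.seed(5)
  for (i in 1:4) {
    g <- rbinom(1500, 2, .5)
    lat <- c(0, .08, .15, .3)[i] * g + rnorm(1500)
    y <- 1 + findInterval(lat, qnorm(c(1, 2) / 3))
    res <- ordinal_test(y, g)
    fit <- MASS::polr(factor(y, ordered = TRUE) ~ g, Hess = TRUE)
    tv <- summary(fit)$coefficients["g", "t value"]
    expect_equal(res$estimate, unname(coef(fit)["g"]), tolerance = 1e-3)
    expect_equal(res$p, 2 * pnorm(-abs(tv)), tolerance = 1e-3)
  }
})

test_that("ordinal test reduces to logistic with two categories and is calibrated", {
  set.seed(6)
  g <- rbinom(1500, 2, .5)
  y <- as.numeric(.15 * g + rnorm(1500) > 0)
  expect_equal(ordinal_test(y, g)$p, logistic_test(y, g)$p, tolerance = 1e-5)

  strong <- 1 + findInterval(.5 * g + rnorm(1500), qnorm(c(1, 2) / 3))
  expect_lt(ordinal_test(strong, g)$p, 1e-20)

  expect_warning(ordinal_test(c(1, 1, 3, 3, 1, 3, 3, 1), rep(0:1, 4),
                              categories = 1:3), "collapsed")

  set.seed(7)
  p <- replicate(1000, {
    gg <- rbinom(300, 2, .5)
    yy <- 1 + findInterval(rnorm(300), qnorm(c(1, 2) / 3))
    ordinal_test(yy, gg)$p
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, .01)
})

test_that("sum score modes agree without missingness and pool available data", {
  set.seed(8)
  Y <- matrix(rnorm(200 * 5), 200, 5)
  g <- rbinom(200, 2, .5)
  a <- sumscore_test(Y, g, mode = "complete")
  b <- sumscore_test(Y, g, mode = "weighted")
  expect_equal(a$p, b$p, tolerance = 1e-12)   # scale invariance of the t test

  # identical copies reduce to the single phenotype
  Y2 <- matrix(rep(Y[, 1], 3), ncol = 3)
  expect_equal(sumscore_test(Y2, g)$p, linear_test(Y[, 1], g)$p,
               tolerance = 1e-12)

  # weighted mode scores a partially observed subject by its mean
  Y3 <- Y; Y3[1, 2] <- NA
  scores <- rowMeans(Y3, na.rm = TRUE)
  expect_equal(scores[1], mean(Y[1, -2]))
  expect_equal(sumscore_test(Y3, g, mode = "weighted")$p,
               linear_test(scores, g)$p, tolerance = 1e-12)
  # complete mode drops that subject
  expect_equal(sumscore_test(Y3, g, mode = "complete")$p,
               linear_test(rowSums(Y3), g)$p, tolerance = 1e-12)
})

test_that("factor scores reduce to sum scores under exchangeability", {
  set.seed(9)
  n <- 400; m <- 6
  f <- rnorm(n)
  Y <- sapply(rep(.7, m), function(l) l * f + sqrt(1 - l^2) * rnorm(n))
  g <- rbinom(n, 2, .5)
  R_ex <- matrix(.49, m, m); diag(R_ex) <- 1
  # equal loadings: Thompson scores proportional to the standardised sum
  got <- factorscore_test(Y, g, R = R_ex)
  want <- linear_test(rowSums(scale(Y)), g)
  expect_equal(got$p, want$p, tolerance = 1e-6)

  expect_equal(factorscore_test(Y[, 1, drop = FALSE], g)$p,
               linear_test(Y[, 1], g)$p, tolerance = 1e-12)

  heywood <- matrix(c(1, .9, .9, .9, 1, .5, .9, .5, 1), 3)
  expect_warning(factorscore_test(matrix(rnorm(300), 100, 3), rbinom(100, 2, .5),
                                  R = heywood), "Heywood")
})

test_that("single-genotype MANOVA equals the multiple-correlation F test", {
  set.seed(10)
  n <- 500; m <- 4
  Y <- matrix(rnorm(n * m), n, m)
  Y[, 1] <- Y[, 1] + .1 * rbinom(n, 2, .5)
  g <- rbinom(n, 2, .5)

  # m = 1 reduces exactly to the linear test
  expect_equal(manova_test(Y[, 1, drop = FALSE], g)$p, linear_test(Y[, 1], g)$p,
               tolerance = 1e-10)

  # Wilks'-lambda canonical-correlation oracle on the same data
  res <- manova_test(Y, g)
  fit <- summary(manova(lm(Y ~ g)), test = "Wilks")
  expect_equal(res$p, fit$stats["g", "Pr(>F)"], tolerance = 1e-8)

  # genotype exactly in the phenotype span
  g2 <- Y[, 1] + 2 * Y[, 2]
  expect_lt(manova_test(Y, g2)$p, 1e-200)

  expect_error(manova_test(Y[1:4, ], g[1:4]), "N > m")
  expect_error(manova_test(cbind(Y, Y[, 1]), g), "singular")
})

test_that("tests are invariant to affine rescaling of continuous phenotypes", {
  set.seed(11)
  n <- 300
  Y <- matrix(rnorm(n * 3), n, 3)
  g <- rbinom(n, 2, .5)
  Y2 <- sweep(sweep(Y, 2, c(2, .5, 10), "*"), 2, c(-1, 3, 0), "+")
  expect_equal(linear_test(Y2[, 1], g)$p, linear_test(Y[, 1], g)$p,
               tolerance = 1e-12)
  expect_equal(manova_test(Y2, g)$p, manova_test(Y, g)$p, tolerance = 1e-9)
  expect_equal(factorscore_test(Y2, g)$p, factorscore_test(Y, g)$p,
               tolerance = 1e-9)
})

test_that("measurement levels route to the matching univariate test", {
  set.seed(12)
  n <- 800
  g <- rbinom(n, 2, .5)
  x <- cbind(cont = rnorm(n),
             dich = as.numeric(rnorm(n) > 0),
             ordi = 1 + findInterval(rnorm(n), qnorm(c(1, 2) / 3)))
  tbl <- phenotype_table(x, levels = c("continuous", "dichotomous", "ordinal"))
  out <- univariate_tests(tbl, g)
  expect_equal(out$test_tag, c("linear", "logistic", "ordinal"))
  expect_equal(unname(out$p["cont"]), linear_test(x[, 1], g)$p)
  expect_true(all(out$p > 0 & out$p <= 1))
})
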