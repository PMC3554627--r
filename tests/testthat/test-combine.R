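# The trait-based combiner and the comparator combination tests.

test_that("effective number matches its defining eigenvalue formula", {
  expect_equal(effective_number(diag(7)), 7)
  expect_equal(effective_number(matrix(1, 20, 20)), 1)
  # 2x2 with off-diagonal .5: eigenvalues 1 +/- .5, so 2 - .5 = 1.5
  expect_equal(effective_number(matrix(c(1, .5, .5, 1), 2)), 1.5)
  expect_error(effective_number(matrix(c(1, .2, .5, 1), 2)), "symmetric")

  set.seed(101)
  for (d in 2:6) {
    R <- random_corr(d)
    expect_equal(effective_number(R), oracle_effective_number(R),
                 tolerance = 1e-10)
  }
})

test_that("trait-based p-value reproduces the enumerated minimum weighted p", {
  # identity correlation: weights m_e/m_ej = m/j, the Simes weights
  res <- tates(c(.04, .9), diag(2))
  expect_equal(res$p_t, .08)
  expect_equal(res$argmin_j, 1L)
  expect_equal(res$m_e, 2)

  # single phenotype: no correction
  expect_equal(tates(.3, matrix(1, 1, 1))$p_t, .3)

  # perfectly correlated phenotypes carry one unit of information
  p <- runif(20, .01, .99)
  expect_equal(tates(p, matrix(1, 20, 20))$p_t, min(p))

  set.seed(7)
  for (i in 1:10) {
    m <- sample(2:8, 1)
    p <- runif(m, 1e-4, 1)
    rho <- random_corr(m)
    expect_equal(tates(p, rho)$p_t, oracle_tates(p, rho), tolerance = 1e-12)
  }
})

test_that("trait-based p-value equals Simes under independence", {
  set.seed(11)
  for (i in 1:20) {
    m <- sample(1:15, 1)
    p <- runif(m, 1e-5, 1)
    expect_equal(tates(p, diag(m))$p_t, simes(p), tolerance = 1e-12)
  }
})

test_that("trait-based p-value is invariant to phenotype reordering", {
  set.seed(21)
  for (i in 1:10) {
    m <- 8
    p <- runif(m)
    rho <- random_corr(m)
    perm <- sample(m)
    expect_equal(tates(p[perm], rho[perm, perm])$p_t, tates(p, rho)$p_t,
                 tolerance = 1e-12)
  }
})

test_that("trait-based p-value scales multiplicatively and respects bounds", {
  set.seed(31)
  for (i in 1:10) {
    m <- 10
    p <- runif(m, .01, 1)
    rho <- random_corr(m)
    base <- tates(p, rho)
    # weights depend only on rho, so shrinking all p shrinks P_T linearly
    for (cc in c(.5, .1)) {
      expect_equal(tates(cc * p, rho)$p_t, cc * base$p_t, tolerance = 1e-12)
    }
    expect_lte(base$p_t, max(p))
    expect_gte(base$p_t, min(p) * base$m_e / m)
    expect_equal(base$univariate_ps, setNames(p, paste0("P", 1:m)))
  }
})

test_that("tied p-values are combined deterministically", {
  rho <- random_corr(4)
  p <- c(.2, .2, .2, .2)
  a <- tates(p, rho); b <- tates(rev(p), rho)
  expect_equal(a$p_t, b$p_t)
  expect_identical(a$argmin_phenotype, b$argmin_phenotype)
  expect_identical(a$argmin_j, b$argmin_j)
})

test_that("p-value domain is validated", {
  expect_error(tates(c(0, .5), diag(2)), "> 0")
  expect_error(tates(c(.1, .5, .9), diag(2)), "does not match")
  expect_error(simes(numeric(0)), "empty")
  expect_error(fisher(c(.5, 0)), "\\(0, 1\\]")
  expect_error(lancaster(c(.5, .5), weights = c(2, -1)), "positive")
})

test_that("Simes combination follows the ordered-minimum definition", {
  expect_equal(simes(c(.01, .5)), .02)
  expect_equal(simes(rep(.37, 9)), .37)
  # direct enumeration oracle
  set.seed(41)
  p <- runif(12)
  expect_equal(simes(p), min(sort(p) * 12 / seq_len(12)))
})

test_that("Fisher's combination matches the chi-square closed form", {
  expect_equal(fisher(c(1, 1)), 1)
  # df = 4 survival has closed form exp(-x/2) (1 + x/2)
  x <- -2 * sum(log(c(.5, .5)))
  expect_equal(fisher(c(.5, .5)), exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(fisher(c(.5, .5)), .596574, tolerance = 1e-6)
  # single p-value is returned unchanged
  for (p in c(.001, .2, .77)) expect_equal(fisher(p), p, tolerance = 1e-12)
})

test_that("Stouffer's Z-transform behaves at and off the null centre", {
  expect_equal(stouffer(c(.5, .5)), .5)
  expect_equal(stouffer(rep(.5, 4)), .5)
  # z_i = qnorm(.9772) ~ 2.000, Z ~ 2.828
  expect_equal(stouffer(c(.0228, .0228)), .0023484, tolerance = 1e-3)
})

test_that("Lancaster's weighted Fisher reduces to Fisher at equal weights", {
  set.seed(51)
  for (i in 1:5) {
    p <- runif(sample(2:10, 1))
    expect_equal(lancaster(p), fisher(p), tolerance = 1e-12)
  }
  expect_equal(lancaster(c(1, 1, 1)), 1)
  # frozen from the chi-square inverse CDF: T = 1.3863 + 3.3567, df 6
  expect_equal(lancaster(c(.5, .5), weights = c(2, 4)), .577, tolerance = 1e-3)
  expect_equal(lancaster_weights(c(1000, 1000, 1000)), rep(2, 3))
})

test_that("sample-size weighting of p-values caps at one and fixes the largest study", {
  expect_equal(df_weight(c(.1, .2), c(500, 500)), c(.1, .2))
  expect_equal(df_weight(c(.02, .02), c(2000, 1000)), c(.02, .04))
  expect_equal(df_weight(c(.9, .5), c(100, 50)), c(.9, 1))
})

test_that("matrix combination handles missing p-values per variant", {
  P <- rbind(V1 = c(.01, .5), V2 = c(.2, NA), V3 = c(NA, NA))
  colnames(P) <- c("A", "B")
  out <- combine_matrix(P, rho = diag(2), method = "tates")
  expect_equal(out$p_combined[1], simes(c(.01, .5)))
  expect_equal(out$p_combined[2], .2)   # single remaining p-value
  expect_true(is.na(out$p_combined[3]) && out$all_missing[3])
  expect_equal(out$argmin_phenotype[1], "A")

  # reduction: identity correlation equals the Simes column
  set.seed(61)
  P2 <- matrix(runif(15), 5, 3)
  t_col <- combine_matrix(P2, diag(3), method = "tates")$p_combined
  s_col <- combine_matrix(P2, method = "simes")$p_combined
  expect_equal(t_col, s_col, tolerance = 1e-12)
  f_col <- combine_matrix(P2, method = "fisher")$p_combined
  expect_equal(f_col, apply(P2, 1, fisher))

  empty <- combine_matrix(matrix(numeric(0), 0, 3), diag(3), method = "tates")
  expect_equal(nrow(empty), 0L)
})

test_that("Simes rejection rate is nominal under independent uniform p-values", {
  set.seed(71)
  n_sim <- 10000
  m <- 20
  alpha <- .05
  rej <- 0L
  P <- matrix(runif(n_sim * m), n_sim, m)
  for (i in seq_len(n_sim)) rej <- rej + (simes(P[i, ]) <= alpha)
  se <- sqrt(alpha * (1 - alpha) / n_sim)
  expect_lt(abs(rej / n_sim - alpha), 3 * se)
})
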