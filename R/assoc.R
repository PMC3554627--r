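# Univariate genotype-phenotype association tests and the composite-score
# / multivariate comparator tests.

assoc_result <- function(estimate, p, df, test_tag) {
  structure(list(estimate = estimate, p = p, df = df, test_tag = test_tag),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s test: estimate = %.4g, p = %.4g, df = %.1f\n",
              x$test_tag, x$estimate, x$p, x$df))
  invisible(x)
}

#' Linear association test (continuous phenotype)
#'
#' OLS regression of `y` on the additively coded genotype over complete
#' pairs; two-sided t test of the slope with `N - 2` residual degrees of
#' freedom. Numerically identical to the correlation t test.
#'
#' @param y continuous phenotype vector.
#' @param g genotype vector coded 0/1/2 (missing allowed).
#' @return an `assoc_result` with fields `estimate` (slope), `p`, `df`.
#' @export
linear_test <- function(y, g) {
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- as.numeric(g[ok])
  if (length(y) < 3) stop("need at least 3 complete pairs")
  if (stats::var(g) == 0) stop("genotype is monomorphic in the analysed sample")
  if (stats::var(y) == 0) stop("phenotype has zero variance")
  r <- stats::cor(y, g)
  df <- length(y) - 2
  r2 <- min(r^2, 1 - 1e-300)
  tval <- r * sqrt(df) / sqrt(1 - r2)
  assoc_result(estimate = r * stats::sd(y) / stats::sd(g),
               p = max(2 * stats::pt(-abs(tval), df), 1e-300),
               df = df, test_tag = "linear")
}

#' Logistic association test (dichotomous phenotype)
#'
#' Maximum-likelihood logistic regression of `y` on the genotype;
#' two-sided Wald p-value for the slope.
#'
#' @param y dichotomous phenotype (two distinct values).
#' @inheritParams linear_test
#' @export
logistic_test <- function(y, g) {
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- as.numeric(g[ok])
  vals <- sort(unique(y))
  if (length(vals) != 2) stop("'y' must have exactly 2 distinct values")
  yb <- as.integer(y == vals[2])
  if (stats::var(g) == 0) stop("genotype is monomorphic in the analysed sample")
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, g), yb, family = stats::binomial()))
  if (!fit$converged || fit$boundary || abs(fit$coefficients[2]) > 50)
    stop("logistic fit did not converge (possible separation); slope = ",
         signif(fit$coefficients[2], 3))
  # Wald: slope / se from the unscaled covariance of the IRLS fit
  cov <- chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE])
  se <- sqrt(cov[2, 2])
  z <- fit$coefficients[2] / se
  assoc_result(estimate = fit$coefficients[2],
               p = max(2 * stats::pnorm(-abs(z)), 1e-300),
               df = fit$df.residual, test_tag = "logistic")
}

#' Ordinal association test (proportional odds)
#'
#' Proportional-odds (cumulative logit) maximum-likelihood fit of the
#' ordered phenotype on the genotype, with a two-sided Wald p-value for
#' the genotype slope. Categories that are empty in the analysed sample
#' are dropped (collapsed with their neighbour) with a warning. With 2
#' observed categories the model is an ordinary logistic regression.
#'
#' @param y ordered categorical phenotype (integer codes).
#' @inheritParams linear_test
#' @param categories optional vector of expected category codes; expected
#'   categories left empty after missingness are collapsed with their
#'   neighbour, with a warning.
#' @export
ordinal_test <- function(y, g, categories = NULL) {
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- as.numeric(g[ok])
  if (stats::var(g) == 0) stop("genotype is monomorphic in the analysed sample")
  cats <- sort(unique(y))
  K <- length(cats)
  if (K < 2) stop("'y' has fewer than 2 observed categories")
  if (!is.null(categories) && length(setdiff(categories, cats)))
    warning("empty ordinal categories collapsed with neighbours: ",
            paste(setdiff(categories, cats), collapse = ", "))
  yi <- match(y, cats)
  n <- length(yi)
  # cumulative logit P(Y <= c) = plogis(zeta_c - beta g); cutpoint
  # ordering enforced by the exp-gap parameterisation
  # zeta = (z1, z1 + cumsum(exp(l)))
  cum <- cumsum(tabulate(yi, K))[-K] / n
  zeta0 <- stats::qlogis(cum)
  start <- c(zeta0[1], if (K > 2) log(diff(zeta0)), 0)
  np <- K  # K - 1 cutpoint parameters + slope
  upper_idx <- yi           # category c uses zeta_c (K -> +Inf)
  lower_idx <- yi - 1L      # and zeta_{c-1} (0 -> -Inf)
  u_mask <- lapply(seq_len(K - 1), function(c) upper_idx == c)
  l_mask <- lapply(seq_len(K - 1), function(c) lower_idx == c)
  zeta_of <- function(par)
    if (K == 2) par[1] else c(par[1], par[1] + cumsum(exp(par[2:(K - 1)])))
  parts <- function(par) {
    zeta <- c(-Inf, zeta_of(par), Inf)
    eta <- par[np] * g
    zu <- zeta[upper_idx + 1L] - eta
    zl <- zeta[lower_idx + 1L] - eta
    pr <- pmax(stats::plogis(zu) - stats::plogis(zl), 1e-300)
    list(zu = zu, zl = zl, pr = pr)
  }
  nll <- function(par) -sum(log(parts(par)$pr))
  grad <- function(par) {
    pp <- parts(par)
    au <- stats::dlogis(pp$zu) / pp$pr   # dlogis(+/-Inf) = 0
    al <- stats::dlogis(pp$zl) / pp$pr
    g_zeta <- vapply(seq_len(K - 1), function(c)
      -sum(au[u_mask[[c]]]) + sum(al[l_mask[[c]]]), numeric(1))
    g_beta <- sum((au - al) * g)
    if (K == 2) c(g_zeta, g_beta)
    else c(sum(g_zeta),
           exp(par[2:(K - 1)]) * rev(cumsum(rev(g_zeta[-1]))),
           g_beta)
  }
  fit <- stats::optim(start, nll, grad, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  if (fit$convergence != 0)
    stop("proportional-odds fit did not converge (code ", fit$convergence, ")")
  H <- stats::optimHess(fit$par, nll, grad)
  cov <- tryCatch(solve(H), error = function(e)
    stop("proportional-odds information matrix is singular"))
  se <- sqrt(cov[np, np])
  z <- fit$par[np] / se
  assoc_result(estimate = fit$par[np],
               p = max(2 * stats::pnorm(-abs(z)), 1e-300),
               df = n - K, test_tag = "ordinal")
}

#' Sum-score association test
#'
#' Reduces the phenotype table to a composite row score and applies the
#' linear test. In `"complete"` mode the score is the plain row sum and
#' subjects with any missing phenotype are dropped; in `"weighted"` mode
#' the score is the mean of the available entries, so partially observed
#' subjects are retained.
#'
#' @param Y phenotype table (matrix; subjects in rows).
#' @inheritParams linear_test
#' @param mode `"complete"` or `"weighted"`.
#' @export
sumscore_test <- function(Y, g, mode = c("complete", "weighted")) {
  mode <- match.arg(mode)
  Y <- as.matrix(Y)
  score <- if (mode == "complete") rowSums(Y) else rowMeans(Y, na.rm = TRUE)
  score[is.nan(score)] <- NA
  res <- linear_test(score, g)
  res$test_tag <- "sumscore"
  res
}

# 1-factor fit by iterated principal-axis uniqueness updates (minimises
# the off-diagonal least-squares residual); returns loadings/uniquenesses.
fit_1factor <- function(R, max_iter = 500, tol = 1e-8) {
  m <- nrow(R)
  inv_ok <- tryCatch(solve(R), error = function(e) NULL)
  h2 <- if (is.null(inv_ok)) rep(0.5, m) else pmin(pmax(1 - 1 / diag(inv_ok), 0.05), 1)
  heywood <- FALSE
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    lambda <- sqrt(max(e$values[1], 0)) * e$vectors[, 1]
    h2_new <- lambda^2
    if (any(h2_new >= 1 - 1e-4)) {
      heywood <- TRUE
      h2_new <- pmin(h2_new, 1 - 1e-4)
    }
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; break }
    h2 <- h2_new
  }
  if (heywood) warning("Heywood case: residual variance clamped at 1e-4")
  Rr <- R
  diag(Rr) <- h2
  e <- eigen(Rr, symmetric = TRUE)
  lambda <- sqrt(max(e$values[1], 0)) * e$vectors[, 1]
  if (sum(lambda) < 0) lambda <- -lambda
  lambda <- pmin(pmax(lambda, -sqrt(1 - 1e-4)), sqrt(1 - 1e-4))
  list(loadings = lambda, uniquenesses = pmax(1 - lambda^2, 1e-4))
}

#' Factor-score association test
#'
#' Fits a 1-factor model to the phenotype correlation matrix, computes
#' Thompson (regression-method) factor scores
#' \eqn{\hat s = \Lambda^t \Sigma^{-1} y} with the model-implied
#' \eqn{\Sigma = \Lambda \Lambda^t + \Theta} on standardised phenotypes,
#' and applies the linear test of the scores on the genotype. Missing
#' phenotype values enter the score as the phenotype mean (zero after
#' standardisation).
#'
#' @inheritParams sumscore_test
#' @param R optional phenotype correlation matrix to fit (defaults to the
#'   pairwise-complete sample correlation of `Y`).
#' @export
factorscore_test <- function(Y, g, R = NULL) {
  Y <- as.matrix(Y)
  if (ncol(Y) == 1L) {
    res <- linear_test(Y[, 1], g)
    res$test_tag <- "factorscore"
    return(res)
  }
  if (is.null(R)) R <- stats::cor(Y, use = "pairwise.complete.obs")
  f <- fit_1factor(R)
  sigma <- tcrossprod(f$loadings) + diag(f$uniquenesses)
  w <- solve(sigma, f$loadings)
  Z <- scale(Y)
  Z[is.na(Z)] <- 0
  scores <- as.vector(Z %*% w)
  res <- linear_test(scores, g)
  res$test_tag <- "factorscore"
  res
}

#' MANOVA / canonical-correlation association test
#'
#' With a single additively coded genotype, MANOVA with the genotype as
#' covariate is identical to canonical correlation analysis, and both
#' reduce to the omnibus F test of the squared multiple correlation of
#' the genotype regressed on all `m` phenotypes:
#' \deqn{F = (R^2/m) / ((1 - R^2)/(N - m - 1))}
#' with `(m, N - m - 1)` degrees of freedom. Missing phenotype entries
#' are expected to be imputed beforehand (see [mean_impute()]).
#'
#' @inheritParams sumscore_test
#' @export
manova_test <- function(Y, g) {
  Y <- as.matrix(Y)
  ok <- !is.na(g) & stats::complete.cases(Y)
  Y <- Y[ok, , drop = FALSE]; g <- as.numeric(g[ok])
  N <- nrow(Y); m <- ncol(Y)
  if (N <= m + 1) stop("need N > m + 1 subjects (have N = ", N, ", m = ", m, ")")
  if (stats::var(g) == 0) stop("genotype is monomorphic in the analysed sample")
  X <- cbind(1, Y)
  qx <- qr(X)
  if (qx$rank < m + 1) stop("phenotype covariance matrix is singular")
  res <- qr.resid(qx, g)
  tss <- sum((g - mean(g))^2)
  R2 <- 1 - sum(res^2) / tss
  R2 <- min(max(R2, 0), 1)
  df2 <- N - m - 1
  Fstat <- (R2 / m) / ((1 - R2) / df2)
  assoc_result(estimate = R2,
               p = max(stats::pf(Fstat, m, df2, lower.tail = FALSE), 1e-300),
               df = df2, test_tag = "manova")
}

#' Univariate association tests for every phenotype of a table
#'
#' Runs the measurement-level-appropriate univariate test (linear,
#' logistic or ordinal) of each phenotype on the genotype, over the
#' available data per phenotype, and returns the per-phenotype p-values
#' and residual degrees of freedom. This is the per-variant input to
#' [tates()] and the other combiners.
#'
#' @param table a [phenotype_table()] (or matrix; levels inferred).
#' @inheritParams linear_test
#' @return list with `p` (named vector), `df`, and `test_tag` per
#'   phenotype.
#' @export
univariate_tests <- function(table, g) {
  x <- as.matrix(table)
  lv <- pheno_levels(table)
  m <- ncol(x)
  p <- numeric(m); df <- numeric(m); tag <- character(m)
  for (j in seq_len(m)) {
    res <- switch(lv[j],
                  continuous = linear_test(x[, j], g),
                  dichotomous = logistic_test(x[, j], g),
                  ordinal = ordinal_test(x[, j], g))
    p[j] <- res$p; df[j] <- res$df; tag[j] <- res$test_tag
  }
  list(p = stats::setNames(p, colnames(x)), df = df, test_tag = tag)
}

# fast vectorised per-column linear-test p-values (continuous phenotypes),
# pairwise-complete in the presence of missing cells
linear_pvalues <- function(Y, g) {
  Y <- as.matrix(Y)
  g <- as.numeric(g)
  if (!anyNA(Y) && !anyNA(g)) {
    n <- nrow(Y)
    r <- as.vector(stats::cor(g, Y))
    df <- n - 2
    tval <- r * sqrt(df) / sqrt(pmax(1 - r^2, 1e-300))
    return(list(p = pmax(2 * stats::pt(-abs(tval), df), 1e-300),
                df = rep(df, ncol(Y))))
  }
  m <- ncol(Y)
  p <- numeric(m); df <- numeric(m)
  for (j in seq_len(m)) {
    res <- linear_test(Y[, j], g)
    p[j] <- res$p; df[j] <- res$df
  }
  list(p = p, df = df)
}
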