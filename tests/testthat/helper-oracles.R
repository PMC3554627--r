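# Independent oracle implementations used to cross-check the package's
# numerical routines. These deliberately take different computational
# routes than the implementation.

# bivariate normal P(X <= h, Y <= k) by adaptive quadrature of the
# conditional-normal integrand (stats::integrate, not Gauss-Legendre)
oracle_bvn <- function(h, k, rho) {
  if (rho == 0) return(pnorm(h) * pnorm(k))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) dnorm(x) * pnorm((k - rho * x) / s),
                   -Inf, h, rel.tol = 1e-12)$value
}

# polychoric ML by grid search over the latent correlation, with exact
# bivariate-normal rectangle probabilities from oracle_bvn
oracle_polychoric <- function(x, y, grid = seq(-0.95, 0.95, by = 0.005)) {
  tab <- table(x, y)
  a <- c(-Inf, qnorm(cumsum(rowSums(tab)) / sum(tab))[-nrow(tab)], Inf)
  b <- c(-Inf, qnorm(cumsum(colSums(tab)) / sum(tab))[-ncol(tab)], Inf)
  ll <- vapply(grid, function(r) {
    pr <- outer(seq_len(nrow(tab)), seq_len(ncol(tab)), Vectorize(function(i, j) {
      oracle_bvn(a[i + 1], b[j + 1], r) - oracle_bvn(a[i], b[j + 1], r) -
        oracle_bvn(a[i + 1], b[j], r) + oracle_bvn(a[i], b[j], r)
    }))
    sum(tab * log(pmax(pr, 1e-300)))
  }, numeric(1))
  grid[which.max(ll)]
}

# effective number of independent tests, re-derived step by step
oracle_effective_number <- function(R) {
  lam <- eigen(R)$values        # unsymmetric path on purpose
  stopifnot(max(abs(Im(lam))) < 1e-10)
  lam <- Re(lam)
  nrow(R) - sum((lam - 1) * (lam > 1))
}

# random correlation matrix of dimension d (factor structure + noise)
random_corr <- function(d, k = 2) {
  L <- matrix(runif(d * k, -0.9, 0.9), d, k)
  S <- tcrossprod(L) + diag(runif(d, 0.1, 1))
  cov2cor(S)
}

# exhaustive trait-based combination: enumerate every j explicitly
oracle_tates <- function(p, rho) {
  ord <- order(p)
  m <- length(p)
  cand <- numeric(m)
  me <- oracle_effective_number(rho)
  for (j in seq_len(m)) {
    sub <- rho[ord[1:j], ord[1:j], drop = FALSE]
    cand[j] <- me / oracle_effective_number(sub) * p[ord[j]]
  }
  min(cand)
}

# equicorrelation implied by an exchangeable stationary network, closed
# form derived from the row sums of (I - B)^{-1}
oracle_exchangeable_network_r <- function(m, beta) {
  a <- 1 / (1 - (m - 1) * beta)
  b <- 1 / (1 + beta)
  (a^2 - b^2) / (a^2 + (m - 1) * b^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
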