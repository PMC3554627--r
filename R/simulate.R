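# Genotype-phenotype data generators: common-factor models, stationary
# network models, mixed measurement levels, effect-size calibration and
# missing-data schemes.

#' Simulate a Hardy-Weinberg genotype vector
#'
#' `N` draws of Binomial(2, maf): additive minor-allele counts 0/1/2.
#'
#' @param n number of subjects.
#' @param maf minor-allele frequency.
#' @param seed optional integer seed.
#' @export
simulate_genotype <- function(n, maf, seed = NULL) {
  if (maf < 0 || maf > 1) stop("'maf' must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(n, 2L, maf)
}

#' Genotype slope for a target proportion of explained variance
#'
#' For a genetic variant explaining a proportion `q` of the variance of a
#' unit-variance target (latent factor or specific phenotype), the
#' additive slope is \eqn{\beta = \sqrt{q / (2\,maf(1-maf))}}, since the
#' genotype variance under Hardy-Weinberg equilibrium is `2 maf (1-maf)`.
#' The target's non-genetic variance is scaled by `1 - q` so total
#' variance stays 1.
#'
#' @param q proportion of variance explained, in `[0, 1)`.
#' @param maf minor-allele frequency in `(0, 1)`.
#' @export
calibrate_effect <- function(q, maf) {
  if (q < 0 || q >= 1) stop("'q' must lie in [0, 1)")
  if (maf <= 0 || maf >= 1) stop("'maf' must lie in (0, 1) to carry an effect")
  sqrt(q / (2 * maf * (1 - maf)))
}

# tertile cut points of the standard normal, used for 3-category ordinal
# phenotypes; dichotomous phenotypes split at the latent median
.ordinal_thresholds <- function() stats::qnorm(c(1, 2) / 3)

#' Specify a common-factor phenotype model
#'
#' Implied phenotype covariance \eqn{\Sigma = \Lambda \Psi \Lambda^t +
#' \Theta} with `m x k` loadings, `k x k` factor covariance and diagonal
#' residuals completing unit total variance per phenotype. The genetic
#' variant targets either one factor (its effect reaches every indicator,
#' weighted by the loadings) or one phenotype's residual channel.
#'
#' @param loadings `m x k` loading matrix (or a vector for `k = 1`).
#' @param factor_cov `k x k` factor covariance (default identity).
#' @param gv_target list `list(type = "factor"|"phenotype", index = i)`.
#' @param q proportion of target variance explained by the variant.
#' @param maf minor-allele frequency.
#' @param levels per-phenotype measurement level (recycled); categorical
#'   phenotypes are produced by thresholding the latent continuous value
#'   (median split / tertiles).
#' @return list of class `factor_model_spec`.
#' @export
factor_model_spec <- function(loadings, factor_cov = NULL,
                              gv_target = list(type = "factor", index = 1L),
                              q = 0, maf = 0.5, levels = "continuous") {
  L <- as.matrix(loadings)
  m <- nrow(L); k <- ncol(L)
  if (is.null(factor_cov)) factor_cov <- diag(k)
  psi <- as.matrix(factor_cov)
  common <- L %*% psi %*% t(L)
  theta <- 1 - diag(common)
  if (any(theta < 0)) stop("communalities exceed 1; reduce loadings")
  sigma <- common + diag(theta, m)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("implied phenotype covariance is not positive definite")
  gv_target$type <- match.arg(gv_target$type, c("factor", "phenotype"))
  idx_max <- if (gv_target$type == "factor") k else m
  if (gv_target$index < 1 || gv_target$index > idx_max) stop("gv_target index out of range")
  levels <- rep_len(match.arg(levels, c("continuous", "dichotomous", "ordinal"),
                              several.ok = TRUE), m)
  structure(list(loadings = L, factor_cov = psi, residuals = theta,
                 sigma = sigma, gv_target = gv_target, q = q, maf = maf,
                 levels = levels, m = m, k = k),
            class = "factor_model_spec")
}

#' Implied phenotype correlation of a factor model (no genetic effect)
#'
#' @param spec a [factor_model_spec()].
#' @export
factor_implied_correlation <- function(spec) {
  stats::cov2cor(spec$sigma)
}

#' Simulate phenotype and genotype data from a factor model
#'
#' Draws factor scores, residuals and an independent Hardy-Weinberg
#' genotype. If the variant targets a factor, the (centred) genotype term
#' is added to that factor with the factor's non-genetic variance scaled
#' by `1 - q`; if it targets a phenotype, the term is added to that
#' phenotype with its non-genetic part scaled by `sqrt(1 - q)`. All
#' continuous phenotypes have unit total variance; categorical levels are
#' produced by thresholding.
#'
#' @param spec a [factor_model_spec()].
#' @param n number of subjects.
#' @param seed optional integer seed.
#' @return list with `phenotypes` (a [phenotype_table()]) and `genotype`.
#' @export
simulate_factor <- function(spec, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- spec$m; k <- spec$k
  beta <- calibrate_effect_safe(spec$q, spec$maf)
  g <- stats::rbinom(n, 2L, spec$maf)
  gc <- g - 2 * spec$maf
  eta <- matrix(stats::rnorm(n * k), n, k)
  if (k > 1 || spec$factor_cov[1, 1] != 1) eta <- eta %*% chol(spec$factor_cov)
  if (spec$gv_target$type == "factor" && spec$q > 0) {
    f <- spec$gv_target$index
    eta[, f] <- sqrt(1 - spec$q) * eta[, f] + beta * gc
  }
  y <- eta %*% t(spec$loadings) +
    matrix(stats::rnorm(n * m), n, m) %*% diag(sqrt(spec$residuals), m)
  if (spec$gv_target$type == "phenotype" && spec$q > 0) {
    i <- spec$gv_target$index
    y[, i] <- sqrt(1 - spec$q) * y[, i] + beta * gc
  }
  y <- threshold_levels(y, spec$levels)
  list(phenotypes = new_phenotype_table(y, spec$levels), genotype = g)
}

calibrate_effect_safe <- function(q, maf) {
  if (q == 0) 0 else calibrate_effect(q, maf)
}

threshold_levels <- function(y, levels) {
  tau <- .ordinal_thresholds()
  for (j in seq_along(levels)) {
    if (levels[j] == "dichotomous") {
      y[, j] <- as.numeric(y[, j] > 0)
    } else if (levels[j] == "ordinal") {
      y[, j] <- 1 + findInterval(y[, j], tau)
    }
  }
  y
}

#' Specify a stationary network phenotype model
#'
#' Phenotypes related by direct mutual regressions: `B[i, j]` is the
#' regression weight of phenotype `i` on phenotype `j`, with zero
#' diagonal (no self-activation). The stationary covariance is
#' \eqn{\Sigma = (I - B)^{-1} \Psi (I - B)^{-t}}, with diagonal
#' conditional variances \eqn{\Psi} solved so that every phenotype's
#' stationary variance (including the genetic contribution at the target
#' node) is exactly 1. Stability requires the largest eigenvalue of
#' \eqn{B B^t} to be below 1.
#'
#' @param B `m x m` weight matrix, zero diagonal.
#' @param gv_target node index receiving the genotype input (default 1;
#'   the effect spreads through the network).
#' @param q proportion of the target node's stationary variance explained
#'   by the variant.
#' @param maf minor-allele frequency.
#' @return list of class `network_model_spec`.
#' @export
network_model_spec <- function(B, gv_target = 1L, q = 0, maf = 0.5) {
  B <- as.matrix(B)
  m <- nrow(B)
  if (any(diag(B) != 0)) stop("'B' must have a zero diagonal")
  rad <- max(eigen(B %*% t(B), symmetric = TRUE, only.values = TRUE)$values)
  if (rad >= 1)
    stop("network is unstable: largest eigenvalue of B B^t is ",
         signif(rad, 5), " (must be < 1)")
  S <- solve(diag(m) - B)
  g_share <- q * S[, gv_target]^2 / S[gv_target, gv_target]^2
  psi <- solve(S^2, 1 - g_share)
  if (any(psi <= 0)) stop("conditional variances are not positive; weaken the network weights or the effect")
  sigma <- S %*% diag(psi, m) %*% t(S)
  if (q > 0) {
    sg <- S[, gv_target]
    sigma <- sigma + (q / S[gv_target, gv_target]^2) * tcrossprod(sg)
  }
  structure(list(B = B, S = S, psi = psi, sigma = sigma,
                 gv_target = as.integer(gv_target), q = q, maf = maf, m = m),
            class = "network_model_spec")
}

#' Implied phenotype correlation of a network model
#'
#' @param spec a [network_model_spec()].
#' @export
network_implied_correlation <- function(spec) {
  stats::cov2cor(spec$sigma)
}

#' Simulate phenotype and genotype data from a stationary network
#'
#' `y = (I - B)^{-1} (beta * g * e_target + epsilon)` with independent
#' normal inputs of variance `psi`; the genotype slope is calibrated so
#' the variant explains `q` of the target node's unit stationary
#' variance.
#'
#' @param spec a [network_model_spec()].
#' @inheritParams simulate_factor
#' @export
simulate_network <- function(spec, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- spec$m
  g <- stats::rbinom(n, 2L, spec$maf)
  gc <- g - 2 * spec$maf
  eps <- matrix(stats::rnorm(n * m), n, m) %*% diag(sqrt(spec$psi), m)
  if (spec$q > 0) {
    beta <- sqrt(spec$q / (2 * spec$maf * (1 - spec$maf))) /
      spec$S[spec$gv_target, spec$gv_target]
    # variance of beta * S[target,target] * g equals q at the target node
    eps[, spec$gv_target] <- eps[, spec$gv_target] + beta * gc
  }
  y <- eps %*% t(spec$S)
  list(phenotypes = new_phenotype_table(y, rep("continuous", m)), genotype = g)
}

#' Weight of an exchangeable network hitting a target equicorrelation
#'
#' For a fully connected `m`-node network with all off-diagonal weights
#' equal, the implied equicorrelation increases monotonically in the
#' weight up to the stability bound `1/(m-1)`. This solves for the weight
#' reproducing a target correlation by root-finding on the implied
#' correlation.
#'
#' @param m number of nodes.
#' @param target_r target pairwise correlation in `(0, 1)`.
#' @export
exchangeable_network_weight <- function(m, target_r) {
  if (target_r <= 0 || target_r >= 1) stop("'target_r' must lie in (0, 1)")
  f <- function(w) {
    B <- matrix(w, m, m); diag(B) <- 0
    network_implied_correlation(network_model_spec(B))[1, 2] - target_r
  }
  stats::uniroot(f, c(1e-8, 1 / (m - 1) - 1e-6), tol = 1e-12)$root
}

#' Weights of a clustered network hitting within/between correlations
#'
#' Block-exchangeable network: equal weights within clusters and (weaker)
#' equal weights between clusters, calibrated by least squares so the
#' implied within- and between-cluster correlations match their targets.
#'
#' @param n_clusters number of clusters.
#' @param size phenotypes per cluster.
#' @param within_r,between_r target correlations.
#' @return list with `B` plus the achieved `within` and `between`
#'   implied correlations.
#' @export
cluster_network_weights <- function(n_clusters, size, within_r, between_r) {
  m <- n_clusters * size
  cluster <- rep(seq_len(n_clusters), each = size)
  same <- outer(cluster, cluster, "==")
  build <- function(w) {
    B <- matrix(w[2], m, m)
    B[same] <- w[1]
    diag(B) <- 0
    B
  }
  obj <- function(w) {
    B <- build(w)
    if (max(eigen(B %*% t(B), symmetric = TRUE, only.values = TRUE)$values) >= 0.98)
      return(1e6)
    R <- network_implied_correlation(network_model_spec(B))
    (R[1, 2] - within_r)^2 + (R[1, size + 1] - between_r)^2
  }
  opt <- stats::optim(c(within_r / (size * 2), between_r / m), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  B <- build(opt$par)
  R <- network_implied_correlation(network_model_spec(B))
  list(B = B, within = R[1, 2], between = R[1, size + 1])
}

#' Specify a missing-data scheme
#'
#' `"mcar"` deletes each cell of each phenotype independently at the
#' given rate; `"blockwise"` removes a fixed block of phenotypes for a
#' random subset of subjects (default: 400 subjects lose phenotypes
#' 11-20, mimicking a combined study where one sample answered only the
#' short form).
#'
#' @param pattern `"none"`, `"mcar"` or `"blockwise"`.
#' @param rate per-cell missingness rate (mcar).
#' @param block_subjects number of subjects losing the block.
#' @param block_phenotypes indices of the phenotypes lost.
#' @param handling `"mean_impute"` or `"available_data"`.
#' @param df_weighting adjust combiner p-values for unequal per-phenotype
#'   sample sizes via [df_weight()] (available-data handling only).
#' @export
missingness_spec <- function(pattern = c("none", "mcar", "blockwise"),
                             rate = 0.10, block_subjects = 400L,
                             block_phenotypes = 11:20,
                             handling = c("mean_impute", "available_data"),
                             df_weighting = FALSE) {
  structure(list(pattern = match.arg(pattern), rate = rate,
                 block_subjects = as.integer(block_subjects),
                 block_phenotypes = block_phenotypes,
                 handling = match.arg(handling),
                 df_weighting = isTRUE(df_weighting)),
            class = "missingness_spec")
}

#' Apply a missing-data scheme to a phenotype table
#'
#' @param table a [phenotype_table()].
#' @param spec a [missingness_spec()].
#' @param seed optional integer seed.
#' @export
apply_missingness <- function(table, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(table)
  lv <- pheno_levels(table)
  if (spec$pattern == "mcar" && spec$rate > 0) {
    drop <- matrix(stats::runif(length(x)) < spec$rate, nrow(x), ncol(x))
    x[drop] <- NA
  } else if (spec$pattern == "blockwise") {
    subj <- sample.int(nrow(x), spec$block_subjects)
    x[subj, spec$block_phenotypes] <- NA
  }
  new_phenotype_table(x, lv)
}

#' Mean-impute missing phenotype values
#'
#' Each missing cell is replaced by its phenotype's observed mean (the
#' handling used for MANOVA and the composite scores when raw-data
#' analysis is not possible). Observed column means are preserved
#' exactly.
#'
#' @param table a [phenotype_table()].
#' @export
mean_impute <- function(table) {
  x <- as.matrix(table)
  lv <- pheno_levels(table)
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2]]
  # an imputed dichotomous column gains a third (mean) value; it is
  # treated as ordinal downstream
  if (nrow(idx)) {
    imputed_cols <- unique(idx[, 2])
    bump <- lv == "dichotomous" & seq_along(lv) %in% imputed_cols
    lv[bump] <- "ordinal"
  }
  new_phenotype_table(x, lv)
}
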