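# Combining m correlated univariate p-values per genetic variant into a
# single trait-based p-value, plus the classical comparator combiners.

#' Effective number of independent p-values
#'
#' Eigenvalue-based correction: for a `j x j` p-value correlation matrix
#' with eigenvalues \eqn{\lambda_i}, the effective number is
#' \eqn{j - \sum_i (\lambda_i - 1) I(\lambda_i > 1)}. Uncorrelated
#' phenotypes give `j`; perfectly correlated phenotypes give 1.
#'
#' @param rho_sub symmetric correlation matrix with unit diagonal.
#' @return the effective number, in `[1, j]`.
#' @export
effective_number <- function(rho_sub) {
  rho_sub <- as.matrix(rho_sub)
  j <- nrow(rho_sub)
  if (j != ncol(rho_sub)) stop("'rho_sub' must be square")
  if (j == 1L) return(1)
  if (max(abs(rho_sub - t(rho_sub))) > 1e-8) stop("'rho_sub' must be symmetric")
  lambda <- eigen(rho_sub, symmetric = TRUE, only.values = TRUE)$values
  excess <- lambda[lambda > 1] - 1
  max(1, j - sum(excess))
}

#' Trait-based combined p-value (extended Simes)
#'
#' Sorts the `m` univariate p-values of one genetic variant ascendingly
#' (ties broken by phenotype index) and weighs the `j`-th ordered p-value
#' by `m_e / m_ej`, where `m_e` is the effective number of independent
#' p-values over all `m` phenotypes and `m_ej` the effective number among
#' the `j` phenotypes with the smallest p-values (computed from the
#' corresponding submatrix of the p-value correlation matrix `rho`, never
#' from the p-value magnitudes). The trait-based p-value is the smallest
#' weighted p-value:
#' \deqn{P_T = \min_j (m_e / m_{ej}) \, p_{(j)}.}
#' The null hypothesis is that no phenotype is associated with the
#' variant.
#'
#' @param p vector of `m` univariate p-values in `(0, 1]`.
#' @param rho `m x m` (approximate) p-value correlation matrix, typically
#'   from [approximate_pvalue_correlations()]; phenotype order must match
#'   `p`.
#' @param phenotype_names optional names for reporting; defaults to
#'   `names(p)` or `P1..Pm`.
#' @return list of class `tates_result`: `p_t`, `m_e`, `argmin_j`,
#'   `argmin_phenotype`, `univariate_ps` (the input, unmodified).
#' @export
tates <- function(p, rho, phenotype_names = NULL) {
  p <- as.numeric(p)
  m <- length(p)
  if (m == 0L) stop("'p' is empty")
  if (any(is.na(p))) stop("'p' contains missing values; drop them first")
  if (any(p <= 0)) stop("p-values must be > 0 (clamp exact zeros, e.g. to machine epsilon)")
  if (any(p > 1)) stop("p-values must be <= 1")
  rho <- as.matrix(rho)
  if (nrow(rho) != m || ncol(rho) != m)
    stop("length of 'p' (", m, ") does not match dimension of 'rho' (", nrow(rho), ")")
  if (is.null(phenotype_names)) phenotype_names <- names(p)
  if (is.null(phenotype_names)) phenotype_names <- paste0("P", seq_len(m))
  ord <- order(p)                       # radix sort: stable, ties by index
  p_sorted <- p[ord]
  m_ej <- vapply(seq_len(m), function(j) {
    effective_number(rho[ord[seq_len(j)], ord[seq_len(j)], drop = FALSE])
  }, numeric(1))
  m_e <- m_ej[m]
  weighted <- (m_e / m_ej) * p_sorted
  argmin_j <- which.min(weighted)
  structure(list(p_t = min(1, weighted[argmin_j]),
                 m_e = m_e,
                 argmin_j = argmin_j,
                 argmin_phenotype = phenotype_names[ord[argmin_j]],
                 univariate_ps = stats::setNames(p, phenotype_names)),
            class = "tates_result")
}

#' @export
print.tates_result <- function(x, ...) {
  cat(sprintf("trait-based p-value P_T = %.6g (m = %d, m_e = %.3f, driven by %s at j = %d)\n",
              x$p_t, length(x$univariate_ps), x$m_e, x$argmin_phenotype, x$argmin_j))
  invisible(x)
}

#' Original Simes combined p-value
#'
#' `min over j of (m / j) * p_(j)`; exact under independent p-values,
#' slightly conservative when the phenotypes are highly correlated.
#'
#' @param p vector of p-values in `(0, 1]`.
#' @export
simes <- function(p) {
  p <- as.numeric(p)
  m <- length(p)
  if (m == 0L) stop("'p' is empty")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  min(1, min(m / seq_len(m) * sort(p)))
}

#' Fisher's combination test
#'
#' `X = -2 sum(log p)` referred to a chi-square distribution with `2m`
#' degrees of freedom. Does not account for correlation between the
#' p-values.
#'
#' @inheritParams simes
#' @export
fisher <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) stop("'p' is empty")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Stouffer's Z-transform combination test
#'
#' `Z = sum(qnorm(1 - p)) / sqrt(m)`, referred to the standard normal
#' upper tail.
#'
#' @inheritParams simes
#' @export
stouffer <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) stop("'p' is empty")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  z <- sum(stats::qnorm(1 - p)) / sqrt(length(p))
  stats::pnorm(z, lower.tail = FALSE)
}

#' Lancaster's weighted Fisher combination test
#'
#' `T = sum of Q_w^{-1}(1 - p_i)` where `Q_w` is the chi-square CDF with
#' `w_i` degrees of freedom, referred to a chi-square with `sum(w)` df.
#' With all weights equal to 2 this reduces exactly to [fisher()]. The
#' default weights are proportional to `weights` as given; a canonical
#' choice is per-phenotype sample size scaled to mean 2.
#'
#' @inheritParams simes
#' @param weights positive weights (degrees of freedom), one per p-value.
#' @export
lancaster <- function(p, weights = rep(2, length(p))) {
  p <- as.numeric(p)
  if (length(p) == 0L) stop("'p' is empty")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (length(weights) != length(p)) stop("'weights' must match 'p' in length")
  if (any(weights <= 0)) stop("weights must be positive")
  T_stat <- sum(stats::qchisq(p, df = weights, lower.tail = FALSE))
  stats::pchisq(T_stat, df = sum(weights), lower.tail = FALSE)
}

#' Scale Lancaster weights from per-phenotype sample sizes
#'
#' Weights proportional to sample size, rescaled to mean 2 so that equal
#' sample sizes reduce Lancaster's test to Fisher's.
#'
#' @param n_per_phenotype positive sample sizes.
#' @export
lancaster_weights <- function(n_per_phenotype) {
  if (any(n_per_phenotype <= 0)) stop("sample sizes must be positive")
  2 * n_per_phenotype / mean(n_per_phenotype)
}

#' Adjust p-values for unequal per-phenotype sample sizes
#'
#' Each p-value is multiplied by `df_max / df_j` (capped at 1), where
#' `df_max` is the largest per-phenotype degrees of freedom. The p-value
#' from the largest sample is unchanged; p-values from smaller samples
#' are adjusted upwards, making them less likely to drive the Simes-type
#' minimum.
#'
#' @param p p-values.
#' @param dfs per-phenotype degrees of freedom (sample sizes).
#' @export
df_weight <- function(p, dfs) {
  if (length(dfs) != length(p)) stop("'dfs' must match 'p' in length")
  if (any(dfs <= 0)) stop("degrees of freedom must be positive")
  pmin(1, p * max(dfs) / dfs)
}

#' Combine a p-value matrix variant by variant
#'
#' Applies a combiner to each row (variant) of an `n x m` p-value matrix.
#' For TATES, phenotypes with a missing p-value for a variant are dropped
#' and the effective numbers are recomputed on the remaining submatrix of
#' `rho`. Variants with no non-missing p-value are flagged and get `NA`.
#'
#' @param P numeric `n x m` matrix of p-values (rownames = variant ids),
#'   or the result of [read_pvalue_matrix()].
#' @param rho p-value correlation matrix (required for `method = "tates"`).
#' @param method one of `"tates"`, `"simes"`, `"fisher"`, `"lancaster"`,
#'   `"stouffer"`.
#' @param weights Lancaster weights (defaults to all 2).
#' @return data frame with one row per variant: `variant_id`, `p_combined`,
#'   and for TATES `m_e` and `argmin_phenotype`, followed by the echoed
#'   univariate p-values under their phenotype names.
#' @export
combine_matrix <- function(P, rho = NULL,
                           method = c("tates", "simes", "fisher", "lancaster", "stouffer"),
                           weights = NULL) {
  method <- match.arg(method)
  P <- as.matrix(P)
  m <- ncol(P)
  if (is.null(rownames(P)) && nrow(P) > 0)
    rownames(P) <- paste0("V", seq_len(nrow(P)))
  if (is.null(colnames(P))) colnames(P) <- paste0("P", seq_len(m))
  if (method == "tates") {
    if (is.null(rho)) stop("'rho' is required for TATES")
    rho <- as.matrix(rho)
    if (ncol(rho) != m) stop("'P' has ", m, " phenotypes but 'rho' is ", ncol(rho), " x ", ncol(rho))
  }
  n <- nrow(P)
  p_comb <- rep(NA_real_, n)
  m_e <- rep(NA_real_, n)
  argmin <- rep(NA_character_, n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    ok <- !is.na(P[i, ])
    if (!any(ok)) { flagged[i] <- TRUE; next }
    pi <- P[i, ok]
    res <- switch(method,
      tates = tates(pi, rho[ok, ok, drop = FALSE], phenotype_names = colnames(P)[ok]),
      simes = simes(pi),
      fisher = fisher(pi),
      stouffer = stouffer(pi),
      lancaster = lancaster(pi, if (is.null(weights)) rep(2, sum(ok)) else weights[ok]))
    if (method == "tates") {
      p_comb[i] <- res$p_t; m_e[i] <- res$m_e; argmin[i] <- res$argmin_phenotype
    } else p_comb[i] <- res
  }
  ids <- if (is.null(rownames(P))) character(0) else rownames(P)
  out <- data.frame(variant_id = ids, p_combined = p_comb,
                    stringsAsFactors = FALSE)
  if (method == "tates") { out$m_e <- m_e; out$argmin_phenotype <- argmin }
  out$all_missing <- flagged
  out <- cbind(out, as.data.frame(P))
  rownames(out) <- NULL
  out
}
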