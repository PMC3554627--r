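# Phenotype correlation estimation across mixed measurement levels, the
# polynomial map from phenotype correlations to p-value correlations, and
# the simulation that re-derives that polynomial.

#' Construct a phenotype table
#'
#' A phenotype table is an `N x m` numeric matrix of observations (missing
#' values allowed) with a per-column measurement level: `"continuous"`,
#' `"dichotomous"` or `"ordinal"`. Levels default to being inferred from
#' the number of distinct observed values (<= 2 dichotomous, <= 6 ordinal,
#' else continuous).
#'
#' @param values numeric matrix or data frame, subjects in rows.
#' @param levels optional character vector of measurement levels, recycled
#'   to the number of columns.
#' @param names optional column names.
#' @return an object of class `phenotype_table` (a numeric matrix with a
#'   `"levels"` attribute).
#' @export
phenotype_table <- function(values, levels = NULL, names = NULL) {
  x <- as.matrix(values)
  storage.mode(x) <- "double"
  if (nrow(x) < 2) stop("a phenotype table needs at least 2 subjects")
  if (!is.null(names)) colnames(x) <- names
  if (is.null(colnames(x))) colnames(x) <- paste0("P", seq_len(ncol(x)))
  if (is.null(levels)) {
    levels <- apply(x, 2, infer_level)
  } else {
    levels <- rep_len(match.arg(levels, c("continuous", "dichotomous", "ordinal"),
                                several.ok = TRUE), ncol(x))
  }
  for (j in seq_len(ncol(x))) {
    obs <- x[!is.na(x[, j]), j]
    if (length(obs) < 2) stop("column '", colnames(x)[j], "' has fewer than 2 non-missing values")
    nd <- length(unique(obs))
    if (levels[j] == "dichotomous" && nd > 2)
      stop("dichotomous column '", colnames(x)[j], "' has more than 2 distinct values")
  }
  structure(x, levels = levels, class = c("phenotype_table", "matrix", "array"))
}

# internal fast path: trusted values/levels, no per-column validation
new_phenotype_table <- function(x, levels) {
  if (is.null(colnames(x))) colnames(x) <- paste0("P", seq_len(ncol(x)))
  structure(x, levels = levels, class = c("phenotype_table", "matrix", "array"))
}

infer_level <- function(col) {
  nd <- length(unique(col[!is.na(col)]))
  if (nd <= 2) "dichotomous" else if (nd <= 6) "ordinal" else "continuous"
}

pheno_levels <- function(table) {
  lv <- attr(table, "levels")
  if (is.null(lv)) lv <- apply(as.matrix(table), 2, infer_level)
  lv
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d subjects x %d phenotypes (%s)\n",
              nrow(x), ncol(x), paste(unique(attr(x, "levels")), collapse = "/")))
  cat(sprintf("missing cells: %d\n", sum(is.na(x))))
  invisible(x)
}

#' Default polynomial mapping phenotype to p-value correlations
#'
#' The shipped 6th-order polynomial
#' \eqn{\rho(r) = -0.0008 - 0.0023 r + 0.6226 r^2 + 0.0149 r^3 + 0.1095 r^4
#' - 0.0219 r^5 + 0.2179 r^6},
#' mapping an observed phenotype correlation `r` to the approximate
#' correlation between the two phenotypes' association p-values under a
#' null genetic variant. Coefficients can be re-derived with
#' [calibrate_polynomial()].
#'
#' @return numeric vector of 7 coefficients, constant term first.
#' @export
tates_polynomial <- function() {
  c(-0.0008, -0.0023, 0.6226, 0.0149, 0.1095, -0.0219, 0.2179)
}

#' Map phenotype correlations to approximate p-value correlations
#'
#' Evaluates the 6th-order polynomial elementwise on the off-diagonal of a
#' phenotype correlation matrix, clips the result to `[-0.999, 0.999]`
#' (so the image stays usable as a correlation-like matrix in the
#' eigenvalue correction), and resets the diagonal to exactly 1.
#'
#' @param r symmetric phenotype correlation matrix with unit diagonal.
#' @param coeffs polynomial coefficients, constant first (7 values).
#' @return the approximated p-value correlation matrix `rho`.
#' @export
approximate_pvalue_correlations <- function(r, coeffs = tates_polynomial()) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("'r' must be square")
  if (length(coeffs) != 7L) stop("'coeffs' must have exactly 7 values")
  if (any(is.na(r))) stop("'r' contains missing values")
  if (max(abs(r - t(r))) > 1e-6) stop("'r' must be symmetric")
  if (any(abs(r) > 1 + 1e-8)) stop("correlation entries must lie in [-1, 1]")
  rho <- matrix(poly_eval(coeffs, pmin(pmax(r, -1), 1)), nrow(r), ncol(r),
                dimnames = dimnames(r))
  rho <- pmin(pmax(rho, -0.999), 0.999)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  rho
}

poly_eval <- function(coeffs, x) {
  out <- 0
  for (c_i in rev(coeffs)) out <- out * x + c_i
  out
}

#' Estimate a mixed-level phenotype correlation matrix
#'
#' Pairwise-complete correlation estimation where the estimator follows
#' the measurement levels: product-moment (Pearson) for
#' continuous-continuous pairs, polyserial for continuous-categorical and
#' polychoric for categorical-categorical pairs (both two-step: thresholds
#' from the marginal category frequencies, then one-dimensional ML for the
#' latent correlation). Also returns the polynomial image of the matrix.
#'
#' @param table a [phenotype_table()] (or matrix; levels then inferred).
#' @param coeffs polynomial used for the p-value correlation map.
#' @return a list of class `correlation_pair` with elements `r`, `rho`
#'   and `method_map` (matrix of `"pearson"`, `"polyserial"`,
#'   `"polychoric"` tags).
#' @export
estimate_phenotype_correlations <- function(table, coeffs = tates_polynomial()) {
  x <- as.matrix(table)
  lv <- pheno_levels(table)
  m <- ncol(x)
  nm <- colnames(x)
  for (j in seq_len(m)) {
    v <- stats::var(x[, j], na.rm = TRUE)
    if (!is.finite(v) || v == 0)
      stop("phenotype '", nm[j], "' has zero variance")
  }
  r <- diag(m)
  method <- matrix("", m, m, dimnames = list(nm, nm))
  categ <- lv %in% c("dichotomous", "ordinal")
  if (!any(categ)) {
    r <- stats::cor(x, use = if (anyNA(x)) "pairwise.complete.obs" else "everything")
    method[] <- "pearson"
  } else {
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        ok <- !is.na(x[, i]) & !is.na(x[, j])
        if (sum(ok) < 3)
          stop("phenotypes ", i, " and ", j, " share fewer than 3 complete observations")
        xi <- x[ok, i]; xj <- x[ok, j]
        if (!categ[i] && !categ[j]) {
          est <- stats::cor(xi, xj); tag <- "pearson"
        } else if (categ[i] && categ[j]) {
          est <- polychoric_cor(xi, xj, pair = c(i, j)); tag <- "polychoric"
        } else if (categ[j]) {
          est <- polyserial_cor(xi, xj, pair = c(i, j)); tag <- "polyserial"
        } else {
          est <- polyserial_cor(xj, xi, pair = c(i, j)); tag <- "polyserial"
        }
        r[i, j] <- r[j, i] <- est
        method[i, j] <- method[j, i] <- tag
      }
    }
    dimnames(r) <- list(nm, nm)
  }
  diag(method) <- "pearson"
  structure(list(r = r, rho = approximate_pvalue_correlations(r, coeffs),
                 method_map = method),
            class = "correlation_pair")
}

#' @export
print.correlation_pair <- function(x, ...) {
  cat(sprintf("correlation_pair: %d phenotypes; estimators used: %s\n",
              nrow(x$r),
              paste(unique(x$method_map[upper.tri(x$method_map)]), collapse = ", ")))
  invisible(x)
}

# thresholds from marginal category frequencies (inverse-normal of the
# cumulative proportions), excluding the trailing 1
marginal_thresholds <- function(y) {
  counts <- tabulate(match(y, sort(unique(y))))
  cum <- cumsum(counts) / length(y)
  stats::qnorm(cum[-length(cum)])
}

#' Polyserial correlation (two-step ML)
#'
#' Latent correlation between a continuous variable `x` and an ordinal or
#' dichotomous variable `y`, assuming an underlying bivariate normal.
#' Thresholds are fixed at the inverse-normal of `y`'s marginal category
#' frequencies, then the correlation is found by one-dimensional
#' likelihood maximisation.
#'
#' @param x numeric vector (continuous).
#' @param y integer-coded categorical vector, same length.
#' @param pair optional pair indices used in error messages.
#' @return the estimated latent correlation.
#' @export
polyserial_cor <- function(x, y, pair = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  z <- (x - mean(x)) / stats::sd(x)
  tau <- marginal_thresholds(y)
  cats <- sort(unique(y))
  lo <- c(-Inf, tau)[match(y, cats)]
  hi <- c(tau, Inf)[match(y, cats)]
  nll <- function(rho) {
    s <- sqrt(1 - rho^2)
    pr <- stats::pnorm((hi - rho * z) / s) - stats::pnorm((lo - rho * z) / s)
    -sum(log(pmax(pr, 1e-300)))
  }
  opt <- stats::optimize(nll, c(-0.999, 0.999), tol = 5e-4)
  if (!is.finite(opt$objective))
    stop("polyserial likelihood failed to converge for pair (",
         paste(pair, collapse = ", "), ")")
  opt$minimum
}

#' Polychoric correlation (two-step ML)
#'
#' Latent correlation between two ordinal/dichotomous variables under a
#' bivariate-normal model. Thresholds are fixed from the marginal
#' frequencies; the correlation maximises the multinomial likelihood of
#' the contingency table, with cell probabilities from the bivariate
#' normal rectangle probabilities.
#'
#' @inheritParams polyserial_cor
#' @export
polychoric_cor <- function(x, y, pair = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  ix <- match(x, sort(unique(x)))
  jy <- match(y, sort(unique(y)))
  R <- max(ix); C <- max(jy)
  counts <- tabulate((jy - 1L) * R + ix, nbins = R * C)
  a <- c(-Inf, stats::qnorm(cumsum(tabulate(ix, R)) / length(x))[-R], Inf)
  b <- c(-Inf, stats::qnorm(cumsum(tabulate(jy, C)) / length(y))[-C], Inf)
  ai <- rep(seq_len(R), C); bj <- rep(seq_len(C), each = R)
  nc <- R * C
  # rectangle probabilities by inclusion-exclusion; one batched CDF call
  hs <- c(a[ai + 1L], a[ai], a[ai + 1L], a[ai])
  ks <- c(b[bj + 1L], b[bj + 1L], b[bj], b[bj])
  nll <- function(rho) {
    q <- pbvnorm(hs, ks, rho, n_nodes = 24L)
    pr <- q[1:nc] - q[nc + 1:nc] - q[2 * nc + 1:nc] + q[3 * nc + 1:nc]
    -sum(counts * log(pmax(pr, 1e-300)))
  }
  opt <- stats::optimize(nll, c(-0.999, 0.999), tol = 5e-4)
  if (!is.finite(opt$objective))
    stop("polychoric likelihood failed to converge for pair (",
         paste(pair, collapse = ", "), ")")
  opt$minimum
}

#' Re-derive the p-value correlation polynomial by simulation
#'
#' Simulates `n_phenotypes` standard-normal phenotypes whose
#' intercorrelations span a stated range (built from a 1-factor structure
#' with signed loadings covering the range evenly), plus an independent
#' Hardy-Weinberg genotype. Each replicate yields one univariate
#' association p-value per phenotype. Across replicates the mean pairwise
#' phenotype correlations and the pairwise p-value correlations are
#' computed, and a 6th-order polynomial of p-value correlation on
#' phenotype correlation is fitted by least squares.
#'
#' @param n_subjects subjects per replicate.
#' @param n_phenotypes number of phenotypes (1485 pairs for the default 55).
#' @param corr_range target range of intercorrelations.
#' @param maf minor-allele frequency of the null genotype.
#' @param n_reps number of replicates (>= 100).
#' @param seed integer seed.
#' @return list of class `polynomial_calibration`: `coefficients` (7),
#'   `r_squared`, `n_pairs`, plus the fitted pair-level vectors
#'   `phenotype_corr` and `pvalue_corr`.
#' @export
calibrate_polynomial <- function(n_subjects = 2000, n_phenotypes = 55,
                                 corr_range = c(-0.90, 0.90), maf = 0.5,
                                 n_reps = 10000, seed = 1) {
  if (n_reps < 100) stop("'n_reps' must be at least 100")
  hi <- sqrt(max(abs(corr_range)))
  load <- seq(-hi, hi, length.out = n_phenotypes)
  sigma <- tcrossprod(load)
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("target correlation matrix is not positive definite")
  L <- chol(sigma)
  set.seed(seed)
  m <- n_phenotypes
  lower <- lower.tri(sigma)
  sum_r <- matrix(0, m, m)
  pmat <- matrix(NA_real_, n_reps, m)
  df <- n_subjects - 2
  for (rep_i in seq_len(n_reps)) {
    y <- matrix(stats::rnorm(n_subjects * m), n_subjects, m) %*% L
    g <- stats::rbinom(n_subjects, 2L, maf)
    r_gy <- as.vector(stats::cor(g, y))
    tval <- r_gy * sqrt(df) / sqrt(1 - r_gy^2)
    pmat[rep_i, ] <- 2 * stats::pt(-abs(tval), df)
    sum_r <- sum_r + stats::cor(y)
  }
  mean_r <- (sum_r / n_reps)[lower]
  p_corr <- stats::cor(pmat)[lower]
  fit <- stats::lm(p_corr ~ mean_r + I(mean_r^2) + I(mean_r^3) +
                     I(mean_r^4) + I(mean_r^5) + I(mean_r^6))
  structure(list(coefficients = unname(stats::coef(fit)),
                 r_squared = summary(fit)$r.squared,
                 n_pairs = length(mean_r),
                 phenotype_corr = mean_r,
                 pvalue_corr = p_corr),
            class = "polynomial_calibration")
}

#' @export
print.polynomial_calibration <- function(x, ...) {
  cat("6th-order p-value correlation polynomial (constant term first):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("R-squared = %.4f over %d phenotype pairs\n", x$r_squared, x$n_pairs))
  invisible(x)
}
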