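# Scenario registry and the replication engine for type-I-error and
# power studies.

#' Attach a genetic effect size to a model specification
#'
#' Returns a copy of the factor or network specification in which the
#' genetic variant explains a proportion `q` of its target's variance.
#'
#' @param spec a [factor_model_spec()] or [network_model_spec()].
#' @param q proportion of variance explained.
#' @export
with_effect <- function(spec, q) UseMethod("with_effect")

#' @export
with_effect.factor_model_spec <- function(spec, q) {
  spec$q <- q
  spec
}

#' @export
with_effect.network_model_spec <- function(spec, q) {
  network_model_spec(spec$B, gv_target = spec$gv_target, q = q, maf = spec$maf)
}

simulate_model <- function(spec, n) {
  if (inherits(spec, "factor_model_spec")) simulate_factor(spec, n)
  else simulate_network(spec, n)
}

#' Build a scenario configuration
#'
#' Bundles a generating model with the study settings: sample size,
#' effect grid, nominal alpha, replicate count, the methods to compare,
#' a missingness scheme and a master seed. Per-replicate seeds are
#' derived as `seed + replicate index`, so runs are reproducible and
#' effect sizes share common random numbers.
#'
#' @param scenario_id label (e.g. `"gA2"`).
#' @param model a [factor_model_spec()] or [network_model_spec()].
#' @param n subjects per replicate.
#' @param effect_grid proportions of variance explained by the variant.
#' @param alpha nominal per-test significance level.
#' @param n_reps replicates per effect size.
#' @param methods subset of `tates`, `simes`, `fisher`, `lancaster`,
#'   `stouffer`, `sumscore`, `factorscore`, `manova`.
#' @param missingness a [missingness_spec()].
#' @param seed master integer seed.
#' @export
scenario_config <- function(scenario_id, model, n = 2000,
                            effect_grid = seq(0, 0.01, by = 0.001),
                            alpha = 0.05, n_reps = 2000,
                            methods = c("tates", "simes", "sumscore", "manova"),
                            missingness = missingness_spec("none"),
                            seed = 1L) {
  methods <- match.arg(methods, c("tates", "simes", "fisher", "lancaster",
                                  "stouffer", "sumscore", "factorscore",
                                  "manova"), several.ok = TRUE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  structure(list(scenario_id = scenario_id, model = model, n = as.integer(n),
                 effect_grid = effect_grid, alpha = alpha,
                 n_reps = as.integer(n_reps), methods = methods,
                 missingness = missingness, seed = as.integer(seed)),
            class = "scenario_config")
}

rasch_spec <- function(loading, m = 20, target = list(type = "factor", index = 1L),
                       maf = 0.5, levels = "continuous") {
  factor_model_spec(matrix(loading, m, 1), gv_target = target, maf = maf,
                    levels = levels)
}

block_loadings <- function(per_factor) {
  k <- length(per_factor)
  m <- sum(lengths(per_factor))
  L <- matrix(0, m, k)
  row <- 1L
  for (f in seq_len(k)) {
    lam <- per_factor[[f]]
    L[row:(row + length(lam) - 1L), f] <- lam
    row <- row + length(lam)
  }
  L
}

#' The twelve headline simulation scenarios
#'
#' Registry of the scenario configurations used in the power comparison:
#' * `gA1`-`gA3`: 1-factor models with the variant on the factor. `gA1`
#'   mixes dichotomous, ordinal and continuous phenotypes with loadings
#'   .60-.90 (pairwise correlations .36-.81); `gA2`/`gA3` are continuous
#'   Rasch models with loadings .75 / .35 (correlations .56 / .12).
#' * `gB1`: 4 factors x 5 phenotypes, loadings .90, factor correlations
#'   .10, variant on factor 4. `gC1`: 2 factors x 10 phenotypes, loadings
#'   .60-.90, factor correlation .5, variant on factor 2. `gD1`: like
#'   `gB1` but with a phenotype-specific variant.
#' * `gE1`-`gE3`: Rasch models (loadings .75/.55/.35) with the variant on
#'   one phenotype.
#' * `gF1`-`gF3`: stationary networks with a phenotype-specific variant;
#'   `gF1` exchangeable with weight .04202 (correlations .56), `gF2`
#'   calibrated to correlations .12, `gF3` four clusters correlating .55
#'   within and .13 between.
#'
#' @param n_reps,seed,alpha,methods,effect_grid settings copied into
#'   every configuration.
#' @return named list of 12 [scenario_config()]s.
#' @export
registry <- function(n_reps = 2000, seed = 1L, alpha = 0.05,
                     methods = c("tates", "simes", "sumscore", "manova"),
                     effect_grid = c(0, 0.005, 0.01)) {
  cfg <- function(id, model)
    scenario_config(id, model, n = 2000, effect_grid = effect_grid,
                    alpha = alpha, n_reps = n_reps, methods = methods,
                    seed = seed)
  # paired grid so the extreme products .36 (= .6^2) and .81 (= .9^2)
  # are attained by actual phenotype pairs
  grid20 <- rep(seq(0.60, 0.90, length.out = 10), each = 2)
  grid10 <- seq(0.60, 0.90, length.out = 10)
  mixed <- rep(c("dichotomous", "ordinal", "continuous"), length.out = 20)
  fac <- function(i) list(type = "factor", index = i)
  phe <- function(i) list(type = "phenotype", index = i)
  psi4 <- matrix(0.1, 4, 4); diag(psi4) <- 1
  psi2 <- matrix(0.5, 2, 2); diag(psi2) <- 1
  L4 <- block_loadings(rep(list(rep(0.9, 5)), 4))
  L2 <- block_loadings(list(grid10, grid10))
  w_f2 <- exchangeable_network_weight(20, 0.12)
  B_f1 <- matrix(0.04202, 20, 20); diag(B_f1) <- 0
  B_f2 <- matrix(w_f2, 20, 20); diag(B_f2) <- 0
  B_f3 <- cluster_network_weights(4, 5, 0.55, 0.13)$B
  list(
    gA1 = cfg("gA1", factor_model_spec(matrix(grid20, 20, 1), gv_target = fac(1),
                                       levels = mixed)),
    gA2 = cfg("gA2", rasch_spec(0.75)),
    gA3 = cfg("gA3", rasch_spec(0.35)),
    gB1 = cfg("gB1", factor_model_spec(L4, factor_cov = psi4, gv_target = fac(4))),
    gC1 = cfg("gC1", factor_model_spec(L2, factor_cov = psi2, gv_target = fac(2))),
    gD1 = cfg("gD1", factor_model_spec(L4, factor_cov = psi4, gv_target = phe(1))),
    gE1 = cfg("gE1", rasch_spec(0.75, target = phe(1))),
    gE2 = cfg("gE2", rasch_spec(0.55, target = phe(1))),
    gE3 = cfg("gE3", rasch_spec(0.35, target = phe(1))),
    gF1 = cfg("gF1", network_model_spec(B_f1)),
    gF2 = cfg("gF2", network_model_spec(B_f2)),
    gF3 = cfg("gF3", network_model_spec(B_f3))
  )
}

#' Run one replicate of a scenario and return per-method p-values
#'
#' @param spec model specification with the effect already attached.
#' @param config the [scenario_config()].
#' @return named numeric vector of p-values (NA on method failure).
#' @keywords internal
run_replicate <- function(spec, config) {
  sim <- simulate_model(spec, config$n)
  tbl <- sim$phenotypes
  g <- sim$genotype
  ms <- config$missingness
  if (ms$pattern != "none") tbl <- apply_missingness(tbl, ms)
  has_na <- anyNA(tbl)
  imputed <- if (has_na) mean_impute(tbl) else tbl
  analysed <- if (has_na && ms$handling == "available_data") tbl else imputed
  methods <- config$methods
  out <- stats::setNames(rep(NA_real_, length(methods)), methods)
  combiners <- intersect(methods, c("tates", "simes", "fisher", "lancaster", "stouffer"))
  if (length(combiners)) {
    univ <- tryCatch({
      if (all(pheno_levels(analysed) == "continuous"))
        linear_pvalues(as.matrix(analysed), g)
      else univariate_tests(analysed, g)
    }, error = function(e) NULL)
    if (!is.null(univ)) {
      p <- univ$p
      if (ms$df_weighting && ms$handling == "available_data")
        p <- df_weight(p, univ$df)
      for (meth in setdiff(combiners, "tates"))
        out[meth] <- tryCatch(switch(meth,
          simes = simes(p), fisher = fisher(p), stouffer = stouffer(p),
          lancaster = lancaster(p, lancaster_weights(univ$df + 2))),
          error = function(e) NA_real_)
      if ("tates" %in% combiners) {
        out["tates"] <- tryCatch({
          cp <- estimate_phenotype_correlations(analysed)
          tates(p, cp$rho)$p_t
        }, error = function(e) NA_real_)
      }
    }
  }
  if ("sumscore" %in% methods)
    out["sumscore"] <- tryCatch(
      sumscore_test(analysed, g,
                    mode = if (has_na && ms$handling == "available_data") "weighted"
                           else "complete")$p,
      error = function(e) NA_real_)
  if ("factorscore" %in% methods)
    out["factorscore"] <- tryCatch(factorscore_test(analysed, g)$p,
                                   error = function(e) NA_real_)
  if ("manova" %in% methods)  # listwise deletion is ruinous under MCAR; mean imputation throughout
    out["manova"] <- tryCatch(manova_test(as.matrix(imputed), g)$p,
                              error = function(e) NA_real_)
  out
}

#' Run a scenario over its effect grid
#'
#' Per replicate: simulate data under the scenario's model, apply the
#' missingness scheme and handling, run every requested method and
#' record whether it rejected at the nominal alpha. Method failures are
#' logged and counted as non-rejections. Deterministic given the seed.
#'
#' @param config a [scenario_config()].
#' @param effects effect sizes to run (defaults to the config's grid).
#' @return data frame of class `scenario_result`: one row per
#'   (effect, method) with `rejections`, `n_reps`, `rate`, `ci_low`,
#'   `ci_high` (95% normal-approximation CI) and `failures`.
#' @export
run_scenario <- function(config, effects = config$effect_grid) {
  rows <- list()
  for (q in effects) {
    spec <- with_effect(config$model, q)
    rej <- stats::setNames(numeric(length(config$methods)), config$methods)
    fail <- rej
    for (i in seq_len(config$n_reps)) {
      set.seed(config$seed + i)
      p <- run_replicate(spec, config)
      rej <- rej + ifelse(!is.na(p) & p <= config$alpha, 1, 0)
      fail <- fail + is.na(p)
    }
    ci <- proportion_ci(rej, config$n_reps)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = config$scenario_id, method = config$methods, effect = q,
      rejections = as.integer(rej), n_reps = config$n_reps,
      rate = rej / config$n_reps, ci_low = ci$low, ci_high = ci$high,
      failures = as.integer(fail), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scenario_result", "data.frame")
  out
}

#' Normal-approximation confidence interval for a proportion
#'
#' `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)`, truncated to `[0, 1]`.
#' A Wilson score interval is available as an alternative.
#'
#' @param rejections number of successes (vectorised).
#' @param n_reps number of trials.
#' @param level confidence level.
#' @param method `"normal"` or `"wilson"`.
#' @return list with `low` and `high`.
#' @export
proportion_ci <- function(rejections, n_reps, level = 0.95,
                          method = c("normal", "wilson")) {
  method <- match.arg(method)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- rejections / n_reps
  if (method == "normal") {
    half <- z * sqrt(p * (1 - p) / n_reps)
    low <- pmax(0, p - half); high <- pmin(1, p + half)
  } else {
    den <- 1 + z^2 / n_reps
    centre <- (p + z^2 / (2 * n_reps)) / den
    half <- z * sqrt(p * (1 - p) / n_reps + z^2 / (4 * n_reps^2)) / den
    low <- pmax(0, centre - half); high <- pmin(1, centre + half)
  }
  list(low = low, high = high)
}

#' Cross-method power ratios per scenario
#'
#' At a given effect size, computes each scenario's power ratio of the
#' trait-based test over the sum-score test and over MANOVA, and counts
#' the scenarios whose ratios reach the given thresholds. Ratios with a
#' zero denominator are flagged infinite and excluded from the counts.
#'
#' @param results row-bound [run_scenario()] outputs covering the
#'   scenarios of interest.
#' @param effect effect size at which to compare.
#' @param ratio_sumscore,ratio_manova count thresholds.
#' @return list with the per-scenario `table` and the counts
#'   `n_sumscore_ratio` / `n_manova_ratio`.
#' @export
power_ratio_table <- function(results, effect = 0.005,
                              ratio_sumscore = 2.5, ratio_manova = 1.5) {
  d <- results[results$effect == effect, ]
  scen <- unique(d$scenario)
  get_rate <- function(s, meth) {
    r <- d$rate[d$scenario == s & d$method == meth]
    if (length(r) != 1L) NA_real_ else r
  }
  tab <- data.frame(
    scenario = scen,
    power_tates = vapply(scen, get_rate, 0, meth = "tates"),
    power_sumscore = vapply(scen, get_rate, 0, meth = "sumscore"),
    power_manova = vapply(scen, get_rate, 0, meth = "manova"),
    row.names = NULL)
  ratio <- function(a, b) ifelse(!is.na(b) & b == 0, Inf, a / b)
  tab$ratio_sumscore <- ratio(tab$power_tates, tab$power_sumscore)
  tab$ratio_manova <- ratio(tab$power_tates, tab$power_manova)
  finite_s <- is.finite(tab$ratio_sumscore)
  finite_m <- is.finite(tab$ratio_manova)
  list(table = tab,
       n_sumscore_ratio = sum(tab$ratio_sumscore[finite_s] >= ratio_sumscore),
       n_manova_ratio = sum(tab$ratio_manova[finite_m] >= ratio_manova),
       n_infinite = sum(!finite_s) + sum(!finite_m))
}

#' Refine borderline trait-based/sum-score power ratios
#'
#' At moderate replication a scenario's power ratio can sit within
#' Monte-Carlo noise of a decision threshold. This takes a finished
#' multi-scenario run, identifies scenarios whose ratio lies within 3
#' delta-method standard errors of the threshold, re-runs exactly those
#' scenarios at higher replication (trait-based and sum-score tests
#' only, same seed), and recounts.
#'
#' @param results row-bound [run_scenario()] outputs with `tates` and
#'   `sumscore` rates for the scenarios of interest.
#' @param registry the named list of [scenario_config()]s the results
#'   came from.
#' @param effect effect size at which ratios are compared.
#' @param threshold ratio decision threshold.
#' @param rerun_reps replication for the borderline re-runs.
#' @return list with the per-scenario `table` (including a `rerun`
#'   flag), and `count` of scenarios with a finite ratio at or above the
#'   threshold.
#' @export
refine_power_ratios <- function(results, registry, effect = 0.005,
                                threshold = 2.5, rerun_reps = 2000) {
  tab <- power_ratio_table(results, effect, ratio_sumscore = threshold)$table
  tab$rerun <- FALSE
  for (i in seq_len(nrow(tab))) {
    pt <- tab$power_tates[i]; ps <- tab$power_sumscore[i]
    if (is.na(pt) || is.na(ps) || ps <= 0) next
    n <- results$n_reps[results$scenario == tab$scenario[i]][1]
    se <- (pt / ps) * sqrt((if (pt > 0) (1 - pt) / (n * pt) else 0) +
                             (1 - ps) / (n * ps))
    if (abs(pt / ps - threshold) <= 3 * se) {
      cfg <- registry[[tab$scenario[i]]]
      cfg$methods <- c("tates", "sumscore")
      cfg$n_reps <- as.integer(rerun_reps)
      rr <- run_scenario(cfg, effects = effect)
      tab$power_tates[i] <- rr$rate[rr$method == "tates"]
      tab$power_sumscore[i] <- rr$rate[rr$method == "sumscore"]
      tab$rerun[i] <- TRUE
    }
  }
  tab$ratio_sumscore <- ifelse(tab$power_sumscore == 0, Inf,
                               tab$power_tates / tab$power_sumscore)
  list(table = tab,
       count = sum(is.finite(tab$ratio_sumscore) &
                     tab$ratio_sumscore >= threshold))
}
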