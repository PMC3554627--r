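---
title: "Trait-based association testing: model, simulators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based association testing: model, simulators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tates)
```

## The problem

A genome-wide association study (GWAS) is usually univariate: each genetic
variant (GV, coded 0/1/2 by minor-allele count) is tested against a single
phenotype. Complex traits, however, are measured as *collections* of
correlated phenotypes — symptoms, items, subtests. Reducing them to a sum
score or case–control status before testing is only harmless when one
common factor generates all phenotypic covariance *and* the variant acts on
that factor. If the variant is specific to one phenotype, or the
phenotypic structure is multifactorial or network-like, composite scores
discard exactly the signal the study is looking for.

The trait-based test implemented here takes the opposite route: run the
*m* univariate associations (linear, logistic or ordinal regression as the
measurement level dictates), then combine the *m* p-values per variant
into a single trait-based p-value while correcting for their correlation.
The null hypothesis is that *no* phenotype is associated with the variant.

## The combination rule

Let $p_{(1)} \le \dots \le p_{(m)}$ be the ordered univariate p-values of
one variant. The combined p-value is

$$P_T = \min_j \; \frac{m_e}{m_{e_j}} \, p_{(j)},$$

an extension of Simes' rule in which the observed counts $m$ and $j$ are
replaced by *effective* counts. For any correlation matrix $\rho$ of the
p-values, the effective number of independent p-values among the top $j$
is

$$m_{e_j} = j - \sum_i (\lambda_i - 1)\, I(\lambda_i > 1),$$

where $\lambda_i$ are the eigenvalues of the $j \times j$ submatrix of
$\rho$ for the $j$ phenotypes with the smallest p-values, and $m_e$ is the
same quantity over all $m$ phenotypes. Uncorrelated phenotypes give
$m_{e_j} = j$ (the rule is then exactly Simes); perfectly correlated
phenotypes give $m_{e_j} = 1$ and $P_T = \min(p)$. The submatrix is
selected by each variant's own p-value ordering — the weights use only
$\rho$, never the p-value magnitudes (`effective_number()`, `tates()`).

Ties in the p-values are broken by phenotype index (a stable sort), which
makes results deterministic; $P_T$ itself is unaffected by the tie order.
Negative eigenvalues of a not-quite-positive-definite $\rho$ are allowed:
they are below 1 and therefore never enter the correction sum.

## From phenotype correlations to p-value correlations

$\rho$ is not observable. It is approximated from the observed phenotype
correlation matrix $r$ through a 6th-order polynomial,

$$\rho(r) = -0.0008 - 0.0023\,r + 0.6226\,r^2 + 0.0149\,r^3 + 0.1095\,r^4
- 0.0219\,r^5 + 0.2179\,r^6,$$

which is dominated by even powers: two-sided p-values lose the sign of the
underlying association, so phenotypes correlated at $-r$ have nearly the
same p-value correlation as at $+r$. The shipped coefficients are exposed
by `tates_polynomial()`, and `calibrate_polynomial()` re-derives them: it
simulates 55 standard-normal phenotypes with intercorrelations spanning
$-.90$ to $.90$, plus an independent Hardy–Weinberg genotype (MAF .5),
computes the 55 univariate association p-values per replicate, and
regresses the $1485$ pairwise p-value correlations (across replicates) on
the $1485$ mean pairwise phenotype correlations.

Two details of the calibration were open design choices:

* **Target correlation structure.** Only the range of the 55
  intercorrelations is prescribed. We generate them from a rank-one
  (1-factor) structure with signed loadings spaced evenly over
  $\pm\sqrt{.90}$, which spans the range exactly and is guaranteed
  positive definite. Other constructions would distribute the 1485 pair
  correlations differently and can perturb individual coefficients — the
  even-power coefficients are strongly collinear on $[-.9, .9]$ — but the
  fitted *curve* and its $R^2$ are stable.
* **What is regressed on what.** We regress across-replicate p-value
  correlations on replicate-mean phenotype correlations (one point per
  pair), the literal reading of the procedure.

The polynomial image is clipped to $[-0.999, 0.999]$ and its diagonal
reset to 1, so the result remains usable in the eigenvalue correction even
when the fitted polynomial strays outside $[-1,1]$.

### Mixed measurement levels

When phenotypes are not all continuous, `estimate_phenotype_correlations()`
chooses the estimator per pair: Pearson product–moment
(continuous–continuous), polyserial (continuous–categorical), polychoric
(categorical–categorical). Both latent-correlation estimators are
*two-step*: thresholds are fixed at the inverse-normal of the marginal
category frequencies, then the single correlation parameter is found by
one-dimensional ML. Two-step estimation is standard practice, much faster
than full ML, and adequate at the sample sizes used here (N = 2000).
Missing data are handled by pairwise-complete observations.

The polychoric likelihood needs bivariate-normal rectangle probabilities;
these are computed by `pbvnorm()`, a Gauss–Legendre quadrature of the
conditional-normal identity with a panel split at the conditional mean
crossing (absolute accuracy about $2\times10^{-7}$ at the default 48
nodes, verified against adaptive quadrature in the tests; the polychoric
likelihood uses 24 nodes). The 1-D ML uses Brent search with tolerance
$5\times10^{-4}$ on the correlation — well below the Monte-Carlo noise of
the studies that consume it.

## Comparator methods

The same engine runs the methods the trait-based test is compared against:

* **Sum score**: the phenotype row sum regressed on the variant
  (`sumscore_test()`; under missingness, either complete rows or the mean
  of available entries).
* **Thompson factor scores**: a 1-factor model is fitted to the phenotype
  correlation matrix and regression-method scores
  $\hat s = \Lambda^t \Sigma^{-1} y$ are tested (`factorscore_test()`).
  The fit is an iterated principal-axis (uniqueness-update) least-squares
  fit, capped at 500 iterations with tolerance $10^{-8}$; Heywood cases
  clamp residual variances at $10^{-4}$ with a warning.
* **MANOVA / canonical correlation**: with one additively coded genotype,
  MANOVA with the genotype as covariate equals canonical correlation
  analysis, and both reduce to the omnibus F test of the squared multiple
  correlation of the genotype on all $m$ phenotypes
  (`manova_test()`; the equivalence with a Wilks'-lambda computation is a
  test oracle). This avoids the Wilks/Pillai choice, which only matters
  with more than one predictor.
* **Naive combiners**: Fisher, Lancaster (weights scaled to mean 2, so
  equal weights reduce it to Fisher) and Stouffer's Z ignore the p-value
  correlation; the original Simes rule ignores it too but stays valid
  (slightly conservative under strong correlation). These are the
  reference points for the false-positive-rate study.

Wald p-values are used for logistic and ordinal regression, matching the
default output of standard GWAS tools; at N = 2000 the difference from
likelihood-ratio tests is negligible. The proportional-odds fit is
implemented in-package (BFGS with analytic gradient, exp-gap
parameterisation of the cutpoints) and is cross-checked against
`MASS::polr` in the test suite.

## Data generators

### Common-factor models

`simulate_factor()` draws data with covariance
$\Sigma = \Lambda \Psi \Lambda^t + \Theta$ (loadings, factor covariance,
diagonal residuals completing unit total variance). The genetic variant is
Binomial(2, MAF) and its slope on a unit-variance target is
$\beta = \sqrt{q / (2\,\mathrm{maf}(1-\mathrm{maf}))}$, so it explains
exactly a proportion $q$ of the target's variance; the target's
non-genetic variance is scaled by $1-q$ to keep total variance at 1
(`calibrate_effect()`). A factor-level effect reaches phenotype $i$
attenuated to $\lambda_i^2 q$; a phenotype-level effect enters that
phenotype's channel directly. Equal loadings with equal residuals (the
Rasch case, where the sum score is sufficient) give equicorrelations
$\lambda^2$: loadings .75, .55, .35 imply correlations .56, .30, .12, and
.8660, .9220, .9747 imply .75, .85, .95.

Categorical phenotypes are produced by thresholding the latent continuous
value: median split for dichotomous, tertile boundaries ($\pm 0.4307$) for
3-category ordinal. The thresholds were not prescribed; symmetric cuts
maximise information and keep the latent correlation recoverable by the
polychoric estimator (a test asserts this).

### Stationary networks

`simulate_network()` generates phenotypes related by direct mutual
regressions: $y = (I-B)^{-1}(\beta g e_{t} + \varepsilon)$ with zero
diagonal in $B$ and diagonal conditional variances $\Psi$, giving
stationary covariance $\Sigma = (I-B)^{-1}\Psi(I-B)^{-t}$. Stability
requires the largest eigenvalue of $BB^t$ to stay below 1. $\Psi$ is
solved from a linear system so every phenotype's stationary variance —
including the genetic contribution at the target node — is exactly 1; the
variant enters one node and spreads through the network. For an
exchangeable network the implied equicorrelation has the closed form
$r = (a^2-b^2)/(a^2+(m-1)b^2)$ with $a = 1/(1-(m-1)\beta)$,
$b = 1/(1+\beta)$, used as a test oracle. Weight .04202 on 20 nodes
reproduces the Rasch-like correlation .56.

The printed weight for the low-correlation network (.08187) violates the
stability bound for a fully connected 20-node network and does not imply
correlation .12; the topology behind that number was evidently different.
We treat the *target correlations* as authoritative and calibrate weights
by root-finding on the implied correlation (`exchangeable_network_weight()`,
weight $\approx .0247$ for $r = .12$; `cluster_network_weights()` for the
4-cluster network with within/between correlations .55/.13).

### Missingness

`apply_missingness()` implements the two schemes: MCAR deletes each cell
independently at rate .10 (about 4000 of the 40000 cells at N = 2000,
m = 20), and blockwise missingness removes phenotypes 11–20 for 400 random
subjects (exactly 4000 cells — two samples, one of which answered only the
short form). Handling is either mean imputation (`mean_impute()`; used for
MANOVA throughout, since listwise deletion under MCAR would be ruinous) or
available-data analysis, where the sum score becomes the mean of available
entries and the univariate tests use per-phenotype complete data.
Optionally each p-value is adjusted by $df_{max}/df_j$ (capped at 1,
`df_weight()`) so p-values from smaller samples are less likely to drive
the Simes-type minimum.

## The study harness

`registry()` returns the twelve headline scenarios (gA1–gA3, gB1, gC1,
gD1, gE1–gE3, gF1–gF3): one-factor models with the variant on the factor
or on one phenotype, 2- and 4-factor models, and the three network
settings, all at N = 2000, m = 20, MAF .5. Choices the scenario
definitions left open, made once here: the mixed-level scenario gA1 cycles
dichotomous/ordinal/continuous across the 20 phenotypes and uses the
loading grid .60–.90 in repeated pairs (so the extreme pairwise
correlations $.36 = .6^2$ and $.81 = .9^2$ are attained); the
phenotype-specific variant in gD1 and the E/F scenarios targets phenotype
1 (an indicator of factor 1 in gD1).

`run_scenario()` simulates, applies missingness, runs every requested
method, and tallies rejections at $\alpha = .05$ with normal-approximation
confidence intervals (Wilson available). Per-replicate seeds are
`seed + replicate`, so runs are reproducible and effect sizes share common
random numbers — power curves are monotone up to Monte-Carlo noise, which
the tests exploit. A replicate in which a method fails (e.g. MANOVA with
more phenotypes than subjects) counts as a non-rejection and is tallied in
a `failures` column rather than resampled, avoiding selection bias.
`power_ratio_table()` summarises cross-method power ratios; ratios with a
zero denominator are reported as infinite and excluded from threshold
counts.

Effect sizes are proportions of explained variance on the grid
$\{0, .001, \dots, .01\}$ with .005 as the headline point.

## Problem sizes used in the checks

The shipped test suite and acceptance script use the study's own scales:
the polynomial calibration runs 10,000 replicates of N = 2000 × 55; the
null calibration runs 2000 replicates of the gA2 setting (plus a
MAF = .05, N = 12000 variant); the power pattern runs the twelve scenarios
at 500 replicates each. Smaller unit tests use reduced N chosen so that
Monte-Carlo standard errors, not runtime, set the tolerances.

## What the generators do and do not emulate

The simulators reproduce the covariance structures, measurement levels,
effect calibration and missingness patterns of the study design. They do
**not** emulate linkage disequilibrium between variants, related
individuals or population stratification (univariate GWAS with
stratification correction is delegated to standard tools, whose p-values
are this package's input), non-normal continuous phenotypes beyond
thresholding, or genome-scale variant counts. Passing tests therefore
demonstrate calibration and relative power under the stated generating
models, not robustness to those real-data features.

## Known limitations

* The polynomial was calibrated for p-values from two-sided tests of
  linear association at N = 2000; very small samples or one-sided tests
  would need recalibration (`calibrate_polynomial()` makes this cheap).
* The trait-based p-value is a minimum over weighted order statistics; it
  inherits Simes-type conservatism under strong positive dependence
  rather than exactness.
* Two-step polyserial/polychoric estimation ignores threshold estimation
  error in the second step; at the N used here the effect is far below
  Monte-Carlo noise.
* MANOVA under missingness is mean-imputed, the common practice it is
  compared against — not full-information ML.
* Power ratios between methods depend on generating details that scenario
  descriptions rarely pin down completely. In the two-factor scenario,
  for instance, the sum score's variance share of the genetic signal —
  and hence its power — follows in closed form from the loading grid and
  factor correlation, so the trait-based/sum-score ratio there is
  structurally more modest than in the phenotype-specific scenarios;
  small changes to the loading grid move it. The harness reports the
  ratios it actually measures.
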