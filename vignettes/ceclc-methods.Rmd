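---
title: "Joint association testing of multiple phenotypes with clustered linear combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint association testing of multiple phenotypes with clustered linear combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A single genetic variant often affects several correlated phenotypes at
once (pleiotropy), and disease studies routinely measure a panel of
related traits on every subject. Testing each trait separately discards
the correlation structure and pays a multiplicity price; testing all
traits as one undifferentiated block dilutes group-localized effects.
The clustered linear combination (CLC) family sits between the two: it
groups traits into positively correlated clusters, combines the
per-trait evidence linearly *within* clusters and quadratically *across*
clusters. This package implements that family for one variant at a time:
the closed-form ceCLC test, the original min-p CLC with its Monte-Carlo
null, the O'Brien and omnibus special cases, a factor-model simulator,
and drivers for calibration and power experiments.

## The model and the statistics

For $N$ unrelated individuals, let $Y_{ik}$ be the $k$-th of $K$
phenotypes (quantitative, or binary coded 0/1) and $G_i \in \{0,1,2\}$
the minor-allele count. Each trait contributes a score statistic

$$T_k = \frac{U_k}{\sqrt{V_k}}, \qquad
U_k = \sum_i Y_{ik}(G_i - \bar G), \qquad
V_k = \frac{1}{N}\sum_i (Y_{ik}-\bar Y_k)^2 \sum_i (G_i - \bar G)^2,$$

which is asymptotically standard normal per trait under no association,
for both trait types (for a binary trait this is the score test of the
logistic model up to the variance estimator). The statistic is sometimes
written with $V_k$ in the denominator; this package divides by
$\sqrt{V_k}$, since $V_k$ estimates the null *variance* of $U_k$ and only
the square-root form is unit-variance — the form every downstream
chi-square distribution relies on. Under the global null the vector $T$
is approximately $MVN(0, \Sigma)$ with $\Sigma$ converging to the trait
correlation matrix, estimated here by the Pearson sample correlation
$\hat\Sigma$ of the phenotype matrix.

With covariates, both genotypes and phenotypes are first replaced by
ordinary least-squares residuals on an intercept plus the covariates
(`adjust_for_covariates()`); binary traits are residualized with the same
linear recipe, which keeps a single formula for both trait types. The
sample correlation is computed on whatever matrix enters
`score_summary()` — i.e. on the residualized traits when covariates are
supplied; recomputing it on raw traits is the other defensible choice,
but the residualized version matches the covariance actually carried by
the residualized scores.

Traits are clustered hierarchically with dissimilarity
$1 - \hat\Sigma_{jk}$ (`build_tree()`). For the cut into $L$ clusters
with 0/1 membership matrix $B$ ($K \times L$), the CLC statistic is

$$T_{CLC}^L = (WT)^T\,(W\hat\Sigma W^T)^{-1}\,(WT), \qquad
W = B^T \hat\Sigma^{-1} \;\sim\; \chi^2_L
\text{ under } H_0,$$

giving the p-value profile $p_1, \dots, p_K$ over all cuts. Because the
true number of clusters is unknown, the original CLC test takes
$\min_L p_L$ and needs simulation for its p-value
(`clc_minp_test()`). The ceCLC test instead aggregates the profile by the
Cauchy combination

$$T_{ceCLC} = \frac{1}{K}\sum_{L=1}^K \tan\{(0.5 - p_L)\pi\},
\qquad p \approx 0.5 - \arctan(T_{ceCLC})/\pi,$$

which is approximately standard Cauchy even though the $p_L$ are strongly
dependent — the heavy tail makes the combination insensitive to the
dependence — so no simulation is needed anywhere (`ceclc_test()`; the
test suite asserts the RNG state is untouched). O'Brien's linear
combination and the omnibus quadratic form $T^T\hat\Sigma^{-1}T$ are the
$L = 1$ and $B = I$ special cases of the same statistic; neither formula
is spelled out in the comparison literature this package mirrors, so both
are implemented *as* those special cases and labelled accordingly.

## Tunable parameters

* `linkage` (`"average"` default, `"complete"`, `"single"`): the
  agglomeration rule. No linkage is canonical for trait clustering on
  correlation distances; average linkage (UPGMA) is the common default
  and is stable under the tie patterns of near-identity correlation
  matrices. This default is an assumption, not a derivation.
* `n_mc` (min-p CLC, default 1000): Monte-Carlo draws for the null of
  $\min_L p_L$. The add-one estimator $(1 + \#\{t' \le t^*\})/(n_{mc}+1)$
  bounds the p-value away from 0; granularity is $1/(n_{mc}+1)$, so
  values below 100 trigger a warning.
* `weights` (Cauchy combination, default equal $1/K$): nonnegative,
  summing to 1. Equal weights treat every cluster count symmetrically.
* Experiment drivers: `n_replicates`, `alpha_levels`, `workers`, and a
  master `seed` from which every replicate derives its own
  L'Ecuyer-CMRG substream, so rejection counts are identical for any
  worker count.

## Numerical choices

* **Ridge for near-singular correlation**: duplicated or near-duplicated
  traits make $\hat\Sigma$ numerically singular. Before inversion a ridge
  $10^{-8} I$ is added (with a warning) whenever the Cholesky factor
  fails or its squared diagonal ratio falls below $10^{-12}$. The ridge
  is far below sampling noise for well-conditioned matrices and merely
  keeps the quadratic forms defined for degenerate ones.
* **Small-p guard in the Cauchy transform**: $\tan\{(0.5-p)\pi\}$
  overflows as $p \to 0$; for $p < 10^{-15}$ the asymptotically exact
  tail form $1/(p\pi)$ is used instead, preserving monotonicity. The
  combined p-value is evaluated with `pcauchy()` rather than the literal
  arctan expression, which keeps precision in the extreme tail. Boundary
  inputs $p \in \{0, 1\}$ are nudged inward with a warning.
* **Ties in clustering**: merge heights can tie (exactly equal
  correlations). `stats::hclust` resolves ties deterministically by its
  scan order, so identical inputs give identical trees on every platform;
  the package adopts that rule rather than re-implementing its own.
* **Fixed memberships in the Monte-Carlo null**: the min-p null draws
  $T' \sim MVN(0, \hat\Sigma)$ reuse the membership matrices of the
  observed $\hat\Sigma$. The clustering is a function of $\hat\Sigma$
  only, which is held fixed across draws under this null, so
  re-clustering per draw would reproduce the same cuts at extra cost.
* **Degenerate inputs**: constant genotype or trait columns raise
  zero-variance errors with the offending column index; rank-deficient
  covariate designs are rejected naming the collinear columns;
  complete-case filtering (with a logged count) is the only missing-data
  policy.

## What the simulator emulates

`factor_model_spec()` + `simulate_cohort()` generate the stated world of
the package's experiments: one common variant under Hardy–Weinberg
equilibrium (default MAF 0.3) and $K$ traits from the factor model

$$Y = \lambda G + c\,\gamma f + \sqrt{1-c^2}\,\varepsilon,
\qquad f \sim MVN(0, (1-\rho)I + \rho J),$$

with defaults $c = 0.5$ and $\rho = 0.6$, so null traits are standard
normal with within-factor correlation $c^2 = 0.25$ and between-factor
correlation $\rho c^2 = 0.15$. Four effect layouts cover one shared
factor with graded effects (model 1), a null and an affected factor
(model 2), and five factors with two or four affected including sign
flips and gradients (models 3 and 4). Binary traits come from the
liability-threshold rule: affected when the underlying trait is at least
one sample SD above the column mean (the lower tail is available by
flag; for symmetric traits the two are equidistributed). In the mixed
setting the second half of the trait vector is dichotomized by default
(`mixed_mask()`), a convention choice the generator exposes rather than
hides.

The simulator deliberately omits linkage disequilibrium, rare variants,
population stratification, relatedness, covariate effects and
missingness. A green calibration or power test therefore establishes the
method's behaviour under a clean single-variant factor model — not
robustness to confounding or to realistic genotype structure.

`align_signs()` is likewise a convenience: real analyses flip
known traits by prior knowledge so that all pairwise correlations are
positive; the greedy reference-column rule here guarantees non-negative
correlation with the reference only.

## Scale of the experiments

The published operating characteristics use $10^6$ null replicates per
cell. The package's acceptance runs use $10^5$ replicates (a cell takes
minutes, not hours, at ~3 ms per replicate through the compiled
statistic kernel) and judge calibration against the matching analytic
95% interval `ci_for_ratio(alpha, 1e5)`; power checks are
property-based (null pass-through, monotonicity in effect size, and the
grouped-effects advantage of ceCLC over the omnibus test), since the
reference power values are published only graphically.

## Limitations

* One variant per test; no genome-wide multiple-testing policy is
  imposed (apply your own threshold, e.g. $5 \times 10^{-8}$).
* Unrelated individuals only; no mixed models.
* The Cauchy approximation is tail-accurate; at lax levels
  (e.g. $\alpha = 0.1$) small deviations from uniformity are expected
  and visible in the calibration suite's tolerances.
* Individual-level phenotypes are required to estimate $\hat\Sigma$;
  summary-statistic-only operation is out of scope.

## A worked run

```{r example}
library(ceclc)

spec <- factor_model_spec(model = 2, K = 10, N = 2000, beta = 0.1, seed = 1)
cohort <- simulate_cohort(spec)
pheno <- dplyr::select(cohort, sample_id, dplyr::starts_with("trait"))
geno <- dplyr::select(cohort, sample_id, snp1 = genotype)

multi_trait_test(pheno, geno, methods = c("ceclc", "clc", "obrien", "omnibus"),
                 seed = 2)

# calibration of the null at desk scale
cfg <- experiment_config(factor_model_spec(model = 1, K = 10, N = 500),
                         n_replicates = 1e4, alpha_levels = 0.01, seed = 3)
tidy(run_type1(cfg))
```
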