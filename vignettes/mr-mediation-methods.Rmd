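---
title: "Methods: two-sample MR estimation and two-step mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR estimation and two-step mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure X on an outcome Y from GWAS summary statistics computed in
non-overlapping samples. Each instrument SNP j contributes an estimated
per-allele effect on the exposure, $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$), and
on the outcome, $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$). Under the three
instrumental-variable assumptions (relevance, independence from confounders,
and exclusion restriction) every Wald ratio
$\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the same causal slope $\theta$.

The mediation layer decomposes a total effect $\beta_c$ of X on Y into an
indirect path through a mediator M and a direct remainder:

* $\beta_a$ — effect of X on M, from univariable MR;
* $\beta_b$ — effect of M on Y *conditional on X*, the mediator coefficient
  of a multivariable MR (MVMR) of Y on (X, M);
* indirect effect $\beta_a\beta_b$ (product method), direct effect
  $\beta_c - \beta_a\beta_b$, proportion mediated
  $\beta_a\beta_b/\beta_c$.

This decomposition assumes linearity of all three relations and no
exposure–mediator interaction; neither is testable from summary data and
both are inherited, not checked, by this package.

## Estimators

**IVW.** Weighted least squares of $\hat\beta_Y$ on $\hat\beta_X$ through
the origin, weights $\sigma_{Yj}^{-2}$ (first-order weights throughout by
default; the paper trail for second-order weights is exposed in
`ratio_estimates()`). The fixed-effect SE is
$(\sum \hat\beta_{Xj}^2\sigma_{Yj}^{-2})^{-1/2}$; the multiplicative
random-effects model scales it by $\max(1, \sqrt{Q/(J-1)})$ where $Q$ is
Cochran's statistic. The additive random-effects variant is deliberately
not the default: the multiplicative form matches the weighted-regression
formulation and never *shrinks* the SE.

**Method decision tree** (`choose_uvmr_method()`): a significant MR-Egger
intercept (p < 0.05) selects MR-Egger; otherwise random-effects IVW is used
exactly when the heterogeneity test has p < 0.05 **and** $I^2 > 0.25$
(both conditions, strictly); otherwise fixed-effects IVW. The $I^2 > 25\%$
threshold is strict inequality; the boundary treatment is configurable in
spirit but hard-coded here because a measured $I^2$ landing exactly on 0.25
has probability zero.

**MR-Egger.** Weighted regression *with* intercept after orienting each SNP
so $\hat\beta_{Xj} \ge 0$; the intercept estimates average directional
pleiotropy. Intercept and slope tests use a t reference with $J-2$ df, the
field convention for small instrument counts. Note that "directional"
pleiotropy is orientation-relative: pleiotropic offsets defined on
unoriented SNPs with mixed effect signs partially cancel after
reorientation, which matters when simulating.

**Weighted median.** Ratios ordered, inverse-variance weights normalized;
the estimate interpolates linearly on the cumulative weight grid
$\mathrm{cum}_j = \sum_{k\le j} w_k - w_j/2$ at 0.5. This is the standard
convention; it returns the middle ratio for three equal weights and
interpolates between bracketing SNPs otherwise. The penalized variant
multiplies weights by $\min(1, 20\,q_j)$ with $q_j$ the upper
$\chi^2_1$ tail of SNP j's heterogeneity contribution about the unpenalized
median; the constant 20 is conventional and configurable. SEs come from a
seeded parametric bootstrap (1,000 draws by default) resampling both effect
columns from their sampling distributions.

**Maximum likelihood.** Bivariate-normal likelihood with per-SNP latent
exposure effects $\xi_j$ and common slope $\theta$; the $\xi_j$ have a
closed-form profile optimum, $\theta$ is maximized in one dimension, and
the SE is the inverse curvature of the profile log-likelihood. As
$\sigma_X \to 0$ the estimator collapses onto fixed-effect IVW (verified to
1e-6 in tests).

**Radial IVW.** Regression of $\sqrt{w_j}\,\mathrm{ratio}_j$ on
$\sqrt{w_j}$ without intercept, $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$.
Algebraically identical to first-order IVW (asserted to 1e-10); its value
is the per-SNP radial Q contributions used for outlier display.

**MR-PRESSO.** The observed residual sum of squares about leave-one-out
IVW fits is compared with `nb_sim` parametric simulations under the
no-pleiotropy null to give an empirical global p; per-SNP contributions
give empirical outlier p-values, Bonferroni-corrected across SNPs and
only acted on when the global test fires. Because the per-SNP p is
empirical, its Bonferroni floor is $J/(\mathrm{nb\_sim}+1)$; the function
warns when that floor exceeds the significance level (with the default
1,000 simulations and 20 SNPs the floor is 0.02). The distortion test
compares the outlier-removal shift against shifts from removing random
subsets of the same size. Outlier removal precedes the final estimator
fit, and both pre- and post-removal estimates are reported.

**Egger-SIMEX.** The simulation-extrapolation correction for regression
dilution of the Egger slope under weak instruments: noise
$N(0, \lambda\sigma_{Xj}^2)$ is added B times per grid point
$\lambda \in \{0, 0.25, \dots, 2\}$ and the mean slope extrapolated
quadratically to $\lambda = -1$. The correction is applied to the
MR-Egger slope: "IVW-SIMEX" citations in this literature conventionally
denote SIMEX on the Egger regression, and that is the reading implemented
(the weak-instrument statistic $I^2_{GX}$ is reported alongside).

**MVMR.** `mvmr_ivw()` regresses outcome effects on the matrix of exposure
effects (no intercept); `mvmr_egger()` adds an intercept after orienting on
the first exposure; `qhet_mvmr()` minimizes the heterogeneity statistic
whose weights include $\sum_k \theta_k^2\sigma_{Xjk}^2$, acknowledging
exposure-effect uncertainty, with seeded nonparametric bootstrap CIs over
SNPs (the interval construction of the cited method is not described at
the summary level, so the assumption-light bootstrap was chosen and is
flagged in the output). The MVMR decision tree mirrors the univariable
one: Egger intercept, then heterogeneity (QHET), else IVW.

## Instrument selection and harmonization

Instruments are SNPs below a p-value threshold (relaxed 5e-5 by default,
strict 5e-8 as a sensitivity setting), greedily clumped (keep the lowest p,
drop neighbours within 10,000 kb on the same chromosome with
$r^2 \ge 0.001$), with ties on p broken lexicographically by SNP id so runs
are reproducible. SNPs absent from the LD panel are treated as unlinked and
kept — silently discarding variants the panel does not cover would be
surprising. Instruments missing from the outcome GWAS may be replaced by
the best proxy with $r^2 > 0.8$ from a user-supplied local proxy table; a
plain-file exclusion list stands in for online pleiotropy screens.
Per-SNP strength is reported as $F = (\hat\beta/\sigma)^2$ (weak below 10)
and explained variance both as $2p(1-p)\hat\beta^2$ (SD-scaled traits,
frequency known) and the frequency-free $F/(F+n-2)$; which formula a
published total refers to is often unstated, so both are labelled.

Harmonization aligns outcome (and mediator) effects to the exposure's
effect allele: swapped labels negate the beta and complement the
frequency; strand-complement labels are rewritten first (attempted only
after direct and swapped matching fail, to avoid mis-resolving
palindromes); incompatible allele sets are dropped. Palindromic (A/T, C/G)
SNPs are resolved by allele frequency: kept when both frequencies fall
outside the open interval (0.4, 0.6) — with a sign flip when they sit on
opposite sides of 0.5 — and removed as ambiguous otherwise, including when
either frequency is missing. The interval is the explicit published rule
for this workflow (not the 0.42–0.58 convention used elsewhere); whether
the boundary is open or closed is unstated in the source and irrelevant in
practice for continuous frequencies, so the open interval is used.

## Mediation uncertainty

The indirect effect uses the first-order delta variance
$\beta_a^2\sigma_b^2 + \beta_b^2\sigma_a^2$; the second-order
$+\sigma_a^2\sigma_b^2$ term is available via `product_var = "second"`.
First-order is the default because it reproduces published CIs of this
design exactly (the depression-to-reflux pathway's printed interval is
matched to 3 decimals in the acceptance tests).

For the proportion mediated two conventions are implemented. The default
(`prop_var = "scaled-indirect"`) divides the indirect effect's CI by the
total effect, treating $\beta_c$ as fixed — reconstruction of published
tables shows this is how such intervals are actually built (the full-ratio
delta interval is far wider than the printed ones). The full ratio
delta-method SE treating numerator and denominator as independent is always
reported (`proportion_se_delta`) and drives the CI under
`prop_var = "delta-ratio"`. Neither accounts for the covariance between
the indirect and total estimates, which share instruments; that covariance
is not identifiable from summary output and the approximation is
documented rather than hidden.

The combined (parallel-mediator) model runs one joint MVMR of the outcome
on the exposure and all mediators, multiplies each $\beta_{a_i}$ by its
joint $\beta_{b_i}$, sums, and takes
$\sqrt{\sum_i \sigma^2_{\mathrm{ind},i}}$ as the combined SE — an
independence working assumption across mediators, again documented; the
synthetic-replicate tests quantify how it behaves under the generating
model, where mediator paths are independent by construction.

## The synthetic world

`sim_truth()` / `make_dataset()` generate individual-level cohorts under a
linear structural model with known mediation structure, then emit
two-sample summary statistics so that every downstream stage is exercised
without external data:

* genotypes Binomial(2, maf), maf ~ U(0.1, 0.5); optional block LD through
  a latent-normal copula (blocks are contiguous, distant blocks are placed
  beyond the clumping window);
* X, M, Y generated as linear combinations with standard-normal noise, a
  shared confounder (loading 0.3 by default — MR should be and is immune
  to it), and true effects $\alpha = -0.17$, $\beta_m = 0.41$,
  $\theta_d = -0.37$, mirroring the strongest published pathway, so the
  true total effect is $-0.4397$ and the true proportion mediated 15.85%;
* 100 SNPs, half direct instruments for the exposure and half for the
  mediator, with per-SNP effects drawn $N(0, r^2/(2pq))$ at mean explained
  variance 1% per SNP. The dispersion is deliberate: near-constant effect
  sizes make the Egger design ill-conditioned and inflate the intercept
  test's false-positive rate through regression dilution, which flips the
  method decision tree to Egger for no substantive reason. At real GWAS
  strength (per-SNP $R^2 \approx$ 8.5e-5) nothing would be discoverable at
  the scaled-down n = 20,000 per trait, so per-SNP strength, not sample
  size, carries the realism here;
* 20% of SNPs receive palindromic allele pairs and half of the outcome
  rows are emitted with swapped allele labels (betas negated, frequencies
  complemented), so harmonization is genuinely exercised and its recovery
  is exact by construction;
* GWAS subsamples for exposure, mediator and outcome are disjoint (strict
  two-sample design); an overlap fraction exists as a parameter because
  sample overlap is a recognized bias source, but it is not the default.

What the generator does **not** emulate: genome-wide scale, realistic LD
maps, ancestry structure, liability-threshold binary traits (a logistic
outcome option exists but its betas are on the linear-probability scale),
or winner's-curse regimes around the discovery threshold. A green recovery
test therefore establishes correctness of the estimators and plumbing
under the stated linear world — not robustness to everything real data do.

Known quantitative caveat: with first-order weights, measurement error in
the exposure and mediator effect estimates attenuates the MVMR mediator
coefficient (and hence the proportion mediated) by roughly $1/\bar F$ —
about 1–2% at the default instrument strength. The recovery tests pass at
their pre-declared three-standard-error Monte-Carlo bands with this
attenuation included; it is a property of the estimator, visible equally
with oracle instruments, not of the selection step.

## Numerical choices

* Ties in clumping broken lexicographically; retention order is the output
  order. Clumping is idempotent and its output is asserted pair-clean.
* `mr_egger()` and MVMR SEs use the unit-weight covariance scaled by
  $\max(1, \hat\sigma)$, so exact-fit data yield finite SEs rather than
  0/0.
* The ML profile is maximized by Brent search on an interval of width
  50 IVW-SEs around the IVW start; non-concave curvature at the optimum is
  an error, not a silent fallback.
* QHET starts from the MVMR-IVW solution (BFGS, relative tolerance 1e-12)
  and errors with the optimizer trace on non-convergence.
* All stochastic procedures (median bootstrap, PRESSO, SIMEX, QHET
  bootstrap) take explicit seeds, restore the caller's RNG state, and are
  bit-reproducible; the pipeline requires a seed in its configuration.
* Empty instrument sets after thresholding warn rather than error (a
  strict-threshold rerun may legitimately find fewer instruments);
  downstream stages error if nothing survives.
* Pipeline configs are JSON (`jsonlite`), and the evidence labels use
  Benjamini–Hochberg q < 0.05 for "significant" and raw p < 0.05 for
  "suggestive"; the FDR family is whatever set of p-values is passed in,
  since family boundaries are an analysis choice, not a package one.

## Limitations

Beyond the generator's scope above: no winner's-curse correction and no
directionality (Steiger) filtering; no conditional F-statistics for MVMR;
no mode-based or contamination-mixture estimators; binary-trait effects are
assumed to arrive on the log-odds scale and are never rescaled internally.
Proportions mediated are only meaningful when the total effect is clearly
nonzero; the implementation reports the proportion as missing when
$\beta_c = 0$ and leaves near-zero instability to the analyst's judgment.
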