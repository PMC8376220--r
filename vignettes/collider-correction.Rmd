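---
title: "Collider-Correction: methods, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collider-Correction: methods, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collidermr)
```

## The problem

One-sample Mendelian randomization (MR) estimates the causal effect $\beta$ of
an exposure $X$ on an outcome $Y$ using genetic variants $G_1,\dots,G_k$ as
instruments, all measured in the same cohort. The structural model is

$$X_i = \sum_j \beta_{XGj} G_{ij} + \beta_{UX}U_i + \varepsilon_{Xi}, \qquad
  Y_i = \beta X_i + \sum_j \alpha_j G_{ij} + \beta_{UY}U_i + \varepsilon_{Yi},$$

with $U$ an unmeasured confounder and $\alpha_j$ direct (pleiotropic) SNP
effects. The rich toolkit of two-sample summary-data MR (IVW, MR-Egger, robust
regressions, RAPS) assumes the errors of the SNP-exposure and SNP-outcome
association estimates are independent. In one sample they are not: both come
from the same individuals, so weak instruments bias naive estimates towards
the observational association rather than diluting them towards zero.

## The collider-correction device

Regressing $Y$ on $X$ *and* all SNPs jointly deliberately conditions on a
collider ($X$ is caused by both $G$ and $U$). The SNP coefficients
$\hat\alpha^*_j$ of that regression are biased for $\alpha_j$, but obey the
linear relation

$$\hat\alpha^*_j = \alpha_j + (\beta-\beta^*)\,\beta_{XGj} + \theta_j,$$

where $\beta^*$ is the coefficient on $X$ in the same regression, and —
crucially — the errors $\theta_j$ are uncorrelated with the first-stage errors
$\hat\delta_j = \hat\beta_{XGj} - \beta_{XGj}$, *whether or not* the InSIDE
condition ($\widehat{\mathrm{cov}}(\alpha_j,\beta_{XGj}) = 0$) holds. The
algorithm is therefore:

1. regress $Y$ on $(X, G)$: get $\hat\beta^*$ and $\hat\alpha^*_1,\dots,\hat\alpha^*_k$
   (`collider_summary()`);
2. regress $X$ on $G$ jointly: get $\hat\beta_{XG1},\dots,\hat\beta_{XGk}$
   (same call);
3. fit $\hat\alpha^*_j = \alpha_0 + (\beta-\beta^*)\hat\beta_{XGj}$ with any
   two-sample MR loss (`ivw_slope()`, `egger_slope()`, `lad_slope()`,
   `liml_raps_slope()`);
4. recover $\hat\beta = \hat\beta^* + \widehat{\beta-\beta^*}$
   (`causal_estimate()`).

Because of step 1's conditioning, first-stage uncertainty acts on step 3 as
*classical* measurement error: the fitted slope is diluted by a predictable
factor — $(\bar F - 1)/\bar F$ for IVW and LAD, $I^2_{GX}$ for MR-Egger — and
SIMEX (`simex_adjust()`) removes the dilution by adding synthetic first-stage
noise at multipliers $\lambda$ and extrapolating the slope curve back to
$\lambda = -1$. The profile estimator `liml_raps_slope()` instead absorbs the
first-stage variance into its residual standardization
$r_j(s,\tau^2) = (\hat\alpha^*_j - s\hat\beta_{XGj}) /
\sqrt{s^2\sigma^2_{XGj} + \sigma^2_{\alpha^*_j} + \tau^2}$ and needs no SIMEX;
with $z=0$ ($\tau^2 \equiv 0$) its minimized objective is the exact Q
statistic, the weak-instrument-robust pleiotropy test exposed by `exact_q()`.

## What the simulator emulates

`simulate_dataset()` draws bi-allelic SNP dosages Binomial(2, maf) with
maf = 0.3, mutually independent (no linkage disequilibrium), and Gaussian
residuals realized through a shared standard-normal confounder whose loadings
reproduce exactly the requested residual moments. Three pleiotropy regimes
mirror the estimators they stress:

* `ivw`: $\alpha_j$ mean-zero, independent of $\beta_{XGj}$ (InSIDE holds);
* `egger`: $\alpha_j$ with non-zero mean 0.01, independent (directional
  pleiotropy, InSIDE holds);
* `lad`: the first 15 of 50 $\alpha_j$ non-zero and correlated with their
  $\beta_{XGj}$ at 0.5, the rest exactly zero (InSIDE violated on a subset);
* `fig3_toy`: every $\alpha_j$ correlated with $\beta_{XGj}$ at 0.45 (InSIDE
  violated globally) — the preset used to demonstrate residual-error
  independence itself.

### Calibration of defaults

The printed study conditions are targets, not parameters, so the generator's
defaults were fixed once to reproduce them and not revisited:

* **Causal effect** $\beta = 0.5$; **confounding** $\rho = 0.9$ between the
  residuals of $X|G$ and $Y|X,G$.
* **Residual sds** $(\sigma_X, \sigma_Y) = (1, 0.69)$, chosen because the
  large-sample conditional observational coefficient is
  $\beta^* = \beta + \rho\sigma_Y/\sigma_X = 1.121$ and the correction slope
  $\beta - \beta^* = -0.621$, matching the calibration values of
  approximately 1.12 and −0.62.
* **SNP effects** drawn $N(0.026, 0.007^2)$ and rescaled so that
  $\sum_j \beta_{XGj}^2 \cdot 2\,\mathrm{maf}(1-\mathrm{maf})$ equals exactly
  $h^2_X \sigma_X^2/(1-h^2_X)$ with $h^2_X = 0.015$: the 50 SNPs explain 1.5%
  of exposure variance, and the between-SNP spread makes $I^2_{GX}$ rise from
  ≈ 0.1 at $n = 5000$ to ≈ 0.5 at $n = 50000$ — the weak-instrument regime the
  SIMEX adjustment is designed for.
* **Pleiotropy scale** 0.004 (sd) and 0.01 (directional mean): comparable to
  the SNP-outcome association standard errors at these sample sizes, large
  enough to overdisperse the slope fits ($\phi > 1$) without dominating them.
* **fig3_toy** sets $\beta = 0$, $\sigma_Y = 1$, $\rho = 0.5$. The benchmark
  for this preset is that the first-stage errors correlate with the *standard*
  SNP-outcome residuals at the structural residual correlation (0.5) and with
  the collider-correction residuals at 0. The standard residual's
  individual-level noise is $\beta e_X + e_Y$, so its correlation with $e_X$
  equals the structural $\rho$ only under a null causal effect; with
  $\beta = 0.5$ it would be ≈ 0.76. A null effect is therefore the only
  calibration consistent with both stated properties, and the collider path
  (via $\rho$) is still fully active.

Genotypes and effect vectors are re-drawn per replicate (the replicates are
fully independent datasets); a flag-free deterministic scheme
(`child_seed(root, i)`) makes any single replicate reproducible in isolation.

### What the simulator does *not* emulate

Linkage disequilibrium, binary exposures or outcomes, covariate structure,
population stratification, winner's curse in instrument selection, and
non-Gaussian residuals are all absent. Passing tests on these simulations
therefore demonstrate correctness of the estimators under the stated linear
Gaussian model with independent SNPs — not robustness to real-data violations
of it. For user data, `collider_summary()` accepts covariates and a per-SNP
first-stage option for pre-pruned SNP panels, but those paths are exercised
only on simulated inputs here.

## Numerical choices

* OLS is solved by Cholesky on the normal equations (designs are tall,
  well-conditioned dosage matrices), with a QR fallback that names the
  offending columns on rank deficiency. Homoskedastic SEs are the default;
  HC0 sandwich SEs by flag.
* The weighted L1 fit through the origin is computed exactly as a weighted
  median of the per-SNP ratios (weights $|\hat\beta_{XGj}|/\sigma_{\alpha^*_j}$);
  on flat segments the point closest to zero is returned (smallest-|slope|
  tie-break). Its SE is a bootstrap over SNPs (default B = 1000, seeded).
* `liml_raps_slope()` searches `slope_IVW` ± 10 SE. For $z=0$ it minimizes the
  exact-Q objective piecewise with `optimize()`, SE from profile curvature
  ($\mathrm{Var} \approx 2/Q''$, which reduces to the fixed-effect IVW
  variance under NOME). For $z=1$ it solves Tukey-penalized estimating
  equations (tuning constant 4.685), profiling $\tau^2$ via
  $\sum_j \psi(r_j) r_j = k\,E[\psi(Z)Z]$ with $\tau^2$ floored at 0; *all*
  score roots are located on a grid-refined bracket and reported, the root
  with the smallest robust objective is returned. Multimodality is expected —
  profile likelihoods of this model are known to be unstable under
  InSIDE-violating pleiotropy — and is surfaced via `extras$roots` and the
  `converged` flag rather than hidden.
* SIMEX uses $\lambda \in \{0, 0.5, 1, 1.5, 2\}$, B = 100 pseudo-datasets per
  positive $\lambda$ (the $\lambda = 0$ arm anchors the curve with the
  observed fit), and a quadratic extrapolant by default: on the analytic IVW
  dilution curve $s/(1+(1+\lambda)/\bar F)$ the quadratic extrapolation to
  $\lambda = -1$ is accurate to ~0.3% at $\bar F = 15$, and the linear
  extrapolant is offered as the conservative alternative. The SE combines the
  unadjusted estimator's SE with a delete-one jackknife over the
  pseudo-replicates.
* Overdispersion $\phi$ is floored at 1 (multiplicative random effects apply
  only when residual variance exceeds the fixed-effect value); raw values are
  kept in `extras`. Negative $I^2_{GX}$ is floored at 0, raw value in an
  attribute.
* `variance_explained()` reports the adjusted $R^2$ of $X$ on $G$: the raw
  $R^2$ of a 50-SNP regression overstates the population variance explained
  by about $k/n$ (0.5 percentage points at $n = 10^4$), so the adjusted value
  is the meaningful check against $h^2_X$.
* The final causal SE combines $SE(\hat\beta^*)$ and the slope SE as if
  independent; `causal_bootstrap()` offers a paired bootstrap over individuals
  through all four steps when the covariance matters.

## Problem sizes used in the test suite

The packaged checks run at desk scale, chosen to keep Monte-Carlo error well
below the tolerances they assert: 200 replicates per benchmark (Monte-Carlo
SEs of the reported means are in the third decimal), sample sizes 5000–50000
for the estimator benchmarks, 10000 for the residual-independence and
variance-explained checks, 500 null replicates for the exact-Q size check,
and SIMEX B = 50 inside replicated fits. The same quantities at the paper's
1000 replicates are available through `run_experiment()`.

## Known limitations

* The Egger/LAD pleiotropy magnitudes and the RAPS penalization details are
  reconstructions (the source material names the options but not the
  constants); both are exposed as arguments rather than buried.
* LAD's weak-instrument dilution only approximately follows
  $(\bar F-1)/\bar F$ — it is somewhat more vulnerable than IVW, which is
  visible in its SIMEX curve and is the reason its predicted factor is
  labelled approximate in `predicted_dilution()`.
* The exact-Q p-value uses the $\chi^2_{k-1}$ reference; with very few SNPs
  the profile minimization absorbs one effective degree of freedom
  imperfectly.
* Logistic first stages (binary exposures) are accepted conceptually but not
  simulated; estimates are then on the log-odds exposure scale.
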