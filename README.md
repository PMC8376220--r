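# collidermr

Collider-Correction for one-sample Mendelian randomization: estimate the
causal effect of an exposure on an outcome from a single fully-genotyped
cohort while borrowing the entire toolkit of two-sample summary-data MR —
pleiotropy-robust estimators, weak-instrument diagnostics and
measurement-error corrections — without splitting the sample.

## Who this is for

Analysts with individual-level data (genotype dosages, exposure, outcome,
optional covariates) who want weak-instrument- and pleiotropy-robust causal
estimates, and methodologists studying the behaviour of summary-data MR
estimators under one-sample error correlation.

## The method

Naively applying two-sample MR methods within one sample biases estimates
towards the observational association, because the errors of the SNP-exposure
and SNP-outcome association estimates are correlated. Collider-Correction
turns this problem inside out:

1. **Induce collider bias deliberately.** Regress $Y$ on $X$ and all $k$ SNPs
   jointly. The coefficient on $X$ is the conditional observational
   association $\hat\beta^*$; the SNP coefficients $\hat\alpha^*_j$ are
   collider-biased versions of the direct SNP effects.
2. **First stage.** Regress $X$ on all SNPs jointly for
   $\hat\beta_{XG1},\dots,\hat\beta_{XGk}$.
3. **Fit the correction slope.** The associations satisfy
   $\hat\alpha^*_j = \alpha_j + (\beta-\beta^*)\beta_{XGj} + \theta_j$ with
   $\theta_j$ *independent* of the first-stage errors — even when the InSIDE
   assumption fails. Any two-sample estimator can therefore fit the slope
   $(\beta-\beta^*)$: inverse-variance weighted (IVW), MR-Egger, weighted
   least-absolute-deviation (LAD), or a LIML/RAPS-style profile estimator.
4. **Recover the causal effect:**
   $\hat\beta = \hat\beta^* + \widehat{\beta-\beta^*}$.

Because the step-3 errors behave like classical measurement error, weak
instruments dilute the slope by the predictable factor $(\bar F - 1)/\bar F$
(IVW/LAD) or $I^2_{GX}$ (Egger), and SIMEX — refit the slope under synthetic
extra first-stage noise at multipliers $\lambda$, extrapolate to
$\lambda = -1$ — removes the dilution. The exact Q statistic (the minimized
profile objective, $\chi^2_{k-1}$ under no pleiotropy) tests for pleiotropy
without weak-instrument size distortion and flags outlying SNPs.

## Worked example

Simulate a cohort of 20,000 individuals under the package's calibrated
defaults — 50 independent bi-allelic SNPs (MAF 0.3) explaining 1.5% of
exposure variance, causal effect $\beta = 0.5$, strong confounding
(residual correlation 0.9) — and run the full pipeline:

```r
library(collidermr)
cfg <- scenario_config("ivw", n = 20000, seed = 7)
d   <- simulate_dataset(cfg)
rep <- end_to_end(d, simex = simex_config(B = 100, seed = 7), seed = 7)
print(rep)
```

```
Collider-correction analysis: k = 50 SNPs
  mean F = 7.04  I2_GX = 32.0%  Q = 58 (df 49, p = 0.17)
                    method estimate      se  p_value
 beta_star (observational)   1.1210 0.00211 0.00e+00
                      tsls   0.5775 0.03300 1.34e-68
              standard_ivw   0.5790 0.06170 6.22e-21
                    cc_ivw   0.5761 0.03890 9.86e-50
              cc_ivw_simex   0.4874 0.03960 7.32e-35
            standard_egger   0.8727 0.13600 1.21e-10
                  cc_egger   0.8627 0.07320 4.97e-32
            cc_egger_simex   0.6915 0.07410 1.03e-20
              standard_lad   0.5893 0.05740 1.01e-24
                    cc_lad   0.5745 0.05640 2.35e-24
              cc_lad_simex   0.4662 0.06120 2.60e-14
                   cc_raps   0.4953 0.04540 1.05e-27
```

Reading the output: confounding pushes the observational association to 1.12,
far from the true effect 0.5. TSLS and the unadjusted collider-corrected IVW
agree (0.578 vs 0.576, the expected asymptotic equivalence) but both retain
residual weak-instrument bias towards 1.12 at mean F = 7. The SIMEX-adjusted
collider-corrected IVW (0.487) and the RAPS-style profile estimator (0.495)
land on the true value within their standard errors; the exact Q (p = 0.17)
correctly finds no evidence of directional pleiotropy in this
zero-mean-pleiotropy scenario.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/collidermr.R simulate --scenario ivw --n 20000 --seed 7 --out data.tsv
Rscript inst/cli/collidermr.R report --data data.tsv --out report/ --seed 7
```

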