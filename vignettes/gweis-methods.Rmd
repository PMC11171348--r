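---
title: "Robust genome-wide genotype-by-environment interaction scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust genome-wide genotype-by-environment interaction scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A conventional GWAS asks whether a variant shifts a phenotype on average.
A genome-wide genotype-by-environment interaction scan (GWEIS) asks a
different question: does the variant's effect *depend* on an environmental
exposure? In a multi-farm livestock setting — animals raised on farms in
different climates, with a continuous per-individual mean-temperature
exposure — loci whose effect reverses or vanishes across environments carry
no detectable main effect and are invisible to a GWAS, yet they matter for
joint genetic evaluation across farms.

`gxescan` implements the full scan: per-marker interaction regression with
heteroskedasticity-robust inference, the quality-control cascade, a
mixed-model main-effect baseline, inflation diagnostics, LD clumping of
hits, and gene-level / gene-set aggregation, together with a synthetic-data
generator that reproduces the statistical structure the analysis assumes.

## The interaction model

At each marker the scan fits, by ordinary least squares,

$$y_i = \mu_0 + \beta_g G_i + \beta_e E_i + \beta_{g\times e} G_i E_i
      + \beta_c' C_i + \beta_{c\times g}' C_i G_i
      + \beta_{c\times e}' C_i E_i + \varepsilon_i,$$

where $G_i \in \{0,1,2\}$ is the allele count, $E_i$ the environmental
measure, and $C_i$ the covariates (age, sex, birth weight, and genotype
principal components). The covariate-by-SNP and covariate-by-environment
columns keep confounded covariate interactions from masquerading as
$\beta_{g\times e}$. The parameter of interest is $\beta_{g\times e}$; the
test is a t-test (one interaction column) or a multi-df Wald test
(categorical environment with $L$ levels contributes $L-1$
treatment-coded columns).

A continuous environment is centered before interaction columns are formed,
so $\beta_g$ is the SNP effect at the mean environment and the collinearity
between $G$ and $G\cdot E$ stays modest. A categorical environment uses
treatment contrasts against a documented reference level (first sorted
level by default); the interaction Wald test is invariant to that choice,
which a test asserts to $10^{-8}$.

## Why robust standard errors

When the residual variance differs across environmental exposure —
heteroskedasticity, the rule rather than the exception when environments
differ in management, climate, or measurement — the single-$\sigma^2$
model-based covariance misestimates the sampling variance of
$\beta_{g\times e}$, and the interaction statistics inflate genome-wide.
The Huber-White sandwich estimator

$$\widehat{\mathrm{Var}}(\hat\beta) =
  (X'X)^{-1} X' \,\mathrm{diag}(w_i)\, X (X'X)^{-1}$$

replaces the pooled variance with per-observation weights built from
squared residuals and stays valid under arbitrary heteroskedasticity.
Four standard weightings are implemented: $w_i = e_i^2$ (HC0),
$\tfrac{n}{n-p} e_i^2$ (HC1), $e_i^2/(1-h_i)$ (HC2) and
$e_i^2/(1-h_i)^2$ (HC3), with $h_i$ the hat values.

**Flavor default.** The genome scan defaults to HC3. At cohort scale
($n \approx 1000$, $p \approx 13$) the empirical size of the nominal-5%
robust interaction test under a strongly heteroskedastic null measures at
about 0.055 for HC1, 0.053 for HC2 and 0.049-0.050 for HC3 in this
package's own calibration experiment: the unadjusted flavors are measurably
liberal, the leverage-corrected jackknife-type HC3 is closest to nominal
(the familiar "use HC3 below $n$ in the thousands" guidance). HC0-HC2
remain available for comparison with other implementations. Reference
distribution: t with $n-p$ degrees of freedom for 1-df tests, chi-square
for multi-df Wald tests.

No flavor is exact in finite samples: the remaining size error of the best
flavor is a few parts in a thousand, which matters when interpreting
calibration experiments that pool hundreds of thousands of tests.

## The scan's numerical path

One QR decomposition of the SNP-free column block (intercept, environment,
covariates, covariate-by-environment) is computed once and reused for every
marker; the per-SNP columns ($G$, $G\cdot E$, $C\cdot G$) and the phenotype
are residualized against it (Frisch-Waugh-Lovell), and the small
residualized system is solved per SNP. Coefficients, residuals, model and
sandwich covariances from this path are identical to the naive full-design
per-SNP solve — asserted in the tests to $10^{-8}$ and holding to machine
precision in practice. Markers with missing genotypes drop to the naive
complete-case path (PLINK-like per-SNP complete-case handling, no genotype
imputation in regressions). Markers that are monomorphic in the analyzed
subset, or whose residualized interaction column has variance below
$10^{-12}$, are skipped with a reason code; a scan that skips more than
half its markers aborts, since that pattern indicates misaligned inputs.

## Quality control

Filters run in a fixed, documented order, and each marker is attributed to
the first filter that removes it: samples with more than 10% missing
genotypes are dropped first; then markers with missing/invalid positions,
duplicate (chromosome, position) pairs, call rate below 90%, minor allele
frequency below 0.05 (computed on non-missing genotypes after sample
filtering), Hardy-Weinberg exact-test p below $10^{-6}$, and (when trios
are supplied) Mendelian-error rate above 2%. The HWE test is the exact
conditional test (the PLINK default behavior), checked against a full
enumeration oracle; monomorphic markers return p = 1 by convention.
Re-running QC on its own output removes nothing.

## The mixed-model baseline

The main-effect GWAS uses the standard univariate mixed model
$y = X\beta + Zu + \varepsilon$ with $u \sim N(0, G\sigma_a^2)$,
$\varepsilon \sim N(0, I\sigma_e^2)$, and $G$ the genomic relationship
matrix $WW'/m$ from mean-imputed, centered, variance-standardized
genotypes. The null variance components come from REML profiled over the
ratio $\lambda = \sigma_a^2/\sigma_e^2$ after a single eigendecomposition
of $G$, optimized on $\log_{10}\lambda \in [-5, 5]$; per-SNP tests are
EMMAX-style generalized least squares in the rotated space with $\lambda$
fixed at the null estimate. This is an approximation to exact per-SNP
REML, adequate for its role here: checking that interaction hits carry no
main effect. With an identity relationship matrix the whole machinery
degenerates exactly to OLS (flat profile; the lower search bound is
returned by convention and only the total variance is identifiable), which
the tests assert to $10^{-6}$. No leave-one-chromosome-out GRM is used;
proximal contamination is a known caveat.

## Inflation diagnostics

QQ tables use $-\log_{10}$ of the uniform order statistics
$i/(m+1)$. The genomic inflation factor is
$\lambda_{GC} = \mathrm{median}(\chi^2)/0.4549$. LD score regression
regresses per-SNP $\chi^2$ on in-sample windowed LD scores
$\ell_j = 1 + \sum_{k \ne j} \big(r^2_{jk} - (1-r^2_{jk})/(n-2)\big)$
(1 Mb windows, self term 1, bias-adjusted $r^2$; the adjustment can push
scores slightly below 1 for markers with independent neighbors). The fit
is single-step weighted least squares with weights $1/\max(\ell, 1)$ —
simpler than the iterative weighting of the reference LDSC software but
adequate for the intercept-direction diagnostic — and the intercept SE is
a delete-one-block jackknife over 50 contiguous marker blocks (fewer than
the reference software's 200 because desk-scale panels have fewer
markers). In the orchestrated pipeline the intercept is estimated on
markers with $\chi^2 \le 30$, the usual step-1 exclusion that keeps a
handful of true association outliers from leveraging the extrapolation to
$\ell = 0$; an intercept near 1 indicates no
confounding/heteroskedasticity-driven inflation. No sample-overlap or
attenuation corrections are applied (single cohort, in-sample LD; the
paper-scale question is only whether the robust intercept sits near 1
while the model-based one exceeds it).

## Clumping

Greedy p-value clumping: sort by ascending p (ties by chromosome,
position, marker ID), repeatedly take the best remaining marker as an
index SNP and absorb all remaining markers within 1 Mb on the same
chromosome with $r^2 \ge 0.8$ (genotype correlation, the PLINK `--r2`
convention on unphased data). The window is a package choice — the
independence criterion upstream analyses state is only $r^2 < 0.8$ — with
a whole-chromosome option. Output equals direct application of the rule
definition, asserted against an independent oracle on 200 random
instances.

## Gene and gene-set aggregation

Markers map to genes when their position falls within 50 kb of the
annotated gene start/stop (inclusive; multi-gene assignment allowed). The
gene statistic is the mean of the member SNPs' 1-df chi-squares (the
"snp-wise mean" construction). Its null must respect inter-SNP LD: for
standard normal scores with correlation $r$,
$\mathrm{cov}(\chi^2_i, \chi^2_j) = 2r^2$, so the sum $S$ has
$E[S] = m$ and $\mathrm{Var}(S) = 2\sum_{ij} r_{ij}^2$. A Satterthwaite
moment-matched scaled chi-square $a\chi^2_\nu$ with $a = \mathrm{Var}/2E$,
$\nu = 2E^2/\mathrm{Var}$ supplies the p-value; this reproduces the
independence case ($\chi^2_m$) and the perfect-LD case (1 df, gene p equal
to the single SNP p) exactly, and agrees with a seeded multivariate-normal
sampling fallback (used when the moments degenerate) within
$|\Delta\log_{10} p| < 0.2$ for 95% of genes in simulation. The member-SNP
correlation matrix comes from the genotypes (mean-imputed Pearson).

Competitive gene-set analysis regresses gene Z-scores
($Z = \Phi^{-1}(1-p)$) on a set-membership indicator plus gene-size
covariates (marker count and its log, proxies for size/density
corrections), reporting the one-sided p for a positive membership
coefficient. Sets need at least two analyzed member genes; a set covering
every gene is degenerate and skipped. The Bonferroni denominator for sets
is the analyzed-set count of the run at hand.

## The synthetic-data generator

The generator is the package's study stand-in, and its defaults are the
study conditions, not tuning knobs:

* **Genotypes** — per-SNP target frequencies uniform on a configurable MAF
  range; two haplotypes per individual by first-order Markov copying with
  probability `ld_decay` (0 gives independent markers; 0.5-0.6 gives
  adjacent $r^2$ around 0.25-0.36 with geometric decay); markers spread
  over up to 29 autosomes with strictly increasing positions at ~1 kb
  spacing; missingness injected completely at random; optional
  parent-parent-offspring trios by Mendelian transmission with a
  configurable genotyping-error rate.
* **Environment** — seven farms; continuous exposure is each individual's
  mean of a monthly series (farm baseline + 12-month sinusoid + noise)
  over its own birth-to-recording window, giving a multimodal,
  farm-structured temperature distribution with SD around 5 °C; the farm
  label itself serves as the categorical environment. Farm baselines are
  free parameters (defaults span 5-17 °C, a north-south spread) since no
  real station data is shipped.
* **Phenotype** — the generative mirror of the fitted model: optional
  additive, environmental, and interaction effects at chosen causal
  markers, covariate effects, and residuals
  $\varepsilon_i \sim N(0, \sigma_0^2 e^{\delta z_i})$ with $z$ the
  standardized environment; $\delta$ (`hetero_delta`) is the
  heteroskedasticity the sandwich estimator exists to absorb, the
  canonical violation in which trait variance differs across exposure
  levels. $\delta = 0.8$ makes the residual SD differ by a factor ~2.2
  between $\pm 1$ SD of exposure.

What the generator does **not** emulate: realistic cattle demography and
relatedness beyond trios, chip-specific LD structure, genotype-calling
error models, imputation artifacts, or real NOAA temperature series.
Passing calibration on these simulations shows the estimator behaves as
designed under the assumed data-generating process, not that any
particular real dataset is free of other confounding.

## Problem sizes and numerical choices

The calibration experiments use one simulated genome of 2000 markers at
$n = 1000$ with 200 phenotype replicates (type-I), a 5000-marker LD panel
(`ld_decay` 0.6) with 10 replicates (LD score intercepts), a 500-marker
panel at $n = 2000$ with 20 causal loci and 5 replicates per effect-size
grid point (recovery/power), and 3000 markers tiled into 1000 genes with
50 random sets (null uniformity) — sizes chosen so the whole suite runs on
a desktop in minutes while keeping Monte-Carlo error well below the
effects being measured. The power grid (0.01, 0.02, 0.035 kg per allele
per °C) comes from the generator's own scales: with
$\mathrm{sd}(E) \approx 5$ °C, $\mathrm{var}(G) \approx 0.39$ and
$n = 2000$, $\mathrm{SE}(\hat\beta_{g\times e}) \approx 0.007$, so the
grid spans low, intermediate and near-complete power at the suggestive
threshold $1/m$.

Calibration bands: a single genome fixes the leverage structure of every
test, so empirical sizes are judged against the binomial band of one
$m$-marker scan ($0.05 \pm 1.96\sqrt{0.05\cdot 0.95/m}$), with replicates
serving to pin the rate estimate itself; no finite-sample sandwich flavor
is exact at the $\pm 10^{-3}$ resolution a pooled-count band would imply.

Other numerical conventions: rank-deficient designs are an error naming
the collinear columns, never silent dropping; PCA mean-imputes missing
genotypes (regressions never do); PCs are computed once on the post-QC
panel; eigenvalues are clipped at zero when factorizing gene LD matrices,
with seeded sampling as fallback; p-values of exactly zero are clamped to
the smallest positive double in QQ tables with a warning; thresholds
("suggestive" $1/m$, "significant" $\alpha/m$) always derive from the
counts of the run at hand, never from constants.

## Known limitations

* The EMMAX-style fixed-ratio approximation understates per-SNP variance
  re-estimation; fine for a main-effect cross-check, not for reporting
  exact mixed-model p-values at strong loci.
* In-sample LD scores on short simulated chromosomes compress the
  $\ell$ range, so the LDSC intercept extrapolates; with true signal in
  the panel the $\chi^2 \le 30$ exclusion stabilizes it, but the
  intercept remains a direction diagnostic here, not a calibrated
  confounding estimate.
* The snp-wise mean null is a two-moment approximation; genes built from
  extremely ill-conditioned LD blocks fall back to sampling.
* Binary traits, variance-QTL tests, reaction-norm random-slope models,
  and two-step screening designs are out of scope.
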