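# gxescan

Genome-wide genotype-by-environment interaction scans (GWEIS) with
heteroskedasticity-robust inference, for quantitative traits measured
across heterogeneous environments — the motivating setting is growth
traits in beef cattle raised on farms in different climates, where a
variant's effect can reverse with temperature or farm and therefore shows
no main effect in an ordinary GWAS.

At every marker the package fits, by least squares,

```
y_i = mu0 + bg*G_i + be*E_i + bgxe*G_i*E_i
          + bc'C_i + bcxg'C_i*G_i + bcxe'C_i*E_i + e_i
```

with `G` the allele count, `E` the environmental measure (continuous
temperature or categorical farm), and `C` covariates (age, sex, birth
weight, genotype PCs). The parameter of interest is `bgxe`. Because the
residual variance typically differs across environmental exposure, the
interaction test uses Huber–White sandwich standard errors
`(X'X)^-1 X' diag(w) X (X'X)^-1` (HC0–HC3; the scan defaults to the
leverage-corrected HC3), which hold their nominal size where the
single-variance model-based test inflates genome-wide.

Around that core the package provides:

* marker/sample QC (MAF ≥ 0.05, call rate ≥ 90%, exact Hardy–Weinberg
  p ≥ 1e-6, trio Mendelian-error rate ≤ 2%, sample missingness ≤ 10%),
  with first-filter attribution and an idempotence guarantee;
* PLINK BED/BIM/FAM input and output, TSV sample tables, BED-like gene
  annotations, GMT gene sets;
* an EMMAX-style mixed-model GWAS baseline (GRM + REML + rotated GLS) to
  check that interaction hits lack main effects;
* inflation diagnostics: QQ tables, genomic-control lambda, and LD score
  regression intercepts with block-jackknife errors, computed separately
  for the robust and model-based statistics;
* greedy LD clumping (r² ≥ 0.8 within 1 Mb) for independent-SNP
  reporting;
* MAGMA-style gene aggregation ("snp-wise mean" with an LD-aware
  Satterthwaite null) and competitive gene-set regression;
* a synthetic-data generator (farms, seasonal temperature exposure,
  covariates, local LD, heteroskedastic residuals, trios) that makes the
  whole pipeline testable end to end without any external data.

## Worked example

The numbered scripts under `analysis/` are the study workflow. Stage 1
simulates a desk-scale analogue of a multi-farm cattle study (1350
animals, 8000 SNPs on 8 chromosomes with local LD, mean-temperature
exposure, three true interaction loci of 1.2 kg per allele per °C,
heteroskedastic residuals) and writes PLINK/TSV/BED/GMT files; stage 2
runs the full pipeline on those files:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_pipeline.R
```

which prints (abridged):

```
post-QC panel: 1350 samples x 8000 SNPs
suggestive threshold 1/m = 0.000125; 5 suggestive SNPs, 5 independent after clumping
inflation: lambda_GC robust 1.031 vs model-based 1.072; LDSC intercepts 1.135 vs 1.196

top interaction signals (robust):
       SNP CHR      BP      BETA            P
 SNP002001   3     659  1.538073 4.129866e-12
 SNP006000   6 1259274  1.492149 5.517554e-09
 SNP004000   4 1235414  1.059092 4.185647e-06
```

The three planted loci (`SNP002001`, `SNP004000`, `SNP006000`) head the
ranking, each `BETA` is near the simulated 1.2 kg/allele/°C, and the
robust statistics show less inflation than the model-based ones on the
same scan. Stage 3 quantifies that contrast under a pure null (empirical
type-I error 0.048 for the robust test vs 0.077 for the model-based test
at alpha = 0.05; 10-replicate mean LD score intercepts 1.15 vs 1.50), and
stage 4 verifies unbiased effect recovery with power rising
0.07 → 0.39 → 0.87 across the effect grid. All tables land under
`results/`.

The same machinery is available programmatically — `sim_config()`,
`simulate_study()`, `apply_qc()`, `run_gweis()`, `run_pipeline()`,
`gweis_type1_calibration()` and friends; see the function documentation
and the methods vignette (`vignettes/gweis-methods.Rmd`).

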