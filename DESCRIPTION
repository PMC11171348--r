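Package: gxescan
Title: Genome-Wide Genotype-by-Environment Interaction Scans with
    Heteroskedasticity-Robust Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-SNP genome-wide genotype-by-environment interaction
    (GWEIS) regression with Huber-White sandwich standard errors, marker
    and sample quality control, an EMMAX-style mixed-model main-effect
    GWAS baseline, inflation diagnostics (QQ tables, genomic control,
    LD score regression intercepts), greedy LD clumping, and MAGMA-style
    gene-based and competitive gene-set aggregation. Ships a synthetic
    cattle-study generator (farms, temperature exposure, covariates,
    heteroskedastic residuals) so the whole pipeline is testable without
    external data, plus PLINK BED/BIM/FAM input and output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    lmtest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
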