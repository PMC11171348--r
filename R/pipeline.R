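# End-to-end orchestration: QC -> PCA/design -> GWEIS (+ LMM GWAS baseline)
# -> diagnostics -> clumping -> gene and gene-set aggregation, from a single
# config, with a JSON run manifest of counts, thresholds and output hashes.

#' Multiple-testing thresholds
#'
#' The dual-threshold convention for genome-wide reporting: "suggestive"
#' is one expected false positive per scan (`1 / m`), "significant" is the
#' Bonferroni bound (`alpha / m`). With m = 598,430 markers these are
#' 1.67e-6 and 8.36e-8 to three significant figures.
#'
#' @param m_tests Number of tests (markers, genes, or sets).
#' @param alpha Family-wise error rate (default 0.05).
#' @return List `suggestive`, `bonferroni` at full precision.
#' @export
significance_thresholds <- function(m_tests, alpha = 0.05) {
  if (length(m_tests) != 1L || is.na(m_tests) || m_tests <= 0) {
    stop("m_tests must be a positive count", call. = FALSE)
  }
  list(suggestive = 1 / m_tests, bonferroni = alpha / m_tests)
}

.hash_file <- function(path) unname(tools::md5sum(path))

#' Validate a pipeline run configuration
#'
#' @param config Named list (or YAML path) with elements: `plink_prefix`,
#'   `sample_table`, `phenotype`, `environment` (list `column`, `kind`,
#'   optional `reference_level`), optional `covariates` (character),
#'   `n_pcs` (default 20), optional `gene_annotation`, `gene_sets`,
#'   `out_dir`, `alpha` (default 0.05), `seed`, and logical stage toggles
#'   `run_gwas`, `run_diagnostics`, `run_clump`, `run_genes`.
#' @return The validated config (class `run_config`).
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("plink_prefix", "sample_table", "phenotype", "environment",
            "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop("run config missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (f in paste0(config$plink_prefix, c(".bed", ".bim", ".fam"))) {
    if (!file.exists(f)) stop("missing input file: ", f, call. = FALSE)
  }
  if (!file.exists(config$sample_table)) {
    stop("missing input file: ", config$sample_table, call. = FALSE)
  }
  if (!all(c("column", "kind") %in% names(config$environment))) {
    stop("environment spec needs 'column' and 'kind'", call. = FALSE)
  }
  defaults <- list(covariates = character(0), n_pcs = 20L, alpha = 0.05,
                   seed = 1L, flavor = "HC1", run_gwas = TRUE,
                   run_diagnostics = TRUE, run_clump = TRUE,
                   run_genes = TRUE, clump_r2 = 0.8, clump_window_bp = 1e6,
                   gene_window_bp = 50000, ld_window_bp = 1e6)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  # schema check before any compute
  tbl_head <- utils::read.delim(config$sample_table, nrows = 1,
                                check.names = FALSE)
  want <- c("IID", config$phenotype, config$covariates,
            config$environment$column)
  absent <- setdiff(want, names(tbl_head))
  if (length(absent)) {
    stop("sample table lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  class(config) <- "run_config"
  config
}

#' Run the full interaction-scan pipeline
#'
#' Stages, in order: load and QC the genotypes; build PCs and covariates;
#' GWEIS at every marker (robust and model-based interaction p-values);
#' main-effect mixed-model GWAS baseline; inflation diagnostics (QQ
#' tables, genomic control lambda, LD score intercepts for both variance
#' estimators); greedy LD clumping of the robust interaction results; and
#' gene / gene-set aggregation of the robust interaction p-values with the
#' GWAS baseline carried alongside. Every stage writes a TSV under
#' `out_dir`; a JSON manifest records counts, the thresholds derived from
#' this run's post-QC panel, the seed, and an md5 hash per output.
#'
#' @param config A `run_config` (or list/YAML path accepted by
#'   [validate_run_config()]).
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  log_stage <- function(fmt, ...) message(sprintf(paste0("[%s] ", fmt),
                                                  format(Sys.time(), "%H:%M:%S"),
                                                  ...))

  log_stage("load: reading %s", config$plink_prefix)
  G0 <- read_plink(config$plink_prefix)
  tbl <- read_sample_table(config$sample_table,
                           phenotype = config$phenotype,
                           covariates = config$covariates,
                           environment = config$environment$column)
  tbl <- align_samples(tbl, G0)

  log_stage("qc: %d samples x %d SNPs in", n_samples(G0), n_markers(G0))
  qc <- apply_qc(G0)
  G <- qc$genotypes
  write_qc_report(qc$report, subset_genotypes(G0, qc$report$sample_mask),
                  file.path(config$out_dir, "qc"))
  outputs <- c(outputs, file.path(config$out_dir,
                                  c("qc_snps.tsv", "qc.json")))
  tbl <- align_samples(tbl, G)
  y <- tbl[[config$phenotype]]
  E <- env_vector(tbl[[config$environment$column]],
                  kind = config$environment$kind)
  if (E$kind == "categorical" &&
      !is.null(config$environment$reference_level)) {
    E$levels <- c(config$environment$reference_level,
                  setdiff(E$levels, config$environment$reference_level))
  }

  log_stage("design: %d covariates + %d PCs", length(config$covariates),
            config$n_pcs)
  C <- tbl[, config$covariates, drop = FALSE]
  if (config$n_pcs > 0) {
    C <- cbind(C, genotype_pca(G, config$n_pcs))
  }
  C <- as.matrix(C)

  thresholds <- significance_thresholds(n_markers(G), config$alpha)
  log_stage("gweis: %d SNPs; suggestive %.3g, bonferroni %.3g",
            n_markers(G), thresholds$suggestive, thresholds$bonferroni)
  gweis <- run_gweis(G, E, C, y, flavor = config$flavor,
                     reference_level = config$environment$reference_level)
  gweis_path <- file.path(config$out_dir, "gweis.tsv")
  write_snp_summary(gweis, gweis_path)
  outputs <- c(outputs, gweis_path)

  gwas <- NULL
  if (isTRUE(config$run_gwas)) {
    log_stage("gwas: mixed-model baseline")
    used <- !is.na(y)
    Gu <- subset_genotypes(G, samples = used)
    K <- compute_grm(Gu)
    null <- fit_null_reml(y[used], C[used, , drop = FALSE], K)
    gwas <- lmm_assoc(Gu, y[used], C[used, , drop = FALSE], null)
    gwas_path <- file.path(config$out_dir, "gwas.tsv")
    write_summary_tsv(gwas, gwas_path)
    outputs <- c(outputs, gwas_path)
    gweis$p_gwas <- gwas$p[match(gweis$snp, gwas$snp)]
  }

  diag_res <- NULL
  if (isTRUE(config$run_diagnostics)) {
    log_stage("diagnostics: QQ, lambda, LDSC intercepts")
    ok <- gweis$reason == "."
    ell <- ld_scores(G, window_bp = config$ld_window_bp)
    fit_r <- ldsc_intercept(p = gweis$p_robust[ok], ld = ell[ok],
                            chi2_max = 30)
    fit_m <- ldsc_intercept(p = gweis$p_model[ok], ld = ell[ok],
                            chi2_max = 30)
    diag_res <- data.frame(
      estimator = c("robust", "model"),
      lambda_gc = c(genomic_inflation(p = gweis$p_robust[ok]),
                    genomic_inflation(p = gweis$p_model[ok])),
      ldsc_intercept = c(fit_r$intercept, fit_m$intercept),
      ldsc_intercept_se = c(fit_r$intercept_se, fit_m$intercept_se))
    diag_path <- file.path(config$out_dir, "diagnostics.tsv")
    write_summary_tsv(diag_res, diag_path)
    qq <- qq_table(gweis$p_robust[ok])
    qq_path <- file.path(config$out_dir, "qq_robust.tsv")
    write_summary_tsv(qq, qq_path)
    outputs <- c(outputs, diag_path, qq_path)
  }

  clump_res <- NULL
  if (isTRUE(config$run_clump)) {
    hits <- gweis[!is.na(gweis$p_robust) &
                    gweis$p_robust < thresholds$suggestive, , drop = FALSE]
    log_stage("clump: %d suggestive SNPs", nrow(hits))
    if (nrow(hits)) {
      clump_res <- clump(hits, G, r2_threshold = config$clump_r2,
                         window_bp = config$clump_window_bp)
      clump_path <- file.path(config$out_dir, "clumps.tsv")
      write_summary_tsv(clump_res, clump_path)
      outputs <- c(outputs, clump_path)
    }
  }

  gene_res <- set_res <- NULL
  gene_thresholds <- set_thresholds <- NULL
  if (isTRUE(config$run_genes) && !is.null(config$gene_annotation)) {
    log_stage("genes: snp-wise mean aggregation")
    genes <- read_gene_annotation(config$gene_annotation)
    gene_res <- run_gene_analysis(gweis, G, genes,
                                  window_bp = config$gene_window_bp)
    if (!is.null(gwas)) {
      gwas_gene <- run_gene_analysis(
        structure(data.frame(gweis[, c("snp", "chr", "pos")],
                             p_robust = gwas$p[match(gweis$snp, gwas$snp)]),
                  class = c("snp_summary", "data.frame")),
        G, genes, window_bp = config$gene_window_bp)
      gene_res$p_gwas <- gwas_gene$p[match(gene_res$gene, gwas_gene$gene)]
    }
    gene_thresholds <- significance_thresholds(nrow(gene_res), config$alpha)
    write_summary_tsv(gene_res, file.path(config$out_dir, "genes.tsv"))
    outputs <- c(outputs, file.path(config$out_dir, "genes.tsv"))
    if (!is.null(config$gene_sets)) {
      sets <- read_gene_sets(config$gene_sets, annotation = genes)
      set_res <- gene_set_competitive(gene_res, sets)
      if (!is.null(gwas)) {
        gr2 <- gene_res
        gr2$z <- stats::qnorm(gr2$p_gwas, lower.tail = FALSE)
        set_gwas <- gene_set_competitive(gr2, sets)
        set_res$p_gwas <- set_gwas$p[match(set_res$set, set_gwas$set)]
      }
      n_sets <- sum(set_res$reason == ".")
      set_thresholds <- significance_thresholds(max(n_sets, 1L),
                                                config$alpha)
      write_summary_tsv(set_res, file.path(config$out_dir, "gene_sets.tsv"))
      outputs <- c(outputs, file.path(config$out_dir, "gene_sets.tsv"))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gxescan")),
    seed = config$seed,
    n_samples_post_qc = n_samples(G),
    n_snps_post_qc = n_markers(G),
    qc_counts = as.list(qc$report$counts),
    thresholds = list(snp = thresholds, gene = gene_thresholds,
                      gene_set = set_thresholds),
    n_suggestive_snps = sum(gweis$p_robust < thresholds$suggestive,
                            na.rm = TRUE),
    n_independent_snps = if (!is.null(clump_res)) nrow(clump_res) else 0L,
    outputs = as.list(stats::setNames(vapply(outputs, .hash_file,
                                             character(1)),
                                      basename(outputs)))
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
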