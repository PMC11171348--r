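# MAGMA-style aggregation: SNP-to-gene mapping with 50 kb windows, the
# snp-wise mean gene test with an LD-aware null, and competitive gene-set
# regression on gene Z-scores.

#' Map markers to genes with a flanking window
#'
#' A marker belongs to a gene when its position lies in
#' `[start - window_bp, stop + window_bp]`, inclusive on both ends;
#' markers may map to several overlapping genes.
#'
#' @param map Marker map data frame (`snp`, `chr`, `pos`).
#' @param genes Gene annotation from [read_gene_annotation()].
#' @param window_bp Flank size (default 50000, i.e. 50 kb up- and
#'   downstream of the transcription start/stop).
#' @return List with `gene_snps` (named list of marker indices per gene,
#'   genes with no marker omitted) and `n_unmapped` (markers in no gene).
#' @export
map_snps_to_genes <- function(map, genes, window_bp = 50000) {
  hit <- rep(FALSE, nrow(map))
  gene_snps <- vector("list", nrow(genes))
  names(gene_snps) <- genes$gene
  for (i in seq_len(nrow(genes))) {
    jj <- which(map$chr == genes$chr[i] &
                  map$pos >= genes$start[i] - window_bp &
                  map$pos <= genes$stop[i] + window_bp)
    if (length(jj)) {
      gene_snps[[i]] <- jj
      hit[jj] <- TRUE
    }
  }
  keep <- lengths(gene_snps) > 0L
  list(gene_snps = gene_snps[keep], n_unmapped = sum(!hit))
}

#' Snp-wise mean gene test
#'
#' Transforms the member SNP p-values to 1-df chi-squares and tests their
#' mean against an LD-aware null. The null of the sum is approximated by a
#' Satterthwaite moment-matched scaled chi-square: for standard normal
#' scores with correlation `r`, `cov(chi2_i, chi2_j) = 2 r^2`, so
#' `Var(sum) = 2 * sum(R * R)`. This reproduces the independence case
#' (`chi2_m`) and the perfect-LD case (1 df) exactly. When the
#' moment-matched solution degenerates, a seeded multivariate-normal
#' sampling fallback is used.
#'
#' @param snp_p Member SNP p-values (length >= 1).
#' @param R SNP genotype correlation matrix (not squared), dimensions
#'   matching `snp_p`. Ignored for single-SNP genes.
#' @param method `"satterthwaite"` (default) or `"sampling"` to force the
#'   empirical fallback.
#' @param n_draws Draws for the sampling fallback.
#' @param seed Seed for the sampling fallback.
#' @return List: `stat` (mean chi-square), `p`, `z` (probit of `1 - p`),
#'   `n_snps`, `method`.
#' @export
gene_test_snpwise_mean <- function(snp_p, R = NULL,
                                   method = c("satterthwaite", "sampling"),
                                   n_draws = 1e5, seed = 20240101) {
  method <- match.arg(method)
  m <- length(snp_p)
  if (m < 1L) stop("need at least one SNP p-value", call. = FALSE)
  if (any(snp_p <= 0 | snp_p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  chi2 <- stats::qchisq(snp_p, df = 1, lower.tail = FALSE)
  S <- sum(chi2)
  if (m == 1L) {
    p <- snp_p
    return(list(stat = S, p = p, z = stats::qnorm(p, lower.tail = FALSE),
                n_snps = 1L, method = "exact"))
  }
  if (is.null(R) || !all(dim(R) == c(m, m))) {
    stop("R must be an m x m correlation matrix", call. = FALSE)
  }
  vS <- 2 * sum(R^2)
  eS <- m
  if (method == "satterthwaite" && is.finite(vS) && vS > 0) {
    a <- vS / (2 * eS)
    nu <- 2 * eS^2 / vS
    p <- stats::pchisq(S / a, df = nu, lower.tail = FALSE)
  } else {
    method <- "sampling"
    p <- NA_real_
  }
  if (method == "sampling" || !is.finite(p)) {
    ev <- eigen(R, symmetric = TRUE)
    vals <- pmax(ev$values, 0)
    if (sum(vals) <= 0) stop("R is not PSD after clipping", call. = FALSE)
    set.seed(seed)
    Lhalf <- ev$vectors %*% diag(sqrt(vals), m)
    draws <- matrix(stats::rnorm(n_draws * m), n_draws, m) %*% t(Lhalf)
    Ssim <- rowSums(draws^2)
    p <- (1 + sum(Ssim >= S)) / (n_draws + 1)
    method <- "sampling"
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  list(stat = S / m, p = p, z = stats::qnorm(p, lower.tail = FALSE),
       n_snps = m, method = method)
}

#' Gene-based analysis of a GWEIS summary
#'
#' Maps markers to genes and applies the snp-wise mean test per gene,
#' with the member-SNP correlation matrix estimated from the genotypes
#' (mean-imputed, Pearson).
#'
#' @param summary A `snp_summary` from [run_gweis()].
#' @param G The [genotype_matrix()] behind the summary.
#' @param genes Gene annotation data frame.
#' @param window_bp Mapping window (default 50 kb).
#' @param p_col Summary column holding the SNP p-values (default
#'   `p_robust`).
#' @param method Passed to [gene_test_snpwise_mean()].
#' @return Data frame (class `gene_result`): `gene`, `chr`, `start`,
#'   `stop`, `n_snps`, `stat`, `p`, `z`.
#' @export
run_gene_analysis <- function(summary, G, genes, window_bp = 50000,
                              p_col = "p_robust",
                              method = "satterthwaite") {
  mapping <- map_snps_to_genes(G$map, genes, window_bp)
  X <- impute_mean(G)
  out <- vector("list", length(mapping$gene_snps))
  for (i in seq_along(mapping$gene_snps)) {
    gene <- names(mapping$gene_snps)[i]
    jj <- mapping$gene_snps[[i]]
    pv <- summary[[p_col]][jj]
    ok <- !is.na(pv)
    jj <- jj[ok]; pv <- pv[ok]
    if (!length(jj)) next
    R <- if (length(jj) > 1L) {
      stats::cor(X[, jj, drop = FALSE])
    } else NULL
    gt <- gene_test_snpwise_mean(pv, R, method = method)
    gi <- match(gene, genes$gene)
    out[[i]] <- data.frame(gene = gene, chr = genes$chr[gi],
                           start = genes$start[gi], stop = genes$stop[gi],
                           n_snps = gt$n_snps, stat = gt$stat, p = gt$p,
                           z = gt$z, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no gene mapped any analyzed SNP", call. = FALSE)
  class(res) <- c("gene_result", "data.frame")
  res
}

#' Competitive gene-set analysis
#'
#' For each gene set, regresses the gene Z-scores on a membership
#' indicator plus gene-size covariates (`n_snps` and `log(n_snps)`), over
#' all analyzed genes, and reports the one-sided p-value for a positive
#' membership coefficient: do member genes carry more interaction signal
#' than the rest of the genome?
#'
#' @param gene_results A `gene_result` data frame (needs `gene`, `z`,
#'   `n_snps`).
#' @param sets A `gene_set_collection` (named list of gene IDs).
#' @param min_genes Minimum analyzed member genes per set (default 2;
#'   smaller sets are excluded before analysis).
#' @return Data frame: `set`, `n_genes`, `beta`, `se`, `p`, `reason`
#'   ("." when analyzed; skipped sets carry the reason).
#' @export
gene_set_competitive <- function(gene_results, sets, min_genes = 2L) {
  z <- gene_results$z
  covar <- cbind(n_snps = gene_results$n_snps,
                 log_n_snps = log(gene_results$n_snps))
  n_gene <- nrow(gene_results)
  rows <- lapply(names(sets), function(s) {
    member <- as.integer(gene_results$gene %in% sets[[s]])
    n_in <- sum(member)
    if (n_in < min_genes) {
      return(data.frame(set = s, n_genes = n_in, beta = NA_real_,
                        se = NA_real_, p = NA_real_,
                        reason = "too_few_genes", stringsAsFactors = FALSE))
    }
    if (n_in == n_gene) {
      return(data.frame(set = s, n_genes = n_in, beta = NA_real_,
                        se = NA_real_, p = NA_real_,
                        reason = "covers_all_genes", stringsAsFactors = FALSE))
    }
    fit <- stats::lm(z ~ member + covar)
    sm <- summary(fit)$coefficients
    bi <- match("member", rownames(sm))
    tt <- sm[bi, "t value"]
    data.frame(set = s, n_genes = n_in, beta = sm[bi, "Estimate"],
               se = sm[bi, "Std. Error"],
               p = stats::pt(tt, df = fit$df.residual, lower.tail = FALSE),
               reason = ".", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
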