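# Marker and sample quality control: exact Hardy-Weinberg test, trio-based
# Mendelian-error rates, and the ordered filter cascade with per-filter
# attribution.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the sum of the probabilities of all heterozygote counts whose
#' conditional probability is less than or equal to that of the observed
#' count. Probabilities follow the standard hypergeometric-type recurrence
#' over heterozygote counts of matching parity. Monomorphic SNPs (one
#' allele absent) return `p = 1` by convention.
#'
#' @param n_hom1 Count of one homozygote class.
#' @param n_het Heterozygote count.
#' @param n_hom2 Count of the other homozygote class.
#' @return Exact two-sided p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  if (any(c(n_hom1, n_het, n_hom2) < 0)) {
    stop("genotype counts must be non-negative", call. = FALSE)
  }
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) stop("no genotypes", call. = FALSE)
  rare <- 2L * min(n_hom1, n_hom2) + n_het   # rare allele copies
  if (rare == 0L) return(1)                  # monomorphic
  # possible heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2L, min(rare, 2L * n - rare), by = 2L)
  # unnormalized probabilities via the recurrence
  #   P(h + 2) / P(h) = 4 * hom_rare(h) * hom_common(h) / ((h+2) * (h+1))
  logp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1L]
    hr <- (rare - h) / 2
    hc <- n - h - hr
    logp[k] <- logp[k - 1L] +
      log(4 * hr * hc) - log((h + 2) * (h + 1))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_het, hets)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

#' Per-SNP Mendelian-error rate from trios
#'
#' A trio is an error at a SNP when the child genotype is impossible given
#' the parents under biallelic Mendelian transmission: the child's A1
#' count must lie between `(father == 2) + (mother == 2)` and
#' `(father >= 1) + (mother >= 1)`. The rate is errors over trios with all
#' three genotypes non-missing; SNPs with no complete trio get `NA`.
#'
#' @param G A [genotype_matrix()].
#' @param trios Data frame with columns `child`, `father`, `mother`
#'   (sample IDs present in `G`).
#' @return Numeric vector of per-SNP error rates (NA when undefined).
#' @export
mendel_error_rate <- function(G, trios) {
  idx <- function(ids) {
    i <- match(ids, G$samples)
    if (anyNA(i)) stop("trio member(s) not in sample list", call. = FALSE)
    i
  }
  ci <- idx(trios$child); fi <- idx(trios$father); mi <- idx(trios$mother)
  X <- G$genotypes
  kid <- X[ci, , drop = FALSE]
  fat <- X[fi, , drop = FALSE]
  mot <- X[mi, , drop = FALSE]
  ok <- !is.na(kid) & !is.na(fat) & !is.na(mot)
  lo <- (fat == 2L) + (mot == 2L)
  hi <- (fat >= 1L) + (mot >= 1L)
  err <- ok & (kid < lo | kid > hi)
  denom <- colSums(ok)
  rate <- colSums(err) / denom
  rate[denom == 0] <- NA_real_
  rate
}

#' QC thresholds
#'
#' @param maf Minimum minor allele frequency (markers below are dropped).
#' @param call_rate Minimum SNP call rate.
#' @param hwe Hardy-Weinberg exact-test p-value floor.
#' @param mind Maximum per-sample missingness.
#' @param mendel Maximum per-SNP Mendelian-error rate (used when trios are
#'   supplied).
#' @return List of thresholds.
#' @export
qc_thresholds <- function(maf = 0.05, call_rate = 0.90, hwe = 1e-6,
                          mind = 0.10, mendel = 0.02) {
  th <- list(maf = maf, call_rate = call_rate, hwe = hwe, mind = mind,
             mendel = mendel)
  if (any(unlist(th) <= 0)) stop("thresholds must be positive", call. = FALSE)
  th
}

#' Apply marker and sample quality control
#'
#' Single-pass cascade in a documented order. Samples first: individuals
#' missing more than `mind` of their genotypes are dropped. Then per SNP,
#' each marker is attributed to the first filter that removes it, in the
#' order: missing/invalid position; duplicate (chromosome, position); call
#' rate below `call_rate`; minor allele frequency below `maf` (computed on
#' non-missing genotypes of retained samples); Hardy-Weinberg exact p
#' below `hwe`; Mendelian-error rate above `mendel` (only when `trios` is
#' supplied). Re-running on the filtered output removes nothing.
#'
#' @param G A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()] list.
#' @param trios Optional trio table for the Mendelian filter.
#' @return List with `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (class `qc_report`: per-filter counts, masks, thresholds).
#' @export
apply_qc <- function(G, thresholds = qc_thresholds(), trios = NULL) {
  n <- n_samples(G); m <- n_markers(G)
  sample_miss <- rowMeans(is.na(G$genotypes))
  keep_sample <- sample_miss <= thresholds$mind
  Gs <- subset_genotypes(G, samples = keep_sample)
  X <- Gs$genotypes
  reason <- rep(NA_character_, m)
  bad_pos <- is.na(Gs$map$pos) | Gs$map$pos <= 0
  reason[bad_pos & is.na(reason)] <- "position_missing"
  dup <- duplicated(Gs$map[, c("chr", "pos")]) & !bad_pos
  reason[dup & is.na(reason)] <- "duplicate"
  call_rate <- colMeans(!is.na(X))
  reason[is.na(reason) & call_rate < thresholds$call_rate] <- "call_rate"
  f <- colMeans(X, na.rm = TRUE) / 2
  mafv <- pmin(f, 1 - f)
  mafv[is.nan(mafv)] <- 0
  reason[is.na(reason) & mafv < thresholds$maf] <- "maf"
  todo <- which(is.na(reason))
  if (length(todo)) {
    hwe_p <- vapply(todo, function(j) {
      g <- X[, j]
      hwe_exact_test(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                     sum(g == 2L, na.rm = TRUE))
    }, numeric(1))
    reason[todo[hwe_p < thresholds$hwe]] <- "hwe"
  }
  if (!is.null(trios)) {
    present <- trios$child %in% Gs$samples & trios$father %in% Gs$samples &
      trios$mother %in% Gs$samples
    if (any(present)) {
      mer <- mendel_error_rate(Gs, trios[present, , drop = FALSE])
      fail <- !is.na(mer) & mer > thresholds$mendel
      reason[is.na(reason) & fail] <- "mendel"
    }
  }
  keep_snp <- is.na(reason)
  if (!any(keep_snp)) {
    stop("QC removed every SNP: empty panel, pipeline cannot proceed",
         call. = FALSE)
  }
  filters <- c("position_missing", "duplicate", "call_rate", "maf", "hwe",
               "mendel")
  counts <- vapply(filters, function(f) sum(reason == f, na.rm = TRUE),
                   integer(1))
  report <- structure(list(
    n_samples_in = n, n_snps_in = m,
    n_samples_removed = sum(!keep_sample),
    n_snps_removed = sum(!keep_snp),
    counts = counts, reason = reason,
    snp_mask = keep_snp, sample_mask = keep_sample,
    thresholds = thresholds
  ), class = "qc_report")
  list(genotypes = subset_genotypes(Gs, markers = keep_snp),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d/%d samples and %d/%d SNPs removed\n",
              x$n_samples_removed, x$n_samples_in,
              x$n_snps_removed, x$n_snps_in))
  for (f in names(x$counts)) {
    cat(sprintf("  %-17s %d\n", f, x$counts[[f]]))
  }
  invisible(x)
}

#' Serialize a QC report
#'
#' Writes a per-SNP TSV (snp, reason, kept) and a JSON summary of counts
#' and thresholds.
#'
#' @param report A `qc_report`.
#' @param G The pre-QC [genotype_matrix()] the report refers to (its
#'   retained-sample marker map is used for SNP IDs).
#' @param prefix Output prefix; writes `prefix_snps.tsv`, `prefix.json`.
#' @return Invisibly, the two paths.
#' @export
write_qc_report <- function(report, G, prefix) {
  snp_path <- paste0(prefix, "_snps.tsv")
  json_path <- paste0(prefix, ".json")
  utils::write.table(
    data.frame(snp = G$map$snp,
               kept = report$snp_mask,
               reason = ifelse(is.na(report$reason), ".", report$reason)),
    snp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(counts = as.list(report$counts),
         n_samples_removed = report$n_samples_removed,
         n_snps_removed = report$n_snps_removed,
         thresholds = report$thresholds),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(snp_path, json_path))
}
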