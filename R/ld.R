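# Genotype-based LD: pairwise r^2 (composite, unphased), greedy p-value
# clumping for independent-SNP reporting, and windowed LD scores for the
# LD score regression diagnostics.

#' Squared genotype correlation between two markers
#'
#' Squared Pearson correlation of the additive genotype codes over shared
#' non-missing samples (composite LD on unphased data, the PLINK `--r2`
#' convention). Invariant to allele flips.
#'
#' @param G A [genotype_matrix()].
#' @param snp_i,snp_j Marker indices or IDs.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(G, snp_i, snp_j) {
  ix <- if (is.character(snp_i)) match(snp_i, G$map$snp) else snp_i
  jx <- if (is.character(snp_j)) match(snp_j, G$map$snp) else snp_j
  gi <- G$genotypes[, ix]
  gj <- G$genotypes[, jx]
  ok <- !is.na(gi) & !is.na(gj)
  if (stats::var(gi[ok]) == 0 || stats::var(gj[ok]) == 0) {
    stop("r2 undefined for a monomorphic SNP", call. = FALSE)
  }
  stats::cor(gi[ok], gj[ok])^2
}

#' Greedy LD clumping of a SNP summary
#'
#' Sorts markers by ascending p-value (ties by chromosome, position, then
#' marker ID), repeatedly takes the best remaining marker as an index SNP,
#' and removes every remaining marker on the same chromosome within
#' `window_bp` whose genotype r-squared with the index reaches
#' `r2_threshold`. Retained index SNPs are mutually "independent" at the
#' chosen threshold.
#'
#' @param summary A `snp_summary` data frame (needs `snp`, `chr`, `pos`
#'   and a p-value column).
#' @param G The [genotype_matrix()] the summary rows map into.
#' @param r2_threshold Clumping threshold (markers with `r2 >=` this are
#'   absorbed into the index SNP's clump). Default 0.8.
#' @param window_bp Physical window around the index SNP. Default 1 Mb;
#'   `Inf` clumps whole chromosomes.
#' @param p_col Which p-value column to rank on (default `p_robust`).
#' @return Data frame of index SNPs: `snp`, `chr`, `pos`, `p`,
#'   `n_clumped`, `members` (comma-separated absorbed marker IDs).
#' @export
clump <- function(summary, G, r2_threshold = 0.8, window_bp = 1e6,
                  p_col = "p_robust") {
  rows <- which(!is.na(summary[[p_col]]))
  ord <- rows[order(summary[[p_col]][rows],
                    summary$chr[rows], summary$pos[rows],
                    summary$snp[rows])]
  gidx <- match(summary$snp, G$map$snp)
  remaining <- ord
  out <- list()
  while (length(remaining)) {
    i <- remaining[1]
    remaining <- remaining[-1]
    same <- remaining[summary$chr[remaining] == summary$chr[i] &
                        abs(summary$pos[remaining] - summary$pos[i]) <=
                        window_bp]
    absorbed <- integer(0)
    if (length(same)) {
      r2 <- vapply(same, function(j) ld_r2(G, gidx[i], gidx[j]), numeric(1))
      absorbed <- same[r2 >= r2_threshold]
      remaining <- setdiff(remaining, absorbed)
    }
    out[[length(out) + 1L]] <- data.frame(
      snp = summary$snp[i], chr = summary$chr[i], pos = summary$pos[i],
      p = summary[[p_col]][i], n_clumped = length(absorbed),
      members = paste(summary$snp[absorbed], collapse = ","),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Windowed LD scores
#'
#' For each marker, the sum of bias-adjusted squared correlations with all
#' markers within `window_bp` on the same chromosome:
#' `r2_adj = r2 - (1 - r2) / (n - 2)`, with the self term included as
#' exactly 1. The adjustment removes the `1/n` upward bias of the sample
#' r-squared under the null, so independent panels have scores near 1.
#'
#' @param G A [genotype_matrix()].
#' @param window_bp Window size in base pairs (default 1 Mb).
#' @return Numeric vector of LD scores aligned with `G$map`.
#' @export
ld_scores <- function(G, window_bp = 1e6) {
  if (window_bp <= 0) stop("window_bp must be positive", call. = FALSE)
  X <- impute_mean(G)
  n <- nrow(X)
  ell <- rep(1, ncol(X))
  for (c in unique(G$map$chr)) {
    jj <- which(G$map$chr == c)
    if (length(jj) < 2L) next
    pos <- G$map$pos[jj]
    o <- order(pos)
    jj <- jj[o]; pos <- pos[o]
    Xc <- scale(X[, jj, drop = FALSE])
    mono <- attr(Xc, "scaled:scale") == 0
    block <- 512L
    for (s in seq(1L, length(jj), by = block)) {
      e <- min(s + block - 1L, length(jj))
      lo <- findInterval(pos[s:e] - window_bp, pos, left.open = TRUE) + 1L
      hi <- findInterval(pos[s:e] + window_bp, pos)
      nb_lo <- min(lo); nb_hi <- max(hi)
      nb <- nb_lo:nb_hi
      R <- crossprod(Xc[, s:e, drop = FALSE], Xc[, nb, drop = FALSE]) /
        (n - 1)
      r2 <- R^2
      r2a <- r2 - (1 - r2) / (n - 2)
      for (t in seq_len(e - s + 1L)) {
        cols <- (lo[t]:hi[t]) - nb_lo + 1L
        self <- (s + t - 1L) - nb_lo + 1L
        cols <- setdiff(cols, self)
        if (mono[s + t - 1L]) next
        good <- cols[!mono[cols + nb_lo - 1L]]
        ell[jj[s + t - 1L]] <- 1 + sum(r2a[t, good])
      }
    }
  }
  ell
}
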