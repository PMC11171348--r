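# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-derivations (enumeration, dense linear algebra,
# direct rule application) kept separate from the package's own code paths.

# Exact HWE probabilities by direct enumeration: P(het = h | allele counts)
# = n! / (n_AA! n_AB! n_BB!) * 2^h * nA! nB! / (2n)!  summed over all h
# with the observed h's probability or less.
hwe_enum_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  nA <- 2 * n_hom1 + n_het
  nB <- 2 * n_hom2 + n_het
  hs <- seq(nA %% 2, min(nA, nB), by = 2)
  logp <- vapply(hs, function(h) {
    naa <- (nA - h) / 2
    nbb <- (nB - h) / 2
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_het, hs)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

# Dense-matrix sandwich oracle: (X'X)^-1 X' diag(w) X (X'X)^-1 with the
# literal triple product.
sandwich_oracle <- function(X, res, flavor = "HC1") {
  n <- nrow(X); p <- ncol(X)
  bread <- solve(t(X) %*% X)
  H <- X %*% bread %*% t(X)
  h <- diag(H)
  w <- switch(flavor,
              HC0 = res^2,
              HC1 = res^2 * n / (n - p),
              HC2 = res^2 / (1 - h),
              HC3 = res^2 / (1 - h)^2)
  bread %*% t(X) %*% diag(w) %*% X %*% bread
}

# Direct application of the greedy clumping rule, written independently of
# clump(): repeatedly pick the smallest-p remaining SNP, drop all remaining
# SNPs on its chromosome within the window with r2 >= threshold.
clump_oracle <- function(p, chr, pos, ids, geno, r2_threshold, window_bp) {
  alive <- order(p, chr, pos, ids)
  kept <- character(0)
  while (length(alive)) {
    i <- alive[1]
    kept <- c(kept, ids[i])
    drop <- logical(length(alive))
    for (k in seq_along(alive)[-1]) {
      j <- alive[k]
      if (chr[j] == chr[i] && abs(pos[j] - pos[i]) <= window_bp) {
        r2 <- suppressWarnings(cor(geno[, i], geno[, j])^2)
        if (!is.na(r2) && r2 >= r2_threshold) drop[k] <- TRUE
      }
    }
    alive <- alive[-c(1, which(drop))]
  }
  kept
}

# Small complete synthetic study used by several test files.
make_study <- function(n = 300, m = 200, seed = 1, ...) {
  cfg <- sim_config(n_samples = n, n_snps = m, seed = seed, ...)
  simulate_study(cfg, env_kind = "continuous", n_causal = 0)
}
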