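# LD tools: pairwise r2, greedy clumping vs the rule oracle, LD scores.

test_that("r2 basics: identity, allele flips, independence, monomorphic error", {
  cfg <- sim_config(n_samples = 10000, n_snps = 4, seed = 71)
  G <- simulate_genotypes(cfg)
  G$genotypes[, 2] <- G$genotypes[, 1]
  G$genotypes[, 3] <- 2L - G$genotypes[, 1]
  expect_equal(ld_r2(G, 1, 2), 1)
  expect_equal(ld_r2(G, 1, 3), 1) # flip-invariant after squaring
  expect_lt(ld_r2(G, 1, 4), 0.01) # null r2 ~ chi2_1 / n
  G$genotypes[, 4] <- 0L
  expect_error(ld_r2(G, 1, 4), "monomorphic")
})

test_that("clumping applies the greedy rule on the worked example", {
  set.seed(72)
  n <- 500
  g1 <- rbinom(n, 2, 0.4)
  g2 <- ifelse(runif(n) < 0.95, g1, rbinom(n, 2, 0.4)) # r2 ~ 0.9 with g1
  g3 <- rbinom(n, 2, 0.4)
  geno <- cbind(g1, g2, g3)
  map <- data.frame(snp = c("s1", "s2", "s3"), chr = "1",
                    pos = c(1000, 2000, 3000), a1 = "A", a2 = "B")
  G <- genotype_matrix(geno, map, sprintf("I%03d", 1:n))
  expect_gt(ld_r2(G, 1, 2), 0.8)
  expect_lt(ld_r2(G, 1, 3), 0.5)
  summ <- data.frame(snp = map$snp, chr = map$chr, pos = map$pos,
                     p_robust = c(1e-8, 1e-6, 1e-4))
  cl <- clump(summ, G, r2_threshold = 0.8, window_bp = 1e6)
  expect_equal(cl$snp, c("s1", "s3"))
  expect_equal(cl$members[1], "s2")
})

test_that("mutually independent SNPs are all retained", {
  cfg <- sim_config(n_samples = 800, n_snps = 12, ld_decay = 0, seed = 73)
  G <- simulate_genotypes(cfg)
  summ <- data.frame(snp = G$map$snp, chr = G$map$chr, pos = G$map$pos,
                     p_robust = runif(12))
  cl <- clump(summ, G)
  expect_equal(nrow(cl), 12L)
})

test_that("greedy clumping equals the exhaustive rule oracle on random instances", {
  set.seed(74)
  for (rep in 1:50) {
    m <- sample(5:30, 1)
    n <- 150
    cfg <- sim_config(n_samples = n, n_snps = m, n_chr = sample(1:3, 1),
                      ld_decay = runif(1, 0, 0.9), seed = 7000 + rep)
    G <- simulate_genotypes(cfg)
    keep <- apply(G$genotypes, 2, var) > 0
    G <- subset_genotypes(G, markers = keep)
    m <- n_markers(G)
    if (m < 2) next
    summ <- data.frame(snp = G$map$snp, chr = G$map$chr, pos = G$map$pos,
                       p_robust = runif(m))
    thr <- runif(1, 0.2, 0.9)
    win <- sample(c(2000, 10000, 1e6), 1)
    cl <- clump(summ, G, r2_threshold = thr, window_bp = win)
    oracle <- clump_oracle(summ$p_robust, summ$chr, summ$pos, summ$snp,
                           G$genotypes, thr, win)
    expect_identical(cl$snp, oracle)
  }
})

test_that("clump output is a maximal independent set under the greedy order", {
  cfg <- sim_config(n_samples = 300, n_snps = 40, n_chr = 1,
                    ld_decay = 0.7, seed = 75)
  G <- simulate_genotypes(cfg)
  set.seed(75)
  summ <- data.frame(snp = G$map$snp, chr = G$map$chr, pos = G$map$pos,
                     p_robust = runif(40))
  cl <- clump(summ, G, r2_threshold = 0.5, window_bp = 1e6)
  kept <- match(cl$snp, G$map$snp)
  # every retained pair within the window is below threshold
  for (a in seq_along(kept)) {
    for (b in seq_along(kept)) {
      if (a < b) expect_lt(ld_r2(G, kept[a], kept[b]), 0.5)
    }
  }
  # every removed SNP is tagged by a retained SNP with smaller p
  removed <- setdiff(seq_len(40), kept)
  for (j in removed) {
    taggers <- kept[summ$p_robust[kept] <= summ$p_robust[j]]
    expect_true(any(vapply(taggers, function(i) ld_r2(G, i, j) >= 0.5,
                           logical(1))))
  }
})

test_that("LD scores: self term, perfect proxies, and the null mean", {
  map1 <- data.frame(snp = "a", chr = "1", pos = 500, a1 = "A", a2 = "B")
  g <- rbinom(400, 2, 0.3)
  G1 <- genotype_matrix(matrix(g, ncol = 1), map1, sprintf("I%03d", 1:400))
  expect_equal(ld_scores(G1), 1)

  # duplicated SNP within the window: score ~ 2
  G2 <- genotype_matrix(cbind(g, g),
                        data.frame(snp = c("a", "b"), chr = "1",
                                   pos = c(500, 900), a1 = "A", a2 = "B"),
                        sprintf("I%03d", 1:400))
  expect_equal(ld_scores(G2), c(2, 2), tolerance = 1e-6)

  cfg <- sim_config(n_samples = 5000, n_snps = 300, n_chr = 1,
                    ld_decay = 0, seed = 76)
  G3 <- simulate_genotypes(cfg)
  ell <- ld_scores(G3)
  expect_lt(abs(mean(ell) - 1), 0.05)
  expect_true(all(is.finite(ell)))
  expect_error(ld_scores(G3, window_bp = 0), "positive")
})

test_that("LD score contributions are symmetric between markers", {
  cfg <- sim_config(n_samples = 500, n_snps = 30, n_chr = 1,
                    ld_decay = 0.6, seed = 77)
  G <- simulate_genotypes(cfg)
  n <- 500
  ell <- ld_scores(G)
  # recompute by the definition with an explicit double loop
  X <- impute_mean(G)
  ell_oracle <- rep(1, 30)
  for (j in 1:30) {
    for (k in setdiff(1:30, j)) {
      if (abs(G$map$pos[j] - G$map$pos[k]) <= 1e6) {
        r2 <- cor(X[, j], X[, k])^2
        ell_oracle[j] <- ell_oracle[j] + r2 - (1 - r2) / (n - 2)
      }
    }
  }
  expect_equal(ell, ell_oracle, tolerance = 1e-10)
})
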