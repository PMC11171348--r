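# Quality control: exact HWE test against an enumeration oracle, the
# filter cascade with first-filter attribution, Mendelian errors.

test_that("HWE exact test matches full enumeration", {
  # perfect proportions: clearly non-significant
  expect_gt(hwe_exact_test(25, 50, 25), 0.5)
  # total het depletion with 100 of each allele: vanishingly small p
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  expect_equal(hwe_exact_test(50, 0, 50), hwe_enum_oracle(50, 0, 50),
               tolerance = 1e-12)
  # monomorphic convention
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 7), 1)
  # random configurations vs the oracle
  set.seed(1)
  for (i in 1:50) {
    nh1 <- rpois(1, 30); nh2 <- rpois(1, 10)
    nhet <- rpois(1, 25)
    expect_equal(hwe_exact_test(nh1, nhet, nh2),
                 hwe_enum_oracle(nh1, nhet, nh2), tolerance = 1e-10)
  }
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("a low-MAF SNP is removed and attributed to the maf filter", {
  cfg <- sim_config(n_samples = 500, n_snps = 10, maf_range = c(0.3, 0.4),
                    seed = 21)
  G <- simulate_genotypes(cfg)
  # force SNP 4 to MAF 0.04
  g <- rep(0L, 500)
  g[1:40] <- 1L
  G$genotypes[, 4] <- g
  res <- apply_qc(G)
  expect_equal(unname(res$report$counts["maf"]), 1L)
  expect_false("SNP000004" %in% res$genotypes$map$snp)
})

test_that("high-missingness samples are removed before SNP filters", {
  cfg <- sim_config(n_samples = 100, n_snps = 60, seed = 22)
  G <- simulate_genotypes(cfg)
  G$genotypes[7, sample(60, 9)] <- NA_integer_ # 15% missing
  res <- apply_qc(G)
  expect_equal(res$report$n_samples_removed, 1L)
  expect_false("IID0007" %in% res$genotypes$samples)
})

test_that("QC is idempotent", {
  cfg <- sim_config(n_samples = 300, n_snps = 80, maf_range = c(0.02, 0.5),
                    missing_rate = 0.03, seed = 23)
  G <- simulate_genotypes(cfg)
  first <- apply_qc(G)
  second <- apply_qc(first$genotypes)
  expect_equal(second$report$n_snps_removed, 0L)
  expect_equal(second$report$n_samples_removed, 0L)
})

test_that("duplicate positions and missing positions are attributed in order", {
  cfg <- sim_config(n_samples = 200, n_snps = 10, n_chr = 1, seed = 24)
  G <- simulate_genotypes(cfg)
  G$map$pos[3] <- G$map$pos[2] # duplicate (chr,pos)
  G$map$pos[5] <- NA_integer_
  res <- apply_qc(G)
  expect_equal(unname(res$report$counts["duplicate"]), 1L)
  expect_equal(unname(res$report$counts["position_missing"]), 1L)
})

test_that("Mendelian transmission rules classify trios correctly", {
  map <- data.frame(snp = "S1", chr = "1", pos = 100, a1 = "A", a2 = "B")
  G <- genotype_matrix(matrix(c(0L, 0L, 1L, 2L, 0L, 1L), ncol = 1),
                       map, c("f1", "m1", "k1", "f2", "m2", "k2"))
  trios <- data.frame(child = c("k1", "k2"), father = c("f1", "f2"),
                      mother = c("m1", "m2"))
  # trio 1: parents 0/0, child 1 -> impossible; trio 2: parents 2/0,
  # child 1 -> forced heterozygote, legal
  rate <- mendel_error_rate(G, trios)
  expect_equal(unname(rate), 0.5)
  expect_error(
    mendel_error_rate(G, data.frame(child = "zz", father = "f1",
                                    mother = "m1")),
    "not in sample list")
})

test_that("SNPs exceeding the 2% Mendelian-error rate are filtered", {
  cfg <- sim_config(n_samples = 250, n_snps = 30, maf_range = c(0.2, 0.5),
                    seed = 25)
  G <- simulate_genotypes(cfg)
  tr <- simulate_trios(G, n_trios = 100, error_rate = 0, seed = 9)
  Gt <- tr$genotypes
  # inject 3 impossible transmissions at SNP 12: child of 0x0 parents set het
  k <- 0
  for (t in seq_len(nrow(tr$trios))) {
    if (k >= 3) break
    fi <- match(tr$trios$father[t], Gt$samples)
    mi <- match(tr$trios$mother[t], Gt$samples)
    ci <- match(tr$trios$child[t], Gt$samples)
    Gt$genotypes[fi, 12] <- 0L
    Gt$genotypes[mi, 12] <- 0L
    Gt$genotypes[ci, 12] <- 1L
    k <- k + 1
  }
  rate <- mendel_error_rate(Gt, tr$trios)
  expect_gte(rate[12], 0.03)
  res <- apply_qc(Gt, trios = tr$trios)
  expect_false("SNP000012" %in% res$genotypes$map$snp)
  expect_gte(unname(res$report$counts["mendel"]), 1L)
})

test_that("retained SNPs satisfy the MAF and call-rate floors and sample order is irrelevant", {
  cfg <- sim_config(n_samples = 400, n_snps = 120, maf_range = c(0.02, 0.5),
                    missing_rate = 0.05, seed = 26)
  G <- simulate_genotypes(cfg)
  res <- apply_qc(G)
  expect_true(all(maf(res$genotypes) >= 0.05 - 1e-12))
  expect_true(all(colMeans(!is.na(res$genotypes$genotypes)) >= 0.9))

  perm <- sample(n_samples(G))
  Gp <- subset_genotypes(G, samples = perm)
  resp <- apply_qc(Gp)
  expect_identical(resp$report$reason, res$report$reason)
})

test_that("removing every SNP is an explicit empty-panel error", {
  map <- data.frame(snp = "S1", chr = "1", pos = 100, a1 = "A", a2 = "B")
  G <- genotype_matrix(matrix(rep(0L, 50), ncol = 1), map,
                       sprintf("I%02d", 1:50))
  expect_error(apply_qc(G), "empty panel")
})
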