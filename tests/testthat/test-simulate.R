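# Synthetic-data generator: frequency targets, LD structure, seasonal
# environment, phenotype model, heteroskedasticity, trios, determinism.

test_that("allele frequency hits the binomial target without LD", {
  cfg <- sim_config(n_samples = 10000, n_snps = 1, maf_range = c(0.3, 0.3),
                    ld_decay = 0, seed = 42)
  G <- simulate_genotypes(cfg)
  se <- sqrt(0.3 * 0.7 / (2 * 10000))
  expect_lt(abs(allele_freq(G) - 0.3), 3 * se)
})

test_that("adjacent-pair r2 is at the null level when ld_decay = 0 and grows with ld_decay", {
  cfg <- sim_config(n_samples = 500, n_snps = 501, n_chr = 1,
                    ld_decay = 0, seed = 7)
  G <- simulate_genotypes(cfg)
  r2 <- vapply(1:500, function(j) ld_r2(G, j, j + 1), numeric(1))
  # null E[r2] for a sample correlation of independent markers is 1/(n-1)
  mc_se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - 1 / (500 - 1)), 3 * mc_se)

  means <- vapply(c(0, 0.4, 0.8), function(ld) {
    Gld <- simulate_genotypes(sim_config(n_samples = 500, n_snps = 201,
                                         n_chr = 1, ld_decay = ld, seed = 7))
    mean(vapply(1:200, function(j) ld_r2(Gld, j, j + 1), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("empty panels and marker maps are well formed", {
  cfg <- sim_config(n_samples = 10, n_snps = 0, seed = 1)
  G <- simulate_genotypes(cfg)
  expect_equal(n_markers(G), 0L)
  expect_equal(n_samples(G), 10L)
  expect_named(G$map, c("snp", "chr", "pos", "a1", "a2"))

  Gfull <- simulate_genotypes(sim_config(n_samples = 20, n_snps = 100,
                                         n_chr = 4, seed = 2))
  for (c in unique(Gfull$map$chr)) {
    pos <- Gfull$map$pos[Gfull$map$chr == c]
    expect_true(all(pos > 0))
    expect_true(all(diff(pos) > 0))
  }
})

test_that("configuration validation rejects invalid settings", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(ld_decay = 1), "ld_decay")
  expect_error(sim_config(n_farms = 1), "n_farms")
  expect_error(sim_config(n_samples = -1), "non-negative")
})

test_that("identical configurations give bit-identical data", {
  cfg <- sim_config(n_samples = 50, n_snps = 40, ld_decay = 0.3,
                    missing_rate = 0.05, hetero_delta = 0.5, seed = 99)
  a <- simulate_study(cfg, env_kind = "continuous", n_causal = 3)
  b <- simulate_study(cfg, env_kind = "continuous", n_causal = 3)
  expect_identical(a$genotypes$genotypes, b$genotypes$genotypes)
  expect_identical(a$env$values, b$env$values)
  expect_identical(a$phenotype, b$phenotype)
})

test_that("degenerate temperature series is exactly the baseline", {
  cfg <- sim_config(n_samples = 30, n_snps = 1, temp_seasonal_amplitude = 0,
                    temp_noise_sd = 0, farm_temp_baselines = rep(10, 7),
                    seed = 5)
  E <- simulate_environment(cfg, "continuous")
  expect_equal(E$values, rep(10, 30))
})

test_that("a full seasonal period averages back to the farm baseline", {
  cfg <- sim_config(n_samples = 24, n_snps = 1, temp_seasonal_amplitude = 10,
                    temp_noise_sd = 0, farm_temp_baselines = rep(8, 7),
                    seed = 6)
  birth <- rep(1:12, 2)
  E <- simulate_environment(cfg, "continuous", birth_months = birth,
                            record_months = birth + 11L)
  expect_equal(E$values, rep(8, 24), tolerance = 1e-12)
})

test_that("identical windows give identical exposures without noise", {
  cfg <- sim_config(n_samples = 2, n_snps = 1, temp_noise_sd = 0,
                    farm_temp_baselines = rep(12, 7), seed = 8)
  E <- simulate_environment(cfg, "continuous", birth_months = c(3, 3),
                            record_months = c(9, 9))
  expect_identical(E$values[1], E$values[2])
})

test_that("recording before birth is a domain error", {
  cfg <- sim_config(n_samples = 2, n_snps = 1, seed = 1)
  expect_error(
    simulate_environment(cfg, "continuous", birth_months = c(5, 5),
                         record_months = c(4, 10)),
    "record month before birth")
})

test_that("null phenotype variance matches sigma0^2", {
  cfg <- sim_config(n_samples = 5000, n_snps = 2, sigma0 = 2,
                    hetero_delta = 0, seed = 10)
  st <- simulate_study(cfg, env_kind = "continuous", n_causal = 0)
  v <- var(st$phenotype)
  se_var <- 4 * sqrt(2 / (5000 - 1)) # Var(s^2) ~ 2 sigma^4 / (n-1)
  expect_lt(abs(v - 4), 3 * se_var)
})

test_that("hetero_delta makes residual variance rise across environment quartiles", {
  cfg <- sim_config(n_samples = 5000, n_snps = 2, sigma0 = 1,
                    hetero_delta = 0.8, seed = 11)
  st <- simulate_study(cfg, env_kind = "continuous", n_causal = 0)
  q <- quantile(st$env$values, c(0.25, 0.75))
  v_low <- var(st$phenotype[st$env$values <= q[1]])
  v_high <- var(st$phenotype[st$env$values >= q[2]])
  expect_gt(v_high, v_low)
})

test_that("noise-free phenotype is the exact interaction identity", {
  cfg <- sim_config(n_samples = 200, n_snps = 10, sigma0 = 0, mu0 = 5,
                    beta_gxe = 2, beta_g = 0, beta_e = 0, seed = 12)
  G <- simulate_genotypes(cfg)
  E <- env_vector(rnorm(200), "continuous")
  y <- simulate_phenotype(G, E, NULL, cfg, causal_snps = 4L)
  e_centered <- E$values - mean(E$values)
  expect_equal(y, 5 + 2 * G$genotypes[, 4] * e_centered, tolerance = 1e-12)
})

test_that("causal index out of range is a domain error", {
  cfg <- sim_config(n_samples = 20, n_snps = 5, seed = 1)
  G <- simulate_genotypes(cfg)
  E <- env_vector(rnorm(20), "continuous")
  expect_error(simulate_phenotype(G, E, NULL, cfg, causal_snps = 6L),
               "out of range")
})

test_that("noise-free fits recover the generative coefficients to high precision", {
  cfg <- sim_config(n_samples = 400, n_snps = 20, sigma0 = 0, mu0 = 3,
                    beta_g = 0.7, beta_e = -0.4, beta_gxe = 1.3,
                    beta_c = c(0.2, -0.1, 0.05), seed = 13)
  G <- simulate_genotypes(cfg)
  E <- env_vector(rnorm(400, 15, 5), "continuous")
  C <- simulate_covariates(cfg)
  y <- simulate_phenotype(G, E, C, cfg, causal_snps = 7L)
  dm <- build_design(as.numeric(G$genotypes[, 7]), E, as.matrix(C), y)
  fit <- fit_ols(y, dm)
  co <- fit$coefficients
  expect_equal(unname(co[dm$groups$snp]), 0.7, tolerance = 1e-10)
  expect_equal(unname(co[dm$groups$snp_env]), 1.3, tolerance = 1e-10)
  expect_equal(unname(co[dm$groups$env]), -0.4, tolerance = 1e-10)
  expect_equal(unname(co[dm$groups$covariates]), c(0.2, -0.1, 0.05),
               tolerance = 1e-9)
})

test_that("trio offspring obey Mendelian transmission and error injection raises the rate", {
  cfg <- sim_config(n_samples = 220, n_snps = 60, seed = 14)
  G <- simulate_genotypes(cfg)
  clean <- simulate_trios(G, n_trios = 100, error_rate = 0, seed = 2)
  rate0 <- mendel_error_rate(clean$genotypes, clean$trios)
  expect_equal(unname(rate0), rep(0, 60))
  noisy <- simulate_trios(G, n_trios = 100, error_rate = 0.1, seed = 2)
  rate1 <- mendel_error_rate(noisy$genotypes, noisy$trios)
  expect_gt(mean(rate1), 0.01)
})
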