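# Interaction regression: OLS against closed forms and a normal-equations
# oracle, sandwich covariance against the dense triple-product oracle and
# an independent library, test behavior under null/signal/heteroskedastic
# data, and the genome-wide scan's fast path vs the naive per-SNP solve.

test_that("fit_ols matches closed forms and the normal-equations oracle", {
  set.seed(41)
  # perfect linear data: zero residuals and zero covariance
  X <- cbind(1, rnorm(30), runif(30))
  y <- X %*% c(2, -1, 0.5)
  f <- fit_ols(as.vector(y), X)
  expect_equal(max(abs(f$residuals)), 0, tolerance = 1e-12)
  expect_equal(max(abs(f$model_cov)), 0, tolerance = 1e-20)

  # intercept-only closed form
  y2 <- rnorm(40)
  f2 <- fit_ols(y2, matrix(1, 40, 1))
  expect_equal(unname(f2$coefficients), mean(y2))
  expect_equal(sqrt(f2$model_cov[1, 1]), sd(y2) / sqrt(40))

  # random instance vs independent solve
  X3 <- cbind(1, matrix(rnorm(50 * 4), 50, 4))
  y3 <- rnorm(50)
  f3 <- fit_ols(y3, X3)
  beta_oracle <- solve(t(X3) %*% X3, t(X3) %*% y3)
  expect_equal(unname(f3$coefficients), as.vector(beta_oracle),
               tolerance = 1e-10)
  # residual orthogonality on standardized columns
  Xs <- scale(X3[, -1])
  expect_lt(max(abs(crossprod(Xs, f3$residuals))) / 50, 1e-8)
})

test_that("sandwich covariance equals the dense oracle and the sandwich package", {
  set.seed(42)
  for (i in 1:10) {
    n <- 60; p <- 5
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
    y <- rnorm(n) * exp(X[, 2] / 2)
    f <- fit_ols(y, X)
    for (fl in c("HC0", "HC1", "HC2", "HC3")) {
      V <- sandwich_covariance(f, flavor = fl)
      Vo <- sandwich_oracle(X, f$residuals, fl)
      expect_lt(max(abs(V - Vo)) / max(abs(Vo)), 1e-12)
    }
  }
  # independent library cross-check
  X <- cbind(1, rnorm(80), runif(80))
  y <- rnorm(80)
  f <- fit_ols(y, X)
  lmf <- lm(y ~ X - 1)
  for (fl in c("HC0", "HC1", "HC2", "HC3")) {
    expect_equal(sandwich_covariance(f, flavor = fl),
                 unname(sandwich::vcovHC(lmf, type = fl)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("equal-magnitude residuals make HC1 equal the model covariance", {
  n <- 40
  y <- rep(c(1, -1), n / 2)
  X <- matrix(1, n, 1)
  f <- fit_ols(y, X)
  expect_equal(sandwich_covariance(f, flavor = "HC1"), f$model_cov,
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("robust covariance stays PSD with zeroed high-leverage residuals", {
  set.seed(43)
  x <- c(rnorm(30), 15) # one extreme-leverage point
  X <- cbind(1, x)
  y <- rnorm(31)
  f <- fit_ols(y, X)
  f$residuals[31] <- 0
  V <- sandwich_covariance(f, flavor = "HC0")
  expect_gte(min(eigen(V, symmetric = TRUE)$values), -1e-12)
})

test_that("single-column interaction test is the squared-t Wald test", {
  set.seed(44)
  st <- make_study(n = 3000, m = 3)
  g <- as.numeric(st$genotypes$genotypes[, 2])
  dm <- build_design(g, st$env, as.matrix(st$covariates), st$phenotype)
  fit <- fit_ols(st$phenotype, dm)
  it <- interaction_test(fit, "robust")
  expect_equal(it$stat, it$t^2, tolerance = 1e-12)
  # at large residual df the t and chi-square references agree closely
  expect_equal(it$p, pchisq(it$stat, 1, lower.tail = FALSE),
               tolerance = 1e-3)
})

test_that("an exactly-zero interaction coefficient gives p = 1", {
  set.seed(45)
  st <- make_study(n = 200, m = 3)
  g <- as.numeric(st$genotypes$genotypes[, 1])
  dm <- build_design(g, st$env, as.matrix(st$covariates), st$phenotype)
  fit <- fit_ols(st$phenotype[dm$rows_used], dm)
  ie <- dm$groups$snp_env
  y2 <- st$phenotype[dm$rows_used] -
    dm$X[, ie] * fit$coefficients[ie]
  fit2 <- fit_ols(y2, dm)
  expect_lt(abs(fit2$coefficients[ie]), 1e-12)
  expect_gt(interaction_test(fit2, "robust")$p, 0.999)
})

test_that("joint test covers SNP main plus interaction and is null-uniform", {
  set.seed(46)
  st <- make_study(n = 400, m = 1200, seed = 8)
  C <- as.matrix(st$covariates)
  ps <- numeric(300)
  for (j in 1:300) {
    g <- as.numeric(st$genotypes$genotypes[, j])
    dm <- build_design(g, st$env, C, st$phenotype)
    fit <- fit_ols(st$phenotype, dm)
    ps[j] <- joint_test(fit, "model")$p
    if (j == 1) expect_equal(joint_test(fit, "model")$df, 2L)
  }
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("joint test beats the interaction test on pure main effects", {
  set.seed(47)
  n <- 300
  rej_joint <- rej_int <- 0
  for (r in 1:200) {
    g <- rbinom(n, 2, 0.3)
    e <- rnorm(n)
    y <- 0.25 * g + rnorm(n)
    dm <- build_design(g, env_vector(e, "continuous"), NULL, y)
    fit <- fit_ols(y, dm)
    rej_joint <- rej_joint + (joint_test(fit, "model")$p < 0.05)
    rej_int <- rej_int + (interaction_test(fit, "model")$p < 0.05)
  }
  expect_gt(rej_joint, rej_int)
})

test_that("the genome scan matches the naive per-SNP solve", {
  set.seed(48)
  cfg <- sim_config(n_samples = 250, n_snps = 100, ld_decay = 0.4,
                    hetero_delta = 0.5, missing_rate = 0.02, seed = 17)
  st <- simulate_study(cfg, env_kind = "continuous", n_causal = 2)
  C <- as.matrix(st$covariates)
  sm <- run_gweis(st$genotypes, st$env, C, st$phenotype, flavor = "HC1")
  for (j in sample(which(sm$reason == "."), 40)) {
    g <- as.numeric(st$genotypes$genotypes[, j])
    dm <- build_design(g, st$env, C, st$phenotype)
    fit <- fit_ols(st$phenotype[dm$rows_used], dm)
    rob <- interaction_test(fit, "robust", "HC1")
    mod <- interaction_test(fit, "model")
    expect_equal(sm$beta_gxe[j], unname(fit$coefficients[dm$groups$snp_env]),
                 tolerance = 1e-8)
    expect_equal(sm$p_robust[j], rob$p, tolerance = 1e-8)
    expect_equal(sm$p_model[j], mod$p, tolerance = 1e-8)
    expect_equal(sm$n_used[j], fit$n_used)
  }
})

test_that("allele flips negate the betas and leave p-values unchanged", {
  set.seed(49)
  st <- make_study(n = 300, m = 30, seed = 18)
  C <- as.matrix(st$covariates)
  sm <- run_gweis(st$genotypes, st$env, C, st$phenotype)
  Gf <- st$genotypes
  Gf$genotypes[, 7] <- 2L - Gf$genotypes[, 7]
  smf <- run_gweis(Gf, st$env, C, st$phenotype)
  expect_equal(smf$beta_gxe[7], -sm$beta_gxe[7], tolerance = 1e-10)
  expect_equal(smf$p_robust[7], sm$p_robust[7], tolerance = 1e-10)
  expect_equal(smf$p_model[7], sm$p_model[7], tolerance = 1e-10)
})

test_that("jointly permuting samples leaves the scan unchanged", {
  set.seed(50)
  st <- make_study(n = 200, m = 25, seed = 19)
  C <- as.matrix(st$covariates)
  sm <- run_gweis(st$genotypes, st$env, C, st$phenotype)
  perm <- sample(200)
  Gp <- subset_genotypes(st$genotypes, samples = perm)
  Ep <- env_vector(st$env$values[perm], "continuous")
  smp <- run_gweis(Gp, Ep, C[perm, , drop = FALSE], st$phenotype[perm])
  expect_equal(smp$p_robust, sm$p_robust, tolerance = 1e-9)
  expect_equal(smp$beta_gxe, sm$beta_gxe, tolerance = 1e-9)
})

test_that("a noise-free causal interaction attains the genome-wide minimum p", {
  cfg <- sim_config(n_samples = 300, n_snps = 150, sigma0 = 1e-8,
                    beta_gxe = 2, seed = 20)
  st <- simulate_study(cfg, env_kind = "continuous", n_causal = 1)
  sm <- run_gweis(st$genotypes, st$env, as.matrix(st$covariates),
                  st$phenotype)
  expect_equal(which.min(sm$p_robust), st$causal_snps)
})

test_that("robust p-values are null-uniform and the model-based chi-squares inflate under heteroskedasticity", {
  cfg <- sim_config(n_samples = 500, n_snps = 2000, hetero_delta = 0,
                    seed = 51)
  st <- simulate_study(cfg, env_kind = "continuous", n_causal = 0)
  sm <- run_gweis(st$genotypes, st$env, as.matrix(st$covariates),
                  st$phenotype)
  expect_gt(ks.test(sm$p_robust[sm$reason == "."], "punif")$p.value, 0.01)

  cfgh <- sim_config(n_samples = 800, n_snps = 1200, hetero_delta = 0.8,
                     seed = 52)
  sth <- simulate_study(cfgh, env_kind = "continuous", n_causal = 0)
  smh <- run_gweis(sth$genotypes, sth$env, as.matrix(sth$covariates),
                   sth$phenotype)
  chi_m <- qchisq(smh$p_model, 1, lower.tail = FALSE)
  chi_r <- qchisq(smh$p_robust, 1, lower.tail = FALSE)
  expect_gt(median(chi_m, na.rm = TRUE), median(chi_r, na.rm = TRUE))
})

test_that("model and robust p agree under homoskedasticity at large n", {
  cfg <- sim_config(n_samples = 4000, n_snps = 300, hetero_delta = 0,
                    seed = 53)
  st <- simulate_study(cfg, env_kind = "continuous", n_causal = 0)
  sm <- run_gweis(st$genotypes, st$env, as.matrix(st$covariates),
                  st$phenotype, flavor = "HC1")
  rel <- abs(sm$p_robust - sm$p_model) / sm$p_model
  expect_gte(mean(rel < 0.10, na.rm = TRUE), 0.95)
})

test_that("mass skipping escalates to an error", {
  cfg <- sim_config(n_samples = 100, n_snps = 20, seed = 54)
  st <- simulate_study(cfg, env_kind = "continuous", n_causal = 0)
  G <- st$genotypes
  G$genotypes[, 1:15] <- 1L # monomorphic
  expect_error(run_gweis(G, st$env, as.matrix(st$covariates), st$phenotype),
               "skipped")
})
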