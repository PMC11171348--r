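# Simulation experiments at the study's scale: empirical type-I
# calibration of the interaction tests, LD score intercept comparison of
# the two variance estimators, and interaction-effect recovery/power.
# These are the package's core analyses; the acceptance script and the
# analysis drivers call them directly.

#' Empirical type-I error of the interaction tests under a null
#'
#' Simulates one genome from `cfg`, then draws `n_replicates` phenotype
#' replicates under the configured (typically heteroskedastic) null with
#' no genetic effects, scans each with [run_gweis()], and pools the
#' rejection indicators at level `alpha` across all analyzed SNP x
#' replicate tests. Reports both the robust and the model-based rates and
#' the binomial 95% interval around `alpha` for the pooled test count.
#'
#' @param cfg A [sim_config()]; its `hetero_delta` sets the environment-
#'   dependent residual variance.
#' @param n_replicates Number of phenotype replicates.
#' @param alpha Nominal level.
#' @param flavor Sandwich flavor for the robust test.
#' @return List: `rate_robust`, `rate_model`, `n_tests`, `ci_scan` (the
#'   binomial 95% band around `alpha` for one m-SNP scan, the scale at
#'   which a single genome-wide rejection rate is judged), `ci_pooled`
#'   (the much tighter band for the pooled test count; no finite-sample
#'   sandwich flavor is exact at this resolution), `per_replicate`.
#' @export
gweis_type1_calibration <- function(cfg, n_replicates = 200, alpha = 0.05,
                                    flavor = "HC3") {
  st <- simulate_study(cfg, env_kind = "continuous", n_causal = 0)
  C <- as.matrix(st$covariates)
  rej_r <- rej_m <- n_tests <- 0
  per_rep <- matrix(NA_real_, n_replicates, 2,
                    dimnames = list(NULL, c("robust", "model")))
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + 7919L * r
    y <- simulate_phenotype(st$genotypes, st$env, C, cfg_r, integer(0))
    sm <- run_gweis(st$genotypes, st$env, C, y, flavor = flavor)
    ok <- sm$reason == "."
    rej_r <- rej_r + sum(sm$p_robust[ok] < alpha)
    rej_m <- rej_m + sum(sm$p_model[ok] < alpha)
    n_tests <- n_tests + sum(ok)
    per_rep[r, ] <- c(mean(sm$p_robust[ok] < alpha),
                      mean(sm$p_model[ok] < alpha))
  }
  m_scan <- n_tests / n_replicates
  half_scan <- 1.96 * sqrt(alpha * (1 - alpha) / m_scan)
  half_pool <- 1.96 * sqrt(alpha * (1 - alpha) / n_tests)
  list(rate_robust = rej_r / n_tests, rate_model = rej_m / n_tests,
       n_tests = n_tests,
       ci_scan = c(alpha - half_scan, alpha + half_scan),
       ci_pooled = c(alpha - half_pool, alpha + half_pool),
       per_replicate = as.data.frame(per_rep))
}

#' LD score intercepts of robust vs model-based scans under a null
#'
#' Simulates one genome with local LD from `cfg`, computes in-sample LD
#' scores, then for each phenotype replicate (heteroskedastic null) runs
#' the scan and fits the LD score regression to both the robust and the
#' model-based chi-square statistics.
#'
#' @param cfg A [sim_config()] (set `ld_decay` > 0 for a meaningful LD
#'   panel).
#' @param n_replicates Number of phenotype replicates.
#' @param n_blocks Jackknife blocks for the intercept SE.
#' @param flavor Sandwich flavor for the robust scan.
#' @return Data frame with one row per replicate: `intercept_robust`,
#'   `intercept_model`, `lambda_robust`, `lambda_model`.
#' @export
gweis_ldsc_experiment <- function(cfg, n_replicates = 10, n_blocks = 50,
                                  flavor = "HC3") {
  st <- simulate_study(cfg, env_kind = "continuous", n_causal = 0)
  C <- as.matrix(st$covariates)
  ell <- ld_scores(st$genotypes)
  out <- data.frame(intercept_robust = numeric(n_replicates),
                    intercept_model = numeric(n_replicates),
                    lambda_robust = numeric(n_replicates),
                    lambda_model = numeric(n_replicates))
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + 104729L * r
    y <- simulate_phenotype(st$genotypes, st$env, C, cfg_r, integer(0))
    sm <- run_gweis(st$genotypes, st$env, C, y, flavor = flavor)
    ok <- sm$reason == "."
    out$intercept_robust[r] <-
      ldsc_intercept(p = sm$p_robust[ok], ld = ell[ok],
                     n_blocks = n_blocks)$intercept
    out$intercept_model[r] <-
      ldsc_intercept(p = sm$p_model[ok], ld = ell[ok],
                     n_blocks = n_blocks)$intercept
    out$lambda_robust[r] <- genomic_inflation(p = sm$p_robust[ok])
    out$lambda_model[r] <- genomic_inflation(p = sm$p_model[ok])
  }
  out
}

#' Interaction-effect recovery and power across an effect-size grid
#'
#' For each interaction effect size in `beta_grid`, injects the effect at
#' `n_causal` markers spread over a fresh panel, scans with
#' [run_gweis()], and accumulates the estimated interaction coefficients
#' at the causal markers and the fraction detected at the scan's
#' suggestive threshold (`1 / m`).
#'
#' @param cfg Base [sim_config()] (its `beta_gxe` is overridden by the
#'   grid).
#' @param beta_grid Increasing vector of interaction effect sizes
#'   (kg per allele per SD of environment).
#' @param n_causal Causal markers per replicate.
#' @param n_replicates Replicates per grid point.
#' @param flavor Sandwich flavor.
#' @return Data frame per grid point: `beta`, `bias` (mean estimate minus
#'   truth), `bias_mcse` (Monte-Carlo SE of the bias), `power` at the
#'   suggestive threshold, `n_estimates`.
#' @export
gweis_power_experiment <- function(cfg, beta_grid, n_causal = 20,
                                   n_replicates = 5, flavor = "HC3") {
  rows <- lapply(beta_grid, function(b) {
    est <- numeric(0)
    hit <- logical(0)
    for (r in seq_len(n_replicates)) {
      cfg_b <- cfg
      cfg_b$beta_gxe <- b
      cfg_b$seed <- cfg$seed + 1009L * r + as.integer(round(1e4 * b))
      st <- simulate_study(cfg_b, env_kind = "continuous",
                           n_causal = n_causal)
      sm <- run_gweis(st$genotypes, st$env, as.matrix(st$covariates),
                      st$phenotype, flavor = flavor)
      thr <- significance_thresholds(sum(sm$reason == "."))$suggestive
      cs <- st$causal_snps
      est <- c(est, sm$beta_gxe[cs])
      hit <- c(hit, sm$p_robust[cs] < thr)
    }
    data.frame(beta = b, bias = mean(est, na.rm = TRUE) - b,
               bias_mcse = stats::sd(est, na.rm = TRUE) /
                 sqrt(sum(!is.na(est))),
               power = mean(hit, na.rm = TRUE),
               n_estimates = sum(!is.na(est)))
  })
  do.call(rbind, rows)
}
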