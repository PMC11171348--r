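# Synthetic-data generator: genotypes with tunable local LD, a multi-farm
# seasonal temperature exposure, covariates, and phenotypes with optional
# G, E, GxE effects and environment-dependent residual variance.

#' Simulate an additive-coded genotype panel
#'
#' Draws per-SNP target allele frequencies uniformly from
#' `cfg$maf_range`, spreads markers evenly over `cfg$n_chr` chromosomes
#' with strictly increasing base-pair positions, and generates two
#' haplotypes per individual by first-order Markov copying: at each marker
#' after the first on a chromosome, the haplotype copies its allele state
#' from the previous marker with probability `cfg$ld_decay`, otherwise
#' draws a fresh Bernoulli allele at that marker's frequency. `ld_decay = 0`
#' gives fully independent markers. Missingness is injected completely at
#' random at `cfg$missing_rate`.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_matrix()] whose A1 allele is the simulated
#'   frequency-`p` allele.
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(unclass(cfg))
  n <- cfg$n_samples
  m <- cfg$n_snps
  if (m == 0L) {
    return(genotype_matrix(matrix(integer(0), nrow = n, ncol = 0),
                           data.frame(snp = character(0), chr = character(0),
                                      pos = integer(0), a1 = character(0),
                                      a2 = character(0)),
                           sprintf("IID%04d", seq_len(n))))
  }
  set.seed(cfg$seed)
  p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  # even split, contiguous blocks per chromosome
  chr <- as.character(sort(rep_len(seq_len(cfg$n_chr), m)))
  pos <- integer(m)
  for (c in unique(chr)) {
    idx <- which(chr == c)
    steps <- sample(seq(cfg$spacing_bp %/% 2L, cfg$spacing_bp * 2L),
                    length(idx), replace = TRUE)
    pos[idx] <- cumsum(steps)
  }
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  first_of_chr <- !duplicated(chr)
  for (j in seq_len(m)) {
    fresh1 <- stats::rbinom(n, 1L, p[j])
    fresh2 <- stats::rbinom(n, 1L, p[j])
    if (first_of_chr[j] || cfg$ld_decay == 0) {
      H1[, j] <- fresh1
      H2[, j] <- fresh2
    } else {
      copy1 <- stats::runif(n) < cfg$ld_decay
      copy2 <- stats::runif(n) < cfg$ld_decay
      H1[, j] <- ifelse(copy1, H1[, j - 1L], fresh1)
      H2[, j] <- ifelse(copy2, H2[, j - 1L], fresh2)
    }
  }
  G <- H1 + H2
  if (cfg$missing_rate > 0) {
    drop <- stats::runif(n * m) < cfg$missing_rate
    G[drop] <- NA_integer_
  }
  map <- data.frame(snp = sprintf("SNP%06d", seq_len(m)), chr = chr,
                    pos = pos, a1 = "A", a2 = "B",
                    stringsAsFactors = FALSE)
  genotype_matrix(G, map, sprintf("IID%04d", seq_len(n)))
}

#' Simulate the environmental exposure
#'
#' Categorical: individuals are assigned uniformly at random to
#' `cfg$n_farms` farm labels. Continuous: each individual's exposure is the
#' mean of a simulated monthly temperature series over its own window from
#' birth month to phenotype-recording month (inclusive). The monthly series
#' is the individual's farm baseline plus a sinusoidal seasonal cycle of
#' amplitude `cfg$temp_seasonal_amplitude` (period 12 months) plus i.i.d.
#' noise with SD `cfg$temp_noise_sd`.
#'
#' @param cfg A [sim_config()].
#' @param kind `"categorical"` (farm) or `"continuous"` (mean temperature).
#' @param birth_months Integer month index of birth per individual (any
#'   origin; month `t` maps to calendar month `((t - 1) %% 12) + 1`).
#'   Default: random months in year one.
#' @param record_months Integer month index of phenotype recording per
#'   individual; must be `>= birth_months` elementwise. Default: one full
#'   year after birth.
#' @param farms Optional farm labels per individual used for continuous
#'   baselines; defaults to a fresh categorical assignment.
#' @return An [env_vector()].
#' @export
simulate_environment <- function(cfg,
                                 kind = c("continuous", "categorical"),
                                 birth_months = NULL,
                                 record_months = NULL,
                                 farms = NULL) {
  kind <- match.arg(kind)
  n <- cfg$n_samples
  farm_levels <- sprintf("farm%d", seq_len(cfg$n_farms))
  set.seed(cfg$seed + 1L)
  if (is.null(farms)) {
    farms <- sample(farm_levels, n, replace = TRUE)
  }
  if (kind == "categorical") {
    return(env_vector(farms, "categorical", levels = farm_levels))
  }
  if (is.null(birth_months)) birth_months <- sample(1:12, n, replace = TRUE)
  if (is.null(record_months)) record_months <- birth_months + 11L
  birth_months <- as.integer(birth_months)
  record_months <- as.integer(record_months)
  if (any(record_months < birth_months)) {
    stop("record month before birth month", call. = FALSE)
  }
  base <- cfg$farm_temp_baselines[match(farms, farm_levels)]
  vals <- numeric(n)
  for (i in seq_len(n)) {
    months <- birth_months[i]:record_months[i]
    seasonal <- cfg$temp_seasonal_amplitude *
      sin(2 * pi * (months - 1) / 12)
    noise <- if (cfg$temp_noise_sd > 0) {
      stats::rnorm(length(months), 0, cfg$temp_noise_sd)
    } else 0
    vals[i] <- mean(base[i] + seasonal + noise)
  }
  env_vector(vals, "continuous")
}

# Numeric design encoding of an environment: centered scalar column for
# continuous, treatment-coded dummies against the reference level for
# categorical. Returns a matrix with one row per sample.
encode_environment <- function(E, reference_level = NULL, center = TRUE) {
  if (E$kind == "continuous") {
    v <- E$values
    if (center) v <- v - mean(v, na.rm = TRUE)
    return(matrix(v, ncol = 1, dimnames = list(NULL, "env")))
  }
  lev <- E$levels
  if (!is.null(reference_level)) {
    if (!reference_level %in% lev) {
      stop("reference_level not among environment levels", call. = FALSE)
    }
    lev <- c(reference_level, setdiff(lev, reference_level))
  }
  f <- factor(E$values, levels = lev)
  X <- stats::model.matrix(~f)[, -1, drop = FALSE]
  # model.matrix drops NA rows; rebuild with NA propagation
  out <- matrix(NA_real_, length(E$values), length(lev) - 1L,
                dimnames = list(NULL, paste0("env_", lev[-1])))
  ok <- !is.na(f)
  out[ok, ] <- X
  out
}

#' Simulate a phenotype under the interaction generative model
#'
#' Generates `y = mu0 + sum_causal (beta_g g + beta_gxe g * E") + beta_e E"
#' + C beta_c + eps`, where `E"` is the numeric environment encoding
#' (centered continuous value, or treatment dummies for farms) and
#' `eps_i ~ N(0, sigma0^2 * exp(hetero_delta * z_i))` with `z` the
#' standardized continuous environment (for farms, the standardized level
#' index). `hetero_delta = 0` gives homoskedastic residuals. Missing
#' genotypes at causal SNPs are mean-imputed for generation.
#'
#' @param G A [genotype_matrix()].
#' @param E An [env_vector()].
#' @param C Data frame or matrix of numeric covariates (may be NULL).
#' @param cfg A [sim_config()] carrying `mu0`, `beta_g`, `beta_e`,
#'   `beta_gxe`, `beta_c`, `hetero_delta`, `sigma0`.
#' @param causal_snps Integer indices of causal markers (may be empty).
#' @return Numeric phenotype vector (kg).
#' @export
simulate_phenotype <- function(G, E, C = NULL, cfg, causal_snps = integer(0)) {
  n <- n_samples(G)
  if (length(E$values) != n) stop("E length mismatch", call. = FALSE)
  causal_snps <- as.integer(causal_snps)
  if (length(causal_snps) &&
      (min(causal_snps) < 1L || max(causal_snps) > n_markers(G))) {
    stop("causal SNP index out of range", call. = FALSE)
  }
  set.seed(cfg$seed + 2L)
  Ecols <- encode_environment(E)
  e_lin <- rowSums(Ecols) # scalar for continuous; dummy sum for categorical
  g_term <- 0
  if (length(causal_snps)) {
    Gc <- impute_mean(subset_genotypes(G, markers = causal_snps))
    g_term <- rowSums(cfg$beta_g * Gc) + rowSums(cfg$beta_gxe * Gc * e_lin)
  }
  c_term <- 0
  if (!is.null(C) && ncol(as.matrix(C)) > 0) {
    Cm <- as.matrix(C)
    c_term <- as.vector(Cm %*% rep_len(cfg$beta_c, ncol(Cm)))
  }
  if (E$kind == "continuous") {
    z <- as.vector(scale(E$values))
    if (any(!is.finite(z))) z <- rep(0, n) # constant environment
  } else {
    li <- match(E$values, E$levels)
    z <- as.vector(scale(li))
    if (any(!is.finite(z))) z <- rep(0, n)
  }
  sd_i <- cfg$sigma0 * exp(cfg$hetero_delta * z / 2)
  eps <- if (cfg$sigma0 > 0) stats::rnorm(n, 0, sd_i) else 0
  cfg$mu0 + g_term + cfg$beta_e * e_lin + c_term + eps
}

#' Simulate covariates (age, sex, birth weight)
#'
#' Plain numeric covariates with realistic cattle-study scales: age in days
#' around weaning-to-yearling, sex as 0/1, birth weight in kg.
#'
#' @param cfg A [sim_config()].
#' @return Data frame with columns `age_days`, `sex`, `birth_weight`.
#' @export
simulate_covariates <- function(cfg) {
  set.seed(cfg$seed + 3L)
  n <- cfg$n_samples
  data.frame(
    age_days = round(stats::rnorm(n, 400, 60)),
    sex = stats::rbinom(n, 1L, 0.5),
    birth_weight = round(stats::rnorm(n, 40, 5), 1)
  )
}

#' Simulate parent-parent-offspring trios by Mendelian transmission
#'
#' Appends `n_trios` offspring to a simulated panel: for each trio, two
#' distinct existing samples are taken as parents and each transmits one
#' allele per marker (heterozygotes transmit either allele with probability
#' 1/2). Genotyping errors replace the child's true genotype with a
#' uniformly random different genotype at rate `error_rate`.
#'
#' @param G A [genotype_matrix()] of potential parents (no missing calls at
#'   transmitted markers; missing parent genotypes yield missing child calls).
#' @param n_trios Number of trios to create.
#' @param error_rate Per-genotype error probability in the children.
#' @param seed Integer seed.
#' @return List with `genotypes` (a [genotype_matrix()] containing parents
#'   then children) and `trios` (data frame `child`, `father`, `mother`).
#' @export
simulate_trios <- function(G, n_trios, error_rate = 0, seed = 1L) {
  set.seed(seed)
  n <- n_samples(G)
  m <- n_markers(G)
  if (2L * n_trios > n) stop("not enough parents for trios", call. = FALSE)
  pick <- matrix(sample(n, 2L * n_trios), ncol = 2)
  kids <- matrix(NA_integer_, n_trios, m)
  transmit <- function(g) {
    # allele transmitted from a parent genotype (A1 count)
    out <- integer(length(g))
    out[g == 2L] <- 1L
    out[g == 0L] <- 0L
    het <- which(g == 1L)
    out[het] <- stats::rbinom(length(het), 1L, 0.5)
    out[is.na(g)] <- NA_integer_
    out
  }
  for (t in seq_len(n_trios)) {
    gf <- G$genotypes[pick[t, 1], ]
    gm <- G$genotypes[pick[t, 2], ]
    kid <- transmit(gf) + transmit(gm)
    if (error_rate > 0) {
      err <- which(stats::runif(m) < error_rate & !is.na(kid))
      for (j in err) kid[j] <- sample(setdiff(0:2, kid[j]), 1L)
    }
    kids[t, ] <- kid
  }
  child_ids <- sprintf("KID%04d", seq_len(n_trios))
  Gall <- genotype_matrix(rbind(G$genotypes, kids), G$map,
                          c(G$samples, child_ids))
  trios <- data.frame(child = child_ids,
                      father = G$samples[pick[, 1]],
                      mother = G$samples[pick[, 2]],
                      stringsAsFactors = FALSE)
  list(genotypes = Gall, trios = trios)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: genotypes, farm assignment, temperature exposure,
#' covariates, and a phenotype with the configured effects at
#' `n_causal` markers spread evenly over the panel.
#'
#' @param cfg A [sim_config()].
#' @param env_kind `"continuous"` or `"categorical"`.
#' @param n_causal Number of causal interaction markers.
#' @return List with `genotypes`, `env`, `covariates`, `phenotype`,
#'   `causal_snps`, and `sample_table` (a data frame mirroring the on-disk
#'   TSV layout).
#' @export
simulate_study <- function(cfg, env_kind = "continuous", n_causal = 0L) {
  G <- simulate_genotypes(cfg)
  set.seed(cfg$seed + 4L)
  farm_levels <- sprintf("farm%d", seq_len(cfg$n_farms))
  farms <- sample(farm_levels, cfg$n_samples, replace = TRUE)
  birth <- sample(1:12, cfg$n_samples, replace = TRUE)
  record <- birth + sample(9:15, cfg$n_samples, replace = TRUE)
  E <- if (env_kind == "continuous") {
    simulate_environment(cfg, "continuous", birth, record, farms = farms)
  } else {
    env_vector(farms, "categorical", levels = farm_levels)
  }
  C <- simulate_covariates(cfg)
  causal <- if (n_causal > 0L) {
    # interior quantiles: keep causal loci off the chromosome edges
    unique(round(seq(1L, n_markers(G), length.out = n_causal + 2L)))[
      seq_len(n_causal) + 1L]
  } else integer(0)
  y <- simulate_phenotype(G, E, C, cfg, causal)
  if (env_kind == "categorical") {
    y <- y + cfg$farm_effects[match(farms, farm_levels)]
  }
  tbl <- data.frame(IID = G$samples, phenotype = y, sex = C$sex,
                    age_days = C$age_days, birth_weight = C$birth_weight,
                    farm = farms,
                    mean_temp = if (env_kind == "continuous") E$values else NA,
                    stringsAsFactors = FALSE)
  list(genotypes = G, env = E, covariates = C, phenotype = y,
       causal_snps = causal, sample_table = tbl)
}
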