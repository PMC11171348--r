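#' Simulation configuration for the synthetic cattle study
#'
#' Bundles every knob of the synthetic-data generator: panel dimensions,
#' allele-frequency and LD structure, farm structure, the seasonal
#' temperature model, genetic and interaction effect sizes, and the
#' heteroskedastic residual model. The defaults emulate the structure of a
#' multi-farm beef-cattle growth study: seven farms, a continuous
#' per-individual mean-temperature exposure, and residual variance that
#' increases with environmental exposure.
#'
#' @param n_samples Number of individuals.
#' @param n_snps Number of markers.
#' @param maf_range Length-2 numeric in (0, 0.5]; per-SNP target minor
#'   allele frequencies are drawn uniformly from this interval.
#' @param ld_decay Adjacent-marker haplotype copying probability in
#'   `[0, 1)`. 0 gives independent markers; larger values give stronger
#'   local LD (first-order Markov haplotype copying).
#' @param n_chr Number of chromosomes the panel is spread over (autosome
#'   labels "1", "2", ...; capped at 29 as for cattle).
#' @param spacing_bp Mean inter-marker spacing in base pairs.
#' @param n_farms Number of farms (categorical environment levels).
#' @param farm_effects Numeric vector of per-farm phenotype offsets (kg),
#'   recycled to `n_farms`.
#' @param farm_temp_baselines Per-farm annual mean temperature (degrees C),
#'   recycled to `n_farms`.
#' @param temp_seasonal_amplitude Amplitude of the sinusoidal seasonal
#'   temperature cycle (degrees C).
#' @param temp_noise_sd SD of month-to-month temperature noise (degrees C).
#' @param mu0 Phenotype intercept (kg).
#' @param beta_g Additive SNP effect per effect allele (kg).
#' @param beta_e Environment main effect (kg per environment unit).
#' @param beta_gxe Interaction effect (kg per allele x environment unit).
#' @param beta_c Covariate effects, recycled over covariate columns.
#' @param hetero_delta Log-variance slope on the standardized environment:
#'   residual variance is `sigma0^2 * exp(hetero_delta * z(E))`. 0 gives
#'   homoskedastic residuals.
#' @param sigma0 Baseline residual SD (kg); must be positive unless exactly
#'   zero is requested for noise-free checks.
#' @param missing_rate Genotype missingness rate (completely at random).
#' @param seed Integer seed; identical configurations (including seed)
#'   produce bit-identical simulated data.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 1350L,
                       n_snps = 5000L,
                       maf_range = c(0.05, 0.5),
                       ld_decay = 0,
                       n_chr = 5L,
                       spacing_bp = 1000L,
                       n_farms = 7L,
                       farm_effects = c(0, 12, -8, 25, 5, -15, 18),
                       farm_temp_baselines = c(6, 5, 7, 5, 15, 17, 16),
                       temp_seasonal_amplitude = 12,
                       temp_noise_sd = 1.5,
                       mu0 = 0,
                       beta_g = 0,
                       beta_e = 0,
                       beta_gxe = 0,
                       beta_c = 0,
                       hetero_delta = 0,
                       sigma0 = 1,
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range), ld_decay = as.numeric(ld_decay),
    n_chr = as.integer(n_chr), spacing_bp = as.integer(spacing_bp),
    n_farms = as.integer(n_farms),
    farm_effects = rep_len(as.numeric(farm_effects), as.integer(n_farms)),
    farm_temp_baselines = rep_len(as.numeric(farm_temp_baselines),
                                  as.integer(n_farms)),
    temp_seasonal_amplitude = as.numeric(temp_seasonal_amplitude),
    temp_noise_sd = as.numeric(temp_noise_sd),
    mu0 = as.numeric(mu0), beta_g = as.numeric(beta_g),
    beta_e = as.numeric(beta_e), beta_gxe = as.numeric(beta_gxe),
    beta_c = as.numeric(beta_c),
    hetero_delta = as.numeric(hetero_delta), sigma0 = as.numeric(sigma0),
    missing_rate = as.numeric(missing_rate), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_samples < 0L || cfg$n_snps < 0L) {
    stop("sim_config: n_samples and n_snps must be non-negative",
         call. = FALSE)
  }
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("sim_config: maf_range must be an increasing pair within (0, 0.5]",
         call. = FALSE)
  }
  if (cfg$ld_decay < 0 || cfg$ld_decay >= 1) {
    stop("sim_config: ld_decay must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$sigma0 < 0) stop("sim_config: sigma0 must be >= 0", call. = FALSE)
  if (cfg$n_farms < 2L) stop("sim_config: n_farms must be >= 2", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("sim_config: missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$n_chr < 1L || cfg$n_chr > 29L) {
    stop("sim_config: n_chr must lie in 1..29 (cattle autosomes)",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match [sim_config()] arguments.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown sim_config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, vals)
}
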