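# Design construction for the per-SNP interaction regression: genotype
# principal components and the full design matrix with SNP, environment,
# SNP x environment, covariate, covariate x SNP and covariate x environment
# columns. A categorical environment is expanded to treatment-coded
# contrasts against a documented reference level; a continuous environment
# is centered before interaction columns are formed.

#' Genotype principal components
#'
#' Top eigenvectors of the centered-and-scaled genotype covariance,
#' computed by SVD of the standardized genotype matrix. Missing genotypes
#' are mean-imputed per SNP for this computation only (per-SNP regressions
#' stay complete-case). Columns are orthonormal, ordered by decreasing
#' eigenvalue, with the sign fixed so each component's largest-magnitude
#' entry is positive.
#'
#' @param G A [genotype_matrix()].
#' @param n_components Number of components (default 20, truncated to what
#'   the panel supports).
#' @return Numeric matrix `n x n_components` with columns `PC1`, `PC2`, ...
#'   (a zero-column matrix when `n_components` is 0).
#' @export
genotype_pca <- function(G, n_components = 20L) {
  n_components <- as.integer(n_components)
  if (n_components < 0L) stop("n_components must be >= 0", call. = FALSE)
  n <- n_samples(G)
  if (n_components == 0L) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  X <- impute_mean(G)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  X <- scale(X[, keep, drop = FALSE])
  k_max <- min(n - 1L, ncol(X))
  if (n_components > k_max) {
    stop(sprintf("n_components = %d exceeds the panel's rank (%d)",
                 n_components, k_max), call. = FALSE)
  }
  sv <- svd(X, nu = n_components, nv = 0)
  U <- sv$u
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) U[, k] <- -U[, k]
  }
  colnames(U) <- paste0("PC", seq_len(ncol(U)))
  U
}

#' Build the per-SNP interaction design matrix
#'
#' Columns, in order: intercept; SNP allele count; environment (1 centered
#' column when continuous, `levels - 1` treatment contrasts when
#' categorical); SNP x environment; covariates; covariate x SNP;
#' covariate x environment. Rows with any missing value in `g`, `E`, `C`
#' or `y` are removed and recorded in `rows_used`. The matrix must be full
#' column rank; a rank-deficient design is an error naming the collinear
#' columns, never silent dropping.
#'
#' @param g Numeric per-sample SNP allele counts (may contain NA).
#' @param E An [env_vector()].
#' @param C Optional covariate data frame/matrix (numeric columns).
#' @param y Optional phenotype vector; only used for complete-case removal.
#' @param reference_level Categorical reference level (default: first level
#'   in sorted order).
#' @param center_env Center a continuous environment before interactions
#'   (default TRUE; SNP main effects are then "at mean environment").
#' @return Object of class `design_matrix`: list with `X`, `groups` (named
#'   list of column indices: intercept, snp, env, snp_env, covariates,
#'   cov_snp, cov_env), and `rows_used`.
#' @export
build_design <- function(g, E, C = NULL, y = NULL,
                         reference_level = NULL, center_env = TRUE) {
  n <- length(g)
  Cm <- if (is.null(C)) matrix(numeric(0), n, 0) else as.matrix(C)
  if (ncol(Cm) && is.null(colnames(Cm))) {
    colnames(Cm) <- paste0("cov", seq_len(ncol(Cm)))
  }
  e_missing <- if (E$kind == "continuous") is.na(E$values) else is.na(E$values)
  used <- !is.na(g) & !e_missing
  if (ncol(Cm)) used <- used & stats::complete.cases(Cm)
  if (!is.null(y)) used <- used & !is.na(y)
  rows_used <- which(used)
  if (length(rows_used) == 0L) stop("no complete cases", call. = FALSE)
  Esub <- if (E$kind == "continuous") {
    env_vector(E$values[rows_used], "continuous")
  } else {
    env_vector(E$values[rows_used], "categorical", levels = E$levels)
  }
  Ecols <- encode_environment(Esub, reference_level = reference_level,
                              center = center_env)
  if (E$kind == "categorical" &&
      length(unique(Esub$values)) < 2L ||
      (E$kind == "continuous" && stats::sd(Esub$values) == 0)) {
    stop("environment is constant after complete-case removal",
         call. = FALSE)
  }
  gs <- g[rows_used]
  Cs <- Cm[rows_used, , drop = FALSE]
  L <- ncol(Ecols)
  k <- ncol(Cs)
  snp_env <- gs * Ecols
  colnames(snp_env) <- paste0("snp_x_", colnames(Ecols))
  cov_snp <- Cs * gs
  if (k) colnames(cov_snp) <- paste0(colnames(Cs), "_x_snp")
  cov_env <- matrix(numeric(0), length(rows_used), 0)
  if (k && L) {
    cov_env <- do.call(cbind, lapply(seq_len(L), function(l) {
      M <- Cs * Ecols[, l]
      colnames(M) <- paste0(colnames(Cs), "_x_", colnames(Ecols)[l])
      M
    }))
  }
  X <- cbind(`(Intercept)` = 1, snp = gs, Ecols, snp_env, Cs, cov_snp,
             cov_env)
  p <- ncol(X)
  groups <- list(
    intercept = 1L,
    snp = 2L,
    env = seq.int(3L, length.out = L),
    snp_env = seq.int(3L + L, length.out = L),
    covariates = seq.int(3L + 2L * L, length.out = k),
    cov_snp = seq.int(3L + 2L * L + k, length.out = k),
    cov_env = seq.int(3L + 2L * L + 2L * k, length.out = k * L)
  )
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(X = X, groups = groups, rows_used = rows_used),
            class = "design_matrix")
}
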