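# Main-effect GWAS baseline: genomic relationship matrix, REML variance
# components via a single eigendecomposition, and EMMAX-style per-SNP
# association with the variance ratio fixed at the null estimate.

#' Genomic relationship matrix
#'
#' `K = W W' / m` with `W` the per-SNP mean-imputed, centered,
#' variance-standardized genotype matrix. Symmetric, PSD to numerical
#' tolerance, mean diagonal approximately 1.
#'
#' @param G A [genotype_matrix()] (post-QC, no monomorphic SNPs).
#' @return Object of class `grm`: list with `K` (n x n), `n_snps_used`,
#'   `samples`.
#' @export
compute_grm <- function(G) {
  X <- impute_mean(G)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("monomorphic SNP reached compute_grm: QC contract violated",
         call. = FALSE)
  }
  W <- scale(X)
  K <- tcrossprod(W) / ncol(W)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(G$samples, G$samples)
  structure(list(K = K, n_snps_used = ncol(W), samples = G$samples),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("GRM: %d samples from %d SNPs; mean diagonal %.3f\n",
              nrow(x$K), x$n_snps_used, mean(diag(x$K))))
  invisible(x)
}

# REML log-likelihood for variance ratio lambda = sigma_a^2 / sigma_e^2,
# in the rotated space: V = sigma_e^2 (lambda * D + I).
.reml_ll <- function(log10_lambda, yt, Xt, d) {
  lambda <- 10^log10_lambda
  w <- 1 / (lambda * d + 1)
  sw <- sqrt(w)
  Xw <- Xt * sw
  yw <- yt * sw
  qx <- qr(Xw)
  res <- qr.resid(qx, yw)
  n <- length(yt); q <- ncol(Xt)
  rss <- sum(res^2)
  sigma_e2 <- rss / (n - q)
  R <- qr.R(qx)
  ldXVX <- 2 * sum(log(abs(diag(R))))
  ll <- -0.5 * ((n - q) * (log(2 * pi * sigma_e2) + 1) -
                  sum(log(w)) + ldXVX)
  if (!is.finite(ll)) {
    stop(sprintf("non-finite REML log-likelihood at log10(lambda) = %.3f",
                 log10_lambda), call. = FALSE)
  }
  ll
}

#' REML fit of the null (no-SNP) mixed model
#'
#' Eigendecomposes the GRM once and profiles the REML log-likelihood over
#' the variance ratio `lambda = sigma_a^2 / sigma_e^2` on
#' `log10(lambda) in [-5, 5]` by 1-d optimization. When the likelihood is
#' flat in `lambda` (e.g. `K = I`, where only the total variance is
#' identifiable) the lower search bound is returned by convention.
#'
#' @param y Phenotype vector.
#' @param C Optional covariate matrix/data frame (an intercept is added).
#' @param K A [compute_grm()] result or a plain n x n matrix.
#' @return Object of class `lmm_null`: `lambda`, `sigma_a2`, `sigma_e2`,
#'   `h2`, eigen pair (`U`, `d`), rotated data (`yt`, `Xt`), `loglik`.
#' @export
fit_null_reml <- function(y, C = NULL, K) {
  Km <- if (inherits(K, "grm")) K$K else as.matrix(K)
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(C)) as.matrix(C))
  if (n <= ncol(X)) stop("need n > number of covariates", call. = FALSE)
  eig <- eigen(Km, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- as.vector(crossprod(U, y))
  Xt <- crossprod(U, X)
  lo <- -5; hi <- 5
  ll_lo <- .reml_ll(lo, yt, Xt, d)
  ll_hi <- .reml_ll(hi, yt, Xt, d)
  opt <- stats::optimize(.reml_ll, c(lo, hi), yt = yt, Xt = Xt, d = d,
                         maximum = TRUE, tol = 1e-8)
  cand_ll <- c(opt$objective, ll_lo, ll_hi)
  cand_lx <- c(opt$maximum, lo, hi)
  if (max(cand_ll) - min(cand_ll) < 1e-8) {
    best <- lo # flat profile: unidentifiable split, lower-bound convention
  } else {
    best <- cand_lx[which.max(cand_ll)]
  }
  lambda <- 10^best
  w <- 1 / (lambda * d + 1)
  sw <- sqrt(w)
  qx <- qr(Xt * sw)
  rss <- sum(qr.resid(qx, yt * sw)^2)
  sigma_e2 <- rss / (n - ncol(X))
  sigma_a2 <- lambda * sigma_e2
  structure(list(lambda = lambda, sigma_a2 = sigma_a2,
                 sigma_e2 = sigma_e2, h2 = lambda / (1 + lambda),
                 U = U, d = d, yt = yt, Xt = Xt,
                 loglik = .reml_ll(best, yt, Xt, d)),
            class = "lmm_null")
}

#' @export
print.lmm_null <- function(x, ...) {
  cat(sprintf("LMM null fit: sigma_a2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
              x$sigma_a2, x$sigma_e2, x$h2))
  invisible(x)
}

#' EMMAX-style per-SNP mixed-model association
#'
#' Generalized least squares Wald test for each marker in the whitened
#' (eigen-rotated) space with the variance ratio fixed at the null REML
#' estimate. Missing genotypes are mean-imputed per SNP. p-values come
#' from a t distribution with `n - q - 1` degrees of freedom.
#'
#' @param G A [genotype_matrix()].
#' @param y Phenotype vector aligned to `G`.
#' @param C Optional covariates aligned to `G`.
#' @param null A [fit_null_reml()] result for the same `y`, `C`, GRM.
#' @return Data frame: `snp`, `chr`, `pos`, `beta`, `se`, `stat`, `p`.
#' @export
lmm_assoc <- function(G, y, C = NULL, null) {
  w <- 1 / (null$lambda * null$d + 1)
  sw <- sqrt(w)
  Xw <- null$Xt * sw
  yw <- null$yt * sw
  qx <- qr(Xw)
  yr <- qr.resid(qx, yw)
  n <- length(yw); q <- ncol(Xw)
  df <- n - q - 1L
  Xg <- impute_mean(G)
  Gt <- crossprod(null$U, Xg) * sw  # rotated, whitened genotypes
  m <- n_markers(G)
  beta <- se <- stat <- p <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    gr <- qr.resid(qx, Gt[, j])
    s2g <- sum(gr^2)
    if (s2g < 1e-12) next # monomorphic after whitening
    b <- sum(gr * yr) / s2g
    res <- yr - gr * b
    sig2 <- sum(res^2) / df
    sej <- sqrt(sig2 / s2g)
    beta[j] <- b
    se[j] <- sej
    stat[j] <- b / sej
    p[j] <- 2 * stats::pt(-abs(b / sej), df)
  }
  data.frame(snp = G$map$snp, chr = G$map$chr, pos = G$map$pos,
             beta = beta, se = se, stat = stat, p = p,
             stringsAsFactors = FALSE)
}
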