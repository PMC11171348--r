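# Per-SNP interaction regression with model-based and Huber-White sandwich
# covariance. run_gweis() uses a shared QR of the SNP-free column block
# (intercept, environment, covariates, covariate x environment), residualizes
# the per-SNP columns against it (Frisch-Waugh-Lovell), and is asserted in
# the tests to agree with the naive full-design solve to high precision.

#' Ordinary least squares fit with model-based covariance
#'
#' @param y Response vector.
#' @param X Numeric design matrix or a `design_matrix` from
#'   [build_design()] (whose `rows_used` must already match `y`).
#' @return Object of class `gweis_fit`: coefficients, residuals,
#'   `model_cov` (`sigma2 * (X'X)^{-1}`), `sigma2`, `n_used`, `df_resid`,
#'   and the term `groups` when available.
#' @export
fit_ols <- function(y, X) {
  groups <- NULL
  if (inherits(X, "design_matrix")) {
    groups <- X$groups
    if (length(y) != nrow(X$X)) y <- y[X$rows_used]
    X <- X$X
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need n_used > p", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) stop("rank-deficient design in fit_ols", call. = FALSE)
  beta <- qr.coef(qrX, y)
  res <- as.vector(y - X %*% beta)
  df <- n - p
  sigma2 <- sum(res^2) / df
  R <- qr.R(qrX)
  XtX_inv <- chol2inv(R)
  # undo the QR pivot, if any
  piv <- qrX$pivot
  XtX_inv <- XtX_inv[order(piv), order(piv), drop = FALSE]
  model_cov <- sigma2 * XtX_inv
  dimnames(model_cov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, residuals = res,
                 model_cov = model_cov, xtx_inv = XtX_inv,
                 sigma2 = sigma2, n_used = n, df_resid = df,
                 X = X, groups = groups),
            class = "gweis_fit")
}

#' Huber-White sandwich covariance
#'
#' `(X'X)^{-1} X' diag(w) X (X'X)^{-1}` with per-observation weights
#' `w_i = e_i^2` (HC0), `n/(n-p) * e_i^2` (HC1, degrees-of-freedom
#' scaled), `e_i^2 / (1 - h_i)` (HC2) or `e_i^2 / (1 - h_i)^2` (HC3,
#' jackknife-like), where `h_i` is the hat-value of observation `i`.
#' Valid under heteroskedastic residuals, where the single-variance
#' model-based covariance is not. HC2/HC3 correct the downward bias of
#' squared residuals at high-leverage observations and are preferred at
#' moderate sample sizes.
#'
#' @param fit A `gweis_fit`, or a numeric design matrix (then `residuals`
#'   is required).
#' @param residuals Residual vector when `fit` is a plain matrix.
#' @param flavor `"HC1"` (default), `"HC0"`, `"HC2"` or `"HC3"`.
#' @return p x p robust covariance matrix.
#' @export
sandwich_covariance <- function(fit, residuals = NULL,
                                flavor = c("HC1", "HC0", "HC2", "HC3")) {
  flavor <- match.arg(flavor)
  if (inherits(fit, "gweis_fit")) {
    X <- fit$X; res <- fit$residuals; XtX_inv <- fit$xtx_inv
  } else {
    X <- as.matrix(fit); res <- residuals
    if (is.null(res)) stop("residuals required", call. = FALSE)
    XtX_inv <- chol2inv(chol(crossprod(X)))
  }
  n <- nrow(X); p <- ncol(X)
  if (length(res) != n) stop("residual length mismatch", call. = FALSE)
  w <- switch(flavor,
    HC0 = res^2,
    HC1 = res^2 * n / (n - p),
    HC2 = res^2 / (1 - .hat_values(X, XtX_inv)),
    HC3 = res^2 / (1 - .hat_values(X, XtX_inv))^2
  )
  meat <- crossprod(X * sqrt(w))  # X' diag(w) X
  V <- XtX_inv %*% meat %*% XtX_inv
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

.hat_values <- function(X, XtX_inv) {
  rowSums((X %*% XtX_inv) * X)
}

# Wald test on a coefficient subset under a chosen covariance.
.wald_group <- function(beta, V, idx, df_resid) {
  b <- beta[idx]
  L <- length(idx)
  if (L == 1L) {
    se <- sqrt(V[idx, idx])
    t_stat <- b / se
    if (b == 0) t_stat <- 0
    p <- 2 * stats::pt(-abs(t_stat), df_resid)
    list(stat = unname(t_stat^2), t = unname(t_stat), se = unname(se),
         df = 1L, p = unname(p))
  } else {
    Vs <- V[idx, idx, drop = FALSE]
    W <- tryCatch(as.numeric(t(b) %*% solve(Vs, b)),
                  error = function(e) NA_real_)
    if (is.na(W)) {
      stop("singular interaction sub-covariance", call. = FALSE)
    }
    list(stat = W, t = NA_real_, se = NA_real_, df = L,
         p = stats::pchisq(W, df = L, lower.tail = FALSE))
  }
}

#' Test the SNP-environment interaction coefficients
#'
#' One interaction column: t-test with `df_resid` degrees of freedom.
#' Multiple columns (categorical environment): Wald chi-square on the
#' interaction group's sub-covariance.
#'
#' @param fit A `gweis_fit` carrying term `groups`.
#' @param cov_choice `"robust"` (sandwich, default) or `"model"`.
#' @param flavor Sandwich flavor when robust.
#' @return List `stat`, `df`, `p` (plus `t`, `se` for the 1-df case).
#' @export
interaction_test <- function(fit, cov_choice = c("robust", "model"),
                             flavor = "HC1") {
  cov_choice <- match.arg(cov_choice)
  if (is.null(fit$groups) || !length(fit$groups$snp_env)) {
    stop("fit has no snp_env term group", call. = FALSE)
  }
  V <- if (cov_choice == "model") fit$model_cov else {
    sandwich_covariance(fit, flavor = flavor)
  }
  .wald_group(fit$coefficients, V, fit$groups$snp_env, fit$df_resid)
}

#' Joint test of SNP main and interaction effects
#'
#' Wald test on the concatenated `{snp, snp_env}` group (the original
#' joint-test formulation kept as an option), `df = 1 + L`.
#'
#' @inheritParams interaction_test
#' @return List `stat`, `df`, `p`.
#' @export
joint_test <- function(fit, cov_choice = c("robust", "model"),
                       flavor = "HC1") {
  cov_choice <- match.arg(cov_choice)
  if (is.null(fit$groups) || !length(fit$groups$snp) ||
      !length(fit$groups$snp_env)) {
    stop("fit lacks snp and snp_env term groups", call. = FALSE)
  }
  V <- if (cov_choice == "model") fit$model_cov else {
    sandwich_covariance(fit, flavor = flavor)
  }
  idx <- c(fit$groups$snp, fit$groups$snp_env)
  b <- fit$coefficients[idx]
  Vs <- V[idx, idx, drop = FALSE]
  W <- as.numeric(t(b) %*% solve(Vs, b))
  list(stat = W, df = length(idx),
       p = stats::pchisq(W, df = length(idx), lower.tail = FALSE))
}

# Naive per-SNP fit: full design + fit_ols + both tests. Reference path.
.gweis_one_naive <- function(g, E, C, y, flavor, reference_level = NULL) {
  dm <- build_design(g, E, C, y, reference_level = reference_level)
  fit <- fit_ols(y[dm$rows_used], dm)
  rob <- interaction_test(fit, "robust", flavor)
  mod <- interaction_test(fit, "model")
  L <- length(dm$groups$snp_env)
  list(n_used = fit$n_used,
       beta_gxe = if (L == 1L) unname(fit$coefficients[dm$groups$snp_env])
                  else NA_real_,
       se_model = mod$se, se_robust = rob$se,
       stat_model = mod$stat, stat_robust = rob$stat, df = rob$df,
       p_model = mod$p, p_robust = rob$p)
}

#' Genome-wide SNP-environment interaction scan
#'
#' Fits the full interaction model at every marker and reports both
#' model-based and Huber-White robust interaction tests. SNPs without
#' missing genotypes ride a fast path that reuses one QR decomposition of
#' the SNP-free column block across markers; SNPs with missing calls fall
#' back to the naive per-SNP complete-case solve. Markers monomorphic in
#' the analyzed subset, or whose residualized interaction column has
#' variance below `1e-12`, are skipped with a reason code.
#'
#' @param G A [genotype_matrix()] (post-QC).
#' @param E An [env_vector()] aligned to `G`.
#' @param C Optional covariate data frame aligned to `G`.
#' @param y Phenotype vector aligned to `G`.
#' @param flavor Sandwich flavor: `"HC3"` (default; leverage-corrected,
#'   well calibrated at cohort-scale n), `"HC2"`, `"HC1"` or `"HC0"`.
#' @param reference_level Categorical environment reference level.
#' @return Data frame (class `snp_summary`), one row per marker: `snp`,
#'   `chr`, `pos`, `a1`, `freq`, `n_used`, `beta_gxe`, `se_model`,
#'   `se_robust`, `stat_model`, `stat_robust`, `df`, `p_model`,
#'   `p_robust`, `reason` ("." when analyzed).
#' @export
run_gweis <- function(G, E, C = NULL, y, flavor = "HC3",
                      reference_level = NULL) {
  m <- n_markers(G)
  n <- n_samples(G)
  if (length(y) != n || length(E$values) != n) {
    stop("y and E must align with the genotype samples", call. = FALSE)
  }
  Cm <- if (is.null(C)) matrix(numeric(0), n, 0) else as.matrix(C)
  if (ncol(Cm) && is.null(colnames(Cm))) {
    colnames(Cm) <- paste0("cov", seq_len(ncol(Cm)))
  }
  base_used <- !is.na(y) & !is.na(E$values)
  if (ncol(Cm)) base_used <- base_used & stats::complete.cases(Cm)
  idx <- which(base_used)
  Esub <- if (E$kind == "continuous") {
    env_vector(E$values[idx], "continuous")
  } else {
    env_vector(E$values[idx], "categorical", levels = E$levels)
  }
  Ecols <- encode_environment(Esub, reference_level = reference_level)
  L <- ncol(Ecols)
  Cs <- Cm[idx, , drop = FALSE]
  k <- ncol(Cs)
  ys <- y[idx]
  cov_env <- matrix(numeric(0), length(idx), 0)
  if (k && L) {
    cov_env <- do.call(cbind, lapply(seq_len(L), function(l) Cs * Ecols[, l]))
  }
  Z <- cbind(1, Ecols, Cs, cov_env)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    stop("SNP-free design block is rank deficient", call. = FALSE)
  }
  y_t <- qr.resid(qz, ys)
  p_full <- ncol(Z) + 1L + L + k
  n_used_fast <- length(idx)
  if (n_used_fast <= p_full) stop("need n_used > p", call. = FALSE)
  df_full <- n_used_fast - p_full
  h_z <- rowSums(qr.qy(qz, diag(1, n_used_fast, qz$rank))^2)
  out <- data.frame(
    snp = G$map$snp, chr = G$map$chr, pos = G$map$pos, a1 = G$map$a1,
    freq = allele_freq(G), n_used = NA_integer_, beta_gxe = NA_real_,
    se_model = NA_real_, se_robust = NA_real_, stat_model = NA_real_,
    stat_robust = NA_real_, df = NA_integer_, p_model = NA_real_,
    p_robust = NA_real_, reason = ".", stringsAsFactors = FALSE
  )
  ie <- 2L:(1L + L) # interaction columns within the per-SNP block S
  for (j in seq_len(m)) {
    gj <- as.numeric(G$genotypes[, j])
    if (anyNA(gj[idx])) {
      gsub <- gj[idx]
      ok <- !is.na(gsub)
      if (stats::var(gsub[ok]) < 1e-12) {
        out$reason[j] <- "monomorphic"
        next
      }
      res <- tryCatch(
        .gweis_one_naive(gj, E, if (k) Cm else NULL, y, flavor,
                         reference_level),
        error = function(e) NULL)
      if (is.null(res)) {
        out$reason[j] <- "fit_failed"
        next
      }
      out[j, names(res)] <- res
      next
    }
    gs <- gj[idx]
    if (stats::var(gs) < 1e-12) {
      out$reason[j] <- "monomorphic"
      next
    }
    S <- cbind(gs, gs * Ecols, if (k) Cs * gs)
    St <- qr.resid(qz, S)
    qs <- qr(St)
    if (qs$rank < ncol(St)) {
      out$reason[j] <- "collinear"
      next
    }
    b <- qr.coef(qs, y_t)
    eps <- y_t - St %*% b
    int_var <- diag(crossprod(St[, ie, drop = FALSE])) / n_used_fast
    if (any(int_var < 1e-12)) {
      out$reason[j] <- "degenerate_interaction"
      next
    }
    sigma2 <- sum(eps^2) / df_full
    A <- chol2inv(qr.R(qs))
    pv <- qs$pivot
    A <- A[order(pv), order(pv), drop = FALSE]
    Vm <- sigma2 * A
    B <- St %*% A            # n x q; rows of (S~'S~)^{-1} S~' transposed
    eps <- as.vector(eps)
    w <- switch(flavor,
      HC0 = eps^2,
      HC1 = eps^2 * n_used_fast / df_full,
      HC2 = eps^2 / (1 - h_z - rowSums(B * St)),
      HC3 = eps^2 / (1 - h_z - rowSums(B * St))^2,
      stop("unknown sandwich flavor: ", flavor, call. = FALSE)
    )
    Vr <- crossprod(B * sqrt(w))
    tm <- .wald_group(b, Vm, ie, df_full)
    tr <- .wald_group(b, Vr, ie, df_full)
    out$n_used[j] <- n_used_fast
    out$beta_gxe[j] <- if (L == 1L) b[ie] else NA_real_
    out$se_model[j] <- tm$se
    out$se_robust[j] <- tr$se
    out$stat_model[j] <- tm$stat
    out$stat_robust[j] <- tr$stat
    out$df[j] <- tr$df
    out$p_model[j] <- tm$p
    out$p_robust[j] <- tr$p
  }
  skipped <- out$reason != "."
  if (m > 0 && mean(skipped) > 0.5) {
    stop(sprintf("run_gweis skipped %d of %d SNPs: likely input misalignment",
                 sum(skipped), m), call. = FALSE)
  }
  class(out) <- c("snp_summary", "data.frame")
  out
}

#' Export a SNP summary in conventional GWAS summary-statistic columns
#'
#' @param summary A `snp_summary` from [run_gweis()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_snp_summary <- function(summary, path) {
  out <- data.frame(SNP = summary$snp, CHR = summary$chr, BP = summary$pos,
                    A1 = summary$a1, FREQ = summary$freq,
                    N = summary$n_used, BETA = summary$beta_gxe,
                    SE = summary$se_robust, P = summary$p_robust,
                    P_MODEL = summary$p_model, REASON = summary$reason)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
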