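# Inflation diagnostics: QQ tables, genomic control lambda, and an LD
# score regression intercept with block-jackknife standard errors.

#' QQ-plot table
#'
#' Sorted observed p-values against the expected uniform order statistics:
#' `expected_i = -log10(i / (m + 1))` for the i-th smallest p. Zero
#' p-values are clamped to the smallest positive double with a warning.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Data frame `expected`, `observed` (both -log10 scale),
#'   ascending in `expected`.
#' @export
qq_table <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]", call. = FALSE)
  if (any(p == 0)) {
    warning("p = 0 clamped to .Machine$double.xmin")
    p[p == 0] <- .Machine$double.xmin
  }
  m <- length(p)
  data.frame(expected = -log10(seq_len(m) / (m + 1)),
             observed = -log10(sort(p)))
}

#' Genomic inflation factor
#'
#' `lambda_GC = median(chi2) / qchisq(0.5, 1)`, the median observed 1-df
#' chi-square over its null median (about 0.4549).
#'
#' @param p P-values (converted via the upper-tail chi-square quantile),
#'   or `NULL` if `chi2` is given.
#' @param chi2 Optional 1-df chi-square statistics.
#' @return Scalar inflation factor.
#' @export
genomic_inflation <- function(p = NULL, chi2 = NULL) {
  if (is.null(chi2)) {
    if (is.null(p)) stop("supply p or chi2", call. = FALSE)
    chi2 <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  }
  chi2 <- chi2[!is.na(chi2)]
  if (!length(chi2)) stop("no statistics", call. = FALSE)
  stats::median(chi2) / stats::qchisq(0.5, df = 1)
}

#' LD score regression intercept
#'
#' Weighted least squares regression of per-SNP 1-df chi-square statistics
#' on LD scores with weights `1 / max(ell, 1)`; the intercept near 1
#' indicates no confounding-driven or heteroskedasticity-driven inflation.
#' The intercept standard error comes from a delete-one-block jackknife
#' over contiguous marker blocks.
#'
#' @param chi2 Per-SNP chi-square statistics (or p-values via `p`).
#' @param ld Per-SNP LD scores aligned with `chi2` (see [ld_scores()]).
#' @param p Optional p-values used instead of `chi2`.
#' @param n_blocks Number of jackknife blocks (default 50).
#' @param chi2_max Markers with larger statistics are excluded before the
#'   fit (the usual step-1 convention that keeps a handful of strong
#'   association outliers from leveraging the intercept; default `Inf`,
#'   i.e. no exclusion).
#' @return Object of class `ldsc_fit`: `intercept`, `intercept_se`,
#'   `slope`, `n_snps`, `n_blocks`.
#' @export
ldsc_intercept <- function(chi2 = NULL, ld, p = NULL, n_blocks = 50L,
                           chi2_max = Inf) {
  if (is.null(chi2)) {
    if (is.null(p)) stop("supply chi2 or p", call. = FALSE)
    chi2 <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  }
  ok <- !is.na(chi2) & !is.na(ld) & chi2 <= chi2_max
  chi2 <- chi2[ok]; ld <- ld[ok]
  m <- length(chi2)
  if (m <= n_blocks) stop("need more markers than jackknife blocks",
                          call. = FALSE)
  w <- 1 / pmax(ld, 1)
  if (stats::sd(ld) == 0) {
    warning("constant LD scores: slope unidentifiable, intercept is the ",
            "weighted mean chi-square")
    est <- c(stats::weighted.mean(chi2, w), NA_real_)
  } else {
    est <- stats::coef(stats::lm(chi2 ~ ld, weights = w))
  }
  blocks <- cut(seq_len(m), breaks = n_blocks, labels = FALSE)
  theta <- vapply(seq_len(n_blocks), function(b) {
    keep <- blocks != b
    if (stats::sd(ld[keep]) == 0) {
      stats::weighted.mean(chi2[keep], w[keep])
    } else {
      stats::coef(stats::lm(chi2[keep] ~ ld[keep], weights = w[keep]))[1]
    }
  }, numeric(1))
  se <- sqrt((n_blocks - 1) / n_blocks * sum((theta - mean(theta))^2))
  structure(list(intercept = unname(est[1]), intercept_se = se,
                 slope = unname(est[2]), n_snps = m,
                 n_blocks = as.integer(n_blocks)),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf("LDSC intercept %.4f (SE %.4f), slope %.3g, m = %d\n",
              x$intercept, x$intercept_se, x$slope, x$n_snps))
  invisible(x)
}
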