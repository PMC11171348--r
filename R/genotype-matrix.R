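#' Construct a genotype matrix container
#'
#' Additive-coded genotypes (count of the A1 allele in each BIM record, the
#' PLINK convention) with a marker map and ordered sample IDs. Missing
#' genotypes are `NA`.
#'
#' @param genotypes n x m integer matrix with values in {0, 1, 2, NA}.
#' @param map Data frame with columns `snp`, `chr`, `pos`, `a1`, `a2`
#'   (1-based positions, cattle autosome labels "1".."29").
#' @param samples Character vector of individual IDs (unique, length n).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, map, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(map) != ncol(genotypes)) {
    stop("map rows must match genotype columns", call. = FALSE)
  }
  if (length(samples) != nrow(genotypes)) {
    stop("samples must match genotype rows", call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample IDs", call. = FALSE)
  }
  need <- c("snp", "chr", "pos", "a1", "a2")
  if (!all(need %in% names(map))) {
    stop("map must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 2L)) {
    stop("genotype values must be 0, 1, 2 or NA", call. = FALSE)
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  map$chr <- as.character(map$chr)
  rownames(map) <- NULL
  dimnames(genotypes) <- list(samples, map$snp)
  structure(list(genotypes = genotypes, map = map,
                 samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers on %d chromosome(s)\n",
              n_samples(x), n_markers(x), length(unique(x$map$chr))))
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing rate %.4f\n", miss))
  invisible(x)
}

#' Number of samples in a genotype matrix
#' @param G A `genotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(G) nrow(G$genotypes)

#' Number of markers in a genotype matrix
#' @param G A `genotype_matrix`.
#' @return Integer count.
#' @export
n_markers <- function(G) ncol(G$genotypes)

#' Subset a genotype matrix by samples and/or markers
#'
#' @param G A `genotype_matrix`.
#' @param samples Logical/integer index over samples (default all).
#' @param markers Logical/integer index over markers (default all).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(G, samples = NULL, markers = NULL) {
  if (is.null(samples)) samples <- seq_len(n_samples(G))
  if (is.null(markers)) markers <- seq_len(n_markers(G))
  genotype_matrix(G$genotypes[samples, markers, drop = FALSE],
                  G$map[markers, , drop = FALSE],
                  G$samples[samples])
}

#' Per-SNP allele frequency of the A1 allele
#'
#' Computed over non-missing genotypes; `NaN` for fully missing SNPs.
#'
#' @param G A `genotype_matrix`.
#' @return Numeric vector of length `n_markers(G)`.
#' @export
allele_freq <- function(G) {
  colMeans(G$genotypes, na.rm = TRUE) / 2
}

#' Per-SNP minor allele frequency
#' @param G A `genotype_matrix`.
#' @return Numeric vector, `pmin(f, 1 - f)` of the A1 frequency.
#' @export
maf <- function(G) {
  f <- allele_freq(G)
  pmin(f, 1 - f)
}

#' Mean-imputed, numeric genotype matrix
#'
#' Replaces missing genotypes by the per-SNP mean; used for PCA, the GRM,
#' and LD computations (never for the per-SNP regressions, which are
#' complete-case).
#'
#' @param G A `genotype_matrix`.
#' @return Numeric n x m matrix without missing values.
#' @export
impute_mean <- function(G) {
  X <- G$genotypes
  storage.mode(X) <- "double"
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- cm[idx[, 2]]
  X
}

#' Environment vector container
#'
#' @param values Per-sample environment measure (farm label or degrees C).
#' @param kind Either `"categorical"` or `"continuous"`.
#' @param levels Ordered level labels (categorical only).
#' @return An object of class `environment_vector`.
#' @export
env_vector <- function(values, kind = c("continuous", "categorical"),
                       levels = NULL) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    values <- as.character(values)
    if (is.null(levels)) levels <- sort(unique(values[!is.na(values)]))
    if (!all(values[!is.na(values)] %in% levels)) {
      stop("categorical environment values outside declared levels",
           call. = FALSE)
    }
  } else {
    values <- as.numeric(values)
    if (any(!is.finite(values) & !is.na(values))) {
      stop("continuous environment values must be finite or NA",
           call. = FALSE)
    }
    levels <- NULL
  }
  structure(list(values = values, kind = kind, levels = levels),
            class = "environment_vector")
}

#' @export
print.environment_vector <- function(x, ...) {
  cat(sprintf("environment_vector (%s), n = %d\n", x$kind, length(x$values)))
  invisible(x)
}
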