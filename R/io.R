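# PLINK BED/BIM/FAM, TSV sample tables, gene annotation and GMT gene sets.
# The BED codec follows the PLINK 1 binary spec: magic bytes 0x6c 0x1b,
# mode byte 0x01 (SNP-major), then ceil(n/4) bytes per SNP, two bits per
# sample packed little-endian within each byte. 2-bit codes (A1 counts):
# 00 = A1/A1 (2), 01 = missing, 10 = het (1), 11 = A2/A2 (0).

.bed_code_to_geno <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)

#' Write a genotype matrix as a PLINK BED/BIM/FAM triple
#'
#' @param G A [genotype_matrix()].
#' @param prefix Output path prefix; writes `prefix.bed`, `.bim`, `.fam`.
#' @return Invisibly, the prefix.
#' @export
write_plink <- function(G, prefix) {
  n <- n_samples(G)
  m <- n_markers(G)
  bpp <- ceiling(n / 4) # bytes per SNP
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  geno_to_code <- function(g) {
    code <- integer(length(g))
    code[is.na(g)] <- 1L
    code[!is.na(g) & g == 2L] <- 0L
    code[!is.na(g) & g == 1L] <- 2L
    code[!is.na(g) & g == 0L] <- 3L
    code
  }
  pad <- 4L * bpp - n
  shift <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(m)) {
    code <- c(geno_to_code(G$genotypes[, j]), rep(0L, pad))
    dim(code) <- c(4L, bpp)
    bytes <- as.integer(shift %*% code)
    writeBin(as.raw(bytes), con)
  }
  bim <- data.frame(chr = G$map$chr, snp = G$map$snp, cm = 0,
                    pos = G$map$pos, a1 = G$map$a1, a2 = G$map$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = G$samples, iid = G$samples, pat = 0, mat = 0,
                    sex = 0, phe = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK BED/BIM/FAM triple
#'
#' Decodes the 2-bit SNP-major PLINK 1 encoding; the genotype value is the
#' count of the BIM A1 allele, missing calls become `NA`. Markers on
#' non-autosomal or out-of-vocabulary chromosomes (anything outside
#' "1".."29") are dropped with a message, mirroring an autosome-only
#' cattle analysis.
#'
#' @param prefix Path prefix of the `.bed`/`.bim`/`.fam` triple.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  miss <- paths[!file.exists(paths)]
  if (length(miss)) {
    stop("missing PLINK file(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bim <- utils::read.table(paths[2], header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           col.names = c("chr", "snp", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("character", "character",
                                          "numeric", "integer",
                                          "character", "character"))
  fam <- utils::read.table(paths[3], header = FALSE, sep = "",
                           stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  bpp <- ceiling(n / 4)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop(sprintf("not a PLINK BED file: bad magic bytes at offset 0 in %s",
                 paths[1]), call. = FALSE)
  }
  if (raw[3] != as.raw(0x01)) {
    stop(sprintf("unsupported BED mode byte 0x%02x at offset 2 (need ",
                 as.integer(raw[3])), "SNP-major 0x01)", call. = FALSE)
  }
  need <- 3L + bpp * m
  if (length(raw) < need) {
    stop(sprintf("truncated BED file: expected %d bytes, found %d (first missing offset %d)",
                 need, length(raw), length(raw)), call. = FALSE)
  }
  body <- as.integer(raw[4:need])
  dim(body) <- c(bpp, m)
  # expand each byte into its 4 two-bit codes
  codes <- matrix(0L, 4L * bpp, m)
  b <- body
  for (k in 1:4) {
    codes[seq(k, by = 4L, length.out = bpp), ] <- b %% 4L
    b <- b %/% 4L
  }
  geno <- matrix(.bed_code_to_geno[codes[seq_len(n), , drop = FALSE] + 1L],
                 nrow = n, ncol = m)
  G <- genotype_matrix(geno,
                       data.frame(snp = bim$snp, chr = bim$chr,
                                  pos = bim$pos, a1 = bim$a1, a2 = bim$a2,
                                  stringsAsFactors = FALSE),
                       as.character(fam[[2]]))
  auto <- G$map$chr %in% as.character(1:29)
  if (!all(auto)) {
    message(sum(!auto), " non-autosomal marker(s) dropped at load")
    G <- subset_genotypes(G, markers = auto)
  }
  G
}

#' Read a TSV sample table
#'
#' Header and an `IID` column are required; IIDs must be unique. Requested
#' phenotype/covariate/environment columns are checked for presence and a
#' schema error lists the available columns if any is absent. Rows with a
#' missing phenotype or environment are retained and flagged (column
#' `.complete`), never silently dropped.
#'
#' @param path TSV file with header.
#' @param phenotype Phenotype column name.
#' @param covariates Character vector of covariate column names.
#' @param environment Environment column name.
#' @return Data frame with attribute `"roles"` recording the column roles
#'   and a logical `.complete` column.
#' @export
read_sample_table <- function(path, phenotype = NULL, covariates = NULL,
                              environment = NULL) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"IID" %in% names(tbl)) {
    stop("sample table must have an IID column; found: ",
         paste(names(tbl), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tbl$IID)) {
    stop("duplicate IID in sample table: ",
         paste(unique(tbl$IID[duplicated(tbl$IID)]), collapse = ", "),
         call. = FALSE)
  }
  want <- c(phenotype, covariates, environment)
  absent <- setdiff(want, names(tbl))
  if (length(absent)) {
    stop("column(s) not in sample table: ",
         paste(absent, collapse = ", "), "; available: ",
         paste(names(tbl), collapse = ", "), call. = FALSE)
  }
  comp <- rep(TRUE, nrow(tbl))
  for (col in c(phenotype, environment)) {
    comp <- comp & !is.na(tbl[[col]])
  }
  tbl$.complete <- comp
  attr(tbl, "roles") <- list(phenotype = phenotype, covariates = covariates,
                             environment = environment)
  tbl
}

#' Align a sample table to the genotype sample order
#'
#' Pure permutation: reorders rows so `tbl$IID` matches `G$samples`;
#' errors if any genotyped sample is absent from the table.
#'
#' @param tbl Data frame with an `IID` column.
#' @param G A [genotype_matrix()].
#' @return The reordered data frame.
#' @export
align_samples <- function(tbl, G) {
  idx <- match(G$samples, tbl$IID)
  if (anyNA(idx)) {
    stop("sample table is missing ", sum(is.na(idx)),
         " genotyped sample(s)", call. = FALSE)
  }
  out <- tbl[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "roles") <- attr(tbl, "roles")
  out
}

#' Read a BED-like gene annotation
#'
#' Four tab-separated columns: chromosome, start, stop, gene ID, with
#' 1-based inclusive coordinates (documented dialect; this is not the
#' 0-based UCSC BED convention).
#'
#' @param path Annotation file (no header).
#' @return Data frame `gene`, `chr`, `start`, `stop`.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chr", "start", "stop", "gene"))
  if (any(ann$start > ann$stop)) {
    stop("gene annotation has start > stop", call. = FALSE)
  }
  data.frame(gene = ann$gene, chr = as.character(ann$chr),
             start = as.integer(ann$start), stop = as.integer(ann$stop),
             stringsAsFactors = FALSE)
}

#' Read a GMT gene-set file
#'
#' GMT dialect: tab-separated lines of set name, description, then member
#' gene IDs. Sets are filtered to those with at least two member genes
#' present in the annotation (sets must contain multiple analyzable genes);
#' the number filtered out is reported via `message()` and recorded in the
#' `"n_dropped"` attribute.
#'
#' @param path GMT file.
#' @param annotation Optional gene annotation data frame (from
#'   [read_gene_annotation()]); when given, membership is intersected with
#'   annotated genes before the size filter.
#' @return Named list of character vectors (class `gene_set_collection`),
#'   with attributes `n_dropped` and `n_read`.
#' @export
read_gene_sets <- function(path, annotation = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: no gene sets read")
    out <- structure(list(), class = "gene_set_collection",
                     n_dropped = 0L, n_read = 0L)
    return(out)
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      stop(sprintf("malformed GMT line %d: fewer than 2 fields", i),
           call. = FALSE)
    }
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  n_read <- length(sets)
  if (!is.null(annotation)) {
    sets <- lapply(sets, intersect, y = annotation$gene)
  }
  keep <- vapply(sets, function(g) length(g) >= 2L, logical(1))
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message(n_dropped, " gene set(s) dropped (fewer than 2 annotated genes)")
  }
  structure(sets[keep], class = "gene_set_collection",
            n_dropped = n_dropped, n_read = n_read)
}

#' Write a summary-statistic table as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
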