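#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-farm cattle study the rest of the
# analysis runs on, and write it in the standard on-disk formats
# (PLINK BED/BIM/FAM, TSV sample table, gene annotation, GMT gene sets).
#
# The panel emulates the structure of the real study at desk scale:
# 1350 animals on 7 farms, a continuous per-individual mean-temperature
# exposure, age/sex/birth-weight covariates, local LD, heteroskedastic
# residuals, and a handful of true interaction loci.

suppressPackageStartupMessages(library(gxescan))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  n_samples = 1350, n_snps = 8000, n_chr = 8, ld_decay = 0.5,
  maf_range = c(0.05, 0.5), missing_rate = 0.01,
  hetero_delta = 0.5, sigma0 = 25,      # kg; growth-trait scale
  mu0 = 250, beta_gxe = 1.2,            # kg per allele per degree C
  beta_c = c(0.05, 12, 0.8),            # age (d), sex, birth weight (kg)
  seed = 20240605
)
st <- simulate_study(cfg, env_kind = "continuous", n_causal = 3)

write_plink(st$genotypes, file.path(out, "panel"))
write.table(st$sample_table, file.path(out, "samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# tile genes of ~6 markers across the map; 50 kb windows are added at
# mapping time, mirroring an annotation of transcription start/stop sites
map <- st$genotypes$map
genes <- do.call(rbind, lapply(unique(map$chr), function(c) {
  pos <- map$pos[map$chr == c]
  starts <- pos[seq(1, length(pos) - 5, by = 6)]
  stops <- pos[pmin(seq(6, length(pos), by = 6), length(pos))]
  data.frame(chr = c, start = starts, stop = stops[seq_along(starts)])
}))
genes$gene <- sprintf("gene%04d", seq_len(nrow(genes)))
write.table(genes[, c("chr", "start", "stop", "gene")],
            file.path(out, "genes.bed"), sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)

set.seed(cfg$seed)
gmt <- vapply(1:60, function(i) {
  paste(c(sprintf("set%03d", i), "synthetic Reactome-like set",
          sample(genes$gene, sample(10:40, 1))), collapse = "\t")
}, character(1))
writeLines(gmt, file.path(out, "sets.gmt"))

cat(sprintf("wrote %d samples x %d SNPs, %d genes, 60 gene sets to %s\n",
            n_samples(st$genotypes), n_markers(st$genotypes),
            nrow(genes), out))
cat(sprintf("true interaction loci: %s\n",
            paste(map$snp[st$causal_snps], collapse = ", ")))
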