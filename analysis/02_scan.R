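#!/usr/bin/env Rscript
# Stage 2 -- selection scan, XP against each control population.
#
# Hard filters + cohort QC, then per comparison: 100 kb / 10 kb windowed
# Weir-Cockerham Fst and theta-pi ratio, joint top-5% outlier windows,
# merged candidate regions. One run directory per comparison under
# results/scan/, plus a summary table of realized thresholds and counts.

library(sweepscan)

gm <- parse_vcf("results/data/cohort.vcf")
popmap <- read_popmap("results/data/popmap.tsv")
genes <- load_gff("results/data/genes.gff3")
gene_sets <- read_gmt("results/data/sets.gmt")
chrom_lengths <- c("1" = 10000000, "2" = 10000000)

summary_rows <- list()
for (control in c("TT", "MS", "DU", "LW")) {
  res <- run_scan_pipeline(
    gm, popmap, target = "XP", control = control,
    chrom_lengths = chrom_lengths,
    out_dir = file.path("results/scan", paste0("XP_vs_", control)),
    genes = genes, gene_sets = gene_sets,
    vcf_path = "results/data/cohort.vcf"
  )
  summary_rows[[control]] <- data.frame(
    comparison = paste0("XP_vs_", control),
    windows = res$counts$windows_scanned,
    fst_threshold = res$thresholds["fst"],
    ratio_threshold = res$thresholds["ratio"],
    outlier_windows = res$counts$outlier_windows,
    regions = res$counts$regions,
    region_genes = res$counts$region_genes
  )
  cat(sprintf(
    "XP vs %s: %d outlier windows (Fst > %.3f, ratio > %.3f) -> %d regions, %d genes\n",
    control, res$counts$outlier_windows, res$thresholds["fst"],
    res$thresholds["ratio"], res$counts$regions, res$counts$region_genes
  ))
}
summary <- do.call(rbind, summary_rows)
write.table(summary, "results/scan/summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
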