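#!/usr/bin/env Rscript
# TSS-centric annotation of the primary peak set: distance-to-TSS
# histogram, promoter fraction (within 1 kb of a TSS), simplified feature
# classification, and single-nearest-gene assignment within 50 kb.

suppressPackageStartupMessages(library(chipcoloc))

A <- read_peaks("results/world/peaks_primary.narrowPeak",
                label = "primary", genome_id = "syn")
genes <- read_genes_bed("results/world/genes.bed")

hist_df <- tss_histogram(A, genes)
write.table(hist_df, "results/tss_histogram.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

prom <- promoter_fraction(A, genes)
feats <- table(classify_feature(A, genes))
assign <- assign_nearest_gene(A, genes)
write.table(assign, "results/gene_assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

n_genes_hit <- length(unique(assign$gene_id[!is.na(assign$gene_id)]))
write.table(
  data.frame(metric = c("promoter_pct", names(feats), "peaks_assigned",
                        "unique_genes_within_50kb"),
             value = c(prom, as.integer(feats), sum(assign$within_50kb),
                       n_genes_hit)),
  "results/annotation.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("finding: %.1f %% of peaks lie within 1 kb of a TSS;", prom))
message(sprintf("  %d peaks assign to %d unique genes within 50 kb",
                sum(assign$within_50kb), n_genes_hit))
message("  (feature classes use the simplified promoter/gene-body/intergenic scheme)")
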