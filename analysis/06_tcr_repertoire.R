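#!/usr/bin/env Rscript
# TCR repertoire statistics from the 10x-style contig table: paired-chain
# clonotype assembly with retention report, clonal fractions per
# cluster x group, clone-space occupancy by clonotype rank, inter-cluster
# repertoire overlap (both conventions), V-J usage, and the clone-size
# distribution.

suppressPackageStartupMessages(library(ggnsc))

cohort <- read_dataset("results/cohort")
ct <- assign_clonotypes(cohort$contigs, meta = cohort$dataset$cell_meta)
cat(sprintf("retained %d of %d T cells (%.2f%%)\n",
            ct$report$n_retained, ct$report$n_cells_input,
            ct$report$retention_percent))
write.table(ct$cells, "results/clonotypes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cf <- clonal_fraction(ct, by = c("cluster", "group"))
write.table(cf, "results/clonal_fractions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nclonal fraction by cluster x group:\n")
print(cf, row.names = FALSE)

occ <- clone_space_occupancy(ct)
write.table(occ, "results/clone_space_occupancy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ov <- clonotype_overlap(ct)
jac <- clonotype_overlap(ct, mode = "jaccard")
cat("\nclonotype overlap (overlap coefficient, %):\n")
print(round(ov$percent, 2))
write.table(ov$percent, "results/clonotype_overlap_min.tsv", sep = "\t",
            quote = FALSE)
write.table(jac$percent, "results/clonotype_overlap_jaccard.tsv",
            sep = "\t", quote = FALSE)

vj <- vj_usage(ct, chain = "TRB")
write.table(vj, "results/vj_usage_trb.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
csd <- clone_size_distribution(ct)
write.table(csd, "results/clone_size_distribution.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nclone-size distribution (cells conserved per group):\n")
print(aggregate(I(clone_size * n_clonotypes) ~ group, csd, sum),
      row.names = FALSE)
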