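#!/usr/bin/env Rscript
# Binned-control gene-set scores (naive / cytotoxic / exhaustion) per
# cell, cluster-level summaries, and the dysfunction-gene selection:
# genes whose expression tracks the cytotoxic score and differ between
# nLung and AIS/IAC.

suppressPackageStartupMessages(library(ggnsc))

cohort <- read_dataset("results/cohort")
sets <- lapply(cohort$gene_sets, unlist)
sc <- score_cells(cohort$dataset, sets = sets, seed = 2026)
write.table(sc, "results/cell_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (s in names(sets)) {
  cat("\n--", s, "score by cluster --\n")
  print(score_summaries(sc, s, by = "cluster"), row.names = FALSE)
}

# dysfunction genes among T cells (cytotoxic-score correlates that shift
# between normal lung and tumour)
tc <- subset_dataset(cohort$dataset,
                     cells = which(cohort$dataset$cell_meta$cluster %in%
                                     c("T_naive", "T_cytotoxic",
                                       "T_exhausted")))
cyt <- sc$cytotoxic[match(tc$cell_meta$barcode, sc$barcode)]
sel <- select_dysfunction_genes(tc, cyt)
cat("\nselected dysfunction genes:", sum(sel$selected), "\n")
write.table(sel, "results/dysfunction_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
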