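#!/usr/bin/env Rscript
# Build the synthetic GGN cohort used throughout the workflow: 12 samples
# (5 nLung, 3 AIS, 4 IAC), a malignant epithelial subpopulation carrying a
# +1 log2 chromosome-1 segment, five stage-trajectory co-expression
# modules, three T-cell functional programs, and clonally expanded TCR
# repertoires. Writes the dataset in exchange formats under
# results/cohort/ so later steps (and any external tool) can read it back.

suppressPackageStartupMessages(library(ggnsc))

cfg <- sim_config(n_cells_per_sample = 300, n_genes = 2000, seed = 2026,
                  cnv_segments = list(list(chrom = 1, start = 20,
                                           end = 169, shift = 1)))
sim <- simulate_dataset(cfg)

dir.create("results", showWarnings = FALSE)
paths <- write_dataset(sim, "results/cohort")
cat("cohort:", nrow(sim$dataset$counts), "genes x",
    ncol(sim$dataset$counts), "cells;",
    length(sim$truth$malignant), "planted malignant cells;",
    nrow(sim$contigs), "TCR contigs\n")
cat("files:\n"); print(unname(paths))
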