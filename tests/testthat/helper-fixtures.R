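# Small cohort configurations and hand-built fixtures shared across tests.

small_sim <- function(seed = 1, n_cells_per_sample = 60, n_genes = 600,
                      ...) {
  cfg <- sim_config(n_cells_per_sample = n_cells_per_sample,
                    n_genes = n_genes, seed = seed,
                    cnv_segments = list(list(chrom = 1, start = 1,
                                             end = 40, shift = 1)),
                    ...)
  simulate_dataset(cfg)
}

# cohort sized for module detection: ~100 metacells from epithelial cells
module_sim <- function(seed) {
  cfg <- sim_config(n_cells_per_sample = 300, n_genes = 1000, seed = seed,
                    cnv_segments = list(list(chrom = 1, start = 1,
                                             end = 80, shift = 1)))
  simulate_dataset(cfg)
}

# minimal dataset built by hand: counts matrix with labelled metadata
toy_dataset <- function(counts, groups = NULL, clusters = NULL,
                        samples = NULL, gene_pos = NULL) {
  n <- ncol(counts)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("c%03d", 1:n)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  meta <- data.frame(
    barcode = colnames(counts),
    sample = if (is.null(samples)) rep("s1", n) else samples,
    group = if (is.null(groups)) rep("nLung", n) else groups,
    cluster = if (is.null(clusters)) rep("A", n) else clusters,
    stringsAsFactors = FALSE)
  ggn_dataset(counts, meta, gene_pos)
}

# contig row helper for hand-enumerated TCR fixtures
contig_row <- function(barcode, chain, v = "V1", j = "J1", cdr3 = "CASS",
                       productive = "True", high_confidence = "True") {
  data.frame(barcode = barcode, chain = chain, v_gene = v, j_gene = j,
             cdr3 = cdr3, productive = productive,
             high_confidence = high_confidence, stringsAsFactors = FALSE)
}

# hand-built table: 4 valid cells (2 sharing both chains), 1 dual-TRB,
# 1 TRA-only
toy_contigs <- function() {
  rbind(
    contig_row("cell1", "TRA", cdr3 = "AAA"),
    contig_row("cell1", "TRB", cdr3 = "BBB"),
    contig_row("cell2", "TRA", cdr3 = "AAA"),
    contig_row("cell2", "TRB", cdr3 = "BBB"),
    contig_row("cell3", "TRA", cdr3 = "CCC"),
    contig_row("cell3", "TRB", cdr3 = "DDD"),
    contig_row("cell4", "TRA", cdr3 = "EEE"),
    contig_row("cell4", "TRB", cdr3 = "FFF"),
    contig_row("cell5", "TRA", cdr3 = "GGG"),
    contig_row("cell5", "TRB", cdr3 = "HHH"),
    contig_row("cell5", "TRB", cdr3 = "III"),
    contig_row("cell6", "TRA", cdr3 = "JJJ"))
}
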