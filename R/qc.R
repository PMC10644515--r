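#' Cell-level quality-control thresholds
#'
#' The exclusion rules applied to droplet scRNA-seq cells: a cell is
#' removed when any of (1) total UMI count > `max_counts`, (2) detected
#' genes > `max_genes`, (3) detected genes < `min_genes`, (4) mitochondrial
#' fraction > `max_mito_fraction` fires. All inequalities are strict, so a
#' cell at exactly a boundary (e.g. exactly 200 detected genes, or exactly
#' 50,000 counts) is kept.
#'
#' @param max_counts UMI ceiling (default 50000)
#' @param max_genes detected-gene ceiling (default 6000)
#' @param min_genes detected-gene floor (default 200)
#' @param max_mito_fraction mitochondrial-fraction ceiling (default 0.20)
#' @param mito_gene_prefix feature-name prefix identifying mitochondrial
#'   genes (default `"MT-"`)
#' @return a `qc_thresholds` list
#' @export
qc_thresholds <- function(max_counts = 50000, max_genes = 6000,
                          min_genes = 200, max_mito_fraction = 0.20,
                          mito_gene_prefix = "MT-") {
  stopifnot(min_genes < max_genes,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  structure(list(max_counts = max_counts, max_genes = max_genes,
                 min_genes = min_genes,
                 max_mito_fraction = max_mito_fraction,
                 mito_gene_prefix = mito_gene_prefix),
            class = "qc_thresholds")
}

#' Filter cells by QC thresholds
#'
#' @param dataset a [ggn_dataset()]
#' @param thresholds a [qc_thresholds()]
#' @return list with `dataset` (survivors only) and `report`, a per-cell
#'   data.frame recording each cell's QC metrics, which rule(s) fired, and
#'   whether it was kept
#' @export
filter_cells <- function(dataset, thresholds = qc_thresholds()) {
  stopifnot(inherits(dataset, "ggn_dataset"),
            inherits(thresholds, "qc_thresholds"))
  counts <- dataset$counts
  total <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  mito <- startsWith(rownames(counts), thresholds$mito_gene_prefix)
  mito_frac <- if (any(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1)
  else rep(0, ncol(counts))
  rule_counts <- total > thresholds$max_counts
  rule_maxg <- detected > thresholds$max_genes
  rule_ming <- detected < thresholds$min_genes
  rule_mito <- mito_frac > thresholds$max_mito_fraction
  keep <- !(rule_counts | rule_maxg | rule_ming | rule_mito)
  report <- data.frame(
    barcode = colnames(counts), total_counts = as.numeric(total),
    n_genes = as.numeric(detected), mito_fraction = as.numeric(mito_frac),
    fail_max_counts = rule_counts, fail_max_genes = rule_maxg,
    fail_min_genes = rule_ming, fail_mito = rule_mito,
    kept = keep, row.names = NULL)
  if (!any(keep)) stop("empty dataset: no cells survive QC filtering")
  list(dataset = subset_dataset(dataset, cells = which(keep)),
       report = report)
}

#' Per-sample cell-type composition
#'
#' For every sample, the fraction of its cells in each cluster (clusters
#' absent from a sample get fraction 0, so the table is a complete
#' sample x cluster grid and fractions sum to 1 within each sample).
#'
#' @param metadata data.frame with columns `sample`, `group`, `cluster`
#'   (e.g. `dataset$cell_meta`)
#' @return data.frame with columns `sample`, `group`, `cluster`,
#'   `n_cells`, `fraction`
#' @export
composition <- function(metadata) {
  need <- c("sample", "group", "cluster")
  if (!all(need %in% names(metadata)) || anyNA(metadata[need]))
    stop("metadata must have complete sample, group and cluster labels")
  tab <- as.data.frame(table(sample = metadata$sample,
                             cluster = metadata$cluster),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n_cells"
  grp <- unique(metadata[, c("sample", "group")])
  tab$group <- grp$group[match(tab$sample, grp$sample)]
  totals <- tapply(tab$n_cells, tab$sample, sum)
  tab$fraction <- tab$n_cells / as.numeric(totals[tab$sample])
  tab <- tab[order(tab$sample, tab$cluster),
             c("sample", "group", "cluster", "n_cells", "fraction")]
  rownames(tab) <- NULL
  tab
}

#' Per-group share of cells within each cluster
#'
#' Answers "what fraction of this cell type comes from each disease
#' group" — e.g. the share of epithelial cells originating from normal
#' lung. Percentages follow the shared [pct()] rounding rule.
#'
#' @param metadata data.frame with `group` and `cluster` columns
#' @return data.frame with `cluster`, `group`, `n_cells`, `percent`
#' @export
group_share <- function(metadata) {
  tab <- as.data.frame(table(cluster = metadata$cluster,
                             group = metadata$group),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n_cells"
  totals <- tapply(tab$n_cells, tab$cluster, sum)
  tab$percent <- pct(tab$n_cells, as.numeric(totals[tab$cluster]))
  tab[order(tab$cluster, tab$group), ]
}

#' Compare per-sample composition between two groups
#'
#' Per cluster, an exact two-sided Wilcoxon rank-sum test (see
#' [ranksum_test()]) on the per-sample fractions of the two groups. No
#' multiplicity correction is applied: each cluster is reported on its
#' own, matching per-cluster composition figures.
#'
#' @param table a [composition()] table
#' @param group_a,group_b group labels to compare
#' @return data.frame with `cluster`, `n_a`, `n_b`, `p_value`, `method`
#' @export
compare_composition <- function(table, group_a, group_b) {
  a <- table[table$group == group_a, , drop = FALSE]
  b <- table[table$group == group_b, , drop = FALSE]
  if (!nrow(a) || !nrow(b))
    stop("both groups must contain at least one sample")
  clusters <- sort(unique(table$cluster))
  out <- lapply(clusters, function(cl) {
    fa <- a$fraction[a$cluster == cl]
    fb <- b$fraction[b$cluster == cl]
    ts <- ranksum_test(fa, fb)
    data.frame(cluster = cl, n_a = length(fa), n_b = length(fb),
               p_value = ts$p_value, method = ts$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
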