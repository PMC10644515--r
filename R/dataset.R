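#' Expression dataset container
#'
#' Bundles a sparse gene-by-cell UMI count matrix with per-cell metadata
#' (sample, disease group, cluster) and per-gene genomic positions. This is
#' the substrate every pipeline stage operates on.
#'
#' @param counts gene x cell matrix of non-negative integer counts
#'   (coerced to [Matrix::dgCMatrix-class]); rownames are gene ids,
#'   colnames are cell barcodes.
#' @param cell_meta data.frame with columns `barcode`, `sample`, `group`
#'   and `cluster`; one row per cell, barcodes matching `colnames(counts)`.
#' @param gene_pos optional data.frame with columns `gene`, `chrom`,
#'   `start`, `end` (0-based half-open, BED convention). Genes missing a
#'   position are allowed; CNV inference drops them.
#' @return an object of class `ggn_dataset` (a list with elements
#'   `counts`, `cell_meta`, `gene_pos`).
#' @export
ggn_dataset <- function(counts, cell_meta, gene_pos = NULL) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and cell-barcode colnames")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  need <- c("barcode", "sample", "group", "cluster")
  miss <- setdiff(need, names(cell_meta))
  if (length(miss))
    stop("cell_meta missing column(s): ", paste(miss, collapse = ", "))
  cell_meta <- as.data.frame(cell_meta)
  if (!identical(as.character(cell_meta$barcode), colnames(counts)))
    stop("cell_meta$barcode must match colnames(counts) in order")
  if (anyNA(cell_meta[need])) stop("cell_meta labels must not be missing")
  if (!is.null(gene_pos)) {
    gene_pos <- as.data.frame(gene_pos)
    nead <- setdiff(c("gene", "chrom", "start", "end"), names(gene_pos))
    if (length(nead))
      stop("gene_pos missing column(s): ", paste(nead, collapse = ", "))
  }
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_pos = gene_pos),
            class = "ggn_dataset")
}

#' @export
print.ggn_dataset <- function(x, ...) {
  cat(sprintf("ggn_dataset: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  groups:  ", paste(names(table(x$cell_meta$group)), collapse = ", "),
      "\n")
  cat("  clusters:", length(unique(x$cell_meta$cluster)), "\n")
  cat("  gene positions:",
      if (is.null(x$gene_pos)) "none" else nrow(x$gene_pos), "\n")
  invisible(x)
}

#' @export
dim.ggn_dataset <- function(x) dim(x$counts)

#' Subset a dataset by cells and/or genes
#'
#' @param dataset a [ggn_dataset()]
#' @param cells character barcodes or logical/integer index over cells
#' @param genes character gene ids or logical/integer index over genes
#' @return a `ggn_dataset` restricted to the requested cells/genes
#' @export
subset_dataset <- function(dataset, cells = NULL, genes = NULL) {
  counts <- dataset$counts
  meta <- dataset$cell_meta
  if (!is.null(cells)) {
    if (is.character(cells)) cells <- match(cells, colnames(counts))
    counts <- counts[, cells, drop = FALSE]
    meta <- meta[cells, , drop = FALSE]
    rownames(meta) <- NULL
  }
  gp <- dataset$gene_pos
  if (!is.null(genes)) {
    if (is.character(genes)) genes <- match(genes, rownames(counts))
    counts <- counts[genes, , drop = FALSE]
    if (!is.null(gp)) gp <- gp[gp$gene %in% rownames(counts), , drop = FALSE]
  }
  ggn_dataset(counts, meta, gp)
}

#' Log-normalized expression
#'
#' Library-size normalization to counts per `scale_factor` followed by a
#' natural-log `log1p` transform, the conventional single-cell working
#' scale for correlations, scores and rank tests.
#'
#' @param x a `ggn_dataset` or a gene x cell count matrix
#' @param scale_factor target library size (default 1e4)
#' @return sparse gene x cell matrix of `ln(1 + cp10k)` values
#' @export
lognorm <- function(x, scale_factor = 1e4) {
  counts <- if (inherits(x, "ggn_dataset")) x$counts else
    methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
  libs <- Matrix::colSums(counts)
  libs[libs == 0] <- 1
  out <- counts %*% Matrix::Diagonal(x = scale_factor / libs)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  out
}

#' Natural chromosome order (1..22, X, Y)
#'
#' @param chrom character chromosome labels, with or without "chr" prefix
#' @return integer rank usable for sorting
#' @export
chrom_order <- function(chrom) {
  key <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.integer(key))
  rank <- ifelse(!is.na(num), num,
                 ifelse(key == "X", 23L, ifelse(key == "Y", 24L, 25L)))
  rank + match(key, sort(unique(key))) / (length(unique(key)) + 1) * 0
}

#' Percentage of a count over a total
#'
#' Shared formatting rule for every reported proportion: `100 * n / total`,
#' rounded to `digits` decimal places.
#'
#' @param n numerator count
#' @param total denominator count
#' @param digits decimal places (default 1)
#' @return numeric percentage
#' @export
pct <- function(n, total, digits = 1) {
  stopifnot(total > 0)
  round(100 * n / total, digits)
}
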