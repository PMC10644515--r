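#' Default functional gene-set library
#'
#' The three marker sets used to summarize T-cell state: exhaustion
#' (coinhibitory receptors), naive (lymph-node homing / stemness) and
#' cytotoxic (effector molecules).
#'
#' @return named list of character gene vectors
#' @export
default_gene_sets <- function() {
  list(
    exhaustion = c("LAG3", "TIGIT", "PDCD1", "CTLA4", "HAVCR2"),
    naive = c("CCR7", "TCF7", "LEF1", "SELL"),
    cytotoxic = c("PRF1", "IFNG", "GNLY", "NKG7", "GZMB", "GZMA", "GZMH",
                  "KLRK1", "KLRB1", "KLRD1", "CTSW", "CST7"))
}

#' Validate a gene-set library
#'
#' @param sets named list of character gene vectors (e.g. read from JSON)
#' @return the library, with duplicate genes within a set removed
#' @export
gene_set_library <- function(sets) {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("gene sets must be a non-empty named list")
  out <- lapply(sets, function(g) unique(as.character(g)))
  if (any(vapply(out, length, 1L) == 0)) stop("empty gene set")
  out
}

#' Binned-control gene-set score
#'
#' Per-cell score of a gene set against expression-matched controls: all
#' genes are binned into `n_bins` equal-frequency bins of average
#' log-normalized expression; for each set gene, `n_ctrl` control genes
#' are sampled from its bin (set genes excluded as controls; with
#' replacement only when the bin is smaller than `n_ctrl`); the score is
#' `mean(set-gene expression) - mean(control-gene expression)` per cell.
#' Deterministic under `seed`.
#'
#' @param dataset a [ggn_dataset()] or a gene x cell log-normalized
#'   matrix
#' @param gene_set character vector of gene ids; genes absent from the
#'   matrix are dropped with a warning, and an all-absent set is an error
#' @param n_bins expression bins (default 24)
#' @param n_ctrl controls per set gene (default 100; `Inf` = whole bin)
#' @param seed RNG seed for control sampling (default 0)
#' @param set_name label used in error messages
#' @return named numeric vector of per-cell scores
#' @export
module_score <- function(dataset, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 0, set_name = "gene set") {
  X <- if (inherits(dataset, "ggn_dataset")) lognorm(dataset) else dataset
  X <- as.matrix(X)
  present <- intersect(gene_set, rownames(X))
  if (!length(present))
    stop("all genes of ", set_name, " are absent from the matrix")
  if (length(present) < length(unique(gene_set)))
    warning(length(unique(gene_set)) - length(present), " gene(s) of ",
            set_name, " absent; dropped")
  avg <- rowMeans(X)
  n_bins <- min(n_bins, nrow(X))
  bin <- ceiling(rank(avg, ties.method = "first") / (nrow(X) / n_bins))
  bin_members <- split(rownames(X), bin)
  set.seed(seed)
  ctrl <- character(0)
  for (g in present) {
    cand <- setdiff(bin_members[[as.character(bin[g])]], present)
    if (!length(cand)) next
    take <- if (is.infinite(n_ctrl)) cand
    else if (length(cand) >= n_ctrl)
      cand[sample.int(length(cand), n_ctrl)]
    else cand[sample.int(length(cand), n_ctrl, replace = TRUE)]
    ctrl <- c(ctrl, take)
  }
  ctrl <- unique(ctrl)
  if (!length(ctrl))
    stop("no control genes available for ", set_name)
  set_mean <- colMeans(X[present, , drop = FALSE])
  ctrl_mean <- colMeans(X[ctrl, , drop = FALSE])
  set_mean - ctrl_mean
}

#' Score every set of a library
#'
#' @param dataset a [ggn_dataset()]
#' @param sets a [gene_set_library()] (default [default_gene_sets()])
#' @param ... passed to [module_score()]
#' @return data.frame (one row per cell) with `barcode`, `cluster`,
#'   `group`, and one score column per set
#' @export
score_cells <- function(dataset, sets = default_gene_sets(), ...) {
  stopifnot(inherits(dataset, "ggn_dataset"))
  X <- as.matrix(lognorm(dataset))
  out <- data.frame(barcode = dataset$cell_meta$barcode,
                    cluster = dataset$cell_meta$cluster,
                    group = dataset$cell_meta$group,
                    stringsAsFactors = FALSE)
  for (nm in names(sets))
    out[[nm]] <- as.numeric(module_score(X, sets[[nm]], set_name = nm,
                                         ...))
  out
}

#' Stratified score summaries
#'
#' Mean, median, sd and n of a score per stratum, ordered by descending
#' mean; ties keep stable label order.
#'
#' @param scores a [score_cells()] table (or any data.frame)
#' @param score_col name of the score column
#' @param by stratifying column(s), e.g. `"cluster"` or
#'   `c("cluster", "group")`
#' @return data.frame with the strata, `n`, `mean`, `median`, `sd`,
#'   `rank`
#' @export
score_summaries <- function(scores, score_col, by = "cluster") {
  stopifnot(score_col %in% names(scores), all(by %in% names(scores)))
  key <- interaction(scores[by], drop = TRUE, sep = "\r")
  agg <- lapply(split(seq_len(nrow(scores)), key), function(ix) {
    v <- scores[[score_col]][ix]
    cbind(scores[ix[1], by, drop = FALSE],
          data.frame(n = length(v), mean = mean(v), median = stats::median(v),
                     sd = stats::sd(v)))
  })
  out <- do.call(rbind, agg)
  lab <- do.call(paste, c(out[by], sep = " "))
  out <- out[order(-out$mean, lab), , drop = FALSE]
  out$rank <- rank(-out$mean, ties.method = "min")
  rownames(out) <- NULL
  out
}

#' Select dysfunction-associated genes
#'
#' Genes tracking the cytotoxic score that also differ between normal
#' lung and tumour (AIS/IAC) cells: selected iff `|r| >= r_min` (Pearson
#' correlation of log-normalized expression with the per-cell cytotoxic
#' score), `|logFC| >= logfc_min` (difference of group means,
#' natural-log scale: tumour minus normal), and BH-adjusted Wilcoxon
#' rank-sum p < `alpha`. Selected genes are classified into the two
#' dysfunction-relevant directions: `"pos_cor_down"` (positively
#' correlated with cytotoxicity, down in tumour) and `"neg_cor_up"`
#' (negatively correlated, up in tumour); other selected combinations
#' get `"other"`. Zero-variance genes get r = 0.
#'
#' @param dataset a [ggn_dataset()] restricted to the scored cells
#' @param cytotoxic_scores per-cell numeric score aligned with the cells
#' @param tumor_groups group labels counted as tumour
#'   (default `c("AIS", "IAC")`)
#' @param r_min correlation cutoff (default 0.3)
#' @param logfc_min log-fold-change cutoff (default 0.3)
#' @param alpha adjusted-p cutoff (default 0.05)
#' @return data.frame with `gene`, `r`, `logfc`, `p`, `adj_p`,
#'   `selected`, `class`
#' @export
select_dysfunction_genes <- function(dataset, cytotoxic_scores,
                                     tumor_groups = c("AIS", "IAC"),
                                     r_min = 0.3, logfc_min = 0.3,
                                     alpha = 0.05) {
  stopifnot(inherits(dataset, "ggn_dataset"),
            length(cytotoxic_scores) == ncol(dataset$counts))
  in_tumor <- dataset$cell_meta$group %in% tumor_groups
  if (!any(in_tumor) || all(in_tumor))
    stop("both tumour and normal cells required")
  X <- as.matrix(lognorm(dataset))
  sds <- apply(X, 1, stats::sd)
  r <- rep(0, nrow(X))
  ok <- sds > 0
  r[ok] <- as.numeric(stats::cor(t(X[ok, , drop = FALSE]),
                                 cytotoxic_scores))
  p <- ranksum_rows(X, in_tumor)
  adj <- stats::p.adjust(p, "BH")
  lfc <- rowMeans(X[, in_tumor, drop = FALSE]) -
    rowMeans(X[, !in_tumor, drop = FALSE])
  sel <- abs(r) >= r_min & abs(lfc) >= logfc_min & adj < alpha
  cls <- rep(NA_character_, nrow(X))
  cls[sel & r >= r_min & lfc <= -logfc_min] <- "pos_cor_down"
  cls[sel & r <= -r_min & lfc >= logfc_min] <- "neg_cor_up"
  cls[sel & is.na(cls)] <- "other"
  data.frame(gene = rownames(X), r = r, logfc = lfc, p = p, adj_p = adj,
             selected = sel, class = cls, row.names = NULL)
}
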