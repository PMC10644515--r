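#' Infer smoothed CNV profiles from expression along the genome
#'
#' Large-scale copy-number changes leave a footprint in expression: genes
#' inside an amplified or deleted segment shift coherently. The profile is
#' built as: library-size normalize; relative log2 expression against the
#' reference-cell mean, `log2(x + 1) - log2(mean_ref + 1)`; clip to
#' `+/- clip`; per-chromosome centered moving average over `window` genes
#' (truncated windows at chromosome edges); per-cell median centering
#' (whole-genome offsets reflect library composition, not copy number);
#' finally subtract the reference-cell per-gene mean so the reference
#' centers at exactly zero.
#' Immune and stromal cells, which carry no somatic CNVs, serve as the
#' reference.
#'
#' Genes without a genomic position are dropped (at most 10% may be
#' missing); genes are ordered by chromosome (natural order 1..22, X, Y)
#' and start coordinate. A chromosome with fewer than 3 positioned genes
#' is passed through unsmoothed with a warning.
#'
#' @param dataset a [ggn_dataset()] with `gene_pos`
#' @param query_cells barcodes of the cells to profile (e.g. AIS/IAC
#'   epithelial cells)
#' @param reference_cells barcodes of CNV-free reference cells; disjoint
#'   from the query
#' @param window odd moving-average width in genes (default 101)
#' @param clip symmetric clip bound on relative log2 expression
#'   (default 3)
#' @return object of class `cnv_profile`: list with `matrix` (cells x
#'   genes, query rows first), `query_cells`, `reference_cells`,
#'   `gene_order` (data.frame gene/chrom/start), `window`
#' @export
infer_cnv_profiles <- function(dataset, query_cells, reference_cells,
                               window = 101, clip = 3) {
  stopifnot(inherits(dataset, "ggn_dataset"), window >= 1,
            window %% 2 == 1, clip > 0)
  if (is.null(dataset$gene_pos)) stop("dataset has no gene positions")
  if (length(intersect(query_cells, reference_cells)))
    stop("query and reference cells must be disjoint")
  if (!length(reference_cells)) stop("no reference cells given")

  gp <- dataset$gene_pos
  gp <- gp[gp$gene %in% rownames(dataset$counts) & !is.na(gp$start), ]
  frac_pos <- nrow(gp) / nrow(dataset$counts)
  if (frac_pos < 0.9)
    stop(sprintf("only %.0f%% of genes have positions (need >= 90%%)",
                 100 * frac_pos))
  gp <- gp[order(chrom_order(gp$chrom), gp$start), ]

  cells <- c(query_cells, reference_cells)
  miss <- setdiff(cells, colnames(dataset$counts))
  if (length(miss)) stop("unknown cells: ", paste(utils::head(miss, 3),
                                                  collapse = ", "))
  ln <- lognorm(dataset$counts[gp$gene, cells, drop = FALSE])
  # relative log2 expression vs the reference mean, on the cp10k scale
  cp <- expm1(as.matrix(ln))
  ref_mean <- rowMeans(cp[, reference_cells, drop = FALSE])
  rel <- log2(cp + 1) - log2(ref_mean + 1)
  rel[rel > clip] <- clip
  rel[rel < -clip] <- -clip
  rel <- t(rel)                                    # cells x genes

  smoothed <- moving_average_by_chrom(rel, gp$chrom, window)
  # per-cell median centering removes cell-level offsets (library
  # composition differences between cell types masquerade as whole-genome
  # shifts); reference centering last, so reference means are exactly 0
  smoothed <- sweep(smoothed, 1, apply(smoothed, 1, stats::median))
  ref_center <- colMeans(smoothed[reference_cells, , drop = FALSE])
  smoothed <- sweep(smoothed, 2, ref_center)

  structure(list(matrix = smoothed, query_cells = query_cells,
                 reference_cells = reference_cells,
                 gene_order = gp[, c("gene", "chrom", "start")],
                 window = window),
            class = "cnv_profile")
}

# centered moving average along columns (genes), restarted per chromosome;
# truncated windows at the edges. Implemented as multiplication by a
# sparse column-stochastic smoother so the cells x genes matrix is
# smoothed in one pass.
moving_average_by_chrom <- function(mat, chrom, window) {
  n <- ncol(mat)
  half <- (window - 1) %/% 2
  ii <- vector("list", n); jj <- vector("list", n); xx <- vector("list", n)
  idx_by_chr <- split(seq_len(n), factor(chrom, levels = unique(chrom)))
  for (ix in idx_by_chr) {
    m <- length(ix)
    if (m < 3 && window > 1) {
      warning("chromosome with fewer than 3 genes passed through unsmoothed")
      for (j in seq_len(m)) {
        ii[[ix[j]]] <- ix[j]; jj[[ix[j]]] <- ix[j]; xx[[ix[j]]] <- 1
      }
      next
    }
    for (j in seq_len(m)) {
      win <- max(1, j - half):min(m, j + half)
      ii[[ix[j]]] <- ix[win]
      jj[[ix[j]]] <- rep(ix[j], length(win))
      xx[[ix[j]]] <- rep(1 / length(win), length(win))
    }
  }
  S <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                            x = unlist(xx), dims = c(n, n))
  out <- as.matrix(mat %*% S)
  dimnames(out) <- dimnames(mat)
  out
}

#' CNV score: correlation with the most aberrant cells
#'
#' Query cells are sorted by the mean square (MS) of their CNV profile
#' across the genome; the per-gene mean profile of the top
#' `ceil(top_fraction * n)` cells (largest MS, ties broken by cell order)
#' defines the aberrant reference `R`; each cell's CNV score is the
#' Pearson correlation of its profile with `R`. Cells in the top set are
#' scored like any other (self included in `R`). A zero-variance profile
#' cannot be correlated and is scored 0 with a warning.
#'
#' @param profile a `cnv_profile` from [infer_cnv_profiles()]
#' @param top_fraction fraction of cells defining the aberrant reference
#'   (default 0.05)
#' @return object of class `cnv_score_result`: data.frame `scores` with
#'   `barcode`, `ms`, `cnv_score` plus attributes `top_cells` and
#'   `top_fraction`
#' @export
cnv_score <- function(profile, top_fraction = 0.05) {
  stopifnot(inherits(profile, "cnv_profile"),
            top_fraction > 0, top_fraction <= 1)
  q <- profile$matrix[profile$query_cells, , drop = FALSE]
  n <- nrow(q)
  m <- ceiling(top_fraction * n)
  if (n < ceiling(1 / top_fraction))
    stop(sprintf("need at least %d query cells", ceiling(1 / top_fraction)))
  ms <- rowMeans(q^2)
  top <- order(-ms, seq_len(n))[seq_len(m)]
  R <- colMeans(q[top, , drop = FALSE])
  sds <- apply(q, 1, stats::sd)
  score <- rep(0, n)
  if (stats::sd(R) == 0) {
    warning("aberrant reference profile has zero variance; all scores 0")
  } else {
    ok <- sds > 0
    if (any(!ok))
      warning(sum(!ok), " zero-variance cell profile(s) scored 0")
    score[ok] <- as.numeric(stats::cor(t(q[ok, , drop = FALSE]), R))
  }
  res <- data.frame(barcode = profile$query_cells, ms = ms,
                    cnv_score = score, row.names = NULL)
  structure(list(scores = res,
                 top_cells = profile$query_cells[top],
                 top_fraction = top_fraction),
            class = "cnv_score_result")
}

#' Classify malignant cells by CNV score
#'
#' Strict threshold: a cell is malignant iff `cnv_score > threshold`.
#'
#' @param result a `cnv_score_result` (or its `scores` data.frame)
#' @param threshold score cutoff (default 0.3)
#' @return list with `labels` (data.frame `barcode`, `cnv_score`,
#'   `malignant`) and `summary` (`n_malignant`, `n_total`, `percent`,
#'   percent to 1 decimal place)
#' @export
classify_malignant <- function(result, threshold = 0.3) {
  scores <- if (inherits(result, "cnv_score_result")) result$scores
  else as.data.frame(result)
  stopifnot(all(c("barcode", "cnv_score") %in% names(scores)))
  malignant <- scores$cnv_score > threshold
  labels <- data.frame(barcode = scores$barcode,
                       cnv_score = scores$cnv_score,
                       malignant = malignant, row.names = NULL)
  list(labels = labels,
       summary = list(n_malignant = sum(malignant),
                      n_total = nrow(scores),
                      percent = pct(sum(malignant), nrow(scores)),
                      threshold = threshold))
}

#' Random-split DEG sanity check for malignant calls
#'
#' A real malignant/normal partition should show many differentially
#' expressed genes, while random partitions of the same cells (preserving
#' class sizes) should show none. Per gene: Wilcoxon rank-sum on
#' log-normalized expression, BH correction; a DEG requires
#' `|logFC| >= logfc_min` (natural-log difference of group means) and
#' adjusted p < `alpha`.
#'
#' @param dataset a [ggn_dataset()] restricted to the cells of interest
#' @param labels logical vector (or barcode subset) marking the malignant
#'   class, aligned with the dataset's cells
#' @param n_random_splits number of random label permutations (default 3)
#' @param logfc_min minimum absolute log fold change (default 0.25)
#' @param alpha BH-adjusted p-value cutoff (default 0.05)
#' @param seed RNG seed for the permutations
#' @return list with `observed` (per-gene table: `gene`, `logfc`, `p`,
#'   `adj_p`, `deg`) and `splits` (data.frame `split`, `n_deg`; split 0
#'   is the observed labelling)
#' @export
validate_split_deg <- function(dataset, labels, n_random_splits = 3,
                               logfc_min = 0.25, alpha = 0.05, seed = 1) {
  stopifnot(inherits(dataset, "ggn_dataset"))
  if (is.character(labels))
    labels <- dataset$cell_meta$barcode %in% labels
  labels <- as.logical(labels)
  stopifnot(length(labels) == ncol(dataset$counts))
  if (sum(labels) < 3 || sum(!labels) < 3)
    stop("both classes need at least 3 cells")
  X <- as.matrix(lognorm(dataset))
  deg_count <- function(lab) {
    p <- ranksum_rows(X, lab)
    lfc <- rowMeans(X[, lab, drop = FALSE]) -
      rowMeans(X[, !lab, drop = FALSE])
    adj <- stats::p.adjust(p, "BH")
    list(p = p, lfc = lfc, adj = adj,
         deg = abs(lfc) >= logfc_min & adj < alpha)
  }
  obs <- deg_count(labels)
  observed <- data.frame(gene = rownames(X), logfc = obs$lfc, p = obs$p,
                         adj_p = obs$adj, deg = obs$deg, row.names = NULL)
  set.seed(seed)
  n_deg <- vapply(seq_len(n_random_splits), function(i) {
    perm <- sample(labels)
    sum(deg_count(perm)$deg)
  }, 1L)
  splits <- data.frame(split = 0:n_random_splits,
                       n_deg = c(sum(obs$deg), n_deg),
                       type = c("observed",
                                rep("random", n_random_splits)))
  list(observed = observed, splits = splits)
}
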