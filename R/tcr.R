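#' Assemble paired-chain clonotypes from a contig table
#'
#' Accepts the 10x `filtered_contig_annotations.csv` dialect (columns
#' `barcode`, `chain`, `v_gene`, `j_gene`, `cdr3` and/or `cdr3_nt`,
#' `productive`, `high_confidence`) or an AIRR rearrangement table
#' (`cell_id`, `locus`, `v_call`, `j_call`, `junction_aa`/`junction`,
#' `productive`). Contigs failing the productive / high-confidence flags
#' are removed, rows with a chain label other than TRA/TRB are rejected
#' (counted in the report), and a cell is retained iff exactly one TRA
#' and exactly one TRB contig remain. The clonotype key concatenates
#' CDR3 + V + J of both chains (nucleotide CDR3 when available,
#' amino-acid otherwise). Clone sizes are counted within `scope`
#' (per-sample by default — expansion within a repertoire — or
#' globally).
#'
#' @param contigs contig data.frame in either dialect
#' @param meta optional per-cell metadata (`barcode`, `sample`, `group`,
#'   `cluster`) joined onto retained cells; barcodes absent from `meta`
#'   keep NA labels
#' @param require_productive,require_high_confidence filter flags
#'   (high-confidence is skipped when the column is absent)
#' @param scope `"sample"` (default) or `"global"` clone-size scope;
#'   falls back to global when no sample labels are available
#' @return object of class `clonotype_table`: list with `cells`
#'   (data.frame: `barcode`, TRA/TRB v/j/cdr3, `clonotype`,
#'   `clone_size`, `clonal`, plus metadata columns) and `report`
#'   (`n_cells_input`, `n_retained`, `retention_percent` to 2 d.p.,
#'   `n_rejected_rows`, `n_multi_chain`, `n_missing_chain`)
#' @export
assign_clonotypes <- function(contigs, meta = NULL,
                              require_productive = TRUE,
                              require_high_confidence = TRUE,
                              scope = c("sample", "global")) {
  scope <- match.arg(scope)
  x <- normalize_contigs(contigs)
  n_input <- length(unique(x$barcode))

  bad_chain <- !x$chain %in% c("TRA", "TRB")
  n_rejected <- sum(bad_chain)
  x <- x[!bad_chain, , drop = FALSE]
  if (require_productive) x <- x[x$productive, , drop = FALSE]
  if (require_high_confidence && !all(is.na(x$high_confidence)))
    x <- x[x$high_confidence %in% TRUE, , drop = FALSE]

  ntra <- table(factor(x$barcode)[x$chain == "TRA"])
  ntrb <- table(factor(x$barcode)[x$chain == "TRB"])
  bcs <- unique(x$barcode)
  a <- as.integer(ntra[bcs]); a[is.na(a)] <- 0L
  b <- as.integer(ntrb[bcs]); b[is.na(b)] <- 0L
  keep <- bcs[a == 1 & b == 1]
  n_multi <- sum(a > 1 | b > 1)
  n_missing <- sum((a == 0 | b == 0) & !(a > 1 | b > 1))

  tra <- x[x$chain == "TRA" & x$barcode %in% keep, , drop = FALSE]
  trb <- x[x$chain == "TRB" & x$barcode %in% keep, , drop = FALSE]
  tra <- tra[match(keep, tra$barcode), ]
  trb <- trb[match(keep, trb$barcode), ]
  cells <- data.frame(
    barcode = keep,
    tra_v = tra$v_gene, tra_j = tra$j_gene, tra_cdr3 = tra$cdr3,
    trb_v = trb$v_gene, trb_j = trb$j_gene, trb_cdr3 = trb$cdr3,
    stringsAsFactors = FALSE)
  cells$clonotype <- paste(cells$tra_cdr3, cells$tra_v, cells$tra_j,
                           cells$trb_cdr3, cells$trb_v, cells$trb_j,
                           sep = "|")
  if (!is.null(meta)) {
    mcols <- intersect(c("sample", "group", "cluster"), names(meta))
    cells[mcols] <- meta[match(cells$barcode, meta$barcode), mcols]
  } else {
    # no metadata: a single repertoire
    cells$sample <- "all"
    cells$group <- "all"
    cells$cluster <- "all"
  }
  if (scope == "sample" && !all(is.na(cells$sample))) {
    key <- paste(cells$sample, cells$clonotype, sep = "\r")
  } else key <- cells$clonotype
  sz <- table(key)
  cells$clone_size <- as.integer(sz[key])
  cells$clonal <- cells$clone_size >= 2
  report <- list(n_cells_input = n_input, n_retained = nrow(cells),
                 retention_percent = pct(nrow(cells), max(n_input, 1),
                                         digits = 2),
                 n_rejected_rows = n_rejected,
                 n_multi_chain = n_multi, n_missing_chain = n_missing,
                 scope = scope)
  structure(list(cells = cells, report = report),
            class = "clonotype_table")
}

# harmonize 10x and AIRR column conventions
normalize_contigs <- function(contigs) {
  x <- as.data.frame(contigs, stringsAsFactors = FALSE)
  if ("cell_id" %in% names(x)) {        # AIRR rearrangement dialect
    out <- data.frame(
      barcode = x$cell_id, chain = x$locus,
      v_gene = x$v_call, j_gene = x$j_call,
      cdr3 = if ("junction" %in% names(x) && any(nzchar(x$junction)))
        x$junction else x$junction_aa,
      productive = parse_flag(x$productive),
      high_confidence = NA, stringsAsFactors = FALSE)
    return(out)
  }
  need <- c("barcode", "chain", "v_gene", "j_gene", "productive")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("contig table missing column(s): ", paste(miss, collapse = ", "))
  cdr3 <- if ("cdr3_nt" %in% names(x) && any(nzchar(x$cdr3_nt)))
    x$cdr3_nt else x$cdr3
  data.frame(barcode = x$barcode, chain = x$chain, v_gene = x$v_gene,
             j_gene = x$j_gene, cdr3 = cdr3,
             productive = parse_flag(x$productive),
             high_confidence = if ("high_confidence" %in% names(x))
               parse_flag(x$high_confidence) else NA,
             stringsAsFactors = FALSE)
}

parse_flag <- function(v) {
  if (is.logical(v)) return(v)
  tolower(as.character(v)) %in% c("true", "t", "1", "yes")
}

#' Clonal fraction per stratum
#'
#' Fraction of a stratum's cells belonging to clonotypes of clone size
#' >= 2. Empty strata are reported as NA. When `compare_groups` names two
#' groups and sample labels are present, each cluster additionally gets
#' an exact rank-sum p-value comparing the per-sample clonal fractions
#' of the two groups (see [ranksum_test()]).
#'
#' @param x a `clonotype_table`
#' @param by stratifying columns (default `c("cluster", "group")`)
#' @param compare_groups optional character pair of group labels
#' @return data.frame of strata with `n_cells`, `n_clonal`,
#'   `clonal_fraction`; with `compare_groups`, an attribute
#'   `"comparison"` holds the per-cluster p-values
#' @export
clonal_fraction <- function(x, by = c("cluster", "group"),
                            compare_groups = NULL) {
  stopifnot(inherits(x, "clonotype_table"))
  cells <- x$cells
  stopifnot(all(by %in% names(cells)))
  for (col in by) cells[[col]][is.na(cells[[col]])] <- "NA"
  key <- interaction(cells[by], drop = FALSE, sep = "\r")
  n <- tapply(rep(1, nrow(cells)), key, sum)
  ncl <- tapply(cells$clonal, key, sum)
  labs <- do.call(rbind, strsplit(names(n), "\r", fixed = TRUE))
  out <- data.frame(labs, stringsAsFactors = FALSE)
  names(out) <- by
  out$n_cells <- ifelse(is.na(n), 0L, as.integer(n))
  out$n_clonal <- as.integer(ncl)
  out$clonal_fraction <- ifelse(out$n_cells > 0,
                                out$n_clonal / out$n_cells, NA_real_)
  rownames(out) <- NULL
  if (!is.null(compare_groups)) {
    stopifnot(length(compare_groups) == 2, "sample" %in% names(cells))
    per <- stats::aggregate(clonal ~ cluster + group + sample,
                            data = cells, FUN = mean)
    cmp <- lapply(sort(unique(per$cluster)), function(cl) {
      fa <- per$clonal[per$cluster == cl & per$group == compare_groups[1]]
      fb <- per$clonal[per$cluster == cl & per$group == compare_groups[2]]
      if (!length(fa) || !length(fb))
        return(data.frame(cluster = cl, p_value = NA_real_))
      data.frame(cluster = cl, p_value = ranksum_test(fa, fb)$p_value)
    })
    attr(out, "comparison") <- do.call(rbind, cmp)
  }
  out
}

#' Clone-space occupancy by clonotype rank bins
#'
#' Within each group, clonotypes are ranked by descending clone size
#' (ties by clonotype id); the repertoire is split at clonotype ranks
#' 10, 100, 1,000 and 10,000, and each bin's value is the fraction of
#' the group's cells held by clonotypes in that rank interval. Bin
#' fractions sum to 1 within each group.
#'
#' @param x a `clonotype_table`
#' @param cutoffs rank cutoffs (default `c(10, 100, 1000, 10000)`)
#' @param by grouping column (default `"group"`)
#' @return data.frame with `group`, `bin`, `n_clonotypes`, `n_cells`,
#'   `fraction`
#' @export
clone_space_occupancy <- function(x, cutoffs = c(10, 100, 1000, 10000),
                                  by = "group") {
  stopifnot(inherits(x, "clonotype_table"))
  cells <- x$cells
  stopifnot(by %in% names(cells))
  cutoffs <- sort(cutoffs)
  lower <- c(1, cutoffs + 1)
  upper <- c(cutoffs, Inf)
  bin_lab <- paste0("[", format(lower, trim = TRUE, big.mark = ""), ",",
                    ifelse(is.finite(upper),
                           format(upper, trim = TRUE, big.mark = ""),
                           "Inf"), "]")
  out <- lapply(sort(unique(cells[[by]])), function(g) {
    sub <- cells[cells[[by]] == g, , drop = FALSE]
    if (!nrow(sub)) stop("group ", g, " has no retained cells")
    sz <- table(sub$clonotype)
    ord <- order(-as.integer(sz), names(sz))
    sizes <- as.integer(sz)[ord]
    rank <- seq_along(sizes)
    bin <- findInterval(rank, lower)
    n_cells_bin <- tapply(sizes, factor(bin, levels = seq_along(lower)),
                          sum)
    n_cl_bin <- tapply(rank, factor(bin, levels = seq_along(lower)),
                       length)
    data.frame(group = g, bin = bin_lab,
               n_clonotypes = ifelse(is.na(n_cl_bin), 0L,
                                     as.integer(n_cl_bin)),
               n_cells = ifelse(is.na(n_cells_bin), 0L,
                                as.integer(n_cells_bin)),
               fraction = ifelse(is.na(n_cells_bin), 0,
                                 n_cells_bin / sum(sizes)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Clonotype overlap between clusters
#'
#' Overlap of the clonotype sets of every cluster pair, as a percentage.
#' Default convention is the overlap coefficient,
#' `100 * |A intersect B| / min(|A|, |B|)`; `mode = "jaccard"` uses the
#' Jaccard index `100 * |A intersect B| / |A union B|`. The diagonal is
#' 100 and a cluster with zero clonotypes gets overlap 0 with a warning.
#'
#' @param x a `clonotype_table`
#' @param by cluster column (default `"cluster"`)
#' @param mode `"min"` (overlap coefficient, default) or `"jaccard"`
#' @return list with `percent` (symmetric matrix) and `shared`
#'   (matrix of shared-clonotype counts)
#' @export
clonotype_overlap <- function(x, by = "cluster",
                              mode = c("min", "jaccard")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "clonotype_table"))
  cells <- x$cells
  cl <- sort(unique(cells[[by]]))
  if (length(cl) < 2) stop("need at least 2 clusters with retained cells")
  sets <- lapply(cl, function(g)
    unique(cells$clonotype[cells[[by]] == g]))
  names(sets) <- cl
  if (any(vapply(sets, length, 1L) == 0))
    warning("cluster(s) with zero clonotypes: overlap defined as 0")
  n <- length(cl)
  shared <- matrix(0L, n, n, dimnames = list(cl, cl))
  perc <- matrix(0, n, n, dimnames = list(cl, cl))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    shared[i, j] <- inter
    den <- if (mode == "min") min(length(sets[[i]]), length(sets[[j]]))
    else length(union(sets[[i]], sets[[j]]))
    perc[i, j] <- if (den > 0) 100 * inter / den else 0
  }
  diag(perc) <- 100
  list(percent = perc, shared = shared, mode = mode)
}

#' V-J gene-pair usage
#'
#' Cell-weighted frequency of every (V, J) gene pair of one chain,
#' normalized to sum to 1 within each group.
#'
#' @param x a `clonotype_table`
#' @param chain `"TRA"` or `"TRB"`
#' @param by grouping column (default `"group"`)
#' @return data.frame with `group`, `v_gene`, `j_gene`, `n_cells`,
#'   `frequency`
#' @export
vj_usage <- function(x, chain = c("TRB", "TRA"), by = "group") {
  chain <- match.arg(chain)
  stopifnot(inherits(x, "clonotype_table"))
  cells <- x$cells
  v <- if (chain == "TRA") cells$tra_v else cells$trb_v
  j <- if (chain == "TRA") cells$tra_j else cells$trb_j
  out <- lapply(sort(unique(cells[[by]])), function(g) {
    ix <- cells[[by]] == g
    tab <- table(v_gene = v[ix], j_gene = j[ix])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, , drop = FALSE]
    data.frame(group = g, v_gene = df$v_gene, j_gene = df$j_gene,
               n_cells = df$Freq, frequency = df$Freq / sum(df$Freq),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Clone-size distribution
#'
#' For each observed clone size `s`, the number of clonotypes of that
#' size, per group — the raw material of clones-vs-cells-per-clonotype
#' plots. Conservation holds: `sum(s * count)` equals the retained cells
#' of the group.
#'
#' @param x a `clonotype_table`
#' @param by grouping column (default `"group"`)
#' @return data.frame with `group`, `clone_size`, `n_clonotypes`
#' @export
clone_size_distribution <- function(x, by = "group") {
  stopifnot(inherits(x, "clonotype_table"))
  cells <- x$cells
  out <- lapply(sort(unique(cells[[by]])), function(g) {
    sub <- cells[cells[[by]] == g, , drop = FALSE]
    sz <- table(sub$clonotype)
    dist <- table(as.integer(sz))
    data.frame(group = g, clone_size = as.integer(names(dist)),
               n_clonotypes = as.integer(dist), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
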