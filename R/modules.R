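#' Stage-associated gene selection with a per-gene mixed model
#'
#' Cells from the same sample are not independent, so the stage effect is
#' tested with a linear mixed model per gene: log-normalized expression ~
#' ordinal stage (fixed effect, nLung/AIS/IAC coded 0/1/2) with a random
#' intercept per sample, fitted by maximum likelihood. The p-value is a
#' likelihood-ratio test against the stage-free null (same random
#' structure), followed by Benjamini-Hochberg correction across genes.
#' A gene passes when FDR < `fdr_max`. Zero-variance genes and singular
#' fits get p = 1 with a flag rather than an error.
#'
#' @param dataset a [ggn_dataset()] (typically the epithelial subset)
#' @param fdr_max FDR cutoff (default 0.001)
#' @param stage_map named map from group label to ordinal stage
#' @param categorical treat stage as an unordered factor (2-df test)
#'   instead of ordinal
#' @return data.frame with `gene`, `coef` (stage slope), `p`, `fdr`,
#'   `pass`, `flagged`
#' @export
stage_association_filter <- function(dataset, fdr_max = 0.001,
                                     stage_map = c(nLung = 0, AIS = 1,
                                                   IAC = 2),
                                     categorical = FALSE) {
  stopifnot(inherits(dataset, "ggn_dataset"))
  meta <- dataset$cell_meta
  stage <- stage_map[meta$group]
  if (anyNA(stage)) stop("group labels missing from stage_map")
  if (length(unique(stage)) < 2) stop("need at least 2 stages")
  if (length(unique(meta$sample)) < 2) stop("need at least 2 samples")
  X <- as.matrix(lognorm(dataset))
  df <- data.frame(stage = if (categorical) factor(stage)
                   else as.numeric(stage),
                   sample = factor(meta$sample))
  ndf <- if (categorical) length(unique(stage)) - 1 else 1

  # fit the model structure once, then refit per gene (same design)
  df$y <- X[1, ]
  if (stats::var(df$y) == 0) df$y <- df$y + stats::rnorm(nrow(df), 0, 1e-6)
  alt0 <- lme4::lmer(y ~ stage + (1 | sample), data = df, REML = FALSE,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular =
                                                   "ignore"))
  null0 <- lme4::lmer(y ~ 1 + (1 | sample), data = df, REML = FALSE,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular =
                                                    "ignore"))
  fit_one <- function(y) {
    if (stats::var(y) == 0)
      return(c(coef = 0, p = 1, flagged = 1))
    out <- tryCatch({
      alt <- lme4::refit(alt0, newresp = y)
      null <- lme4::refit(null0, newresp = y)
      lrt <- max(0, 2 * (as.numeric(stats::logLik(alt)) -
                           as.numeric(stats::logLik(null))))
      slope <- if (categorical) NA_real_ else
        lme4::fixef(alt)[["stage"]]
      c(coef = if (is.na(slope)) 0 else slope,
        p = stats::pchisq(lrt, df = ndf, lower.tail = FALSE),
        flagged = 0)
    }, error = function(e) c(coef = 0, p = 1, flagged = 1))
    out
  }
  res <- t(apply(X, 1, fit_one))
  fdr <- stats::p.adjust(res[, "p"], "BH")
  data.frame(gene = rownames(X), coef = res[, "coef"], p = res[, "p"],
             fdr = fdr, pass = fdr < fdr_max,
             flagged = res[, "flagged"] == 1, row.names = NULL)
}

#' Aggregate cells into stage-pure metacells
#'
#' Within each stage independently: cells are embedded in top-PC space of
#' their log-normalized expression, then greedily grouped — each unused
#' cell in turn absorbs its `k - 1` nearest unused neighbours. Metacell
#' expression is the mean log-normalized expression of its members. A
#' final remainder group smaller than `k_min` is discarded, and a stage
#' with fewer than `k` cells yields zero metacells with a warning.
#'
#' @param dataset a [ggn_dataset()]
#' @param k target cells per metacell (default 10)
#' @param k_min minimum members to keep a metacell (default 5)
#' @param n_pcs PCs for the neighbour space (default 20)
#' @param stage_map named map group -> ordinal stage
#' @return object of class `metacell_matrix`: list with `expr`
#'   (metacell x gene matrix), `stage` (per metacell), `n_members`,
#'   `members` (list of barcode vectors)
#' @export
build_metacells <- function(dataset, k = 10, k_min = 5, n_pcs = 20,
                            stage_map = c(nLung = 0, AIS = 1, IAC = 2)) {
  stopifnot(inherits(dataset, "ggn_dataset"), k >= 1, k_min >= 1)
  meta <- dataset$cell_meta
  stage <- stage_map[meta$group]
  if (anyNA(stage)) stop("group labels missing from stage_map")
  X <- as.matrix(lognorm(dataset))       # genes x cells
  rows <- list(); stages <- integer(0); sizes <- integer(0)
  members <- list()
  for (s in sort(unique(stage))) {
    ix <- which(stage == s)
    if (length(ix) < k) {
      warning("stage ", s, " has fewer than k cells; no metacells")
      next
    }
    Y <- t(X[, ix, drop = FALSE])         # cells x genes
    keep_g <- apply(Y, 2, stats::var) > 0
    pc <- if (sum(keep_g) >= 2)
      stats::prcomp(Y[, keep_g, drop = FALSE],
                    rank. = min(n_pcs, sum(keep_g), nrow(Y) - 1),
                    center = TRUE, scale. = FALSE)$x
    else matrix(0, nrow(Y), 1)            # identical cells
    D <- as.matrix(stats::dist(pc))
    used <- rep(FALSE, length(ix))
    for (seed_i in seq_along(ix)) {
      if (used[seed_i]) next
      free <- which(!used)
      if (length(free) < k_min) break
      take <- min(k, length(free))
      nb <- free[order(D[seed_i, free])][seq_len(take)]
      nb <- union(seed_i, nb)[seq_len(take)]
      used[nb] <- TRUE
      rows[[length(rows) + 1]] <- colMeans(Y[nb, , drop = FALSE])
      stages <- c(stages, s)
      sizes <- c(sizes, length(nb))
      members[[length(stages)]] <- meta$barcode[ix[nb]]
    }
  }
  if (!length(rows)) stop("no metacells could be built")
  expr <- do.call(rbind, rows)
  rownames(expr) <- sprintf("mc_%04d", seq_len(nrow(expr)))
  colnames(expr) <- rownames(X)
  structure(list(expr = expr, stage = stages, n_members = sizes,
                 members = members, k = k, k_min = k_min),
            class = "metacell_matrix")
}

#' Pick the soft-threshold power for scale-free topology
#'
#' For each candidate power `beta`, the adjacency is
#' `|cor(g_i, g_j)|^beta` (or, in signed-hybrid mode, `cor^beta` for
#' positive correlations and 0 otherwise) and gene connectivity
#' `k_i = sum_j a_ij` (self excluded). Scale-free fit is the r-squared of
#' `log10 p(k)` against `log10 k` over `n_bins` connectivity bins,
#' counted only when the slope is negative. The chosen power is the
#' smallest candidate reaching `r2_min`, otherwise the argmax.
#'
#' @param metacells a `metacell_matrix` (or metacell x gene matrix)
#' @param candidate_powers powers to scan (default 1:20)
#' @param r2_min target scale-free fit (default 0.8)
#' @param n_bins connectivity bins for the fit (default 10)
#' @param signed_hybrid drop negative correlations instead of taking
#'   absolute values
#' @return list with `power`, and `fit_table` (`power`, `r_squared`,
#'   `slope`, `mean_k`)
#' @export
pick_soft_threshold <- function(metacells, candidate_powers = 1:20,
                                r2_min = 0.8, n_bins = 10,
                                signed_hybrid = FALSE) {
  E <- if (inherits(metacells, "metacell_matrix")) metacells$expr
  else as.matrix(metacells)
  if (nrow(E) < 30) stop("need at least 30 metacells")
  E <- E[, apply(E, 2, stats::var) > 0, drop = FALSE]
  C <- stats::cor(E)
  base <- if (signed_hybrid) pmax(C, 0) else abs(C)
  diag(base) <- 0
  rows <- lapply(candidate_powers, function(b) {
    a <- base^b
    k <- colSums(a)
    data.frame(power = b, r_squared = scale_free_r2(k, n_bins)["r2"],
               slope = scale_free_r2(k, n_bins)["slope"],
               mean_k = mean(k))
  })
  fit <- do.call(rbind, rows)
  rownames(fit) <- NULL
  ok <- which(fit$r_squared >= r2_min)
  power <- if (length(ok)) fit$power[ok[1]]
  else fit$power[which.max(fit$r_squared)]
  list(power = power, fit_table = fit)
}

# scale-free topology fit index: r2 of log10 p(k) vs log10 k over binned
# connectivities; reported as 0 when the slope is non-negative
scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(c(r2 = 0, slope = 0))
  bins <- cut(k, breaks = n_bins)
  pk <- tapply(k, bins, length) / length(k)
  mk <- tapply(k, bins, mean)
  keep <- !is.na(pk) & pk > 0
  if (sum(keep) < 3) return(c(r2 = 0, slope = 0))
  fit <- stats::lm(log10(pk[keep]) ~ log10(mk[keep]))
  slope <- stats::coef(fit)[2]
  r2 <- summary(fit)$r.squared
  c(r2 = if (slope < 0) r2 else 0, slope = unname(slope))
}

# standard module color palette, assigned to modules by decreasing size
wgcna_colors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                  "black", "pink", "magenta", "purple", "greenyellow",
                  "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                  "grey60", "lightgreen", "lightyellow", "royalblue")

#' Detect co-expression modules from a metacell matrix
#'
#' The WGCNA core: soft-thresholded adjacency, topological overlap matrix
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' (diagonal 1), average-linkage hierarchical clustering of `1 - TOM`, a
#' static tree cut at `cut_height`, small clusters relabelled `"grey"`,
#' module eigengenes (first principal component of the standardized
#' module submatrix, unit norm, sign fixed so mean own-module kME is
#' positive), merging of modules whose eigengenes correlate above
#' `1 - merge_height`, and kME (gene-eigengene correlation) for every
#' gene against every module.
#'
#' @param metacells a `metacell_matrix` (or metacell x gene matrix)
#' @param beta soft-threshold power (>= 1), e.g. from
#'   [pick_soft_threshold()]
#' @param min_module_size smallest retained module (default 30)
#' @param merge_height eigengene-dissimilarity threshold for merging
#'   (default 0.15: merge when cor > 0.85)
#' @param cut_height tree-cut height on the 1 - TOM dendrogram; the
#'   default `"auto"` scans the dendrogram's merge heights and cuts at
#'   the height yielding the most clusters of at least
#'   `min_module_size` genes (ties resolved toward the coarser cut),
#'   which adapts the static cut to the soft-threshold power in use
#' @param kme_min minimum own-module kME to stay in a module (default
#'   0.3): after clustering, genes whose correlation with their module's
#'   eigengene falls below this are reassigned to grey, which keeps
#'   chance-correlated background genes out of module cores
#' @param signed_hybrid see [pick_soft_threshold()]
#' @return object of class `module_assignment`: list with `genes`,
#'   `module` (color labels, `"grey"` = unassigned), `power`,
#'   `eigengenes` (metacell x module, unit columns), `kme` (gene x
#'   module), `stage` (per metacell), `tom` (gene x gene)
#' @export
detect_modules <- function(metacells, beta, min_module_size = 30,
                           merge_height = 0.15, cut_height = "auto",
                           kme_min = 0.3, signed_hybrid = FALSE) {
  stopifnot(beta >= 1)
  E <- if (inherits(metacells, "metacell_matrix")) metacells$expr
  else as.matrix(metacells)
  stage <- if (inherits(metacells, "metacell_matrix")) metacells$stage
  else NULL
  keep <- apply(E, 2, stats::var) > 0
  E <- E[, keep, drop = FALSE]
  genes <- colnames(E)
  ng <- length(genes)
  if (ng < min_module_size) {
    module <- stats::setNames(rep("grey", ng), genes)
    return(structure(list(genes = genes, module = module, power = beta,
                          eigengenes = NULL, kme = NULL, stage = stage,
                          tom = NULL),
                     class = "module_assignment"))
  }
  A <- tom_adjacency(E, beta, signed_hybrid)
  TOM <- tom_similarity(A)
  d <- stats::as.dist(1 - TOM)
  hc <- stats::hclust(d, method = "average")
  if (identical(cut_height, "auto"))
    cut_height <- auto_cut_height(hc, min_module_size)
  cl <- stats::cutree(hc, h = cut_height)

  sizes <- sort(table(cl), decreasing = TRUE)
  big <- names(sizes)[sizes >= min_module_size]
  module <- rep("grey", ng)
  for (i in seq_along(big))
    module[cl == as.integer(big[i])] <-
      wgcna_colors[min(i, length(wgcna_colors))]
  names(module) <- genes

  res <- eigengenes_kme(E, module)
  module <- kme_filter(res, module, kme_min)
  res <- eigengenes_kme(E, module)

  # merge modules with near-identical eigengenes
  repeat {
    mods <- setdiff(colnames(res$eigengenes), "grey")
    if (length(mods) < 2) break
    ec <- stats::cor(res$eigengenes[, mods, drop = FALSE])
    diag(ec) <- 0
    top <- which(ec == max(ec), arr.ind = TRUE)[1, ]
    if (max(ec) <= 1 - merge_height) break
    from <- mods[top[2]]; into <- mods[top[1]]
    if (sum(module == from) > sum(module == into)) {
      tmp <- from; from <- into; into <- tmp
    }
    module[module == from] <- into
    res <- eigengenes_kme(E, module)
    module <- kme_filter(res, module, kme_min)
    res <- eigengenes_kme(E, module)
  }

  structure(list(genes = genes, module = module, power = beta,
                 eigengenes = res$eigengenes, kme = res$kme,
                 stage = stage, tom = TOM),
            class = "module_assignment")
}

# choose the cut height that maximizes the number of clusters of at
# least min_module_size genes; ties go to the coarsest such cut
auto_cut_height <- function(hc, min_module_size) {
  hts <- sort(unique(hc$height))
  cand <- unique(c(hts[-length(hts)] + diff(hts) / 2, max(hts) * 0.999))
  best_h <- cand[1]; best_n <- -1L
  for (h in cand) {
    cl <- stats::cutree(hc, h = h)
    n_big <- sum(table(cl) >= min_module_size)
    if (n_big > best_n || (n_big == best_n && h > best_h)) {
      best_n <- n_big; best_h <- h
    }
  }
  best_h
}

# soft-thresholded adjacency with zero diagonal
tom_adjacency <- function(E, beta, signed_hybrid = FALSE) {
  C <- stats::cor(E)
  A <- if (signed_hybrid) pmax(C, 0)^beta else abs(C)^beta
  diag(A) <- 0
  A
}

# topological overlap from an adjacency (diagonal defined as 1)
tom_similarity <- function(A) {
  k <- rowSums(A)
  num <- A %*% A + A
  den <- outer(k, k, pmin) + 1 - A
  TOM <- num / den
  diag(TOM) <- 1
  TOM
}

# send genes whose own-module kME falls below kme_min back to grey
kme_filter <- function(res, module, kme_min) {
  if (is.null(res$kme)) return(module)
  for (m in setdiff(unique(module), "grey")) {
    own <- res$kme[module == m, m]
    weak <- names(own)[own < kme_min]
    module[weak] <- "grey"
  }
  module
}

# first-PC eigengenes (unit norm, sign so mean own-module kME > 0) and
# the full gene x module kME matrix
eigengenes_kme <- function(E, module) {
  mods <- setdiff(sort(unique(module)), "grey")
  if (!length(mods))
    return(list(module = module, eigengenes = NULL, kme = NULL))
  eg <- sapply(mods, function(m) {
    sub <- E[, module == m, drop = FALSE]
    sub <- scale(sub)
    sub[is.na(sub)] <- 0
    v <- svd(sub, nu = 1, nv = 0)$u[, 1]
    v / sqrt(sum(v^2))
  })
  rownames(eg) <- rownames(E)
  kme <- stats::cor(E, eg)
  kme[is.na(kme)] <- 0
  for (m in mods) {
    own <- mean(kme[module == m, m])
    if (own < 0) {
      eg[, m] <- -eg[, m]
      kme[, m] <- -kme[, m]
    }
  }
  list(module = module, eigengenes = eg, kme = kme)
}

#' Classify module trajectories across disease stages
#'
#' Per module, a stage profile `(m0, m1, m2)` is computed and classified.
#' When the metacell matrix is supplied (recommended), the module's
#' per-metacell value is the mean log-normalized expression of its member
#' genes minus the metacell's median over all genes — the median tracks
#' library-composition shifts shared by all genes, so subtracting it
#' isolates the module's own trajectory. Without the matrix the
#' (unit-norm) eigengene is used directly. With
#' `delta = 0.25 * (max - min)` the module is:
#' biphasic when the middle stage exceeds both ends by `delta`;
#' ascending-step when both later stages exceed the first by `delta` and
#' differ by at most `delta`; descending when means decrease
#' monotonically; ascending-linear when they increase monotonically;
#' otherwise flat. A missing stage yields `"undetermined"`.
#'
#' @param assignment a `module_assignment` with eigengenes and stages
#' @param metacells the `metacell_matrix` the assignment was built from
#'   (optional; enables the median-centered member-mean profile)
#' @param min_per_stage minimum metacells per stage (default 2)
#' @return data.frame with `module`, `m0`, `m1`, `m2`, `class`
#' @export
module_trajectories <- function(assignment, metacells = NULL,
                                min_per_stage = 2) {
  stopifnot(inherits(assignment, "module_assignment"))
  if (is.null(assignment$eigengenes) || is.null(assignment$stage))
    stop("assignment lacks eigengenes or metacell stages")
  stage <- assignment$stage
  mods <- colnames(assignment$eigengenes)
  profile_of <- NULL
  if (!is.null(metacells)) {
    E <- if (inherits(metacells, "metacell_matrix")) metacells$expr
    else as.matrix(metacells)
    med <- apply(E, 1, stats::median)
    profile_of <- function(m) {
      g <- intersect(assignment$genes[assignment$module == m],
                     colnames(E))
      rowMeans(E[, g, drop = FALSE]) - med
    }
  }
  out <- lapply(mods, function(m) {
    e <- if (is.null(profile_of)) assignment$eigengenes[, m]
    else profile_of(m)
    ms <- vapply(0:2, function(s) {
      ix <- which(stage == s)
      if (length(ix) < min_per_stage) NA_real_ else mean(e[ix])
    }, 1.0)
    cls <- if (anyNA(ms)) "undetermined" else
      classify_trajectory(ms[1], ms[2], ms[3])
    data.frame(module = m, m0 = ms[1], m1 = ms[2], m2 = ms[3],
               class = cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

classify_trajectory <- function(m0, m1, m2) {
  rng <- max(m0, m1, m2) - min(m0, m1, m2)
  if (rng == 0) return("flat")
  delta <- 0.25 * rng
  if (m1 > max(m0, m2) + delta) return("biphasic")
  if (m1 > m0 + delta && m2 > m0 + delta && abs(m2 - m1) <= delta)
    return("ascending-step")
  if (m0 > m1 && m1 > m2) return("descending")
  if (m0 < m1 && m1 < m2) return("ascending-linear")
  "flat"
}

#' Hub genes by intramodular connectivity
#'
#' Top `n` genes of each module ranked by own-module kME (descending,
#' ties broken by gene id).
#'
#' @param assignment a `module_assignment`
#' @param n genes per module (default 25)
#' @return data.frame with `module`, `gene`, `kme`, `rank`
#' @export
hub_genes <- function(assignment, n = 25) {
  stopifnot(inherits(assignment, "module_assignment"))
  if (is.null(assignment$kme)) stop("kME not computed")
  mods <- colnames(assignment$kme)
  out <- lapply(mods, function(m) {
    genes <- assignment$genes[assignment$module == m]
    km <- assignment$kme[genes, m]
    ord <- order(-km, genes)
    take <- utils::head(ord, n)
    data.frame(module = m, gene = genes[take], kme = unname(km[take]),
               rank = seq_along(take), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Module share bookkeeping
#'
#' Per-module gene counts and their percentage of all clustered genes
#' (grey included in the denominator), via the shared [pct()] rule.
#'
#' @param module character vector of per-gene module labels
#' @return data.frame with `module`, `n_genes`, `percent`
#' @export
module_shares <- function(module) {
  tab <- sort(table(module), decreasing = TRUE)
  data.frame(module = names(tab), n_genes = as.integer(tab),
             percent = pct(as.integer(tab), length(module)),
             row.names = NULL)
}
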