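#' Simulation configuration for a synthetic GGN cohort
#'
#' Defines a multi-sample cohort spanning three disease stages (normal lung,
#' adenocarcinoma in situ, invasive adenocarcinoma) with planted structure
#' for every downstream stage of the pipeline: chromosome-scale expression
#' shifts in a malignant epithelial subpopulation, stage-trajectory gene
#' modules with correlated within-module noise, elevated functional gene
#' programs in designated T-cell clusters, and clonally expanded TCR
#' repertoires.
#'
#' The default cohort mirrors the study design the pipeline targets: 5
#' normal-lung, 3 AIS and 4 IAC samples. Counts are negative binomial with
#' gene-specific means and a shared dispersion. Module co-expression is
#' induced by latent Gaussian factors on the log-mean scale, one per module,
#' with a sample-level and a cell-level component; stage trajectories are
#' encoded as per-stage mean shifts following one of five shapes. Clone
#' sizes follow a truncated geometric law per T-cell cluster.
#'
#' @param n_samples_per_group named integer vector of sample counts for
#'   groups `nLung`, `AIS`, `IAC`
#' @param n_cells_per_sample cells per sample
#' @param n_genes,n_chromosomes genome size; genes are laid out in
#'   contiguous equal blocks per chromosome
#' @param cnv_segments list of `list(chrom, start, end, shift)`: 1-based
#'   gene indices *within* the chromosome and a log2 fold shift applied to
#'   malignant cells
#' @param malignant_fraction fraction of AIS/IAC epithelial cells carrying
#'   the CNV segments
#' @param module_specs list of `list(size, class, effect, hub_loading)`;
#'   `class` one of `"ascending-linear"`, `"ascending-step"`, `"biphasic"`,
#'   `"descending"`, `"flat"`; `effect` in natural-log expression units at
#'   the top of the trajectory; `hub_loading` multiplies the first gene's
#'   loading (a planted hub)
#' @param program_gene_sets optional named list (`naive`, `cytotoxic`,
#'   `exhaustion`) of gene indices; auto-placed after module genes when NULL
#' @param program_sizes sizes used for auto-placement (mirrors the marker
#'   sets used on real data: 4 naive, 12 cytotoxic, 5 exhaustion genes)
#' @param program_effect natural-log elevation of program genes in their
#'   designated cluster
#' @param cluster_props named proportions of cell clusters per sample
#' @param program_clusters named map program -> cluster
#' @param clone_size_distribution named list per T-cell cluster:
#'   `list(p, max)` parameters of a truncated geometric clone-size law
#' @param latent_sd_sample,latent_sd_cell standard deviations of the
#'   sample- and cell-level components of each module's latent factor
#' @param baseline_mean,baseline_sdlog per-gene baseline means are drawn
#'   log-normally around `baseline_mean` with `sdlog = baseline_sdlog`
#' @param planted_mean_boost multiplier on the baseline mean of planted
#'   module/program genes (stage-associated genes are expressed genes)
#' @param dispersion shared negative-binomial size parameter
#' @param seed integer RNG seed; the whole simulation is deterministic
#'   given the config
#' @return a validated `ggn_sim_config` list
#' @export
sim_config <- function(n_samples_per_group = c(nLung = 5, AIS = 3, IAC = 4),
                       n_cells_per_sample = 150,
                       n_genes = 2000,
                       n_chromosomes = 10,
                       cnv_segments = list(list(chrom = 1, start = 1,
                                                end = 150, shift = 1)),
                       malignant_fraction = 0.4,
                       module_specs = list(
                         list(size = 120, class = "ascending-linear",
                              effect = 1, hub_loading = 1),
                         list(size = 80, class = "ascending-step",
                              effect = 1, hub_loading = 1),
                         list(size = 60, class = "biphasic",
                              effect = 1, hub_loading = 1),
                         list(size = 50, class = "biphasic",
                              effect = 0.8, hub_loading = 1),
                         list(size = 40, class = "descending",
                              effect = 1, hub_loading = 1)),
                       program_gene_sets = NULL,
                       program_sizes = c(naive = 4, cytotoxic = 12,
                                         exhaustion = 5),
                       program_effect = 1.5,
                       cluster_props = c(Epithelial = 0.30, T_naive = 0.12,
                                         T_cytotoxic = 0.12,
                                         T_exhausted = 0.08,
                                         Myeloid = 0.22, Fibroblast = 0.16),
                       program_clusters = c(naive = "T_naive",
                                            cytotoxic = "T_cytotoxic",
                                            exhaustion = "T_exhausted"),
                       clone_size_distribution = list(
                         T_naive = list(p = 0.95, max = 50),
                         T_cytotoxic = list(p = 0.45, max = 50),
                         T_exhausted = list(p = 0.55, max = 50)),
                       latent_sd_sample = 0.15,
                       latent_sd_cell = 1.0,
                       baseline_mean = 0.5,
                       baseline_sdlog = 0.5,
                       planted_mean_boost = 4,
                       dispersion = 2,
                       seed = 1) {
  stopifnot(all(c("nLung", "AIS", "IAC") %in% names(n_samples_per_group)),
            all(n_samples_per_group >= 1),
            n_cells_per_sample >= 1, n_genes >= 10, n_chromosomes >= 1,
            malignant_fraction >= 0, malignant_fraction <= 1,
            dispersion > 0, baseline_mean > 0,
            abs(sum(cluster_props) - 1) < 1e-8)
  traj <- c("ascending-linear", "ascending-step", "biphasic",
            "descending", "flat")
  for (m in module_specs)
    if (!m$class %in% traj)
      stop("unknown trajectory class: ", m$class)
  for (cl in names(clone_size_distribution)) {
    par <- clone_size_distribution[[cl]]
    if (par$p <= 0 || par$p > 1 || par$max < 1)
      stop("clone-size law for ", cl, " has no finite mean")
  }

  # genome layout: contiguous equal blocks of genes per chromosome
  per_chrom <- rep(n_genes %/% n_chromosomes, n_chromosomes)
  per_chrom[seq_len(n_genes %% n_chromosomes)] <-
    per_chrom[seq_len(n_genes %% n_chromosomes)] + 1
  offset <- c(0, cumsum(per_chrom))[seq_len(n_chromosomes)]

  cnv_idx <- integer(0)
  for (seg in cnv_segments) {
    if (seg$chrom < 1 || seg$chrom > n_chromosomes)
      stop("CNV segment on unknown chromosome ", seg$chrom)
    if (seg$start < 1 || seg$end > per_chrom[seg$chrom] ||
        seg$start > seg$end)
      stop("CNV segment indices outside chromosome ", seg$chrom,
           " gene range")
    cnv_idx <- c(cnv_idx, offset[seg$chrom] + seg$start:seg$end)
  }

  # planted genes are spread evenly across the genome (co-expression
  # modules and functional programs are not genomically contiguous, and
  # contiguous placement would mimic a CNV segment)
  free <- setdiff(seq_len(n_genes), cnv_idx)
  msizes <- vapply(module_specs, function(m) as.integer(m$size), 1L)
  psizes <- if (is.null(program_gene_sets)) program_sizes else integer(0)
  n_planted <- sum(msizes) + sum(psizes)
  if (n_planted > length(free)) stop("not enough genes for modules")
  spread <- if (n_planted > 0)
    free[unique(round(seq(1, length(free), length.out = n_planted)))]
  else integer(0)
  if (length(spread) < n_planted)
    stop("not enough genes to spread module/program placement")
  # round-robin so each module's genes are genome-wide
  owner <- integer(0)
  remaining <- c(msizes, psizes)
  while (any(remaining > 0)) {
    nxt <- which(remaining > 0)
    owner <- c(owner, nxt)
    remaining[nxt] <- remaining[nxt] - 1L
  }
  module_idx <- lapply(seq_along(msizes), function(m)
    sort(spread[owner == m]))
  if (length(module_idx))
    names(module_idx) <- paste0("M", seq_along(msizes))
  if (is.null(program_gene_sets)) {
    program_gene_sets <- lapply(seq_along(psizes), function(p)
      sort(spread[owner == length(msizes) + p]))
    names(program_gene_sets) <- names(program_sizes)
  }
  roles <- c(cnv_idx, unlist(module_idx, use.names = FALSE),
             unlist(program_gene_sets, use.names = FALSE))
  if (anyDuplicated(roles))
    stop("overlapping gene-role assignments (CNV/module/program lists ",
         "must be disjoint)")
  if (any(roles < 1 | roles > n_genes))
    stop("gene-role index outside [1, n_genes]")

  structure(list(
    n_samples_per_group = n_samples_per_group,
    n_cells_per_sample = n_cells_per_sample,
    n_genes = n_genes, n_chromosomes = n_chromosomes,
    per_chrom = per_chrom, chrom_offset = offset,
    cnv_segments = cnv_segments, cnv_idx = sort(unique(cnv_idx)),
    malignant_fraction = malignant_fraction,
    module_specs = module_specs, module_idx = module_idx,
    program_gene_sets = program_gene_sets,
    program_effect = program_effect,
    cluster_props = cluster_props, program_clusters = program_clusters,
    clone_size_distribution = clone_size_distribution,
    latent_sd_sample = latent_sd_sample,
    latent_sd_cell = latent_sd_cell,
    baseline_mean = baseline_mean, baseline_sdlog = baseline_sdlog,
    planted_mean_boost = planted_mean_boost,
    dispersion = dispersion, seed = as.integer(seed)),
    class = "ggn_sim_config")
}

# per-stage trajectory shapes on the ordinal stage axis 0/1/2
trajectory_pattern <- function(class) {
  switch(class,
         "ascending-linear" = c(0, 0.5, 1),
         "ascending-step"   = c(0, 1, 1),
         "biphasic"         = c(0, 1, 0.25),
         "descending"       = c(1, 0.5, 0),
         "flat"             = c(0, 0, 0),
         stop("unknown trajectory class: ", class))
}

# largest-remainder apportionment of n cells to cluster proportions
apportion <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Simulate a labelled synthetic cohort
#'
#' Draws a full cohort according to a [sim_config()]: NB counts around
#' gene-specific baselines; malignant AIS/IAC epithelial cells with their
#' CNV-segment genes' means multiplied by `2^shift`; module genes following
#' their trajectory class across stages plus a shared latent factor per
#' module (sample-level + cell-level components, scaled by per-gene
#' loadings); program genes elevated in their designated clusters; and TCR
#' contigs for T-cell clusters with truncated-geometric clone sizes.
#' Deterministic given the config (the seed is part of the config).
#'
#' @param config a [sim_config()]
#' @return list of class `ggn_sim` with elements `dataset`
#'   ([ggn_dataset()]), `contigs` (10x-style contig table), `truth`
#'   (ground-truth labels: `malignant`, `gene_modules`, `module_classes`,
#'   `program_activity`, `clonotypes`, `expected_clonal_fraction`,
#'   `baseline_mu`), and `config`
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "ggn_sim_config"))
  set.seed(config$seed)
  groups <- c("nLung", "AIS", "IAC")
  stage_of <- c(nLung = 0L, AIS = 1L, IAC = 2L)

  samples <- unlist(lapply(groups, function(g)
    paste0(g, "_s", seq_len(config$n_samples_per_group[[g]]))))
  sample_group <- sub("_s[0-9]+$", "", samples)

  nc <- config$n_cells_per_sample
  cell_sample <- rep(samples, each = nc)
  cell_group <- rep(sample_group, each = nc)
  cluster_counts <- apportion(nc, config$cluster_props)
  cell_cluster <- rep(rep(names(cluster_counts), cluster_counts),
                      length(samples))
  n_cells <- length(cell_sample)
  barcodes <- sprintf("cell_%05d", seq_len(n_cells))
  stage <- stage_of[cell_group]

  genes <- sprintf("g%05d", seq_len(config$n_genes))

  # gene-specific baseline means; planted genes are expressed genes
  base_mu <- stats::rlnorm(config$n_genes,
                           meanlog = log(config$baseline_mean) -
                             config$baseline_sdlog^2 / 2,
                           sdlog = config$baseline_sdlog)
  planted <- c(unlist(config$module_idx, use.names = FALSE),
               unlist(config$program_gene_sets, use.names = FALSE))
  base_mu[planted] <- base_mu[planted] * config$planted_mean_boost

  log_mu <- matrix(log(base_mu), nrow = config$n_genes, ncol = n_cells)

  # malignant epithelial cells in AIS/IAC carry the CNV segments
  epi <- cell_cluster == "Epithelial"
  tumor_epi <- which(epi & cell_group %in% c("AIS", "IAC"))
  malignant <- integer(0)
  if (config$malignant_fraction > 0 && length(tumor_epi)) {
    by_sample <- split(tumor_epi, cell_sample[tumor_epi])
    malignant <- sort(unlist(lapply(by_sample, function(ix) {
      k <- round(config$malignant_fraction * length(ix))
      if (k > 0) ix[sample.int(length(ix), k)] else integer(0)
    }), use.names = FALSE))
  }
  if (length(malignant)) {
    for (seg in config$cnv_segments) {
      idx <- config$chrom_offset[seg$chrom] + seg$start:seg$end
      log_mu[idx, malignant] <- log_mu[idx, malignant] + seg$shift * log(2)
    }
  }

  # stage-trajectory modules in epithelial cells, correlated via a shared
  # latent factor (sample-level + cell-level) per module
  epi_ix <- which(epi)
  for (m in seq_along(config$module_specs)) {
    spec <- config$module_specs[[m]]
    idx <- config$module_idx[[m]]
    loading <- rep(1, length(idx))
    loading[1] <- spec$hub_loading
    pat <- trajectory_pattern(spec$class)
    f_sample <- stats::setNames(
      stats::rnorm(length(samples), 0, config$latent_sd_sample), samples)
    f_cell <- stats::rnorm(length(epi_ix), 0, config$latent_sd_cell)
    shift <- spec$effect * pat[stage[epi_ix] + 1] +
      f_sample[cell_sample[epi_ix]] + f_cell
    log_mu[idx, epi_ix] <- log_mu[idx, epi_ix] +
      outer(loading, shift)
  }

  # functional programs elevated in their designated clusters
  program_activity <- matrix(0, n_cells, length(config$program_gene_sets),
                             dimnames = list(barcodes,
                                             names(config$program_gene_sets)))
  for (p in names(config$program_gene_sets)) {
    target <- config$program_clusters[[p]]
    in_cl <- which(cell_cluster == target)
    if (length(in_cl)) {
      log_mu[config$program_gene_sets[[p]], in_cl] <-
        log_mu[config$program_gene_sets[[p]], in_cl] + config$program_effect
      program_activity[in_cl, p] <- 1
    }
  }

  counts <- matrix(stats::rnbinom(length(log_mu), mu = exp(log_mu),
                                  size = config$dispersion),
                   nrow = config$n_genes,
                   dimnames = list(genes, barcodes))
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")

  gene_pos <- data.frame(
    gene = genes,
    chrom = as.character(rep(seq_len(config$n_chromosomes),
                             config$per_chrom)),
    start = unlist(lapply(config$per_chrom,
                          function(k) (seq_len(k) - 1L) * 1000L)),
    end = unlist(lapply(config$per_chrom,
                        function(k) (seq_len(k) - 1L) * 1000L + 500L)),
    stringsAsFactors = FALSE)

  meta <- data.frame(barcode = barcodes, sample = cell_sample,
                     group = cell_group, cluster = cell_cluster,
                     stringsAsFactors = FALSE)
  dataset <- ggn_dataset(counts, meta, gene_pos)

  tcr <- simulate_tcr(config, meta)

  gene_modules <- if (length(config$module_idx))
    stats::setNames(
      rep(names(config$module_idx),
          vapply(config$module_idx, length, 1L)),
      genes[unlist(config$module_idx, use.names = FALSE)])
  else stats::setNames(character(0), character(0))
  module_classes <- stats::setNames(
    vapply(config$module_specs, function(m) m$class, ""),
    names(config$module_idx))

  truth <- list(
    malignant = barcodes[malignant],
    tumor_epithelial = barcodes[tumor_epi],
    gene_modules = gene_modules,
    module_classes = module_classes,
    module_genes = lapply(config$module_idx, function(ix) genes[ix]),
    program_gene_sets = lapply(config$program_gene_sets,
                               function(ix) genes[ix]),
    program_activity = program_activity,
    clonotypes = tcr$truth,
    expected_clonal_fraction = tcr$expected_clonal_fraction,
    baseline_mu = stats::setNames(base_mu, genes))

  structure(list(dataset = dataset, contigs = tcr$contigs, truth = truth,
                 config = config),
            class = "ggn_sim")
}

# truncated geometric clone-size draw
rtruncgeom <- function(n, p, max) {
  s <- 1L + stats::rgeom(n, p)
  while (any(s > max)) s[s > max] <- 1L + stats::rgeom(sum(s > max), p)
  s
}

# cell-weighted probability that a cell sits in a clone of size >= 2
# under the truncated geometric clone-size law
truncgeom_clonal_fraction <- function(p, max) {
  s <- seq_len(max)
  q <- p * (1 - p)^(s - 1)
  q <- q / sum(q)
  1 - q[1] / sum(s * q)
}

# emit paired TRA/TRB contigs for T cells with clonal expansion per
# sample x cluster under the configured clone-size law
simulate_tcr <- function(config, meta) {
  law <- config$clone_size_distribution
  tcells <- meta[meta$cluster %in% names(law), , drop = FALSE]
  v_a <- sprintf("TRAV%d", 1:20); j_a <- sprintf("TRAJ%d", 1:30)
  v_b <- sprintf("TRBV%d", 1:25); j_b <- sprintf("TRBJ%d", 1:12)
  nt <- c("A", "C", "G", "T")
  rows <- list(); truth_rows <- list(); clone_counter <- 0L
  for (key in unique(paste(tcells$sample, tcells$cluster, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    cells <- tcells$barcode[tcells$sample == parts[1] &
                              tcells$cluster == parts[2]]
    par <- law[[parts[2]]]
    n <- length(cells)
    sizes <- integer(0)
    while (sum(sizes) < n)
      sizes <- c(sizes, rtruncgeom(8, par$p, par$max))
    cum <- cumsum(sizes)
    last <- which(cum >= n)[1]
    sizes <- sizes[seq_len(last)]
    sizes[last] <- sizes[last] - (cum[last] - n)
    sizes <- sizes[sizes > 0]
    clone_id <- rep(seq_along(sizes) + clone_counter, sizes)
    clone_counter <- clone_counter + length(sizes)
    uniq <- unique(clone_id)
    cdr3a <- stats::setNames(vapply(uniq, function(i)
      paste(sample(nt, 36, replace = TRUE), collapse = ""), ""), uniq)
    cdr3b <- stats::setNames(vapply(uniq, function(i)
      paste(sample(nt, 39, replace = TRUE), collapse = ""), ""), uniq)
    va <- stats::setNames(sample(v_a, length(uniq), replace = TRUE), uniq)
    ja <- stats::setNames(sample(j_a, length(uniq), replace = TRUE), uniq)
    vb <- stats::setNames(sample(v_b, length(uniq), replace = TRUE), uniq)
    jb <- stats::setNames(sample(j_b, length(uniq), replace = TRUE), uniq)
    ck <- as.character(clone_id)
    rows[[key]] <- data.frame(
      barcode = rep(cells, 2),
      chain = rep(c("TRA", "TRB"), each = n),
      v_gene = c(va[ck], vb[ck]),
      j_gene = c(ja[ck], jb[ck]),
      cdr3 = c(cdr3a[ck], cdr3b[ck]),
      productive = "True", high_confidence = "True",
      stringsAsFactors = FALSE)
    truth_rows[[key]] <- data.frame(
      barcode = cells, clone = clone_id,
      sample = parts[1], cluster = parts[2],
      stringsAsFactors = FALSE)
  }
  contigs <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL
  truth <- if (length(truth_rows))
    do.call(rbind, c(truth_rows, list(make.row.names = FALSE))) else NULL
  if (!is.null(truth)) {
    cs <- table(truth$clone)
    truth$clone_size <- as.integer(cs[as.character(truth$clone)])
  }
  expected <- vapply(law, function(par)
    truncgeom_clonal_fraction(par$p, par$max), 1.0)
  list(contigs = contigs, truth = truth,
       expected_clonal_fraction = expected)
}

#' Write a simulated cohort to plain-text files
#'
#' Emits the standard exchange formats: MatrixMarket counts
#' (`matrix.mtx`, genes x cells) with `features.tsv`/`barcodes.tsv`,
#' per-cell metadata TSV, gene positions as BED4 (0-based half-open),
#' a 10x-dialect `filtered_contig_annotations.csv`, gene-set JSON and
#' ground-truth JSON.
#'
#' @param sim a `ggn_sim` from [simulate_dataset()]
#' @param out_dir output directory (created if missing)
#' @return invisibly, the named vector of file paths written
#' @export
write_dataset <- function(sim, out_dir) {
  stopifnot(inherits(sim, "ggn_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  ds <- sim$dataset
  paths <- c(
    mtx = file.path(out_dir, "matrix.mtx"),
    features = file.path(out_dir, "features.tsv"),
    barcodes = file.path(out_dir, "barcodes.tsv"),
    meta = file.path(out_dir, "cell_metadata.tsv"),
    bed = file.path(out_dir, "genes.bed"),
    contigs = file.path(out_dir, "filtered_contig_annotations.csv"),
    gene_sets = file.path(out_dir, "gene_sets.json"),
    truth = file.path(out_dir, "ground_truth.json"))
  Matrix::writeMM(ds$counts, paths["mtx"])
  writeLines(rownames(ds$counts), paths["features"])
  writeLines(colnames(ds$counts), paths["barcodes"])
  utils::write.table(ds$cell_meta, paths["meta"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed <- ds$gene_pos[, c("chrom", "start", "end", "gene")]
  utils::write.table(bed, paths["bed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(sim$contigs, paths["contigs"], row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(sim$truth$program_gene_sets, paths["gene_sets"])
  truth <- sim$truth
  truth$program_activity <- NULL   # large; recomputable from clusters
  # named atomic vectors must serialize as JSON objects, not bare arrays
  for (f in c("gene_modules", "module_classes",
              "expected_clonal_fraction", "baseline_mu"))
    truth[[f]] <- as.list(truth[[f]])
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a cohort written by [write_dataset()]
#'
#' @param dir directory containing the files
#' @return list with `dataset` ([ggn_dataset()]), `contigs`, `gene_sets`
#'   and `truth` (NULL when absent)
#' @export
read_dataset <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "features.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- utils::read.delim(file.path(dir, "cell_metadata.tsv"),
                            stringsAsFactors = FALSE)
  bed <- utils::read.delim(file.path(dir, "genes.bed"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "gene"))
  gene_pos <- bed[, c("gene", "chrom", "start", "end")]
  gene_pos$chrom <- as.character(gene_pos$chrom)
  contig_path <- file.path(dir, "filtered_contig_annotations.csv")
  contigs <- if (file.exists(contig_path))
    utils::read.csv(contig_path, stringsAsFactors = FALSE) else NULL
  gs_path <- file.path(dir, "gene_sets.json")
  gene_sets <- if (file.exists(gs_path))
    lapply(jsonlite::read_json(gs_path), unlist) else NULL
  tr_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(tr_path)) jsonlite::read_json(
    tr_path, simplifyVector = TRUE) else NULL
  if (!is.null(truth))
    for (f in c("gene_modules", "module_classes",
                "expected_clonal_fraction", "baseline_mu"))
      truth[[f]] <- unlist(truth[[f]])
  list(dataset = ggn_dataset(counts, meta, gene_pos),
       contigs = contigs, gene_sets = gene_sets, truth = truth)
}
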