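test_that("stage association: planted genes pass, degenerate genes never crash", {
  # explicit per-stage means (0, 1, 2) with unit noise, repeated samples
  set.seed(51)
  n_per <- 100
  group <- rep(c("nLung", "AIS", "IAC"), each = n_per)
  samp <- paste0(group, "_", rep(rep(1:2, each = n_per / 2), 3))
  stage <- rep(0:2, each = n_per)
  counts <- matrix(rpois(50 * length(group), 3), nrow = 50)
  rownames(counts) <- sprintf("g%03d", 1:50)
  colnames(counts) <- sprintf("c%04d", seq_along(group))
  # gene 1: strong ordinal trend on the count scale; gene 2: all zero
  counts[1, ] <- rpois(length(group), exp(stage))
  counts[2, ] <- 0L
  ds <- toy_dataset(counts, groups = group, samples = samp)
  res <- suppressMessages(stage_association_filter(ds))
  expect_true(res$pass[1])
  expect_false(res$pass[2])
  expect_equal(res$p[2], 1)
  expect_true(res$flagged[2])
  # FDR is monotone in p rank
  o <- order(res$p)
  expect_true(all(diff(res$fdr[o]) >= -1e-12))
})

test_that("metacells are stage-pure with bounded sizes and counts", {
  sim <- small_sim(seed = 52, n_cells_per_sample = 125)
  meta <- sim$dataset$cell_meta
  epi <- subset_dataset(sim$dataset,
                        cells = which(meta$cluster == "Epithelial"))
  mc <- build_metacells(epi, k = 10, k_min = 5)
  expect_true(all(mc$n_members >= 5 & mc$n_members <= 20))
  expect_equal(length(mc$members), nrow(mc$expr))
  # members of one metacell share one stage
  stage_map <- c(nLung = 0, AIS = 1, IAC = 2)
  for (i in seq_along(mc$members)) {
    s <- stage_map[meta$group[match(mc$members[[i]], meta$barcode)]]
    expect_equal(unname(unique(s)), mc$stage[i])
  }
  # ~450 epithelial cells per stage bound the metacell count
  expect_gte(nrow(mc$expr), 0.6 * ncol(epi$counts) / 10)
  expect_lte(nrow(mc$expr), ncol(epi$counts) / 10 + 3)
})

test_that("a stage with exactly k cells collapses to one metacell of equals", {
  counts <- matrix(rep(c(5L, 3L, 0L, 8L), 10), nrow = 4,
                   dimnames = list(sprintf("g%d", 1:4),
                                   sprintf("c%02d", 1:10)))
  ds <- toy_dataset(counts, groups = rep("nLung", 10),
                    samples = rep("s1", 10))
  mc <- suppressWarnings(build_metacells(ds, k = 10, k_min = 5))
  expect_equal(nrow(mc$expr), 1)
  expect_equal(mc$n_members, 10L)
  expect_equal(as.numeric(mc$expr[1, ]),
               as.numeric(lognorm(counts)[, 1]))
})

test_that("soft-threshold selection behaves on generated and null data", {
  # exact scale-free adjacency: power-law connectivity input
  set.seed(53)
  k <- round(stats::rlnorm(500, 2, 1)) + 1
  sf <- scale_free_r2(k, n_bins = 10)
  expect_gte(sf[["r2"]], 0.9)
  # two perfectly correlated genes have adjacency 1 at any power
  E <- cbind(a = 1:40, b = (1:40) * 2)
  A <- ggnsc:::tom_adjacency(E, beta = 7)
  expect_equal(A["a", "b"], 1)
  # independent Gaussian genes: R^2 improves with beta on average
  set.seed(54)
  En <- matrix(rnorm(60 * 300), nrow = 60,
               dimnames = list(NULL, sprintf("g%03d", 1:300)))
  fit <- pick_soft_threshold(En, candidate_powers = c(1, 6, 12))$fit_table
  expect_lt(fit$r_squared[1], fit$r_squared[3])
})

test_that("TOM matches hand arithmetic and its invariants hold", {
  A <- matrix(c(0, .5, .2,
                .5, 0, .1,
                .2, .1, 0), nrow = 3, byrow = TRUE)
  TOM <- ggnsc:::tom_similarity(A)
  # hand: k = (0.7, 0.6, 0.3); TOM12 = (0.2*0.1 + 0.5)/(0.6 + 1 - 0.5)
  expect_equal(TOM[1, 2], (0.02 + 0.5) / (0.6 + 1 - 0.5),
               tolerance = 1e-12)
  expect_equal(TOM, t(TOM))
  expect_true(all(TOM >= 0 & TOM <= 1))
  expect_equal(diag(TOM), rep(1, 3))
})

test_that("a perfectly correlated gene block forms one module with kME 1", {
  set.seed(55)
  base <- rnorm(80)
  E <- cbind(sapply(1:40, function(i) base * runif(1, 0.5, 2)),
             matrix(rnorm(80 * 10, sd = 1), nrow = 80))
  colnames(E) <- sprintf("g%02d", 1:50)
  ma <- detect_modules(E, beta = 6, min_module_size = 20)
  mods <- setdiff(unique(ma$module), "grey")
  expect_length(mods, 1)
  in_mod <- ma$module == mods
  expect_equal(sum(in_mod), 40)
  expect_equal(unname(ma$kme[ma$genes[in_mod], mods]), rep(1, 40),
               tolerance = 1e-6)
  # eigengene has unit norm; gene partition is complete
  expect_equal(sum(ma$eigengenes[, mods]^2), 1, tolerance = 1e-12)
  expect_equal(sum(in_mod) + sum(ma$module == "grey"), length(ma$genes))
})

test_that("planted modules are recovered with correct trajectories on one cohort", {
  sim <- module_sim(seed = 24)
  meta <- sim$dataset$cell_meta
  epi <- subset_dataset(sim$dataset,
                        cells = which(meta$cluster == "Epithelial"))
  mc <- build_metacells(epi)
  pw <- pick_soft_threshold(mc)
  ma <- detect_modules(mc, beta = pw$power)
  truthmap <- sim$truth$gene_modules
  planted <- rep("none", length(ma$genes))
  names(planted) <- ma$genes
  planted[names(truthmap)] <- truthmap
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(planted, ma$module)
  expect_gte(ari, 0.8)
  tr <- module_trajectories(ma, mc)
  correct <- 0
  for (m in setdiff(unique(ma$module), "grey")) {
    pl <- names(sort(table(planted[ma$module == m]), decreasing = TRUE))[1]
    if (pl != "none" &&
        tr$class[tr$module == m] == sim$truth$module_classes[[pl]])
      correct <- correct + 1
  }
  expect_gte(correct, 4)
})

test_that("trajectory classification follows its definitions", {
  expect_equal(ggnsc:::classify_trajectory(0, 1, 0.25), "biphasic")
  expect_equal(ggnsc:::classify_trajectory(1, 0.5, 0), "descending")
  expect_equal(ggnsc:::classify_trajectory(0, 0.5, 1), "ascending-linear")
  expect_equal(ggnsc:::classify_trajectory(0, 1, 1.01), "ascending-step")
  expect_equal(ggnsc:::classify_trajectory(2, 2, 2), "flat")
})

test_that("hub genes rank by kME with deterministic ties", {
  set.seed(56)
  base <- rnorm(60)
  E <- cbind(sapply(1:10, function(i) base),
             matrix(rnorm(60 * 30), nrow = 60))
  colnames(E) <- sprintf("g%02d", 1:40)
  ma <- detect_modules(E, beta = 6, min_module_size = 8)
  mods <- setdiff(unique(ma$module), "grey")
  hub <- hub_genes(ma, n = 25)
  in_mod <- hub[hub$module == mods[1], ]
  expect_equal(nrow(in_mod), 10)    # truncation returns the whole module
  # perfect module: all kME equal, order falls back to gene id
  expect_equal(in_mod$gene, sort(in_mod$gene))
})

test_that("module shares reproduce printed percentages from printed counts", {
  labels <- rep(c("turquoise", "blue", "brown", "yellow", "green", "grey"),
                c(1457, 561, 433, 362, 302, 254))
  expect_equal(length(labels), 3369)
  sh <- module_shares(labels)
  expect_equal(sh$percent[sh$module == "turquoise"], 43.2)
  expect_equal(sh$percent[sh$module == "blue"], 16.7)
  expect_equal(sh$percent[sh$module == "grey"], 7.5)
})
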