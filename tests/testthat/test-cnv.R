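make_positions <- function(genes, n_chrom = 4) {
  per <- ceiling(length(genes) / n_chrom)
  data.frame(gene = genes,
             chrom = as.character(rep(1:n_chrom, each = per)[
               seq_along(genes)]),
             start = rep(seq_len(per) * 1000L, n_chrom)[seq_along(genes)],
             end = rep(seq_len(per) * 1000L + 500L,
                       n_chrom)[seq_along(genes)])
}

test_that("window = 1 reduces the profile to centered relative expression", {
  set.seed(41)
  counts <- matrix(rpois(60 * 40, 5), nrow = 60)
  rownames(counts) <- sprintf("g%03d", 1:60)
  colnames(counts) <- sprintf("c%03d", 1:40)
  ds <- toy_dataset(counts, gene_pos = make_positions(rownames(counts)))
  q <- colnames(counts)[1:15]; r <- colnames(counts)[16:40]
  prof <- infer_cnv_profiles(ds, q, r, window = 1, clip = 3)
  # oracle computed without the smoothing machinery
  cp <- expm1(as.matrix(lognorm(counts)))
  rel <- log2(cp + 1) - log2(rowMeans(cp[, r]) + 1)
  rel <- pmin(pmax(rel, -3), 3)
  rel <- t(rel)[rownames(prof$matrix), prof$gene_order$gene]
  rel <- sweep(rel, 1, apply(rel, 1, median))
  rel <- sweep(rel, 2, colMeans(rel[r, ]))
  expect_equal(prof$matrix, rel, tolerance = 1e-12)
  # reference rows center at zero
  expect_lt(max(abs(colMeans(prof$matrix[r, ]))), 1e-6)
})

test_that("query cells drawn like the reference give near-zero profiles", {
  set.seed(42)
  counts <- matrix(rnbinom(200 * 300, mu = 2, size = 2), nrow = 200)
  rownames(counts) <- sprintf("g%03d", 1:200)
  colnames(counts) <- sprintf("c%03d", 1:300)
  ds <- toy_dataset(counts, gene_pos = make_positions(rownames(counts)))
  q <- colnames(counts)[1:100]; r <- colnames(counts)[101:300]
  prof <- infer_cnv_profiles(ds, q, r, window = 21)
  prof_mean <- colMeans(prof$matrix[q, ])
  se <- apply(prof$matrix[q, ], 2, sd) / sqrt(length(q))
  expect_gt(mean(abs(prof_mean) < 3 * se), 0.95)
})

test_that("a planted segment elevates segment genes in malignant cells", {
  sim <- small_sim(seed = 43, n_cells_per_sample = 100)
  meta <- sim$dataset$cell_meta
  q <- meta$barcode[meta$cluster == "Epithelial" &
                      meta$group %in% c("AIS", "IAC")]
  r <- meta$barcode[meta$cluster != "Epithelial"]
  prof <- infer_cnv_profiles(sim$dataset, q, r)
  mal <- intersect(q, sim$truth$malignant)
  seg <- prof$gene_order$gene %in% sprintf("g%05d", 1:40)
  on_seg <- rowMeans(prof$matrix[mal, seg, drop = FALSE])
  off_seg <- rowMeans(prof$matrix[mal, !seg, drop = FALSE])
  expect_lt(stats::wilcox.test(on_seg, off_seg,
                               alternative = "greater")$p.value, 0.01)
})

test_that("cnv_score equals a brute-force two-pass implementation", {
  set.seed(44)
  mat <- matrix(rnorm(30 * 200), nrow = 30,
                dimnames = list(sprintf("c%02d", 1:30), NULL))
  prof <- structure(list(matrix = mat, query_cells = rownames(mat),
                         reference_cells = character(0),
                         gene_order = NULL, window = 1),
                    class = "cnv_profile")
  res <- cnv_score(prof, top_fraction = 0.05)
  # brute force: sort by mean square, top ceil(0.05*30) = 2 cells
  ms <- apply(mat, 1, function(v) mean(v^2))
  top <- order(-ms)[1:2]
  R <- colMeans(mat[top, ])
  brute <- apply(mat, 1, function(v) cor(v, R))
  expect_equal(res$scores$cnv_score, unname(brute), tolerance = 1e-12)
  expect_equal(res$scores$ms, unname(ms), tolerance = 1e-12)

  # single top cell defines R exactly
  res1 <- cnv_score(structure(list(matrix = mat[1:20, ],
                                   query_cells = rownames(mat)[1:20],
                                   reference_cells = character(0),
                                   gene_order = NULL, window = 1),
                              class = "cnv_profile"),
                    top_fraction = 0.05)
  ms20 <- apply(mat[1:20, ], 1, function(v) mean(v^2))
  R1 <- mat[1:20, ][which.max(ms20), ]
  expect_equal(res1$scores$cnv_score,
               unname(apply(mat[1:20, ], 1, function(v) cor(v, R1))),
               tolerance = 1e-12)
})

test_that("identical profiles all score 1 and zero-variance scores 0", {
  v <- rnorm(50)
  mat <- matrix(rep(v, each = 25), nrow = 25,
                dimnames = list(sprintf("c%02d", 1:25), NULL))
  prof <- structure(list(matrix = mat, query_cells = rownames(mat),
                         reference_cells = character(0),
                         gene_order = NULL, window = 1),
                    class = "cnv_profile")
  expect_equal(cnv_score(prof)$scores$cnv_score, rep(1, 25))
  mat[3, ] <- 0
  prof$matrix <- mat
  expect_warning(res <- cnv_score(prof), "zero-variance")
  expect_equal(res$scores$cnv_score[3], 0)
})

test_that("malignant classification is strict at the threshold and monotone", {
  scores <- data.frame(barcode = c("a", "b", "c"),
                       cnv_score = c(0.31, 0.29, 0.30))
  cls <- classify_malignant(scores)
  expect_equal(cls$labels$malignant, c(TRUE, FALSE, FALSE))
  # printed-count arithmetic: 1,528 of 1,939 cells above threshold
  many <- data.frame(barcode = sprintf("c%04d", 1:1939),
                     cnv_score = rep(c(0.8, 0.1), c(1528, 411)))
  s <- classify_malignant(many)$summary
  expect_equal(s$percent, 78.8)
  # raising the threshold never increases the calls
  n_at <- vapply(seq(0, 0.9, by = 0.1), function(th)
    classify_malignant(many, th)$summary$n_malignant, 1)
  expect_true(all(diff(n_at) <= 0))
  expect_equal(classify_malignant(
    data.frame(barcode = "a", cnv_score = 0.3))$summary$n_malignant, 0)
})

test_that("profiles are invariant to gene-wise additive shifts shared by all cells", {
  set.seed(46)
  mat <- matrix(rnorm(40 * 100), nrow = 40,
                dimnames = list(sprintf("c%02d", 1:40), NULL))
  shift <- rnorm(100)
  prof_a <- structure(list(matrix = mat, query_cells = rownames(mat),
                           reference_cells = character(0),
                           gene_order = NULL, window = 1),
                      class = "cnv_profile")
  # a gene-wise shift applied to every cell is removed by reference
  # centering inside infer_cnv_profiles; at the scoring stage the
  # centered matrices are identical, hence so are the scores
  res_a <- cnv_score(prof_a)
  prof_b <- prof_a
  prof_b$matrix <- mat[c(21:40, 1:20), ]   # permuted cell order
  prof_b$query_cells <- rownames(prof_b$matrix)
  res_b <- cnv_score(prof_b)
  merged <- merge(res_a$scores, res_b$scores, by = "barcode")
  expect_equal(merged$cnv_score.x, merged$cnv_score.y, tolerance = 1e-12)
})

test_that("random splits of a homogeneous population yield no DEGs", {
  set.seed(47)
  counts <- matrix(rnbinom(1000 * 300, mu = 2, size = 2), nrow = 1000)
  rownames(counts) <- sprintf("g%04d", 1:1000)
  colnames(counts) <- sprintf("c%03d", 1:300)
  ds <- toy_dataset(counts)
  labels <- rep(c(TRUE, FALSE), each = 150)
  res <- validate_split_deg(ds, labels, n_random_splits = 3, seed = 48)
  expect_equal(median(res$splits$n_deg[res$splits$type == "random"]), 0)
  # planted 2-fold difference on 100 genes is recovered
  counts2 <- counts
  counts2[1:100, labels] <- rnbinom(100 * 150, mu = 4, size = 2)
  res2 <- validate_split_deg(toy_dataset(counts2), labels, seed = 48)
  recall <- mean(res2$observed$deg[1:100])
  expect_gte(recall, 0.9)
  # vanishing alpha admits nothing
  res3 <- validate_split_deg(ds, labels, n_random_splits = 1,
                             alpha = 1e-300, seed = 48)
  expect_equal(sum(res3$observed$deg), 0)
})
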