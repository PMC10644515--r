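test_that("clonotype assembly reproduces hand enumeration", {
  ct <- assign_clonotypes(toy_contigs())
  # cells 1-4 valid; cell5 has two TRBs, cell6 lacks a TRB
  expect_equal(ct$report$n_cells_input, 6)
  expect_equal(ct$report$n_retained, 4)
  expect_equal(sort(ct$cells$barcode), sprintf("cell%d", 1:4))
  # cells 1 and 2 share both chains: 3 distinct clonotypes
  expect_equal(length(unique(ct$cells$clonotype)), 3)
  expect_equal(sort(ct$cells$clone_size), c(1, 1, 2, 2))
  expect_equal(ct$report$n_multi_chain, 1)
  expect_equal(ct$report$n_missing_chain, 1)
  # conservation: clone sizes sum to retained cells
  sz <- table(ct$cells$clonotype)
  expect_equal(sum(sz), ct$report$n_retained)
})

test_that("retention percentage follows the printed two-decimal rule", {
  expect_equal(pct(8451, 11847, digits = 2), 71.33)
  # unproductive contigs are dropped before pairing
  tab <- rbind(toy_contigs(),
               contig_row("cell7", "TRA", cdr3 = "KKK",
                          productive = "False"),
               contig_row("cell7", "TRB", cdr3 = "LLL"))
  ct <- assign_clonotypes(tab)
  expect_false("cell7" %in% ct$cells$barcode)
  ct2 <- assign_clonotypes(tab, require_productive = FALSE)
  expect_true("cell7" %in% ct2$cells$barcode)
  # malformed chain labels are rejected at row level
  bad <- rbind(toy_contigs(), contig_row("cell8", "IGH"))
  expect_equal(assign_clonotypes(bad)$report$n_rejected_rows, 1)
})

test_that("AIRR rearrangement input is accepted", {
  airr <- data.frame(cell_id = c("x1", "x1"), locus = c("TRA", "TRB"),
                     v_call = c("TRAV1", "TRBV2"),
                     j_call = c("TRAJ3", "TRBJ4"),
                     junction_aa = c("CAVR", "CASS"),
                     productive = c("T", "T"))
  ct <- assign_clonotypes(airr)
  expect_equal(ct$report$n_retained, 1)
  expect_match(ct$cells$clonotype, "CAVR")
})

test_that("clonal fractions hit the degenerate extremes and the analytic law", {
  # all singletons
  ct <- assign_clonotypes(toy_contigs()[1:8, ][-(1:4), ])
  expect_true(all(clonal_fraction(ct, by = "group")$clonal_fraction %in%
                    c(0, NA)))
  # simulated repertoires approach the truncated-geometric tail
  sim <- small_sim(seed = 71, n_cells_per_sample = 200)
  ct2 <- assign_clonotypes(sim$contigs, meta = sim$dataset$cell_meta)
  cf <- clonal_fraction(ct2, by = "cluster")
  expected <- sim$truth$expected_clonal_fraction
  for (cl in c("T_cytotoxic", "T_exhausted")) {
    obs <- cf$clonal_fraction[cf$cluster == cl]
    n <- cf$n_cells[cf$cluster == cl]
    se <- sqrt(expected[[cl]] * (1 - expected[[cl]]) / n)
    expect_lt(abs(obs - expected[[cl]]), 5 * se + 0.03)
  }
  # expansion ordering: expanded clusters beat the singleton-rich one
  expect_gt(cf$clonal_fraction[cf$cluster == "T_cytotoxic"],
            cf$clonal_fraction[cf$cluster == "T_naive"])
})

test_that("clone-space occupancy matches hand arithmetic and sums to 1", {
  rows <- list()
  for (i in 1:10) for (j in 1:10)
    rows[[length(rows) + 1]] <-
      rbind(contig_row(sprintf("b%03d_%d", i, j), "TRA",
                       cdr3 = sprintf("A%03d", i)),
            contig_row(sprintf("b%03d_%d", i, j), "TRB",
                       cdr3 = sprintf("B%03d", i)))
  for (i in 1:120)
    rows[[length(rows) + 1]] <-
      rbind(contig_row(sprintf("s%03d", i), "TRA",
                       cdr3 = sprintf("X%03d", i)),
            contig_row(sprintf("s%03d", i), "TRB",
                       cdr3 = sprintf("Y%03d", i)))
  ct <- assign_clonotypes(do.call(rbind, rows))
  occ <- clone_space_occupancy(ct)
  # rank bins: clonotype ranks 1-10 hold the 100 expanded cells; ranks
  # 11-100 hold 90 singletons; ranks 101-130 the remaining 30
  expect_equal(occ$fraction[1], 100 / 220, tolerance = 1e-12)
  expect_equal(occ$fraction[2], 90 / 220, tolerance = 1e-12)
  expect_equal(occ$fraction[3], 30 / 220, tolerance = 1e-12)
  expect_equal(sum(occ$fraction), 1, tolerance = 1e-9)
  # permuting input rows changes nothing
  perm <- do.call(rbind, rows[sample(length(rows))])
  expect_equal(clone_space_occupancy(assign_clonotypes(perm)), occ)
  # five clonotypes only: everything in the first bin
  ct5 <- assign_clonotypes(toy_contigs())
  occ5 <- clone_space_occupancy(ct5)
  expect_equal(occ5$fraction[occ5$bin == "[1,10]"], 1)
})

test_that("clonotype overlap follows set arithmetic in both conventions", {
  addcell <- function(bc, id) {
    rbind(contig_row(bc, "TRA", cdr3 = paste0("A", id)),
          contig_row(bc, "TRB", cdr3 = paste0("B", id)))
  }
  bcs <- c(paste0("a", 1:4), paste0("b", 5:7))
  ids <- c("c1", "c2", "c3", "c4", "c3", "c4", "c5")
  rows <- Map(addcell, bcs, ids)
  meta <- data.frame(barcode = bcs, sample = "s1", group = "IAC",
                     cluster = rep(c("A", "B"), c(4, 3)))
  ct <- assign_clonotypes(do.call(rbind, rows), meta = meta)
  ov <- clonotype_overlap(ct)
  expect_equal(ov$percent["A", "B"], 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(ov$percent, t(ov$percent))
  expect_equal(diag(ov$percent), c(A = 100, B = 100))
  expect_equal(ov$shared["A", "B"], 2L)
  jac <- clonotype_overlap(ct, mode = "jaccard")
  expect_equal(jac$percent["A", "B"], 100 * 2 / 5, tolerance = 1e-9)
  # overlap coefficient dominates Jaccard; subsets reach 100
  expect_true(all(ov$percent >= jac$percent - 1e-9))
  rows2 <- Map(addcell, bcs, c("c1", "c2", "c3", "c4", "c3", "c4", "c1"))
  ct2 <- assign_clonotypes(do.call(rbind, rows2), meta = meta)
  expect_equal(clonotype_overlap(ct2)$percent["A", "B"], 100)
  # disjoint repertoires
  rows3 <- Map(addcell, bcs, c("c1", "c2", "c3", "c4", "z1", "z2", "z3"))
  expect_equal(clonotype_overlap(
    assign_clonotypes(do.call(rbind, rows3), meta = meta)
  )$percent["A", "B"], 0)
})

test_that("V-J usage is normalized per group and shrinks with sample size", {
  sim <- small_sim(seed = 72, n_cells_per_sample = 150)
  ct <- assign_clonotypes(sim$contigs, meta = sim$dataset$cell_meta)
  vj <- vj_usage(ct, chain = "TRB")
  sums <- tapply(vj$frequency, vj$group, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # a single-clonotype repertoire has one entry with frequency 1
  ct1 <- assign_clonotypes(toy_contigs()[1:4, ])
  vj1 <- vj_usage(ct1, chain = "TRA")
  expect_equal(nrow(vj1), 1)
  expect_equal(vj1$frequency, 1)
  # uniform V/J draws flatten as n grows (multinomial sampling error)
  spread <- function(seed, n) {
    s <- small_sim(seed = seed, n_cells_per_sample = n)
    v <- vj_usage(assign_clonotypes(s$contigs,
                                    meta = s$dataset$cell_meta))
    max(v$frequency) - min(v$frequency)
  }
  expect_gt(spread(73, 60), spread(73, 400))
})

test_that("clone-size distribution conserves cells and tracks the generative law", {
  sim <- small_sim(seed = 74, n_cells_per_sample = 300)
  ct <- assign_clonotypes(sim$contigs, meta = sim$dataset$cell_meta)
  csd <- clone_size_distribution(ct)
  per_group <- tapply(csd$clone_size * csd$n_clonotypes, csd$group, sum)
  retained <- table(ct$cells$group)
  expect_equal(as.numeric(per_group[names(retained)]),
               as.numeric(retained))
  # all-singleton repertoire: one row per group
  ct1 <- assign_clonotypes(toy_contigs()[5:8, ])
  csd1 <- clone_size_distribution(ct1)
  expect_equal(csd1$clone_size, 1)
  expect_equal(csd1$n_clonotypes, 2)
  # geometric law: log clonotype counts fall roughly linearly in size
  big <- clone_size_distribution(ct, by = "group")
  agg <- stats::aggregate(n_clonotypes ~ clone_size, big, sum)
  agg <- agg[agg$n_clonotypes > 0 & agg$clone_size <= 8, ]
  fit <- summary(stats::lm(log(n_clonotypes) ~ clone_size, agg))
  expect_gte(fit$r.squared, 0.85)
})
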