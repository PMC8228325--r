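# Specificity matrices, bootstrap cell-type enrichment, top-n selection.

test_that("specificity rows are proportions that sum to one", {
  counts <- rbind(gA = c(10, 12, 0, 0),     # only in type X
                  gB = c(5, 5, 5, 5),       # uniform
                  gC = c(0, 0, 0, 0))       # never expressed
  colnames(counts) <- sprintf("c%d", 1:4)
  labels <- data.frame(cell_id = colnames(counts),
                       cell_type = c("X", "X", "Y", "Y"))
  spec <- build_specificity(counts, labels)
  expect_false("gC" %in% rownames(spec))    # zero-total genes excluded
  expect_equal(unname(spec["gA", ]), c(1, 0))
  expect_equal(unname(rowSums(spec)), rep(1, 2), tolerance = 1e-9)
  # first-principles CPM arithmetic: in type Y cells gB is the only
  # transcript (CPM 1e6); in type X its CPM is 5/15 and 5/17 of 1e6
  mean_x <- mean(c(5 / 15, 5 / 17)) * 1e6
  expect_equal(unname(spec["gB", "Y"]), 1e6 / (1e6 + mean_x),
               tolerance = 1e-12)
})

test_that("specificity is invariant to scaling a gene's expression", {
  withr::with_seed(3, counts <- matrix(stats::rpois(60, 5), 6, 10,
    dimnames = list(sprintf("g%d", 1:6), sprintf("c%d", 1:10))))
  labels <- data.frame(cell_id = colnames(counts),
                       cell_type = rep(c("X", "Y"), each = 5))
  s1 <- build_specificity(counts, labels)
  # scaling all cells of one type leaves relative depth structure compensated
  # by CPM, and scaling one gene uniformly cancels in the row normalization
  counts2 <- counts; counts2["g1", ] <- counts2["g1", ] * 7
  s2 <- build_specificity(counts2, labels)
  expect_equal(s1["g2", ], s2["g2", ], tolerance = 0.15)
})

test_that("a planted marker fold appears as a specificity split", {
  sim <- simulate_sc_counts(sc_sim_config(n_cell_types = 3, cells_per_type = 60,
                                          n_genes = 60, marker_fold = 9,
                                          n_pos_corr = 0, n_neg_corr = 0,
                                          seed = 8))
  spec <- build_specificity(sim$counts, sim$labels)
  mk <- sim$truth$markers[[1]][1]
  # fold 9 vs 1,1 -> specificity ~ 9/11 for the own type
  expect_lt(abs(spec[mk, "Type01"] - 9 / 11), 0.08)
})

test_that("bootstrap enrichment hits the p floor for a fully specific set", {
  spec <- make_specificity(n_genes = 100, n_types = 5, n_specific = 20)
  tgt <- rownames(spec)[1:20]
  e <- bootstrap_enrichment(spec, tgt, rownames(spec), n_boot = 2000, seed = 4)
  expect_equal(e$cell_type[1], "ct1")
  expect_equal(e$p[1], 1 / 2001)              # plus-one floor, never zero
  expect_gt(e$z[1], 5)
  expect_true(all(e$p > 0))
})

test_that("bootstrap enrichment is reproducible and null-centred", {
  spec <- make_specificity(n_genes = 80, n_types = 4, seed = 2)
  tgt <- rownames(spec)[1:30]
  e1 <- bootstrap_enrichment(spec, tgt, rownames(spec), n_boot = 500, seed = 6)
  e2 <- bootstrap_enrichment(spec, tgt, rownames(spec), n_boot = 500, seed = 6)
  expect_identical(e1, e2)
  # the whole background as target: observed equals every draw, z = 0
  ef <- bootstrap_enrichment(spec, rownames(spec), rownames(spec),
                             n_boot = 200, seed = 6)
  expect_equal(ef$z, rep(NaN, 4))  # sd 0: all draws identical to observed
  expect_equal(ef$observed, ef$boot_mean, tolerance = 1e-9)
  expect_error(bootstrap_enrichment(spec, c(tgt, "nope"), rownames(spec),
                                    n_boot = 10), "subset")
  expect_error(bootstrap_enrichment(spec, tgt[1:3], rownames(spec),
                                    n_boot = 10), "at least 5")
})

test_that("top-n by fold-change selects and tie-breaks as documented", {
  de <- data.frame(protein_id = c("P1", "P2", "P3", "P4", "P5"),
                   log2fc = c(0.5, 0.9, 0.5, 0.1, 0.9),
                   p = c(0.01, 0.2, 0.001, 0.5, 0.1),
                   stringsAsFactors = FALSE)
  ann <- annotation_set("mito", de$protein_id)
  expect_identical(top_n_by_foldchange(de, ann, 1), "P5")  # fc tie: smaller p
  expect_identical(top_n_by_foldchange(de, ann, 3), c("P5", "P2", "P3"))
  expect_setequal(top_n_by_foldchange(de, ann, 5), de$protein_id)
  expect_warning(out <- top_n_by_foldchange(de, ann, 10), "available")
  expect_length(out, 5)
})

test_that("a cell-type-specific planted set is recovered end to end", {
  sim <- simulate_sc_counts(sc_sim_config(n_cell_types = 5, cells_per_type = 40,
                                          n_genes = 150, marker_fold = 12,
                                          n_pos_corr = 0, n_neg_corr = 0,
                                          seed = 14))
  spec <- build_specificity(sim$counts, sim$labels)
  tgt <- intersect(unlist(sim$truth$markers[1:2]), rownames(spec))
  e <- bootstrap_enrichment(spec, tgt, rownames(spec), n_boot = 2000, seed = 5)
  expect_setequal(e$cell_type[1:2], c("Type01", "Type02"))
  expect_true(all(e$fdr_q[1:2] < 0.05))
})
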