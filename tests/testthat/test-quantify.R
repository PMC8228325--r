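# Peptide filtering, protein roll-up, normalization, replicate CVs.

test_that("the group-qualification filter applies the stated rule", {
  design <- two_group_design(6)
  # helper: Q matrix from per-group pass counts
  qmat <- function(passA, passB) {
    q <- matrix(0.5, 1, 12)
    if (passA > 0) q[1, seq_len(passA)] <- 1e-4
    if (passB > 0) q[1, 6 + seq_len(passB)] <- 1e-4
    colnames(q) <- design$sample_id
    q
  }
  int <- matrix(100, 1, 12, dimnames = list(NULL, design$sample_id))
  # 5/6 in A, 0/6 in B: one qualifying group of two suffices -> retained
  # (the peptide's protein needs a partner peptide to survive min_peptides)
  pt <- rbind(make_peptide_table(int, qmat(5, 0), "P1"),
              make_peptide_table(int, qmat(6, 6), "P1"))
  pt$peptide_id <- c("pep1", "pep2")
  out <- filter_peptides(pt, design)
  expect_setequal(out$peptide_id, c("pep1", "pep2"))
  # 4/6 in both groups: neither reaches 5/6 -> removed
  pt2 <- rbind(make_peptide_table(int, qmat(4, 4), "P1"),
               make_peptide_table(int, qmat(6, 6), "P1"),
               make_peptide_table(int, qmat(6, 6), "P1"))
  pt2$peptide_id <- c("pep1", "pep2", "pep3")
  out2 <- filter_peptides(pt2, design)
  expect_setequal(out2$peptide_id, c("pep2", "pep3"))
})

test_that("proteins need at least two surviving peptides", {
  design <- two_group_design(6)
  int <- matrix(100, 3, 12, dimnames = list(NULL, design$sample_id))
  q <- matrix(1e-4, 3, 12, dimnames = list(NULL, design$sample_id))
  q[2, ] <- 0.5  # peptide 2 of P1 fails everywhere
  pt <- make_peptide_table(int, q, c("P1", "P1", "P2"))
  expect_warning(out <- filter_peptides(pt, design),
                 "no peptides survive")
  expect_equal(nrow(out), 0L)
  # with a second P2 peptide, P2 survives while P1 is dropped entirely
  pt2 <- make_peptide_table(rbind(int, int[1, , drop = FALSE]),
                            rbind(q, q[3, , drop = FALSE]),
                            c("P1", "P1", "P2", "P2"))
  out2 <- filter_peptides(pt2, design)
  expect_setequal(unique(out2$protein_id), "P2")
})

test_that("unknown samples in the peptide table are a design error", {
  design <- two_group_design(2)
  int <- matrix(1, 1, 4, dimnames = list(NULL, c("A1", "A2", "B1", "XX")))
  q <- matrix(1e-4, 1, 4, dimnames = list(NULL, colnames(int)))
  pt <- make_peptide_table(int, q, "P1")
  expect_error(filter_peptides(pt, design), "XX")
})

test_that("roll-up is log2 of summed raw intensities", {
  design <- two_group_design(1)
  int <- matrix(c(3, 5), 2, 2, dimnames = list(NULL, design$sample_id))
  int[, 2] <- int[, 1] * 2            # sample 2 doubled
  q <- matrix(1e-4, 2, 2, dimnames = list(NULL, design$sample_id))
  pt <- make_peptide_table(int, q, c("P1", "P1"))
  pm <- rollup_proteins(pt)
  expect_equal(unname(pm$log2["P1", 1]), 3)            # log2(3+5)
  expect_equal(unname(pm$log2["P1", 2] - pm$log2["P1", 1]), 1)  # homogeneity
  expect_equal(unname(pm$n_peptides["P1"]), 2L)
})

test_that("roll-up of noiseless data recovers planted sample offsets", {
  cfg <- peptide_sim_config(n_proteins = 30, peptide_sd = 0,
                            sample_offset_sd = 0.3, seed = 8)
  sim <- simulate_peptides(cfg)
  pm <- rollup_proteins(sim$peptides)
  off <- attr(sim$design, "sample_offset")
  # between-sample log2 differences equal the planted offsets, per protein
  d <- sweep(pm$log2, 2L, off[colnames(pm$log2)])
  spread <- apply(d, 1L, function(z) diff(range(z)))
  expect_lt(max(spread), 1e-9)
})

test_that("filter and roll-up are idempotent on their own output", {
  sim <- simulate_peptides(peptide_sim_config(n_proteins = 50, seed = 2,
                                              q_fail_rate = 0.2))
  f1 <- filter_peptides(sim$peptides, sim$design)
  f2 <- filter_peptides(f1, sim$design)
  expect_equal(f1, f2, ignore_attr = TRUE)
})

test_that("cyclic loess leaves identical samples unchanged", {
  x <- matrix(rep(stats::rnorm(200, 20), 2), ncol = 2,
              dimnames = list(sprintf("P%03d", 1:200), c("s1", "s2")))
  pm <- structure(list(log2 = x, n_peptides = rep(2L, 200),
                       normalized = FALSE), class = "protein_matrix")
  out <- cyclic_loess_normalize(pm)
  expect_equal(out$log2, x, tolerance = 1e-10)
  expect_true(out$normalized)
})

test_that("cyclic loess absorbs a constant between-sample offset", {
  withr::with_seed(4, {
    base <- stats::rnorm(300, 20, 1.5)
    x <- cbind(s1 = base, s2 = base + 0.6)
    rownames(x) <- sprintf("P%03d", 1:300)
  })
  pm <- structure(list(log2 = x, n_peptides = rep(2L, 300),
                       normalized = FALSE), class = "protein_matrix")
  out <- cyclic_loess_normalize(pm)
  resid <- out$log2[, "s2"] - out$log2[, "s1"]
  expect_lt(stats::median(abs(resid - mean(resid))), 0.01)
  expect_lt(abs(mean(out$log2) - mean(x)), 0.01)  # grand mean preserved
})

test_that("replicate CVs follow their closed-form cases", {
  design <- two_group_design(3)
  x <- rbind(P1 = log2(c(100, 100, 100, 90, 100, 110)),
             P2 = log2(c(50, 50, 50, 200, 200, 200)))
  colnames(x) <- design$sample_id
  cv <- replicate_cv(x, design)
  expect_equal(unname(cv$per_protein[1, "A"]), 0)
  expect_equal(unname(cv$per_protein[1, "B"]), 0.1)   # sd 10 / mean 100
  expect_equal(unname(cv$median_cv["A"]), 0)
  # groups of size one are excluded
  d1 <- data.frame(sample_id = colnames(x), group = c(rep("A", 5), "B"))
  cv1 <- replicate_cv(x, d1)
  expect_false("B" %in% names(cv1$median_cv))
})

test_that("simulated replicate noise maps onto protein-level CV as derived", {
  # Monte-Carlo oracle: with peptide_sd sigma (log2), a single peptide has
  # raw-scale CV sqrt(exp((sigma*ln2)^2) - 1); summing peptides with
  # spread offsets leaves the roll-up CV at or below that bound
  sigma <- 0.13
  cv_single <- sqrt(exp((sigma * log(2))^2) - 1)
  sim <- simulate_peptides(peptide_sim_config(n_proteins = 300,
                                              peptide_sd = sigma, seed = 15,
                                              sample_offset_sd = 0))
  cv <- replicate_cv(rollup_proteins(sim$peptides), sim$design)
  med <- unname(cv$median_cv["WT"])
  expect_lt(med, cv_single * 1.1)
  expect_gt(med, cv_single / 3)
})
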