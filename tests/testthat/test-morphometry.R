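# Shape metrics, proximity filtering, robust outliers, nested inference,
# mito-presence proportions.

test_that("shape metrics match closed forms and are scale invariant", {
  circ <- shape_metrics(pi * 0.2^2, 2 * pi * 0.2)
  expect_equal(circ$circularity, 1)
  expect_equal(circ$elongation, 1)
  sq <- shape_metrics(1, 4)
  expect_equal(sq$circularity, pi / 4, tolerance = 1e-12)
  expect_equal(sq$elongation, 4 / pi, tolerance = 1e-12)
  # scale invariance: A -> k^2 A, P -> k P
  k <- 3.7
  expect_equal(shape_metrics(k^2 * 1, k * 4), sq)
  expect_error(shape_metrics(1, 3), "isoperimetric")
})

test_that("ellipse elongation agrees with a numeric-perimeter oracle", {
  # 2:1 ellipse, a = 0.4, b = 0.2 um; perimeter by numeric integration
  a <- 0.4; b <- 0.2
  P_ram <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  A <- pi * a * b
  m <- shape_metrics(A, P_ram)
  arc <- function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2)
  P_int <- 4 * stats::integrate(arc, 0, pi / 2, rel.tol = 1e-12)$value
  expect_lt(abs(m$elongation - P_int^2 / (4 * pi * A)) /
              (P_int^2 / (4 * pi * A)), 0.01)
  expect_lt(abs(m$elongation - 1.19) / 1.19, 0.01)
})

test_that("the proximity rule drops only distant mitochondria", {
  rec <- make_morpho_records(rep(c("A1", "A2"), each = 2),
                             rep(c("WT", "KO"), each = 2),
                             area = rep(0.05, 4), perimeter = rep(1, 4),
                             distance = c(499, 501, 100, 600))
  out <- proximity_filter(rec, 500)
  expect_equal(out$has_mito, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(attr(out, "n_excluded"), 2L)
  expect_equal(nrow(out), 4L)                     # synapse rows kept
  expect_identical(proximity_filter(rec, Inf)$has_mito, rec$has_mito)
  rec$distance_nm[1] <- -5
  expect_error(proximity_filter(rec), "negative")
})

test_that("uniform distances 0-600 nm keep about five sixths at 500 nm", {
  cfg <- morpho_sim_config(seed = 44, synapses_per_animal = 200,
                           p_mito = c(WT = 0.5, KO = 0.5))
  rec <- simulate_morphometry(cfg)$records
  out <- proximity_filter(rec, 500)
  frac <- sum(out$has_mito) / sum(rec$has_mito)
  n <- sum(rec$has_mito)
  se <- sqrt((5 / 6) * (1 / 6) / n)
  expect_lt(abs(frac - 5 / 6), 4 * se)
})

test_that("robust outlier flagging catches planted contamination only", {
  withr::with_seed(12, x <- stats::rnorm(20))
  x[7] <- 10
  ro <- robust_outliers(x, q = 0.01)
  expect_identical(ro$idx_flagged, 7L)
  expect_length(ro$clean, 19)
  # constant vector: no outliers
  ro0 <- robust_outliers(rep(2, 10))
  expect_length(ro0$idx_flagged, 0)
  expect_error(robust_outliers(c(1, 2, 3)), "at least 5")
})

test_that("robust outlier false-positive rate is controlled on clean data", {
  reps <- 100
  n_flagged <- integer(reps)
  for (r in seq_len(reps)) {
    withr::with_seed(6000 + r, x <- stats::rnorm(100))
    n_flagged[r] <- length(robust_outliers(x, q = 0.01)$idx_flagged)
  }
  expect_gte(mean(n_flagged <= 2), 0.95)
})

test_that("with no animal variance the nested estimate is the mean difference", {
  cfg <- morpho_sim_config(seed = 17, animal_sd = 0,
                           p_mito = c(WT = 0.6, KO = 0.6))
  rec <- simulate_morphometry(cfg)$records
  nt <- nested_genotype_test(rec, "area", "post")
  d <- rec[rec$has_mito & rec$compartment == "post", ]
  diff_means <- mean(d$area_um2[d$genotype == "KO"]) -
    mean(d$area_um2[d$genotype == "WT"])
  expect_lt(abs(nt$estimate - diff_means), 1e-6)
  expect_true(nt$singular)                # sigma_a -> 0 flagged
  expect_equal(nt$df, 10)                 # 12 animals - 2
})

test_that("the nested test is invariant to animal relabeling", {
  cfg <- morpho_sim_config(seed = 23, animal_sd = 0.2)
  rec <- simulate_morphometry(cfg)$records
  nt1 <- nested_genotype_test(rec, "elongation", "post")
  rec2 <- rec[rev(seq_len(nrow(rec))), ]
  map <- stats::setNames(sprintf("animal%02d", seq_along(unique(rec$animal_id))),
                         unique(rec$animal_id))
  rec2$animal_id <- unname(map[rec2$animal_id])
  nt2 <- nested_genotype_test(rec2, "elongation", "post")
  # reversing row order also flips the genotype reference level, so the
  # contrast changes sign; magnitude and p-value are invariant
  expect_equal(abs(nt1$estimate), abs(nt2$estimate), tolerance = 1e-6)
  expect_equal(nt1$p.value, nt2$p.value, tolerance = 1e-6)
})

test_that("mito presence compares per-animal fractions across genotypes", {
  cfg <- morpho_sim_config(seed = 31, synapses_per_animal = 200,
                           p_mito = c(WT = 0.36, KO = 0.42))
  pres <- mito_presence_test(simulate_morphometry(cfg)$records)
  expect_lt(abs(pres$genotype_mean_pct[["WT"]] - 36), 4)
  expect_lt(abs(pres$genotype_mean_pct[["KO"]] - 42), 4)
  # all synapses occupied in both genotypes: p reported as 1 with a flag
  cfg2 <- morpho_sim_config(seed = 32, p_mito = c(WT = 1, KO = 1))
  pres2 <- mito_presence_test(simulate_morphometry(cfg2)$records)
  expect_equal(unname(pres2$genotype_mean_pct), c(100, 100))
  expect_true(pres2$zero_variance)
  expect_equal(pres2$p.value, 1)
})

test_that("the full morphometry pipeline runs in the fixed order", {
  cfg <- morpho_sim_config(seed = 41, outlier_rate = 0.05, outlier_scale = 30)
  rec <- simulate_morphometry(cfg)$records
  res <- morpho_analyze(rec, "area", "post", log_scale = TRUE)
  expect_s3_class(res$nested, "nested_test")
  expect_s3_class(res$presence, "mito_presence")
  expect_gt(res$n_outliers_removed, 0)
})
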