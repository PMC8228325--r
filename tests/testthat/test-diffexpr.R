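# Empirical-Bayes moderated t: group summaries, prior estimation,
# moderation, and agreement with an independent reference implementation.

test_that("group summaries match closed-form cases", {
  design <- two_group_design(3)
  x <- rbind(P1 = c(1, 1, 1, 2, 2, 2),
             P2 = c(0, 1, 2, 3, 4, 5))
  colnames(x) <- design$sample_id
  st <- fit_group_stats(x, design, "A", "B")
  expect_equal(st$log2fc, c(1, 3))
  expect_equal(st$s2_g, c(0, 1))
  expect_equal(st$df_g, c(4, 4))
})

test_that("pooled variances follow the chi-squared sampling distribution", {
  withr::with_seed(99, {
    n <- 2000
    x <- matrix(stats::rnorm(n * 12, sd = 1), n, 12,
                dimnames = list(sprintf("P%04d", 1:n), two_group_design(6)$sample_id))
  })
  st <- fit_group_stats(x, two_group_design(6), "A", "B")
  ks <- stats::ks.test(st$s2_g * st$df_g, function(q) stats::pchisq(q, df = 10))
  expect_gt(ks$p.value, 0.01)
})

test_that("trigamma_inverse inverts trigamma and matches limma", {
  y <- c(1e-5, 0.01, 0.5, 2, 10, 1e8)
  x <- trigamma_inverse(y)
  expect_equal(trigamma(x), y, tolerance = 1e-6)
  expect_equal(x, limma::trigammaInverse(y), tolerance = 1e-6)
})

test_that("prior estimation handles the degenerate equal-variance case", {
  pr <- estimate_prior(c(2, 2), df = 4)
  expect_identical(pr$d0, Inf)
  expect_gt(pr$s0_sq, 0)
  expect_error(estimate_prior(c(0, 0), 4), "zero")
})

test_that("variances from one scaled chi-squared give a near-infinite prior df", {
  withr::with_seed(21, s2 <- stats::rchisq(5000, 4) / 4)
  pr <- estimate_prior(s2, 4)
  expect_true(is.infinite(pr$d0) || pr$d0 > 50)
  expect_lt(abs(pr$s0_sq - 1), 0.05)
})

test_that("moderation interpolates between ordinary t and pure prior", {
  design <- two_group_design(6)
  withr::with_seed(31, {
    x <- matrix(stats::rnorm(100 * 12, mean = 20), 100, 12,
                dimnames = list(sprintf("P%03d", 1:100), design$sample_id))
  })
  st <- fit_group_stats(x, design, "A", "B")
  # d0 = 0: exactly the ordinary pooled two-sample t
  de0 <- moderated_t(st, list(d0 = 0, s0_sq = 1))
  tt <- apply(x, 1, function(r)
    stats::t.test(r[7:12], r[1:6], var.equal = TRUE)$statistic)
  expect_equal(de0$t_mod, unname(tt), tolerance = 1e-10)
  # d0 = Inf: common variance; |t| ordering equals |log2fc| ordering
  deI <- moderated_t(st, list(d0 = Inf, s0_sq = 0.7))
  expect_equal(deI$s2_post, rep(0.7, 100))
  expect_identical(order(abs(deI$t_mod)), order(abs(deI$log2fc)))
  # s2_post increases strictly with s2_g for a fixed finite prior
  pr <- list(d0 = 4, s0_sq = 1)
  s2 <- seq(0.1, 3, length.out = 20)
  post <- (pr$d0 * pr$s0_sq + 10 * s2) / (pr$d0 + 10)
  expect_true(all(diff(post) > 0))
  expect_true(all(post > pmin(s2, 1) & post < pmax(s2, 1)))
})

test_that("the full fit agrees with the limma reference implementation", {
  design <- two_group_design(6)
  withr::with_seed(77, {
    x <- matrix(stats::rnorm(500 * 12, mean = 20, sd = 0.4), 500, 12,
                dimnames = list(sprintf("P%04d", 1:500), design$sample_id))
    x[1:50, 7:12] <- x[1:50, 7:12] + 0.5
  })
  fit <- modt_fit(x, design, "A", "B")
  dm <- cbind(1, design$group == "B")
  lfit <- limma::eBayes(limma::lmFit(x, dm))
  expect_equal(fit$prior$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(fit$prior$s0_sq, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(fit$table$t_mod, unname(lfit$t[, 2]), tolerance = 1e-8)
  expect_equal(fit$table$p, unname(lfit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(fit$table$log2fc, unname(lfit$coefficients[, 2]),
               tolerance = 1e-10)
})

test_that("moderation beats the unmoderated t at small n with weak effects", {
  design <- two_group_design(6)
  reps <- 60
  power_mod <- power_plain <- numeric(reps)
  for (r in seq_len(reps)) {
    withr::with_seed(8000 + r, {
      x <- matrix(stats::rnorm(300 * 12, mean = 20, sd = 0.13), 300, 12,
                  dimnames = list(sprintf("P%03d", 1:300), design$sample_id))
      x[1:60, 7:12] <- x[1:60, 7:12] + 0.2
    })
    st <- fit_group_stats(x, design, "A", "B")
    pr <- estimate_prior(st$s2_g, st$df_g)
    de <- moderated_t(st, pr)
    de0 <- moderated_t(st, list(d0 = 0, s0_sq = 1))
    power_mod[r] <- mean(de$p[1:60] < 0.01)
    power_plain[r] <- mean(de0$p[1:60] < 0.01)
  }
  expect_gt(mean(power_mod), mean(power_plain))
})

test_that("proteins absent in one group get the floor convention and a flag", {
  design <- two_group_design(3)
  x <- rbind(P1 = c(10, 10.5, 10.2, NA, NA, NA),
             P2 = c(12, 12.1, 11.9, 12.2, 12.0, 11.8),
             P3 = c(8, 8.1, 7.9, 9, 9.2, 8.8))
  colnames(x) <- design$sample_id
  st <- fit_group_stats(x, design, "A", "B")
  i <- which(st$protein_id == "P1")
  expect_equal(st$absent_in[i], "B")
  expect_equal(st$log2fc[i], 7.9 - mean(c(10, 10.5, 10.2)))  # floor = min obs
  expect_true(is.na(st$s2_g[i]))
  de <- moderated_t(st[-i, ], estimate_prior(st$s2_g[-i], st$df_g[-i]))
  expect_true(all(is.finite(de$t_mod)))
})
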