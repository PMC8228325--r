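# Two-group differential expression with empirical-Bayes moderated
# t-statistics, written from first principles.
#
# Model: per protein g, the pooled two-group residual variance s2_g on
# df_g degrees of freedom is shrunk toward a prior variance s0^2 with
# prior degrees of freedom d0 estimated across proteins by method of
# moments on log variances:
#
#   e_g  = log(s2_g) - digamma(df_g/2) + log(df_g/2)
#   var(e_g) - mean(trigamma(df_g/2))  -> solve trigamma(d0/2) = excess
#   s0^2 = exp( mean(e_g) + digamma(d0/2) - log(d0/2) )
#
# The posterior variance is the df-weighted blend
#   s2_post = (d0 * s0^2 + df_g * s2_g) / (d0 + df_g)
# and the moderated t uses d0 + df_g degrees of freedom. d0 = 0 recovers
# the ordinary pooled t exactly; d0 = Inf gives every protein the same
# variance s0^2.

#' Per-protein two-group summary statistics
#'
#' Computes group means, log2 fold-change (`g2 - g1`), pooled residual
#' variance and its degrees of freedom for every protein with at least two
#' finite values per group. Proteins measured in only one group (at least
#' `min_per_group` finite values there, none in the other) are retained
#' with an `absent_in` flag; their fold-change is computed against the
#' global minimum observed abundance (an explicit detection-floor
#' convention) and they carry no variance or test statistic.
#'
#' @param pm A `protein_matrix` (or log2 matrix).
#' @param design data.frame with `sample_id`, `group`.
#' @param g1,g2 Group labels to contrast; fold-changes are `g2 - g1`.
#' @param min_per_group Minimum finite values required per group.
#' @return data.frame with columns `protein_id`, `mean_g1`, `mean_g2`,
#'   `avg_abundance`, `log2fc`, `s2_g`, `df_g`, `n1`, `n2`, `absent_in`.
#'   Proteins with insufficient replication in both groups are dropped and
#'   listed in the `excluded` attribute.
#' @export
fit_group_stats <- function(pm, design, g1, g2, min_per_group = 2L) {
  m <- if (inherits(pm, "protein_matrix")) pm$log2 else as.matrix(pm)
  grp <- design$group[match(colnames(m), design$sample_id)]
  if (!all(c(g1, g2) %in% grp)) {
    stop("contrast groups not present in design", call. = FALSE)
  }
  m1 <- m[, grp == g1, drop = FALSE]
  m2 <- m[, grp == g2, drop = FALSE]
  n1 <- rowSums(is.finite(m1))
  n2 <- rowSums(is.finite(m2))
  mu1 <- rowMeans(m1, na.rm = TRUE)
  mu2 <- rowMeans(m2, na.rm = TRUE)
  v1 <- apply(m1, 1L, stats::var, na.rm = TRUE)
  v2 <- apply(m2, 1L, stats::var, na.rm = TRUE)

  both <- n1 >= min_per_group & n2 >= min_per_group
  only1 <- n1 >= min_per_group & n2 == 0L
  only2 <- n2 >= min_per_group & n1 == 0L
  floor_val <- min(m, na.rm = TRUE)

  res <- data.frame(protein_id = rownames(m),
                    mean_g1 = mu1, mean_g2 = mu2,
                    avg_abundance = rowMeans(cbind(mu1, mu2)),
                    log2fc = mu2 - mu1,
                    s2_g = ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2),
                    df_g = n1 + n2 - 2,
                    n1 = n1, n2 = n2,
                    absent_in = NA_character_,
                    stringsAsFactors = FALSE)
  if (any(only1)) {
    res$absent_in[only1] <- g2
    res$log2fc[only1] <- floor_val - mu1[only1]
    res$s2_g[only1] <- NA_real_; res$df_g[only1] <- NA_real_
  }
  if (any(only2)) {
    res$absent_in[only2] <- g1
    res$log2fc[only2] <- mu2[only2] - floor_val
    res$s2_g[only2] <- NA_real_; res$df_g[only2] <- NA_real_
  }
  keep <- both | only1 | only2
  out <- res[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- res$protein_id[!keep]
  attr(out, "contrast") <- c(g1 = g1, g2 = g2)
  out
}

#' Estimate the variance prior across proteins
#'
#' Method-of-moments fit of a scaled inverse-chi-squared prior to the
#' observed residual variances on the log scale (see the header of this
#' file for the moment equations). When the empirical spread of log
#' variances does not exceed what sampling alone explains, the prior
#' degrees of freedom are infinite and the prior variance is the
#' (bias-corrected) geometric mean of the observed variances.
#'
#' @param s2 Per-protein residual variances (positive; non-positive values
#'   are dropped with a warning).
#' @param df Residual degrees of freedom (scalar or vector).
#' @return List of class `variance_prior` with `d0` (possibly `Inf`),
#'   `s0_sq`, and `n_used`.
#' @export
estimate_prior <- function(s2, df) {
  if (length(df) == 1L) df <- rep(df, length(s2))
  ok <- is.finite(s2) & is.finite(df) & s2 > 0 & df > 0
  if (sum(!is.finite(s2) | s2 <= 0, na.rm = TRUE) > 0) {
    if (!any(ok)) stop("all variances are zero or missing", call. = FALSE)
  }
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2L) stop("need at least two positive variances", call. = FALSE)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  excess <- stats::var(e) - mean(trigamma(df / 2))
  if (is.na(excess) || excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_used = length(s2)),
            class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("variance prior: d0 = %s, s0^2 = %.4g (from %d proteins)\n",
              format(x$d0, digits = 4), x$s0_sq, x$n_used))
  invisible(x)
}

#' Moderated t-statistics from group summaries and a variance prior
#'
#' Blends each protein's residual variance with the prior, forms the
#' moderated t on `d0 + df_g` degrees of freedom, and calls regulation by
#' sign at `p < p_threshold`. No multiple-testing correction is applied:
#' the unadjusted threshold deliberately admits more proteins into the
#' downstream annotation-level analyses, which aggregate over sets rather
#' than interpret single proteins.
#'
#' @param stats Output of [fit_group_stats()].
#' @param prior A `variance_prior` (or list with `d0`, `s0_sq`); `d0 = 0`
#'   is accepted as the no-moderation limiting case.
#' @param p_threshold Regulation-call threshold on the unadjusted p-value.
#' @return data.frame (the `DEResult` table): `protein_id`, `log2fc`,
#'   `avg_abundance`, `s2_g`, `df_g`, `s2_post`, `t_mod`, `df_total`, `p`,
#'   `regulated`, `absent_in`.
#' @export
moderated_t <- function(stats, prior, p_threshold = 0.01) {
  d0 <- prior$d0; s0 <- prior$s0_sq
  if (is.na(d0) || d0 < 0 || is.na(s0) || s0 <= 0) {
    stop("invalid variance prior", call. = FALSE)
  }
  s2_post <- if (is.infinite(d0)) rep(s0, nrow(stats)) else
    (d0 * s0 + stats$df_g * stats$s2_g) / (d0 + stats$df_g)
  df_total <- d0 + stats$df_g
  if (any(df_total <= 0, na.rm = TRUE)) {
    stop("non-positive total degrees of freedom", call. = FALSE)
  }
  se <- sqrt(s2_post * (1 / stats$n1 + 1 / stats$n2))
  t_mod <- stats$log2fc / se
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  regulated <- rep("none", nrow(stats))
  regulated[!is.na(p) & p < p_threshold & stats$log2fc > 0] <- "up"
  regulated[!is.na(p) & p < p_threshold & stats$log2fc < 0] <- "down"
  out <- data.frame(protein_id = stats$protein_id,
                    log2fc = stats$log2fc,
                    avg_abundance = stats$avg_abundance,
                    s2_g = stats$s2_g, df_g = stats$df_g,
                    s2_post = s2_post, t_mod = t_mod,
                    df_total = df_total, p = p,
                    regulated = regulated,
                    absent_in = stats$absent_in,
                    stringsAsFactors = FALSE)
  attr(out, "prior") <- prior
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Fit the full two-group moderated-t model
#'
#' Convenience wrapper chaining [fit_group_stats()], [estimate_prior()]
#' and [moderated_t()] into a classed fit with print, summary and volcano
#' plot methods.
#'
#' @inheritParams fit_group_stats
#' @inheritParams moderated_t
#' @return Object of class `modt`: list with `table` (the DEResult
#'   data.frame), `prior`, `contrast`, `p_threshold`.
#' @examples
#' sim <- simulate_peptides(peptide_sim_config(effect_log2 = 0.5, seed = 1))
#' pm <- cyclic_loess_normalize(rollup_proteins(
#'   filter_peptides(sim$peptides, sim$design)))
#' fit <- modt_fit(pm, sim$design, "WT", "KO")
#' fit
#' @export
modt_fit <- function(pm, design, g1, g2, p_threshold = 0.01) {
  st <- fit_group_stats(pm, design, g1, g2)
  prior <- estimate_prior(st$s2_g, st$df_g)
  tab <- moderated_t(st, prior, p_threshold)
  structure(list(table = tab, prior = prior,
                 contrast = c(g1 = g1, g2 = g2),
                 p_threshold = p_threshold),
            class = "modt")
}

#' @export
print.modt <- function(x, ...) {
  tab <- x$table
  cat(sprintf("Moderated t contrast %s - %s: %d proteins\n",
              x$contrast["g2"], x$contrast["g1"], nrow(tab)))
  cat(sprintf("  prior: d0 = %s, s0^2 = %.4g\n",
              format(x$prior$d0, digits = 4), x$prior$s0_sq))
  cat(sprintf("  regulated at p < %g: %d up, %d down\n", x$p_threshold,
              sum(tab$regulated == "up"), sum(tab$regulated == "down")))
  invisible(x)
}

#' @export
summary.modt <- function(object, ...) {
  tab <- object$table
  top <- tab[order(tab$p), ]
  structure(list(contrast = object$contrast, prior = object$prior,
                 n = nrow(tab),
                 n_up = sum(tab$regulated == "up"),
                 n_down = sum(tab$regulated == "down"),
                 top = utils::head(top, 10L)),
            class = "summary.modt")
}

#' @export
print.summary.modt <- function(x, ...) {
  cat(sprintf("Moderated t contrast %s - %s\n", x$contrast["g2"],
              x$contrast["g1"]))
  cat(sprintf("  %d proteins tested; %d up, %d down\n", x$n, x$n_up, x$n_down))
  cat("  top proteins by p-value:\n")
  print(x$top[, c("protein_id", "log2fc", "t_mod", "p", "regulated")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.modt <- function(object, ...) {
  stats::setNames(object$table$log2fc, object$table$protein_id)
}

#' Volcano plot of a moderated-t fit
#'
#' @param x A `modt` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.modt <- function(x, ...) {
  tab <- x$table
  col <- ifelse(tab$regulated == "up", "firebrick",
                ifelse(tab$regulated == "down", "steelblue", "grey60"))
  graphics::plot(tab$log2fc, -log10(tab$p), col = col, pch = 16, cex = 0.6,
                 xlab = "log2 fold-change", ylab = "-log10 p", ...)
  graphics::abline(h = -log10(x$p_threshold), lty = 2)
  invisible(x)
}

# Coerce a modt fit or a DEResult data.frame to the plain table.
as_de_table <- function(de) {
  if (inherits(de, "modt")) de$table
  else if (is.data.frame(de) && all(c("protein_id", "log2fc") %in% names(de))) de
  else stop("expected a 'modt' fit or a DEResult data.frame", call. = FALSE)
}
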