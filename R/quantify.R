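# Peptide-level quality control and protein quantification.
#
# The pipeline enters at a peptide table (one row per peptide, wide
# intensity_<sample> / qvalue_<sample> columns). Identification confidence
# filtering happens at the peptide-sample level, roll-up sums raw peptide
# intensities per protein, and normalization is cyclic loess on the log2
# protein matrix.

# Extract the sample names and the intensity / Q-value matrices from a
# wide peptide table.
pt_samples <- function(pt) {
  sub("^intensity_", "", grep("^intensity_", names(pt), value = TRUE))
}

pt_matrix <- function(pt, what = c("intensity", "qvalue")) {
  what <- match.arg(what)
  cols <- grep(paste0("^", what, "_"), names(pt), value = TRUE)
  m <- as.matrix(pt[, cols, drop = FALSE])
  colnames(m) <- sub(paste0("^", what, "_"), "", cols)
  rownames(m) <- pt$peptide_id
  m
}

#' Filter peptides by identification confidence and peptide support
#'
#' A peptide is retained when its measurement passes the Q-value threshold
#' in "enough" samples of "enough" groups: a group qualifies when at least
#' `group size - allowed_outliers_per_group` of its samples have Q-value
#' `<= q_max`, and the peptide is kept when at least half of the groups
#' (rounded up) qualify. Afterwards, proteins supported by fewer than
#' `min_peptides` surviving peptides are removed together with their
#' peptides. With two groups, "half of the groups" is one group, so a
#' protein confidently measured in only one condition (e.g. a knocked-out
#' gene product) survives the filter.
#'
#' @param pt Peptide table (data.frame with `peptide_id`, `protein_id`,
#'   wide `intensity_*` and `qvalue_*` columns).
#' @param design data.frame with `sample_id` and `group`; every sample in
#'   `pt` must appear.
#' @param q_max Q-value confidence threshold (default 1e-3).
#' @param min_peptides Minimum surviving peptides per retained protein.
#' @param allowed_outliers_per_group Samples per group allowed to miss the
#'   threshold while the group still qualifies.
#' @return The filtered peptide table, with attributes `n_peptides_in`,
#'   `n_peptides_out`, `n_proteins_out` recording the filter log.
#' @examples
#' sim <- simulate_peptides(peptide_sim_config(n_proteins = 30, seed = 1))
#' flt <- filter_peptides(sim$peptides, sim$design)
#' @export
filter_peptides <- function(pt, design, q_max = 1e-3, min_peptides = 2L,
                            allowed_outliers_per_group = 1L) {
  samples <- pt_samples(pt)
  if (!all(samples %in% design$sample_id)) {
    stop("samples in peptide table missing from design: ",
         paste(setdiff(samples, design$sample_id), collapse = ", "),
         call. = FALSE)
  }
  stop_if_not_fraction(q_max, "q_max")
  stop_if_not_count(min_peptides, "min_peptides")
  stop_if_not_count(allowed_outliers_per_group, "allowed_outliers_per_group",
                    min = 0L)
  q <- pt_matrix(pt, "qvalue")
  grp <- design$group[match(colnames(q), design$sample_id)]
  groups <- unique(grp)
  qualifies <- vapply(groups, function(g) {
    cols <- which(grp == g)
    rowSums(q[, cols, drop = FALSE] <= q_max, na.rm = TRUE) >=
      (length(cols) - allowed_outliers_per_group)
  }, logical(nrow(q)))
  if (is.null(dim(qualifies))) qualifies <- matrix(qualifies, nrow = 1L)
  keep_pep <- rowSums(qualifies) >= ceiling(length(groups) / 2)

  kept <- pt[keep_pep, , drop = FALSE]
  tab <- table(kept$protein_id)
  good_prot <- names(tab)[tab >= min_peptides]
  out <- kept[kept$protein_id %in% good_prot, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("no peptides survive filtering; returning an empty table",
            call. = FALSE)
  }
  attr(out, "n_peptides_in") <- nrow(pt)
  attr(out, "n_peptides_out") <- nrow(out)
  attr(out, "n_proteins_out") <- length(good_prot)
  out
}

#' Roll peptides up to a protein-level log2 abundance matrix
#'
#' Protein abundance in a sample is the log2 of the summed raw peptide
#' intensities of that protein in that sample. Samples where a protein's
#' total intensity is zero (or all measurements missing) become `NA` and
#' are counted in the `n_flagged_missing` attribute.
#'
#' @param pt Filtered peptide table.
#' @param method `"sum"` (log2 of summed raw intensities, default) or
#'   `"mean_log2"` (mean of per-peptide log2 intensities).
#' @return Object of class `protein_matrix`: list with `log2` (protein x
#'   sample matrix), `n_peptides` (named integer vector) and `normalized`
#'   flag.
#' @examples
#' sim <- simulate_peptides(peptide_sim_config(n_proteins = 10, seed = 1))
#' pm <- rollup_proteins(sim$peptides)
#' pm$log2[1:3, 1:2]
#' @export
rollup_proteins <- function(pt, method = c("sum", "mean_log2")) {
  method <- match.arg(method)
  if (nrow(pt) == 0L) stop("empty peptide table", call. = FALSE)
  m <- pt_matrix(pt, "intensity")
  f <- factor(pt$protein_id, levels = unique(pt$protein_id))
  if (method == "sum") {
    agg <- rowsum(m, f, na.rm = TRUE)
    log2m <- log2(agg)
    log2m[!is.finite(log2m)] <- NA_real_
  } else {
    lg <- log2(m)
    lg[!is.finite(lg)] <- NA_real_
    agg <- rowsum(lg, f, na.rm = TRUE)
    cnt <- rowsum((!is.na(lg)) * 1, f)
    log2m <- agg / cnt
    log2m[cnt == 0] <- NA_real_
  }
  n_pep <- as.integer(table(f))
  names(n_pep) <- levels(f)
  structure(list(log2 = log2m,
                 n_peptides = n_pep,
                 normalized = FALSE,
                 n_flagged_missing = sum(is.na(log2m))),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix: %d proteins x %d samples (%snormalized)\n",
              nrow(x$log2), ncol(x$log2), if (x$normalized) "" else "not "))
  invisible(x)
}

#' Cyclic loess normalization of a protein matrix
#'
#' Applies the fast variant of cyclic loess: in each iteration, every
#' sample's log-ratio against the across-sample mean profile (M) is
#' loess-smoothed against average abundance (A) and the fitted curve is
#' subtracted. This removes smooth intensity-dependent biases between
#' samples while leaving within-sample rank structure essentially intact.
#' The fit is delegated to the limma implementation.
#'
#' @param pm A `protein_matrix`.
#' @param iterations Number of cyclic passes (default 10).
#' @param span Loess span (default 0.7).
#' @return The normalized `protein_matrix` (`normalized = TRUE`). Samples
#'   with fewer than 10 finite values are left unnormalized with a warning.
#' @examples
#' sim <- simulate_peptides(peptide_sim_config(seed = 1,
#'   intensity_bias_amplitude = 0.3))
#' pm <- cyclic_loess_normalize(rollup_proteins(sim$peptides))
#' @export
cyclic_loess_normalize <- function(pm, iterations = 10L, span = 0.7) {
  stopifnot(inherits(pm, "protein_matrix"))
  stop_if_not_count(iterations, "iterations")
  if (ncol(pm$log2) < 2L) stop("need at least two samples", call. = FALSE)
  n_finite <- colSums(is.finite(pm$log2))
  skip <- n_finite < 10L
  out <- limma::normalizeCyclicLoess(pm$log2, span = span,
                                     iterations = iterations,
                                     method = "fast")
  dimnames(out) <- dimnames(pm$log2)
  if (any(skip)) {
    warning("samples with <10 finite values left unnormalized: ",
            paste(colnames(pm$log2)[skip], collapse = ", "), call. = FALSE)
    out[, skip] <- pm$log2[, skip]
  }
  pm$log2 <- out
  pm$normalized <- TRUE
  pm
}

#' Within-group replicate coefficients of variation
#'
#' CV is computed per protein and group on the raw intensity scale
#' (`2^log2`), as sd/mean over the group's replicates; the per-group
#' summary is the median CV over proteins. Groups with fewer than two
#' finite replicate values for a protein yield `NA` for that protein, and
#' groups of size one are excluded entirely.
#'
#' @param pm A `protein_matrix` (or plain log2 matrix).
#' @param design data.frame with `sample_id`, `group`.
#' @return List with `per_protein` (data.frame, one CV column per group)
#'   and `median_cv` (named numeric, per-group median CV).
#' @examples
#' sim <- simulate_peptides(peptide_sim_config(seed = 1))
#' replicate_cv(rollup_proteins(sim$peptides), sim$design)$median_cv
#' @export
replicate_cv <- function(pm, design) {
  m <- if (inherits(pm, "protein_matrix")) pm$log2 else as.matrix(pm)
  raw <- 2^m
  grp <- design$group[match(colnames(raw), design$sample_id)]
  groups <- unique(grp)
  sizes <- table(grp)[groups]
  groups <- groups[sizes >= 2L]
  cvs <- vapply(groups, function(g) {
    sub <- raw[, grp == g, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    n_ok <- rowSums(!is.na(sub))
    out <- sdv / mu
    out[n_ok < 2L] <- NA_real_
    out
  }, numeric(nrow(raw)))
  per_protein <- data.frame(protein_id = rownames(raw), cvs,
                            stringsAsFactors = FALSE, check.names = FALSE)
  list(per_protein = per_protein,
       median_cv = apply(as.matrix(cvs), 2L, stats::median, na.rm = TRUE))
}
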