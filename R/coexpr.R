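# Cell-type co-expression screen against a target gene (a Grm5-like
# receptor transcript): per-cell-type expression profiles followed by a
# genome-wide Spearman correlation with FDR control.

#' Build per-cell-type expression profiles
#'
#' Per cell: counts are converted to counts per million and log10
#' transformed with pseudo-count 1. Per gene and cell type: the mean is
#' taken over cells with a nonzero value only; a gene never detected in a
#' type gets `NA` there (and is excluded pairwise from correlations).
#' Finally each cell-type column is divided by its median over non-missing
#' genes. Spearman correlations downstream are invariant to this per-column
#' monotone scaling; it only standardizes the intermediate values.
#'
#' @param counts Gene-by-cell count matrix.
#' @param labels data.frame with `cell_id`, `cell_type`.
#' @param exclude Cell-type labels dropped as uninformative. The default
#'   names the conventional quality-control labels of cortical single-cell
#'   atlases.
#' @return Gene-by-cell-type matrix of class `celltype_profile`, with
#'   attributes `excluded` and `n_cells_dropped` (zero-count cells).
#' @export
build_profiles <- function(counts, labels,
                           exclude = c("Low quality", "Batch grouping",
                                       "High intronic", "Doublet")) {
  if (!all(colnames(counts) %in% labels$cell_id)) {
    stop("labels do not cover all cells", call. = FALSE)
  }
  type <- labels$cell_type[match(colnames(counts), labels$cell_id)]
  keep <- !(type %in% exclude)
  if (!any(keep)) stop("no cells left after exclusion", call. = FALSE)
  counts <- counts[, keep, drop = FALSE]
  type <- type[keep]
  depth <- colSums(counts)
  dropped <- sum(depth == 0)
  if (dropped > 0) {
    counts <- counts[, depth > 0, drop = FALSE]
    type <- type[depth > 0]
    depth <- depth[depth > 0]
  }
  cpm <- sweep(counts, 2L, depth / 1e6, "/")
  lg <- log10(cpm + 1)
  types <- unique(type)
  prof <- vapply(types, function(ty) {
    sub <- lg[, type == ty, drop = FALSE]
    nz <- sub != 0
    s <- rowSums(sub * nz)
    n <- rowSums(nz)
    out <- s / n
    out[n == 0] <- NA_real_
    out
  }, numeric(nrow(lg)))
  colnames(prof) <- types
  med <- apply(prof, 2L, stats::median, na.rm = TRUE)
  prof <- sweep(prof, 2L, med, "/")
  structure(prof, class = c("celltype_profile", class(prof)),
            excluded = exclude, n_cells_dropped = dropped)
}

#' Genome-wide Spearman screen against a target gene
#'
#' Correlates every gene's cell-type profile with the target's by Spearman
#' rank correlation over pairwise-complete cell types (minimum 3),
#' computes two-sided p-values from the t approximation, adjusts by
#' Benjamini-Hochberg across all tested genes, and calls significance at
#' `fdr_q`. An optional annotation partitions results (e.g. mitochondrial
#' vs non-mitochondrial genes) with per-partition summaries.
#'
#' @param profiles A `celltype_profile` matrix.
#' @param target_gene Row name of the target.
#' @param partition Optional `annotation_set`; adds an `in_set` column and
#'   per-partition summaries.
#' @param fdr_q Significance threshold on the adjusted q-value.
#' @return List of class `coexpr_screen`: `table` (gene, rho, n, p, fdr_q,
#'   significant, optionally in_set), `target_gene`, `partition_summary`
#'   (or NULL).
#' @export
spearman_screen <- function(profiles, target_gene, partition = NULL,
                            fdr_q = 0.05) {
  if (!target_gene %in% rownames(profiles)) {
    stop("target gene not found in profiles", call. = FALSE)
  }
  tv <- profiles[target_gene, ]
  if (sum(is.finite(tv)) < 3L) {
    stop("target gene has fewer than 3 cell-type values", call. = FALSE)
  }
  if (stats::sd(tv, na.rm = TRUE) == 0) {
    stop("target gene is constant across cell types; rho undefined",
         call. = FALSE)
  }
  others <- setdiff(rownames(profiles), target_gene)
  rho <- n_used <- rep(NA_real_, length(others))
  for (i in seq_along(others)) {
    gv <- profiles[others[i], ]
    ok <- is.finite(tv) & is.finite(gv)
    if (sum(ok) < 3L) next
    n_used[i] <- sum(ok)
    # constant genes have no defined rank correlation; cor returns NA
    rho[i] <- suppressWarnings(stats::cor(tv[ok], gv[ok], method = "spearman"))
  }
  tstat <- rho * sqrt((n_used - 2) / pmax(1 - rho^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n_used - 2)
  p[is.finite(rho) & abs(rho) == 1] <- 0  # perfect monotone association
  q <- stats::p.adjust(p, method = "fdr")
  tab <- data.frame(gene = others, rho = rho, n = n_used, p = p,
                    fdr_q = q, significant = !is.na(q) & q < fdr_q,
                    stringsAsFactors = FALSE)
  part_summary <- NULL
  if (!is.null(partition)) {
    tab$in_set <- toupper(tab$gene) %in% partition$members
    part_summary <- do.call(rbind, lapply(c(TRUE, FALSE), function(v) {
      sub <- tab[tab$in_set == v & !is.na(tab$rho), ]
      data.frame(in_set = v, n = nrow(sub),
                 n_significant = sum(sub$significant),
                 median_rho = stats::median(sub$rho),
                 median_abs_rho = stats::median(abs(sub$rho)))
    }))
  }
  structure(list(table = tab, target_gene = target_gene,
                 partition_summary = part_summary, fdr_q = fdr_q),
            class = "coexpr_screen")
}

#' @export
print.coexpr_screen <- function(x, ...) {
  tab <- x$table
  cat(sprintf("Spearman co-expression screen vs %s: %d genes tested\n",
              x$target_gene, sum(!is.na(tab$rho))))
  cat(sprintf("  significant at FDR < %g: %d (%d positive, %d negative)\n",
              x$fdr_q, sum(tab$significant),
              sum(tab$significant & tab$rho > 0),
              sum(tab$significant & tab$rho < 0)))
  if (!is.null(x$partition_summary)) {
    print(x$partition_summary, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
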