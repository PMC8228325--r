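# Expression-weighted cell-type enrichment: a gene's specificity for a
# cell type is the fraction of its total across-type mean expression
# attributable to that type (rows sum to 1). A target set's summed
# specificity per type is compared against size-matched random sets drawn
# from a declared background.

#' Build a gene-by-cell-type specificity matrix
#'
#' Counts are depth-normalized to counts per million within each cell,
#' averaged per cell type, and each gene's per-type means are divided by
#' their across-type sum. Genes with zero total expression are excluded;
#' cell types listed in `exclude` are removed before averaging.
#'
#' @param counts Gene-by-cell count matrix (genes in rows, named).
#' @param labels data.frame with `cell_id` and `cell_type` covering all
#'   columns of `counts`.
#' @param exclude Cell-type labels to drop (uninformative types).
#' @return Matrix of class `specificity_matrix` (genes x cell types);
#'   every row sums to 1.
#' @examples
#' sim <- simulate_sc_counts(sc_sim_config(n_genes = 80, seed = 5))
#' spec <- build_specificity(sim$counts, sim$labels)
#' rowSums(spec)[1:3]
#' @export
build_specificity <- function(counts, labels, exclude = character()) {
  if (!all(colnames(counts) %in% labels$cell_id)) {
    stop("labels do not cover all cells", call. = FALSE)
  }
  type <- labels$cell_type[match(colnames(counts), labels$cell_id)]
  keep <- !(type %in% exclude)
  if (!any(keep)) stop("no cells left after exclusion", call. = FALSE)
  counts <- counts[, keep, drop = FALSE]
  type <- type[keep]
  depth <- colSums(counts)
  zero_cells <- depth == 0
  if (any(zero_cells)) {
    counts <- counts[, !zero_cells, drop = FALSE]
    type <- type[!zero_cells]
    depth <- depth[!zero_cells]
  }
  cpm <- sweep(counts, 2L, depth / 1e6, "/")
  types <- unique(type)
  means <- vapply(types, function(ty)
    rowMeans(cpm[, type == ty, drop = FALSE]), numeric(nrow(cpm)))
  colnames(means) <- types
  tot <- rowSums(means)
  nonzero <- tot > 0
  if (!all(nonzero)) means <- means[nonzero, , drop = FALSE]
  spec <- means / rowSums(means)
  structure(spec, class = c("specificity_matrix", class(spec)))
}

#' Bootstrap expression-weighted cell-type enrichment
#'
#' For each cell type, compares the summed specificity of the target gene
#' set against `n_boot` random gene sets of the same size drawn without
#' replacement from the background. The p-value is the upper-tail
#' bootstrap probability with a plus-one correction (`(1 + #{null >=
#' observed}) / (n_boot + 1)`), so it is never exactly zero; z-scores use
#' the bootstrap mean and sd. Benjamini-Hochberg adjustment is applied
#' across cell types.
#'
#' @param spec A `specificity_matrix`.
#' @param target Character vector of target genes (>= 5, subset of
#'   `background`).
#' @param background Character vector of background genes (subset of the
#'   rows of `spec`).
#' @param n_boot Number of bootstrap sets (default 10000).
#' @param seed Optional RNG seed.
#' @return data.frame of class `ewce_result`, one row per cell type:
#'   `cell_type`, `observed`, `boot_mean`, `boot_sd`, `z`, `p`, `fdr_q`,
#'   sorted by p.
#' @export
bootstrap_enrichment <- function(spec, target, background, n_boot = 10000L,
                                 seed = NULL) {
  stop_if_not_count(n_boot, "n_boot")
  target <- unique(target); background <- unique(background)
  if (!all(background %in% rownames(spec))) {
    stop("background genes missing from the specificity matrix", call. = FALSE)
  }
  if (!all(target %in% background)) {
    stop("target must be a subset of the background", call. = FALSE)
  }
  if (length(target) < 5L) stop("need at least 5 target genes", call. = FALSE)
  bg_spec <- spec[background, , drop = FALSE]
  m <- length(target)
  observed <- colSums(bg_spec[target, , drop = FALSE])
  with_seed_if(seed, {
    null_sums <- matrix(0, n_boot, ncol(bg_spec))
    for (b in seq_len(n_boot)) {
      null_sums[b, ] <- colSums(bg_spec[sample.int(nrow(bg_spec), m), ,
                                        drop = FALSE])
    }
    boot_mean <- colMeans(null_sums)
    boot_sd <- apply(null_sums, 2L, stats::sd)
    z <- (observed - boot_mean) / boot_sd
    p <- (1 + colSums(null_sums >= rep(observed, each = n_boot))) / (n_boot + 1)
    out <- data.frame(cell_type = colnames(bg_spec),
                      observed = observed, boot_mean = boot_mean,
                      boot_sd = boot_sd, z = z, p = p,
                      fdr_q = stats::p.adjust(p, method = "BH"),
                      stringsAsFactors = FALSE)
    out <- out[order(out$p, -out$z), ]
    rownames(out) <- NULL
    class(out) <- c("ewce_result", class(out))
    out
  })
}

#' Top-n annotated proteins by fold-change
#'
#' Selects the `n` proteins of an annotation with the largest log2
#' fold-change; ties broken by smaller p-value, then by protein ID.
#'
#' @param de A `modt` fit or DEResult data.frame.
#' @param ann An `annotation_set`.
#' @param n Number of proteins to return (default 50).
#' @return Character vector of protein IDs. If fewer than `n` annotated
#'   proteins are available, all are returned with a warning.
#' @export
top_n_by_foldchange <- function(de, ann, n = 50L) {
  stop_if_not_count(n, "n")
  tab <- as_de_table(de)
  tab <- tab[toupper(tab$protein_id) %in% ann$members, , drop = FALSE]
  if (nrow(tab) < n) {
    warning(sprintf("only %d annotated proteins available (requested %d)",
                    nrow(tab), n), call. = FALSE)
    n <- nrow(tab)
  }
  ord <- order(-tab$log2fc, tab$p, tab$protein_id)
  tab$protein_id[ord[seq_len(n)]]
}
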