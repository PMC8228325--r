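#' Simulate a single-cell count matrix with planted cell-type structure
#'
#' Draws negative-binomial counts for `n_genes` genes across cells grouped
#' into cell types. Marker genes are expressed `marker_fold` higher in their
#' own type; the target gene follows a prescribed per-type relative profile;
#' a planted set of genes has per-type mean profiles that are strictly
#' monotone increasing (or decreasing) transforms of the target's profile,
#' so their rank correlation with the target is +1 (or -1) at the level of
#' true means. Optional uninformative cell types (flat expression) are
#' tagged so that downstream stages can exclude them.
#'
#' @param cfg A [sc_sim_config()].
#' @return A list of class `sc_sim` with elements
#'   \describe{
#'     \item{counts}{integer matrix, genes x cells.}
#'     \item{labels}{data.frame: `cell_id`, `cell_type`, `uninformative`.}
#'     \item{truth}{list: marker gene names per type, planted positively /
#'       negatively correlated gene names, true per-type mean profiles.}
#'   }
#' @examples
#' sim <- simulate_sc_counts(sc_sim_config(n_genes = 100, n_pos_corr = 5,
#'                                         n_neg_corr = 5, seed = 2))
#' dim(sim$counts)
#' @export
simulate_sc_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sc_sim_config"))
  if (cfg$cells_per_type < 1L) stop("empty cell types", call. = FALSE)
  with_seed_if(cfg$seed, {
    types <- sprintf("Type%02d", seq_len(cfg$n_cell_types))
    all_types <- c(types, cfg$uninformative_labels)
    cells_type <- rep(all_types, each = cfg$cells_per_type)
    n_cells <- length(cells_type)
    cell_ids <- sprintf("cell%04d", seq_len(n_cells))

    n_mark <- cfg$n_cell_types * cfg$n_marker_genes_per_type
    marker_names <- if (n_mark > 0) {
      as.vector(vapply(seq_len(cfg$n_cell_types), function(i)
        sprintf("MK%s_%d", types[i], seq_len(cfg$n_marker_genes_per_type)),
        character(cfg$n_marker_genes_per_type)))
    } else character()
    pos_names <- if (cfg$n_pos_corr > 0) sprintf("POS%03d", seq_len(cfg$n_pos_corr)) else character()
    neg_names <- if (cfg$n_neg_corr > 0) sprintf("NEG%03d", seq_len(cfg$n_neg_corr)) else character()
    n_bg <- cfg$n_genes - n_mark - 1L - cfg$n_pos_corr - cfg$n_neg_corr
    bg_names <- if (n_bg > 0) sprintf("BG%04d", seq_len(n_bg)) else character()
    genes <- c(cfg$target_gene, marker_names, pos_names, neg_names, bg_names)

    # relative per-type profile for every gene (genes x types), mean ~ 1
    prof <- matrix(1, length(genes), cfg$n_cell_types,
                   dimnames = list(genes, types))
    tp <- cfg$target_gene_profile
    prof[cfg$target_gene, ] <- tp / mean(tp)
    if (n_mark > 0) {
      for (i in seq_len(cfg$n_cell_types)) {
        mk <- sprintf("MK%s_%d", types[i], seq_len(cfg$n_marker_genes_per_type))
        prof[mk, ] <- 1
        prof[mk, i] <- cfg$marker_fold
      }
    }
    # strictly monotone transforms of the target profile: x^gamma preserves
    # order for gamma > 0; (c - x)^gamma with c > max(x) reverses it
    for (g in pos_names) {
      gam <- stats::runif(1, 0.5, 2)
      p <- tp^gam
      prof[g, ] <- p / mean(p)
    }
    for (g in neg_names) {
      gam <- stats::runif(1, 0.5, 2)
      p <- (max(tp) * 1.1 - tp)^gam
      prof[g, ] <- p / mean(p)
    }

    base <- stats::rlnorm(length(genes), meanlog = log(5), sdlog = 0.8)
    names(base) <- genes
    depth <- stats::rlnorm(n_cells, meanlog = log(cfg$depth_mean), sdlog = 0.25)

    mu <- matrix(0, length(genes), n_cells, dimnames = list(genes, cell_ids))
    for (j in seq_len(n_cells)) {
      ty <- cells_type[j]
      rel <- if (ty %in% types) prof[, ty] else rep(1, length(genes))
      mu[, j] <- base * rel * depth[j]
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / cfg$nb_dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    storage.mode(counts) <- "integer"

    labels <- data.frame(cell_id = cell_ids, cell_type = cells_type,
                         uninformative = cells_type %in% cfg$uninformative_labels,
                         stringsAsFactors = FALSE)
    truth <- list(markers = if (n_mark > 0)
      stats::setNames(lapply(seq_len(cfg$n_cell_types), function(i)
        sprintf("MK%s_%d", types[i], seq_len(cfg$n_marker_genes_per_type))), types)
      else list(),
      pos_corr = pos_names, neg_corr = neg_names,
      target = cfg$target_gene, profiles = prof)
    structure(list(counts = counts, labels = labels, truth = truth),
              class = "sc_sim")
  })
}
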