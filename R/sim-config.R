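# Configuration constructors for the three synthetic-data generators.
# Defaults mirror the study design the pipeline is built for: 6 vs 6
# synaptosome replicates, ~35 scored synapses per animal across 6 animals
# per genotype, and a cortical single-cell reference with marker-driven
# cell types.

#' Configuration for the synthetic peptide quantification table
#'
#' Defines a two-group (or multi-group) DIA/SWATH-style peptide table:
#' lognormal peptide intensities, per-sample systematic shifts, a smooth
#' intensity-dependent bias on half of the samples (so cyclic loess has
#' something real to remove), and an independent Bernoulli pass/fail
#' mechanism for the per-measurement identification Q-values.
#'
#' @param n_proteins Number of proteins.
#' @param peptides_per_protein Integer range `c(min, max)`; each protein
#'   draws its peptide count uniformly from this range.
#' @param n_per_group Samples per group (default 6 biological replicates).
#' @param groups Ordered group labels; the planted effect applies to the
#'   second group relative to the first.
#' @param frac_mito Fraction of proteins tagged with the "mito" annotation.
#' @param effect_log2 Planted log2 effect added to the second group for
#'   proteins in `effect_set`.
#' @param effect_set Which annotation stratum carries the effect:
#'   `"mito"`, `"other"`, or `"none"`.
#' @param peptide_sd Residual log2 noise per peptide-sample measurement.
#' @param sample_offset_sd Per-sample systematic log2 shift (library size /
#'   loading differences).
#' @param intensity_bias_amplitude Amplitude (log2) of a monotone,
#'   intensity-dependent bias applied to alternate samples within each group.
#' @param q_fail_rate Probability that a peptide-sample measurement draws an
#'   identification Q-value above the 1e-3 confidence threshold.
#' @param seed RNG seed; the generator is bit-reproducible given the seed.
#' @return An object of class `peptide_sim_config`.
#' @seealso [simulate_peptides()]
#' @export
peptide_sim_config <- function(n_proteins = 300,
                               peptides_per_protein = c(2L, 8L),
                               n_per_group = 6L,
                               groups = c("WT", "KO"),
                               frac_mito = 0.2,
                               effect_log2 = 0,
                               effect_set = c("mito", "other", "none"),
                               peptide_sd = 0.13,
                               sample_offset_sd = 0.1,
                               intensity_bias_amplitude = 0,
                               q_fail_rate = 0,
                               seed = 1L) {
  effect_set <- match.arg(effect_set)
  stop_if_not_count(n_proteins, "n_proteins")
  stopifnot(length(peptides_per_protein) == 2L)
  stop_if_not_count(peptides_per_protein[1], "peptides_per_protein[min]")
  stop_if_not_count(peptides_per_protein[2], "peptides_per_protein[max]",
                    min = peptides_per_protein[1])
  stop_if_not_count(n_per_group, "n_per_group")
  if (length(groups) < 2L || anyDuplicated(groups)) {
    stop("'groups' must hold at least two distinct labels", call. = FALSE)
  }
  stop_if_not_fraction(frac_mito, "frac_mito")
  stop_if_not_fraction(q_fail_rate, "q_fail_rate")
  stop_if_not_positive(peptide_sd, "peptide_sd", strict = FALSE)
  stop_if_not_positive(sample_offset_sd, "sample_offset_sd", strict = FALSE)
  stop_if_not_positive(intensity_bias_amplitude, "intensity_bias_amplitude",
                       strict = FALSE)
  structure(list(
    n_proteins = as.integer(n_proteins),
    peptides_per_protein = as.integer(peptides_per_protein),
    n_per_group = as.integer(n_per_group),
    groups = as.character(groups),
    frac_mito = frac_mito,
    effect_log2 = effect_log2,
    effect_set = effect_set,
    peptide_sd = peptide_sd,
    sample_offset_sd = sample_offset_sd,
    intensity_bias_amplitude = intensity_bias_amplitude,
    q_fail_rate = q_fail_rate,
    seed = as.integer(seed)
  ), class = "peptide_sim_config")
}

#' Configuration for synthetic synapse morphometry records
#'
#' Defines nested electron-microscopy-style measurements: animals within
#' genotype, synapses within animal, and mitochondrial profiles with planted
#' lognormal areas and elongation indices per genotype and compartment.
#' Perimeters are derived as `P = sqrt(4 * pi * A * E)` so the planted
#' elongation index `E` is exactly recoverable from area and perimeter.
#'
#' Per-genotype or per-genotype-by-compartment parameters are given as named
#' lists, e.g. `area_mean_log = list(WT = c(pre = ..., post = ...), KO = ...)`.
#'
#' @param n_animals_per_genotype Animals per genotype (default 6).
#' @param synapses_per_animal Synapses scored per animal.
#' @param p_mito Named vector: probability a synapse contains a mitochondrion,
#'   per genotype.
#' @param p_post Probability a synaptic mitochondrion is postsynaptic.
#' @param area_mean_log Named list of `c(pre, post)` log-mean areas
#'   (log micrometres squared) per genotype.
#' @param area_sd_log Lognormal sd of area.
#' @param elongation_mean Named list of `c(pre, post)` mean elongation
#'   indices per genotype; all values must be >= 1.
#' @param elongation_sd SD of elongation around its mean (values are
#'   truncated at 1, the circular lower bound).
#' @param animal_sd Between-animal random-intercept sd on the log-area scale
#'   (an independent intercept of the same sd perturbs elongation).
#' @param distance_range Uniform range (nm) for the mitochondrion-to-synapse
#'   distance; the default 0--600 straddles the 500-nm proximity cutoff.
#' @param synapse_length_mean,synapse_length_sd Normal parameters (nm) for
#'   the active-zone / postsynaptic-density length.
#' @param outlier_rate,outlier_scale Contamination: each mitochondrial area
#'   is multiplied by `outlier_scale` with probability `outlier_rate`.
#' @param seed RNG seed.
#' @return An object of class `morpho_sim_config`.
#' @seealso [simulate_morphometry()]
#' @export
morpho_sim_config <- function(n_animals_per_genotype = 6L,
                              synapses_per_animal = 35L,
                              p_mito = c(WT = 0.36, KO = 0.42),
                              p_post = 0.6,
                              area_mean_log = list(
                                WT = c(pre = log(0.055), post = log(0.055)),
                                KO = c(pre = log(0.055), post = log(0.044))),
                              area_sd_log = 0.45,
                              elongation_mean = list(
                                WT = c(pre = 1.55, post = 1.55),
                                KO = c(pre = 1.55, post = 1.40)),
                              elongation_sd = 0.35,
                              animal_sd = 0.08,
                              distance_range = c(0, 600),
                              synapse_length_mean = 300,
                              synapse_length_sd = 40,
                              outlier_rate = 0,
                              outlier_scale = 8,
                              seed = 1L) {
  stop_if_not_count(n_animals_per_genotype, "n_animals_per_genotype", min = 2L)
  stop_if_not_count(synapses_per_animal, "synapses_per_animal")
  genotypes <- names(p_mito)
  if (is.null(genotypes) || length(genotypes) < 2L) {
    stop("'p_mito' must be a named vector with one entry per genotype",
         call. = FALSE)
  }
  for (p in p_mito) stop_if_not_fraction(p, "p_mito")
  stop_if_not_fraction(p_post, "p_post")
  for (g in genotypes) {
    if (is.null(area_mean_log[[g]]) || is.null(elongation_mean[[g]])) {
      stop("area_mean_log and elongation_mean need entries for every genotype",
           call. = FALSE)
    }
    if (any(elongation_mean[[g]] < 1)) {
      stop("'elongation_mean' must be >= 1 (circular lower bound)",
           call. = FALSE)
    }
  }
  stop_if_not_positive(area_sd_log, "area_sd_log", strict = FALSE)
  stop_if_not_positive(elongation_sd, "elongation_sd", strict = FALSE)
  stop_if_not_positive(animal_sd, "animal_sd", strict = FALSE)
  stopifnot(length(distance_range) == 2L, distance_range[1] >= 0,
            distance_range[2] >= distance_range[1])
  stop_if_not_fraction(outlier_rate, "outlier_rate")
  structure(list(
    n_animals_per_genotype = as.integer(n_animals_per_genotype),
    synapses_per_animal = as.integer(synapses_per_animal),
    genotypes = genotypes,
    p_mito = p_mito,
    p_post = p_post,
    area_mean_log = area_mean_log,
    area_sd_log = area_sd_log,
    elongation_mean = elongation_mean,
    elongation_sd = elongation_sd,
    animal_sd = animal_sd,
    distance_range = as.numeric(distance_range),
    synapse_length_mean = synapse_length_mean,
    synapse_length_sd = synapse_length_sd,
    outlier_rate = outlier_rate,
    outlier_scale = outlier_scale,
    seed = as.integer(seed)
  ), class = "morpho_sim_config")
}

#' Configuration for a synthetic single-cell count matrix
#'
#' Defines a negative-binomial count matrix over cell types with planted
#' marker genes, a target gene with a prescribed cell-type profile (a
#' `Grm5`-like receptor transcript), and genes whose cell-type profiles are
#' strictly monotone transforms of the target's (positive or negative),
#' which a rank-based co-expression screen should recover.
#'
#' @param n_cell_types Number of informative cell types.
#' @param cells_per_type Cells per type.
#' @param n_genes Total number of genes (must accommodate markers, the
#'   target, and the planted correlated genes).
#' @param n_marker_genes_per_type Marker genes per cell type.
#' @param marker_fold Expression multiplier of a marker in its own type.
#' @param nb_dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param target_gene_profile Relative expression of the target gene per
#'   cell type; defaults to a strictly decreasing profile.
#' @param target_gene Name of the target gene.
#' @param n_pos_corr,n_neg_corr Number of genes with strictly increasing /
#'   decreasing transforms of the target profile.
#' @param uninformative_labels Extra cell-type labels generated with flat
#'   background expression and tagged as excludable.
#' @param depth_mean Mean per-cell scaling of expected counts.
#' @param seed RNG seed.
#' @return An object of class `sc_sim_config`.
#' @seealso [simulate_sc_counts()]
#' @export
sc_sim_config <- function(n_cell_types = 8L,
                          cells_per_type = 40L,
                          n_genes = 600L,
                          n_marker_genes_per_type = 5L,
                          marker_fold = 9,
                          nb_dispersion = 0.3,
                          target_gene_profile = NULL,
                          target_gene = "Grm5",
                          n_pos_corr = 20L,
                          n_neg_corr = 20L,
                          uninformative_labels = character(),
                          depth_mean = 1,
                          seed = 1L) {
  stop_if_not_count(n_cell_types, "n_cell_types", min = 3L)
  stop_if_not_count(cells_per_type, "cells_per_type")
  stop_if_not_count(n_genes, "n_genes")
  stop_if_not_count(n_marker_genes_per_type, "n_marker_genes_per_type", min = 0L)
  stop_if_not_positive(marker_fold, "marker_fold")
  stop_if_not_positive(nb_dispersion, "nb_dispersion")
  stop_if_not_count(n_pos_corr, "n_pos_corr", min = 0L)
  stop_if_not_count(n_neg_corr, "n_neg_corr", min = 0L)
  if (is.null(target_gene_profile)) {
    # strictly decreasing across types: distinct ranks guaranteed
    target_gene_profile <- seq(2, 0.2, length.out = n_cell_types)
  }
  stopifnot(length(target_gene_profile) == n_cell_types,
            all(target_gene_profile > 0))
  reserved <- n_cell_types * n_marker_genes_per_type + 1L +
    n_pos_corr + n_neg_corr
  if (n_genes < reserved) {
    stop(sprintf("'n_genes' must be >= %d to hold markers, target and planted genes",
                 reserved), call. = FALSE)
  }
  structure(list(
    n_cell_types = as.integer(n_cell_types),
    cells_per_type = as.integer(cells_per_type),
    n_genes = as.integer(n_genes),
    n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
    marker_fold = marker_fold,
    nb_dispersion = nb_dispersion,
    target_gene_profile = as.numeric(target_gene_profile),
    target_gene = target_gene,
    n_pos_corr = as.integer(n_pos_corr),
    n_neg_corr = as.integer(n_neg_corr),
    uninformative_labels = as.character(uninformative_labels),
    depth_mean = depth_mean,
    seed = as.integer(seed)
  ), class = "sc_sim_config")
}
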