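# Builders for tiny in-code fixtures shared across test files.

# A wide peptide table from an intensity matrix and a Q-value matrix
# (peptides x samples), with a peptide->protein map.
make_peptide_table <- function(intensity, qvalue, protein_id) {
  samples <- colnames(intensity)
  pt <- data.frame(peptide_id = sprintf("pep%02d", seq_len(nrow(intensity))),
                   protein_id = protein_id, stringsAsFactors = FALSE)
  for (j in seq_along(samples)) pt[[paste0("intensity_", samples[j])]] <- intensity[, j]
  for (j in seq_along(samples)) pt[[paste0("qvalue_", samples[j])]] <- qvalue[, j]
  pt
}

two_group_design <- function(n = 6, groups = c("A", "B")) {
  data.frame(sample_id = as.vector(vapply(groups, function(g)
    sprintf("%s%d", g, seq_len(n)), character(n))),
    group = rep(groups, each = n), stringsAsFactors = FALSE)
}

# Morphometry records with explicit per-row values.
make_morpho_records <- function(animal_id, genotype, area, perimeter,
                                distance = 100, compartment = "post") {
  n <- length(area)
  data.frame(animal_id = animal_id,
             genotype = genotype,
             synapse_id = sprintf("syn%03d", seq_len(n)),
             compartment = rep_len(compartment, n),
             has_mito = TRUE,
             area_um2 = area,
             perimeter_um = perimeter,
             distance_nm = rep_len(distance, n),
             synapse_length_nm = 300,
             stringsAsFactors = FALSE)
}

# A row-stochastic specificity matrix with optional fully specific genes.
make_specificity <- function(n_genes = 60, n_types = 5, n_specific = 0,
                             specific_type = 1, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(n_genes * n_types), n_genes, n_types,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("ct%d", seq_len(n_types))))
    m <- m / rowSums(m)
    if (n_specific > 0) {
      m[seq_len(n_specific), ] <- 0
      m[seq_len(n_specific), specific_type] <- 1
    }
    structure(m, class = c("specificity_matrix", class(m)))
  })
}
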