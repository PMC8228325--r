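#' Simulate a DIA/SWATH-style peptide quantification table
#'
#' Draws peptide intensities on the log2 scale as
#' protein baseline + peptide offset + per-sample shift + planted group
#' effect + monotone intensity-dependent bias + residual noise, then
#' exponentiates to raw intensity units. Each peptide-sample measurement
#' carries an identification Q-value: with probability `1 - q_fail_rate`
#' it is drawn below the 1e-3 confidence threshold (a "pass"), otherwise
#' above it. The intensity bias is `amplitude * tanh(centred log2
#' intensity)` applied to alternate samples within each group, so the two
#' halves of every group see the same distortion and the planted group
#' effect is not confounded.
#'
#' @param cfg A [peptide_sim_config()].
#' @return A list of class `peptide_sim` with elements
#'   \describe{
#'     \item{peptides}{data.frame: `peptide_id`, `protein_id`, then
#'       `intensity_<sample>` and `qvalue_<sample>` columns.}
#'     \item{truth}{data.frame per protein: annotation stratum
#'       (`mito`/`other`), true log2 effect, peptide count.}
#'     \item{design}{data.frame mapping `sample_id` to `group`.}
#'   }
#' @examples
#' sim <- simulate_peptides(peptide_sim_config(n_proteins = 20, seed = 7))
#' head(sim$truth)
#' @export
simulate_peptides <- function(cfg) {
  stopifnot(inherits(cfg, "peptide_sim_config"))
  with_seed_if(cfg$seed, {
    n_prot <- cfg$n_proteins
    prot_ids <- sprintf("PROT%04d", seq_len(n_prot))
    n_mito <- round(cfg$frac_mito * n_prot)
    stratum <- rep("other", n_prot)
    if (n_mito > 0) stratum[sample.int(n_prot, n_mito)] <- "mito"

    effect <- rep(0, n_prot)
    if (cfg$effect_set != "none" && cfg$effect_log2 != 0) {
      effect[stratum == cfg$effect_set] <- cfg$effect_log2
    }

    npep <- sample(seq(cfg$peptides_per_protein[1], cfg$peptides_per_protein[2]),
                   n_prot, replace = TRUE)
    pep_protein <- rep(seq_len(n_prot), npep)
    n_pep <- length(pep_protein)
    pep_ids <- sprintf("PEP%05d", seq_len(n_pep))

    groups <- cfg$groups
    n_g <- length(groups)
    samples <- as.vector(vapply(groups, function(g)
      sprintf("%s_%d", g, seq_len(cfg$n_per_group)), character(cfg$n_per_group)))
    sample_group <- rep(groups, each = cfg$n_per_group)
    n_s <- length(samples)
    # alternate samples within each group carry the intensity bias
    biased <- rep(seq_len(cfg$n_per_group) %% 2L == 0L, times = n_g)

    prot_base <- stats::rnorm(n_prot, mean = 20, sd = 1.5)
    pep_off <- stats::rnorm(n_pep, mean = 0, sd = 1)
    samp_off <- stats::rnorm(n_s, mean = 0, sd = cfg$sample_offset_sd)

    base <- prot_base[pep_protein] + pep_off          # per peptide
    # log2 intensity matrix, peptides x samples
    x <- outer(base, samp_off, "+")
    eff_mat <- outer(effect[pep_protein], as.numeric(sample_group == groups[2]))
    x <- x + eff_mat
    if (cfg$intensity_bias_amplitude > 0) {
      # the bias is a smooth monotone function of the protein's (noiseless)
      # rolled-up log2 abundance, applied to all peptides of the protein in
      # the biased samples -- the shape of a loading / acquisition artifact
      # as it appears after protein roll-up
      prot_ab <- log2(rowsum(2^x, pep_protein))
      ctr <- mean(prot_ab); spr <- stats::sd(as.vector(prot_ab))
      delta <- cfg$intensity_bias_amplitude * tanh((prot_ab - ctr) / spr)
      x[, biased] <- x[, biased] + delta[pep_protein, biased, drop = FALSE]
    }
    x <- x + matrix(stats::rnorm(n_pep * n_s, sd = cfg$peptide_sd), n_pep, n_s)
    intensity <- 2^x

    pass <- matrix(stats::runif(n_pep * n_s) >= cfg$q_fail_rate, n_pep, n_s)
    q <- matrix(NA_real_, n_pep, n_s)
    q[pass] <- stats::runif(sum(pass)) * 1e-3
    q[!pass] <- 1e-3 + stats::runif(sum(!pass)) * (1 - 1e-3)

    pep <- data.frame(peptide_id = pep_ids,
                      protein_id = prot_ids[pep_protein],
                      stringsAsFactors = FALSE)
    for (j in seq_len(n_s)) pep[[paste0("intensity_", samples[j])]] <- intensity[, j]
    for (j in seq_len(n_s)) pep[[paste0("qvalue_", samples[j])]] <- q[, j]

    truth <- data.frame(protein_id = prot_ids,
                        stratum = stratum,
                        effect_log2 = effect,
                        n_peptides = npep,
                        stringsAsFactors = FALSE)
    design <- data.frame(sample_id = samples, group = sample_group,
                         stringsAsFactors = FALSE)
    attr(design, "sample_offset") <- stats::setNames(samp_off, samples)
    structure(list(peptides = pep, truth = truth, design = design),
              class = "peptide_sim")
  })
}
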