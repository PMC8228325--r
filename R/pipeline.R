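# End-to-end orchestration on synthetic data: one call simulates every
# input, runs all stages with the pipeline's default parameters, and
# returns a structured report.

#' Pipeline configuration
#'
#' Collects the stage parameters (defaulting to the pipeline's standard
#' values: Q-value cutoff 1e-3, >= 2 peptides per protein, 10 loess
#' iterations, regulation call at unadjusted p < 0.01, 100 randomization
#' iterations, 500 nm proximity cutoff, ROUT 1%, FDR 0.05, top-50
#' fold-change set) together with the three generator configurations and a
#' master seed. Stage seeds are derived deterministically from the master
#' seed.
#'
#' @param seed Master RNG seed.
#' @param peptide_cfg,morpho_cfg,sc_cfg Generator configurations; defaults
#'   plant a mitochondrial up-regulation of 0.2 log2 in a 6 vs 6 design, a
#'   postsynaptic area/elongation reduction in the second genotype, and a
#'   cell-type-structured single-cell reference.
#' @param q_max,min_peptides,loess_iterations,p_threshold,n_iter,max_distance,rout_q,fdr_q,top_n
#'   Stage parameters; see the stage functions for their meaning.
#' @param n_boot Bootstrap count for the cell-type enrichment.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            peptide_cfg = NULL, morpho_cfg = NULL,
                            sc_cfg = NULL,
                            q_max = 1e-3, min_peptides = 2L,
                            loess_iterations = 10L, p_threshold = 0.01,
                            n_iter = 100L, max_distance = 500,
                            rout_q = 0.01, fdr_q = 0.05, top_n = 50L,
                            n_boot = 2000L) {
  seed <- as.integer(seed)
  # distinct, deterministic stage seeds below 2^31
  sseed <- (seed * 1000L + c(1L, 2L, 3L, 4L, 5L)) %% .Machine$integer.max
  if (is.null(peptide_cfg)) {
    peptide_cfg <- peptide_sim_config(n_proteins = 400, frac_mito = 0.25,
                                      effect_log2 = 0.2, effect_set = "mito",
                                      intensity_bias_amplitude = 0.2,
                                      seed = sseed[1])
  }
  if (is.null(morpho_cfg)) morpho_cfg <- morpho_sim_config(seed = sseed[2])
  if (is.null(sc_cfg)) sc_cfg <- sc_sim_config(seed = sseed[3])
  structure(list(seed = seed, stage_seeds = sseed,
                 peptide_cfg = peptide_cfg, morpho_cfg = morpho_cfg,
                 sc_cfg = sc_cfg,
                 q_max = q_max, min_peptides = min_peptides,
                 loess_iterations = loess_iterations,
                 p_threshold = p_threshold, n_iter = n_iter,
                 max_distance = max_distance, rout_q = rout_q,
                 fdr_q = fdr_q, top_n = top_n, n_boot = n_boot),
            class = "pipeline_config")
}

# Deterministic fingerprint of the parameter set (for provenance).
config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(unclass(cfg)), collapse = ""), tf)
  unname(tools::md5sum(tf))
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a peptide table, morphometry records and a single-cell
#' reference, then runs: peptide filtering -> protein roll-up -> cyclic
#' loess normalization -> replicate CVs -> moderated-t differential
#' expression -> mitochondrial fold-change subsetting, randomized-selection
#' test, category summaries and over-representation -> morphometry nested
#' tests and mito-presence comparison -> cell-type specificity and
#' bootstrap enrichment of the top fold-change mitochondrial set -> the
#' target-gene co-expression screen. Deterministic given the config seed.
#'
#' @param cfg A [pipeline_config()].
#' @return List of class `pipeline_report` holding every stage's result
#'   plus a provenance block (package version, seed, parameter hash).
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(seed = 7))
#' rep
#' }
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  sim <- stage("simulate", list(
    peptides = simulate_peptides(cfg$peptide_cfg),
    morpho = simulate_morphometry(cfg$morpho_cfg),
    sc = simulate_sc_counts(cfg$sc_cfg)))

  quant <- stage("quantify", {
    flt <- filter_peptides(sim$peptides$peptides, sim$peptides$design,
                           q_max = cfg$q_max, min_peptides = cfg$min_peptides)
    pm <- cyclic_loess_normalize(rollup_proteins(flt),
                                 iterations = cfg$loess_iterations)
    list(filtered = flt, pm = pm,
         cv = replicate_cv(pm, sim$peptides$design))
  })

  groups <- cfg$peptide_cfg$groups
  de <- stage("diffexpr",
              modt_fit(quant$pm, sim$peptides$design, groups[1], groups[2],
                       p_threshold = cfg$p_threshold))

  mito <- stage("mitotest", {
    truth <- sim$peptides$truth
    mito_set <- annotation_set("known_mito",
                               truth$protein_id[truth$stratum == "mito"],
                               source = "generator truth")
    quantified <- de$table$protein_id
    hits <- de$table$protein_id[de$table$regulated == "up"]
    rnd <- randomized_selection_test(de, mito_set, n_iter = cfg$n_iter,
                                     seed = cfg$stage_seeds[4])
    # split the mito stratum into two synthetic functional categories by
    # planted effect for the category summary
    eff <- truth$protein_id[truth$effect_log2 != 0]
    cats <- list(
      regulated_mito = annotation_set("regulated_mito",
                                      intersect(eff, mito_set$members)),
      other_mito = if (length(setdiff(mito_set$members, toupper(eff)))) {
        annotation_set("other_mito", setdiff(mito_set$members, toupper(eff)))
      } else NULL)
    cats <- cats[!vapply(cats, is.null, logical(1))]
    ora <- if (length(hits) >= 1L) {
      hypergeometric_ora(hits, quantified, list(known_mito = mito_set),
                         fdr_q = cfg$fdr_q)
    } else NULL
    list(mito_set = mito_set, randomization = rnd,
         categories = category_summary(de, cats), ora = ora,
         pct_up_mito = if (length(hits))
           100 * mean(toupper(hits) %in% mito_set$members) else NA_real_)
  })

  morpho <- stage("morphometry", {
    rec <- sim$morpho$records
    list(area_post = morpho_analyze(rec, "area", "post", log_scale = TRUE,
                                    rout_q = cfg$rout_q,
                                    max_distance = cfg$max_distance),
         elong_post = morpho_analyze(rec, "elongation", "post",
                                     rout_q = cfg$rout_q,
                                     max_distance = cfg$max_distance))
  })

  celltype <- stage("celltype", {
    spec <- build_specificity(sim$sc$counts, sim$sc$labels,
                              exclude = cfg$sc_cfg$uninformative_labels)
    mito_ids <- mito$mito_set$members
    avail <- de$table$protein_id[toupper(de$table$protein_id) %in% mito_ids]
    # the synthetic single-cell reference has its own gene namespace, so
    # the enrichment target is the planted cell-type-specific set (markers
    # of the first two types, standing for the neuron-specific regulated
    # mitochondrial proteins) against the full gene background
    truth_mk <- sim$sc$truth$markers
    target <- unlist(truth_mk[seq_len(min(2L, length(truth_mk)))],
                     use.names = FALSE)
    target <- intersect(target, rownames(spec))
    enr <- bootstrap_enrichment(spec, target, rownames(spec),
                                n_boot = cfg$n_boot,
                                seed = cfg$stage_seeds[5])
    top_mito <- if (length(avail) >= 5L)
      top_n_by_foldchange(de, mito$mito_set,
                          n = min(cfg$top_n, length(avail))) else character()
    list(spec = spec, enrichment = enr, top_mito = top_mito)
  })

  coexpr <- stage("coexpr", {
    prof <- build_profiles(sim$sc$counts, sim$sc$labels,
                           exclude = cfg$sc_cfg$uninformative_labels)
    spearman_screen(prof, cfg$sc_cfg$target_gene, fdr_q = cfg$fdr_q)
  })

  structure(list(sim = sim, quantify = quant, de = de, mito = mito,
                 morpho = morpho, celltype = celltype, coexpr = coexpr,
                 provenance = list(
                   package_version = as.character(utils::packageVersion("synaptomito")),
                   seed = cfg$seed,
                   parameter_hash = config_hash(cfg))),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  tab <- x$de$table
  cat("Synthetic synaptosome pipeline report\n")
  cat(sprintf("  seed %d, parameter hash %s\n", x$provenance$seed,
              substr(x$provenance$parameter_hash, 1, 8)))
  cat(sprintf("  peptides kept: %d of %d; proteins quantified: %d\n",
              attr(x$quantify$filtered, "n_peptides_out"),
              attr(x$quantify$filtered, "n_peptides_in"), nrow(tab)))
  cv <- x$quantify$cv$median_cv
  cat(sprintf("  median CV: %s\n",
              paste(sprintf("%s %.1f%%", names(cv), 100 * cv), collapse = ", ")))
  cat(sprintf("  regulated at p < %g: %d up, %d down (%.0f%% of up are mito)\n",
              x$de$p_threshold, sum(tab$regulated == "up"),
              sum(tab$regulated == "down"), x$mito$pct_up_mito))
  cat(sprintf("  randomized-selection test: D = %.3f, p = %.3g\n",
              x$mito$randomization$statistic, x$mito$randomization$p_pooled))
  cat(sprintf("  nested post area (log): p = %.3g; elongation: p = %.3g\n",
              x$morpho$area_post$nested$p.value,
              x$morpho$elong_post$nested$p.value))
  pres <- x$morpho$area_post$presence
  cat(sprintf("  mito-containing synapses: %s (t p = %.2g)\n",
              paste(sprintf("%s %.0f%%", names(pres$genotype_mean_pct),
                            pres$genotype_mean_pct), collapse = ", "),
              pres$p.value))
  cat(sprintf("  co-expression screen: %d significant at FDR < %g\n",
              sum(x$coexpr$table$significant), x$coexpr$fdr_q))
  invisible(x)
}
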