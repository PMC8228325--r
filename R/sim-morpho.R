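#' Simulate nested synapse/mitochondria morphometry records
#'
#' Generates per-animal, per-synapse records mimicking blinded
#' electron-microscopy scoring: each synapse carries a length measurement
#' and, with genotype-specific probability, a mitochondrial profile in the
#' pre- or post-synaptic compartment with a lognormal area, a planted
#' elongation index (truncated at the circular lower bound of 1), and a
#' uniform distance to the active zone / postsynaptic density. A per-animal
#' random intercept perturbs log-areas (and, independently, elongation), so
#' measurements from the same animal are correlated and naive pooled tests
#' pseudoreplicate. Perimeter is computed as `sqrt(4 * pi * area *
#' elongation)` (with area converted so perimeter is in micrometres), which
#' makes the planted elongation exactly recoverable via [shape_metrics()].
#'
#' @param cfg A [morpho_sim_config()].
#' @return A list of class `morpho_sim` with elements
#'   \describe{
#'     \item{records}{data.frame: `animal_id`, `genotype`, `synapse_id`,
#'       `compartment` (`pre`/`post`/`NA`), `has_mito`, `area_um2`,
#'       `perimeter_um`, `distance_nm`, `synapse_length_nm`.}
#'     \item{truth}{planted genotype-by-compartment means and mito
#'       probabilities.}
#'   }
#' @examples
#' sim <- simulate_morphometry(morpho_sim_config(seed = 3))
#' table(sim$records$genotype, sim$records$has_mito)
#' @export
simulate_morphometry <- function(cfg) {
  stopifnot(inherits(cfg, "morpho_sim_config"))
  with_seed_if(cfg$seed, {
    rows <- vector("list", length(cfg$genotypes) * cfg$n_animals_per_genotype)
    k <- 0L
    for (g in cfg$genotypes) {
      for (a in seq_len(cfg$n_animals_per_genotype)) {
        k <- k + 1L
        animal <- sprintf("%s_A%d", g, a)
        b_area <- stats::rnorm(1, 0, cfg$animal_sd)
        b_elong <- stats::rnorm(1, 0, cfg$animal_sd)
        n_syn <- cfg$synapses_per_animal
        has <- stats::runif(n_syn) < cfg$p_mito[[g]]
        comp <- ifelse(stats::runif(n_syn) < cfg$p_post, "post", "pre")
        comp[!has] <- NA_character_
        area <- elong <- perim <- dist <- rep(NA_real_, n_syn)
        for (cm in c("pre", "post")) {
          idx <- which(has & comp == cm)
          if (!length(idx)) next
          area[idx] <- exp(stats::rnorm(length(idx),
                                        cfg$area_mean_log[[g]][[cm]] + b_area,
                                        cfg$area_sd_log))
          elong[idx] <- pmax(1, stats::rnorm(length(idx),
                                             cfg$elongation_mean[[g]][[cm]] + b_elong,
                                             cfg$elongation_sd))
        }
        midx <- which(has)
        if (cfg$outlier_rate > 0 && length(midx)) {
          contam <- midx[stats::runif(length(midx)) < cfg$outlier_rate]
          area[contam] <- area[contam] * cfg$outlier_scale
        }
        perim[midx] <- sqrt(4 * pi * area[midx] * elong[midx])
        dist[midx] <- stats::runif(length(midx), cfg$distance_range[1],
                                   cfg$distance_range[2])
        rows[[k]] <- data.frame(
          animal_id = animal,
          genotype = g,
          synapse_id = sprintf("%s_S%03d", animal, seq_len(n_syn)),
          compartment = comp,
          has_mito = has,
          area_um2 = area,
          perimeter_um = perim,
          distance_nm = dist,
          synapse_length_nm = stats::rnorm(n_syn, cfg$synapse_length_mean,
                                           cfg$synapse_length_sd),
          stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    truth <- list(
      p_mito = cfg$p_mito,
      area_mean_log = cfg$area_mean_log,
      elongation_mean = cfg$elongation_mean,
      # planted genotype contrasts (second genotype minus first), post side
      area_log_effect_post =
        cfg$area_mean_log[[cfg$genotypes[2]]][["post"]] -
        cfg$area_mean_log[[cfg$genotypes[1]]][["post"]],
      elongation_effect_post =
        cfg$elongation_mean[[cfg$genotypes[2]]][["post"]] -
        cfg$elongation_mean[[cfg$genotypes[1]]][["post"]])
    structure(list(records = records, truth = truth), class = "morpho_sim")
  })
}
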