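# Electron-microscopy mitochondrial morphometry: shape metrics, the 500-nm
# proximity rule, ROUT-style robust outlier flagging, nested mixed-model
# genotype tests, and the mito-containing synapse fraction.
#
# Analysis order is fixed: outlier removal -> proximity filter -> shape
# metrics -> nested inference.

#' Circularity and elongation index from area and perimeter
#'
#' Circularity is `4*pi*A / P^2` (1 for a circle, smaller for elongated or
#' convoluted profiles) and the elongation index is its reciprocal
#' `P^2 / (4*pi*A)`. Both are dimensionless and scale-invariant. Inputs
#' violating the isoperimetric inequality `P^2 >= 4*pi*A` beyond a 1e-9
#' relative tolerance indicate inconsistent measurements and raise an
#' error.
#'
#' @param area Profile areas (micrometres squared), positive.
#' @param perimeter Profile perimeters (micrometres), positive.
#' @return data.frame with `circularity` and `elongation`.
#' @examples
#' shape_metrics(pi * 0.2^2, 2 * pi * 0.2)  # circle: both exactly 1
#' @export
shape_metrics <- function(area, perimeter) {
  stop_if_not_positive(area, "area")
  stop_if_not_positive(perimeter, "perimeter")
  ratio <- 4 * pi * area / perimeter^2
  if (any(ratio > 1 + 1e-9)) {
    stop("perimeter^2 < 4*pi*area: isoperimetric inequality violated; ",
         "check measurement units", call. = FALSE)
  }
  ratio <- pmin(ratio, 1)
  data.frame(circularity = ratio, elongation = 1 / ratio)
}

#' Restrict mitochondria to those near the synaptic contact
#'
#' Mitochondrial profiles farther than `max_distance` from the centre of
#' the active zone / postsynaptic density are no longer counted as
#' synaptic: their rows keep the synapse (so synapse counts and the
#' mito-presence fraction stay correct) but lose the mitochondrion
#' (`has_mito = FALSE`, measurements set to `NA`).
#'
#' @param records Morphometry data.frame (see [simulate_morphometry()] for
#'   the schema).
#' @param max_distance Proximity cutoff in nm (default 500).
#' @return The filtered records, with attribute `n_excluded`.
#' @export
proximity_filter <- function(records, max_distance = 500) {
  if (any(records$distance_nm < 0, na.rm = TRUE)) {
    stop("negative mitochondrion-synapse distance", call. = FALSE)
  }
  far <- !is.na(records$distance_nm) & records$has_mito &
    records$distance_nm > max_distance
  records$has_mito[far] <- FALSE
  records$compartment[far] <- NA_character_
  records$area_um2[far] <- NA_real_
  records$perimeter_um[far] <- NA_real_
  records$distance_nm[far] <- NA_real_
  attr(records, "n_excluded") <- sum(far)
  records
}

#' ROUT-style robust outlier flagging for a univariate sample
#'
#' A robust location model: residuals are taken from the median and scaled
#' by the robust standard deviation (the 68.27th percentile of absolute
#' residuals, corrected for small samples by `n/(n - 1)`, one fitted
#' location parameter). Each point gets a two-sided p-value from the t
#' distribution on `n - 1` degrees of freedom, and outliers are flagged by
#' a step-down false-discovery procedure from the largest residual
#' inward: the i-th most extreme point is flagged while
#' `p_(i) <= q * i / n` holds.
#'
#' @param values Numeric vector, `length >= 5`.
#' @param q Maximum false-discovery rate among flagged points (default
#'   0.01, i.e. "ROUT 1%").
#' @return List with `clean` (values kept), `flagged` (values removed) and
#'   `idx_flagged` (indices into the input).
#' @export
robust_outliers <- function(values, q = 0.01) {
  ok <- which(is.finite(values))
  x <- values[ok]
  n <- length(x)
  if (n < 5L) stop("need at least 5 finite values", call. = FALSE)
  stop_if_not_fraction(q, "q")
  res <- x - stats::median(x)
  scale <- stats::quantile(abs(res), 0.6827, names = FALSE) * n / (n - 1)
  if (scale <= 0) {
    return(list(clean = values[ok], flagged = values[0], idx_flagged = integer()))
  }
  p <- 2 * stats::pt(-abs(res) / scale, df = n - 1)
  ord <- order(p)
  flag <- logical(n)
  for (i in seq_len(n)) {
    if (p[ord[i]] <= q * i / n) flag[ord[i]] <- TRUE else break
  }
  list(clean = values[ok][!flag],
       flagged = values[ok][flag],
       idx_flagged = ok[flag])
}

# Assemble the per-mitochondrion analysis frame for one response.
mito_frame <- function(records, response = c("area", "perimeter",
                                             "elongation", "distance"),
                       compartment = c("all", "pre", "post"),
                       log_scale = FALSE) {
  response <- match.arg(response)
  compartment <- match.arg(compartment)
  d <- records[records$has_mito & !is.na(records$area_um2), , drop = FALSE]
  if (compartment != "all") d <- d[d$compartment == compartment, , drop = FALSE]
  y <- switch(response,
              area = d$area_um2,
              perimeter = d$perimeter_um,
              elongation = shape_metrics(d$area_um2, d$perimeter_um)$elongation,
              distance = d$distance_nm)
  if (log_scale) y <- log(y)
  data.frame(y = y, genotype = d$genotype, animal_id = d$animal_id,
             stringsAsFactors = FALSE)
}

#' Nested genotype test on a morphometric response
#'
#' Fits the random-intercept model `y ~ genotype + (1 | animal)` by REML
#' (lme4) on per-mitochondrion measurements, respecting the animal ->
#' measurement hierarchy, and tests the genotype coefficient by a Wald t
#' with conservative between-animal degrees of freedom
#' (`n_animals - 2`). A singular fit (between-animal variance estimated at
#' zero) falls back to pooled OLS, flagged, with the same animal-level
#' degrees of freedom. Optional ROUT outlier removal (per genotype) and
#' the proximity filter should be applied to `records` beforehand; see
#' [morpho_analyze()] for the full pipeline.
#'
#' @param records Morphometry data.frame.
#' @param response One of `"area"`, `"perimeter"`, `"elongation"`,
#'   `"distance"`.
#' @param compartment `"all"`, `"pre"` or `"post"`.
#' @param log_scale Analyze `log(y)` instead of `y` (natural for the
#'   right-skewed area/perimeter measurements; effects become log ratios).
#' @return Object of class `nested_test`: `estimate` (second minus first
#'   genotype level), `se`, `df`, `statistic`, `p.value`, `conf.int` (95%),
#'   `singular`, `n_obs`, `n_animals`, `response`, `compartment`.
#' @export
nested_genotype_test <- function(records,
                                 response = c("area", "perimeter",
                                              "elongation", "distance"),
                                 compartment = c("all", "pre", "post"),
                                 log_scale = FALSE) {
  response <- match.arg(response); compartment <- match.arg(compartment)
  d <- mito_frame(records, response, compartment, log_scale)
  d <- d[is.finite(d$y), , drop = FALSE]
  genos <- unique(records$genotype)
  if (!all(genos %in% d$genotype) || length(genos) < 2L) {
    stop("need measurements from both genotypes", call. = FALSE)
  }
  d$genotype <- factor(d$genotype, levels = genos)
  n_animals <- length(unique(d$animal_id))
  an_per_g <- tapply(d$animal_id, d$genotype, function(a) length(unique(a)))
  if (any(an_per_g < 2L)) stop("need >=2 animals per genotype", call. = FALSE)
  df_t <- n_animals - 2L

  fit <- suppressMessages(lme4::lmer(y ~ genotype + (1 | animal_id), data = d,
                                     REML = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    ols <- stats::lm(y ~ genotype, data = d)
    est <- stats::coef(ols)[2]
    se <- sqrt(diag(stats::vcov(ols)))[2]
  } else {
    est <- lme4::fixef(fit)[2]
    se <- sqrt(diag(as.matrix(lme4::vcov.merMod(fit))))[2]
  }
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), df = df_t)
  ci <- est + c(-1, 1) * stats::qt(0.975, df = df_t) * se
  structure(list(estimate = unname(est), se = unname(se), df = df_t,
                 statistic = unname(tval), p.value = unname(p),
                 conf.int = ci, singular = singular,
                 n_obs = nrow(d), n_animals = n_animals,
                 response = response, compartment = compartment,
                 log_scale = log_scale),
            class = "nested_test")
}

#' @export
print.nested_test <- function(x, ...) {
  cat(sprintf("Nested genotype test: %s (%s compartment%s)\n", x$response,
              x$compartment, if (x$log_scale) ", log scale" else ""))
  cat(sprintf("  estimate = %.4g (SE %.3g), t(%d) = %.3f, nested p = %.4g\n",
              x$estimate, x$se, x$df, x$statistic, x$p.value))
  if (x$singular) cat("  [singular fit: pooled OLS fallback]\n")
  cat(sprintf("  %d measurements from %d animals\n", x$n_obs, x$n_animals))
  invisible(x)
}

#' Fraction of synapses containing a mitochondrion, by genotype
#'
#' Computes, per animal, the fraction of scored synapses containing at
#' least one mitochondrial profile, then compares genotypes with a
#' two-sample Student t test across animals (the animal is the
#' experimental unit). Animals with zero synapses are excluded.
#'
#' @param records Morphometry data.frame.
#' @return List of class `mito_presence`: `per_animal` (data.frame with
#'   animal fractions), `genotype_mean_pct` (named), `p.value`,
#'   `zero_variance` flag.
#' @export
mito_presence_test <- function(records) {
  syn <- unique(records[, c("animal_id", "genotype", "synapse_id")])
  has <- tapply(records$has_mito, records$synapse_id, any)
  syn$has_mito <- as.logical(has[syn$synapse_id])
  per_animal <- stats::aggregate(has_mito ~ animal_id + genotype, data = syn,
                          FUN = mean)
  names(per_animal)[names(per_animal) == "has_mito"] <- "fraction"
  counts <- stats::aggregate(has_mito ~ animal_id, data = syn, FUN = length)
  keep <- counts$animal_id[counts$has_mito > 0]
  per_animal <- per_animal[per_animal$animal_id %in% keep, , drop = FALSE]
  genos <- unique(per_animal$genotype)
  if (length(genos) < 2L || any(table(per_animal$genotype) < 2L)) {
    stop("need >=2 animals per genotype", call. = FALSE)
  }
  mean_pct <- 100 * tapply(per_animal$fraction, per_animal$genotype, mean)
  v <- tapply(per_animal$fraction, per_animal$genotype, stats::var)
  zero_var <- all(v == 0)
  p <- if (zero_var) 1 else
    stats::t.test(fraction ~ genotype, data = per_animal,
                  var.equal = TRUE)$p.value
  structure(list(per_animal = per_animal,
                 genotype_mean_pct = stats::setNames(as.numeric(mean_pct[genos]),
                                                     genos),
                 p.value = p, zero_variance = zero_var),
            class = "mito_presence")
}

#' @export
print.mito_presence <- function(x, ...) {
  cat("Mito-containing synapse fraction (per-animal Student t):\n")
  for (g in names(x$genotype_mean_pct)) {
    cat(sprintf("  %s: %.1f%%\n", g, x$genotype_mean_pct[[g]]))
  }
  cat(sprintf("  p = %.3g%s\n", x$p.value,
              if (x$zero_variance) " (zero variance in both groups)" else ""))
  invisible(x)
}

#' Full morphometry analysis of one response
#'
#' Applies the fixed pipeline order — ROUT outlier removal (per genotype),
#' 500-nm proximity filter, shape metrics, nested genotype test — and also
#' reports the mito-presence comparison.
#'
#' @param records Morphometry data.frame.
#' @inheritParams nested_genotype_test
#' @param rout_q ROUT false-discovery threshold (default 0.01); `NULL`
#'   disables outlier removal.
#' @param max_distance Proximity cutoff in nm.
#' @return List with the `nested_test`, the `mito_presence` result and the
#'   outlier log.
#' @export
morpho_analyze <- function(records, response = "area", compartment = "post",
                           log_scale = FALSE, rout_q = 0.01,
                           max_distance = 500) {
  records <- proximity_filter(records, max_distance)
  n_out <- 0L
  if (!is.null(rout_q)) {
    resp_col <- switch(response, area = "area_um2", perimeter = "perimeter_um",
                       distance = "distance_nm", elongation = NULL)
    vals <- if (response == "elongation") {
      v <- rep(NA_real_, nrow(records))
      i <- records$has_mito & !is.na(records$area_um2)
      v[i] <- shape_metrics(records$area_um2[i], records$perimeter_um[i])$elongation
      v
    } else records[[resp_col]]
    for (g in unique(records$genotype)) {
      idx <- which(records$genotype == g & records$has_mito & is.finite(vals))
      if (length(idx) >= 5L) {
        ro <- robust_outliers(vals[idx], q = rout_q)
        drop <- idx[ro$idx_flagged]
        if (length(drop)) {
          records$has_mito[drop] <- FALSE
          records$area_um2[drop] <- NA_real_
          records$perimeter_um[drop] <- NA_real_
          records$distance_nm[drop] <- NA_real_
          n_out <- n_out + length(drop)
        }
      }
    }
  }
  list(nested = nested_genotype_test(records, response, compartment, log_scale),
       presence = mito_presence_test(records),
       n_outliers_removed = n_out)
}
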