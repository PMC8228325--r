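# Annotation-driven analysis of fold-change distributions: subsetting by a
# mitochondrial annotation, a randomized-selection distribution test,
# per-category summaries, and hypergeometric over-representation.

#' Construct an annotation set
#'
#' @param name Set name.
#' @param members Character vector of protein/gene IDs (case-normalized to
#'   upper case for matching).
#' @param source Free-text source tag (e.g. `"known_mito"`, `"function"`).
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(name, members, source = "") {
  members <- unique(toupper(as.character(members)))
  if (length(members) == 0L) stop("annotation set is empty", call. = FALSE)
  structure(list(name = name, members = members, source = source),
            class = "annotation_set")
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-separated GMT file (name, description,
#'   members...). Parsing is delegated to fgsea.
#' @param source Source tag applied to every set.
#' @return Named list of `annotation_set` objects.
#' @export
read_gmt <- function(path, source = "") {
  sets <- fgsea::gmtPathways(path)
  lapply(stats::setNames(names(sets), names(sets)), function(nm)
    annotation_set(nm, sets[[nm]], source = source))
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of `annotation_set` objects or character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    s <- sets[[nm]]
    members <- if (inherits(s, "annotation_set")) s$members else s
    paste(c(nm, "na", members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Split fold-changes by annotation membership
#'
#' @param de A `modt` fit or DEResult data.frame.
#' @param ann An `annotation_set`.
#' @return List with `target` (fold-changes of annotated proteins, named)
#'   and `background` (the rest). IDs are matched case-insensitively.
#' @export
subset_foldchanges <- function(de, ann) {
  tab <- as_de_table(de)
  ids <- toupper(tab$protein_id)
  hit <- ids %in% ann$members
  if (!any(hit)) {
    stop(sprintf("no overlap between DE table and annotation '%s'; %s",
                 ann$name, "check the ID namespace (gene vs protein IDs)"),
         call. = FALSE)
  }
  list(target = stats::setNames(tab$log2fc[hit], tab$protein_id[hit]),
       background = stats::setNames(tab$log2fc[!hit], tab$protein_id[!hit]))
}

#' Randomized-selection test on an annotation's fold-change distribution
#'
#' Tests whether the fold-change distribution of an annotated protein set
#' differs from that of randomly selected proteins. For each of `n_iter`
#' iterations a random protein set of the target's size is drawn without
#' replacement from the non-target quantified proteins; the primary
#' statistic is the two-sample Kolmogorov-Smirnov D between the target
#' fold-changes and the `n_iter` pooled random draws. Drawing from the
#' complement keeps the comparison's null calibrated (a pool containing
#' the target's own values would share observations with it and bias the
#' KS p-value upward). Because the pooled draws resample the same
#' complement values, they carry the information of one complement-sized
#' sample, not of `n_iter` independent ones; the p-value therefore uses
#' the asymptotic Kolmogorov tail with effective sample sizes
#' `(n_target, n_background)`. Per-iteration D statistics against each
#' individual draw are also returned.
#'
#' @param de A `modt` fit or DEResult data.frame.
#' @param ann An `annotation_set`; at least 10 members must be quantified.
#' @param n_iter Number of random selections (default 100).
#' @param seed Optional seed for reproducible draws.
#' @return Object of class `dist_test`: `n_target`, `n_iterations`,
#'   `statistic` (KS D), `p_pooled`, `per_iteration` (vector of per-draw
#'   D), `method`.
#' @export
randomized_selection_test <- function(de, ann, n_iter = 100L, seed = NULL) {
  stop_if_not_count(n_iter, "n_iter")
  fc <- subset_foldchanges(de, ann)
  # fix the drawing order by ID so results do not depend on row order
  target <- fc$target[order(names(fc$target))]
  bg <- fc$background[order(names(fc$background))]
  if (length(target) < 10L) {
    stop("need at least 10 annotated proteins in the DE table", call. = FALSE)
  }
  if (length(target) > length(bg)) {
    stop("target set larger than the non-target background", call. = FALSE)
  }
  with_seed_if(seed, {
    draws <- lapply(seq_len(n_iter), function(i)
      bg[sample.int(length(bg), length(target))])
    pooled <- unlist(draws, use.names = FALSE)
    D <- unname(suppressWarnings(stats::ks.test(target, pooled)$statistic))
    # Kolmogorov upper tail at the honest effective sample sizes
    x <- sqrt(length(target) * length(bg) /
                (length(target) + length(bg))) * D
    k <- seq_len(100)
    p <- min(1, max(1e-300, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))))
    per_iter <- vapply(draws, function(d)
      suppressWarnings(stats::ks.test(target, d)$statistic), numeric(1))
    structure(list(n_target = length(target),
                   n_iterations = n_iter,
                   statistic = D,
                   p_pooled = p,
                   per_iteration = unname(per_iter),
                   method = "two-sample KS vs pooled randomized selections"),
              class = "dist_test")
  })
}

#' @export
print.dist_test <- function(x, ...) {
  cat(sprintf("Randomized-selection distribution test (%s)\n", x$method))
  cat(sprintf("  n_target = %d, iterations = %d\n", x$n_target, x$n_iterations))
  cat(sprintf("  KS D = %.4f, p = %.3g\n", x$statistic, x$p_pooled))
  invisible(x)
}

#' Fold-change summaries per functional category
#'
#' @param de A `modt` fit or DEResult data.frame.
#' @param categories Named list of `annotation_set` objects (e.g. OXPHOS,
#'   mitochondrial carrier, dynamics, matrix, ...).
#' @param fc_line Reference fold-change line (log2; default 0.1, matching
#'   the conventional +/-0.1 dotted guides on category boxplots).
#' @return data.frame sorted by decreasing median log2 fold-change:
#'   `category`, `n`, `median_log2fc`, `median_fold` (linear scale), `iqr`,
#'   `frac_above_line` (fraction with |log2fc| > `fc_line`).
#' @export
category_summary <- function(de, categories, fc_line = 0.1) {
  tab <- as_de_table(de)
  ids <- toupper(tab$protein_id)
  rows <- lapply(names(categories), function(nm) {
    memb <- categories[[nm]]$members
    fc <- tab$log2fc[ids %in% memb]
    data.frame(category = nm, n = length(fc),
               median_log2fc = if (length(fc)) stats::median(fc) else NA_real_,
               median_fold = if (length(fc)) 2^stats::median(fc) else NA_real_,
               iqr = if (length(fc)) stats::IQR(fc) else NA_real_,
               frac_above_line = if (length(fc)) mean(abs(fc) > fc_line)
                                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$median_log2fc, out$category, na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "fc_line") <- fc_line
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation, tests whether the hit set overlaps it more than
#' expected under random sampling from the background, via the
#' hypergeometric upper tail; p-values are Benjamini-Hochberg adjusted
#' across annotations.
#'
#' @param hits Character vector of hit IDs (must be a subset of
#'   `background`).
#' @param background Character vector: the quantified universe.
#' @param annotations Named list of `annotation_set` objects.
#' @param fdr_q Significance threshold on the adjusted q-value.
#' @return data.frame sorted by q: `annotation`, `n_set` (in background),
#'   `overlap`, `expected`, `p`, `q`, `significant`.
#' @export
hypergeometric_ora <- function(hits, background, annotations, fdr_q = 0.05) {
  hits <- unique(toupper(hits)); background <- unique(toupper(background))
  if (!all(hits %in% background)) {
    stop("hits must be a subset of the background", call. = FALSE)
  }
  N <- length(background); n <- length(hits)
  rows <- lapply(names(annotations), function(nm) {
    memb <- intersect(annotations[[nm]]$members, background)
    K <- length(memb)
    k <- length(intersect(memb, hits))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(annotation = nm, n_set = K, overlap = k,
               expected = n * K / N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr_q
  out <- out[order(out$q, out$p), ]
  rownames(out) <- NULL
  out
}
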