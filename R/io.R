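# Plain-text readers and writers for the pipeline's tables. All formats
# are TSV/CSV with headers; matrices carry their row names in an `id`
# first column.

#' Read / write a peptide quantification table
#'
#' TSV with columns `peptide_id`, `protein_id`, then `intensity_<sample>`
#' and `qvalue_<sample>` for every sample.
#'
#' @param path File path.
#' @return `read_peptide_table` returns the data.frame after schema
#'   validation (positive intensities where measured, Q-values in [0,1],
#'   one protein per peptide).
#' @export
read_peptide_table <- function(path) {
  pt <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_peptide_table(pt)
  pt
}

#' @rdname read_peptide_table
#' @param pt Peptide table data.frame.
#' @export
write_peptide_table <- function(pt, path) {
  utils::write.table(pt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate the peptide-table schema
#'
#' @param pt Peptide table data.frame.
#' @return Invisibly `TRUE`; errors describe the violated invariant.
#' @export
validate_peptide_table <- function(pt) {
  if (!all(c("peptide_id", "protein_id") %in% names(pt))) {
    stop("peptide table needs 'peptide_id' and 'protein_id' columns",
         call. = FALSE)
  }
  if (anyDuplicated(pt$peptide_id)) {
    stop("duplicate peptide_id: each peptide maps to exactly one protein",
         call. = FALSE)
  }
  ints <- pt_matrix(pt, "intensity")
  if (any(ints <= 0, na.rm = TRUE)) {
    stop("intensities must be positive where measured", call. = FALSE)
  }
  q <- pt_matrix(pt, "qvalue")
  if (any(q < 0 | q > 1, na.rm = TRUE)) {
    stop("Q-values must lie in [0, 1]", call. = FALSE)
  }
  if (!identical(colnames(ints), colnames(q))) {
    stop("intensity and qvalue columns cover different samples", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write a sample-to-group design table
#'
#' TSV with columns `sample_id`, `group` and optionally `block`.
#'
#' @param path File path.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(d))) {
    stop("design needs 'sample_id' and 'group' columns", call. = FALSE)
  }
  if (anyDuplicated(d$sample_id)) {
    stop("every sample must be assigned exactly one group", call. = FALSE)
  }
  d
}

#' @rdname read_design
#' @param design Design data.frame.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a protein matrix to TSV
#'
#' @param pm A `protein_matrix`.
#' @param path File path.
#' @export
write_protein_matrix <- function(pm, path) {
  df <- data.frame(protein_id = rownames(pm$log2),
                   n_peptides = pm$n_peptides[rownames(pm$log2)],
                   pm$log2, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write morphometry records
#'
#' CSV with columns `animal_id`, `genotype`, `synapse_id`, `compartment`,
#' `has_mito`, `area_um2`, `perimeter_um`, `distance_nm`,
#' `synapse_length_nm`.
#'
#' @param path File path.
#' @export
read_morphometry <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "genotype", "synapse_id", "compartment", "has_mito",
            "area_um2", "perimeter_um", "distance_nm")
  if (!all(need %in% names(d))) {
    stop("morphometry file missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  d$has_mito <- as.logical(d$has_mito)
  i <- d$has_mito & !is.na(d$area_um2)
  if (any(d$area_um2[i] <= 0) || any(d$perimeter_um[i] <= 0)) {
    stop("areas and perimeters must be positive where a mitochondrion is present",
         call. = FALSE)
  }
  d
}

#' @rdname read_morphometry
#' @param records Morphometry data.frame.
#' @export
write_morphometry <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a count matrix as TSV
#'
#' Genes in rows (first column `gene`), cells in columns.
#'
#' @param path File path.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts Gene-by-cell integer matrix.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
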