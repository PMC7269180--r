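# TSV interchange: intensity tables are feature-by-sample, first column the
# feature id, header row the sample names, tab-delimited.

#' Read a features x samples intensity table (TSV)
#'
#' @param path TSV file: first column feature ids, header row sample names.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_intensity_table <- function(path) {
  if (!file.exists(path)) stop("intensity table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("intensity table needs a feature column plus >= 1 sample column: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate feature ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric or missing intensities in ", path)
  rownames(m) <- ids
  m
}

#' Read a phenotype table mapping samples to cell types
#'
#' @param path two-column TSV with header: sample_id, cell_type.
#' @return named character vector (sample id -> cell-type label).
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("phenotype table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("phenotype table needs sample_id and cell_type columns: ", path)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read a reference profile from intensity + phenotype TSVs
#'
#' @param counts_path features x reference-samples intensity TSV.
#' @param phenotype_path sample-to-cell-type TSV (see [read_phenotype()]).
#' @return a \code{reference_profile}.
#' @export
read_reference_profile <- function(counts_path, phenotype_path) {
  reference_profile(read_intensity_table(counts_path),
                    read_phenotype(phenotype_path))
}

#' Read a mixture matrix (features x mixture samples) from TSV
#'
#' @param path intensity TSV, same layout as the reference table.
#' @return numeric matrix.
#' @export
read_mixture_matrix <- function(path) {
  m <- read_intensity_table(path)
  if (any(m < 0)) stop("mixture intensities must be nonnegative: ", path)
  m
}

#' Write a numeric matrix as a feature-id-first TSV
#'
#' @param m matrix with rownames (feature ids) and colnames.
#' @param path output path.
#' @param id_col header name for the feature-id column.
#' @return the path, invisibly.
#' @export
write_intensity_table <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
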