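#' Construct a labeled reference intensity profile
#'
#' A reference profile holds a features x samples matrix of nonnegative peak
#' (or gene) intensities for purified reference samples, together with the
#' cell-type label of each sample. It is the raw material from which the
#' signature matrix is derived.
#'
#' @param values numeric matrix, features in rows (unique rownames required),
#'   reference samples in columns (colnames required); entries finite and >= 0.
#' @param labels named character vector mapping every sample (column) name to
#'   a cell-type label; at least two distinct cell types are required.
#' @return an object of class \code{reference_profile}: a list with elements
#'   \code{values} and \code{labels}.
#' @export
reference_profile <- function(values, labels) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("'values' must have unique rownames (feature ids)")
  }
  if (is.null(colnames(values))) stop("'values' must have colnames (sample ids)")
  if (!all(is.finite(values))) stop("intensities must be finite")
  if (any(values < 0)) stop("intensities must be nonnegative")
  missing <- setdiff(colnames(values), names(labels))
  if (length(missing) > 0L) {
    stop("samples without a cell-type label: ", paste(missing, collapse = ", "))
  }
  labels <- labels[colnames(values)]
  if (length(unique(labels)) < 2L) stop("at least 2 cell types are required")
  structure(list(values = values, labels = labels),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("reference_profile: %d features x %d samples, %d cell types\n",
              nrow(x$values), ncol(x$values), length(unique(x$labels))))
  tab <- table(x$labels)
  cat(paste(sprintf("  %s (%d)", names(tab), tab), collapse = "\n"), "\n")
  invisible(x)
}

#' Cell types present in a reference profile
#' @param profile a \code{reference_profile}.
#' @return character vector of cell-type names, in order of first appearance.
#' @export
cell_types <- function(profile) {
  unique(unname(profile$labels))
}

#' Quantile-normalize a reference profile across samples
#'
#' Forces every sample (column) to share the same marginal distribution: the
#' vector of row means of the column-sorted matrix. Tied values within a
#' column receive the mean of the reference quantiles they span (the limma
#' convention), so the operation is deterministic. Applied to the reference
#' only; mixtures are left on their measured scale.
#'
#' @param profile a \code{reference_profile} with >= 2 samples.
#' @return the normalized \code{reference_profile}.
#' @export
quantile_normalize <- function(profile) {
  stopifnot(inherits(profile, "reference_profile"))
  if (ncol(profile$values) < 2L) {
    stop("quantile normalization requires >= 2 samples")
  }
  norm <- limma::normalizeQuantiles(profile$values, ties = TRUE)
  dimnames(norm) <- dimnames(profile$values)
  profile$values <- norm
  profile
}

#' Drop features below the global median intensity
#'
#' Computes the median over all entries of the (already quantile-normalized)
#' matrix and retains a feature iff its maximum intensity across samples is at
#' least that global median. Using the row maximum (rather than the row mean)
#' keeps peaks that are strong in even a single cell type, protecting
#' candidate markers of rare cell types — which is the point of the filter.
#' Single pass: the median is computed once, on the input matrix.
#'
#' @param profile a quantile-normalized \code{reference_profile}.
#' @return the row-subset \code{reference_profile}; warns if fewer than 100
#'   features survive.
#' @export
median_intensity_filter <- function(profile) {
  stopifnot(inherits(profile, "reference_profile"))
  global_median <- stats::median(profile$values)
  row_max <- apply(profile$values, 1L, max)
  keep <- row_max >= global_median
  if (sum(keep) < 100L) {
    warning(sprintf("only %d features survive the median intensity filter",
                    sum(keep)))
  }
  profile$values <- profile$values[keep, , drop = FALSE]
  profile
}
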