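# Signature matrix construction. The signature matrix B (features x cell
# types) holds, for each selected CTSP, its mean intensity in each cell
# type's reference samples. Using too many CTSPs adds noise and can make the
# linear system m = B f ill-conditioned, so the per-type CTSP count n is
# swept from g to G and the candidate whose column-z-scored matrix has the
# smallest 2-norm condition number is retained (the CIBERSORT optimization
# strategy). The z-scoring is a scoring normalization only; deconvolution
# uses the raw means matrix, which carries the nonnegative mixing semantics.

#' Per-cell-type mean intensities for a set of features
#'
#' @param profile a \code{reference_profile}.
#' @param features character vector of feature ids (must exist in the profile).
#' @return features x cell-types matrix; entry (i, k) is the arithmetic mean
#'   of feature i over the samples labeled k.
#' @export
celltype_means <- function(profile, features = rownames(profile$values)) {
  stopifnot(inherits(profile, "reference_profile"))
  unknown <- setdiff(features, rownames(profile$values))
  if (length(unknown) > 0L) {
    stop("unknown features: ", paste(utils::head(unknown, 5L), collapse = ", "))
  }
  types <- cell_types(profile)
  sub <- profile$values[features, , drop = FALSE]
  out <- vapply(types, function(k) {
    rowMeans(sub[, profile$labels == k, drop = FALSE])
  }, numeric(length(features)))
  out <- matrix(out, nrow = length(features), ncol = length(types),
                dimnames = list(features, types))
  out
}

#' 2-norm condition number of a matrix
#'
#' Ratio of the largest to the smallest singular value. Returns \code{Inf}
#' when the smallest singular value is zero within a relative tolerance of
#' \code{1e-12} of the largest (numerically singular).
#'
#' @param m numeric matrix with at least one nonzero entry.
#' @return condition number (>= 1, possibly \code{Inf}).
#' @export
condition_number <- function(m) {
  m <- as.matrix(m)
  if (all(m == 0)) stop("condition number of the all-zero matrix is undefined")
  d <- svd(m, nu = 0L, nv = 0L)$d
  if (min(d) <= 1e-12 * max(d)) return(Inf)
  max(d) / min(d)
}

# Column z-score for condition-number scoring: each cell-type column is
# standardized across the candidate features (the scale()/zscore axis-0
# convention). Row-wise centering would be degenerate here: subtracting the
# row mean makes every row orthogonal to the all-ones vector, so a
# row-centered k-column matrix has rank <= k - 1 and its smallest singular
# value is identically zero — every candidate would score as singular.
# Column standardization preserves rank and makes the condition number
# measure the collinearity of the cell-type profiles themselves. Returns
# NULL when a column is constant (no contrast; candidate skipped).
col_zscore <- function(m) {
  sdv <- apply(m, 2L, stats::sd)
  if (any(sdv == 0)) return(NULL)
  scale(m, center = TRUE, scale = sdv)
}

#' Build the signature matrix by condition-number sweep
#'
#' For each per-type CTSP count n in \code{g..G}: take the top-n CTSPs of each
#' cell type by pi-value, form the union of their features, build the
#' cell-type-means matrix, z-score each cell-type column across the candidate
#' features (a scoring copy only), and compute its condition number.
#' The candidate with the minimum condition number wins (ties: the smallest
#' n); the returned signature holds the raw (un-z-scored) means restricted to
#' the winning feature set. Cell types with fewer than n CTSPs contribute all
#' they have (with a warning when below g); a cell type with none is an error
#' since the signature could not represent it.
#'
#' @param ctsps CTSP table from [call_ctsps()].
#' @param profile the \code{reference_profile} the CTSPs were called from.
#' @param g,G minimum and maximum per-type CTSP count (2 <= g <= G).
#'   Defaults 50 and 150, the customary marker-sweep range for
#'   condition-number-optimized signatures.
#' @return object of class \code{signature_matrix}: list with \code{values}
#'   (features x cell-types means matrix), \code{condition_number},
#'   \code{n_per_type}, \code{g}, \code{G}.
#' @export
build_signature <- function(ctsps, profile, g = 50L, G = 150L) {
  stopifnot(inherits(profile, "reference_profile"))
  if (!(g >= 2L && g <= G)) stop("need 2 <= g <= G")
  types <- cell_types(profile)
  missing_types <- setdiff(types, unique(ctsps$cell_type))
  if (length(missing_types) > 0L) {
    stop("cell types with zero CTSPs (signature cannot represent them): ",
         paste(missing_types, collapse = ", "))
  }
  by_type <- split(ctsps, ctsps$cell_type)
  by_type <- lapply(by_type, function(d) d[order(-d$pi_value), , drop = FALSE])
  avail <- vapply(by_type, nrow, 0L)
  if (any(avail < g)) {
    warning("cell types with fewer than g = ", g, " CTSPs contribute all ",
            "they have: ",
            paste(names(avail)[avail < g], collapse = ", "))
  }
  best <- NULL
  for (n in seq.int(g, G)) {
    feats <- unique(unlist(lapply(by_type, function(d) {
      d$feature_id[seq_len(min(n, nrow(d)))]
    }), use.names = FALSE))
    if (length(feats) < length(types)) next  # unidentifiable candidate
    B <- celltype_means(profile, feats)
    Z <- col_zscore(B)
    if (is.null(Z)) next
    kappa <- condition_number(Z)
    if (!is.finite(kappa)) next  # numerically singular candidate, skip
    if (is.null(best) || kappa < best$condition_number) {
      best <- list(values = B, condition_number = kappa, n_per_type = n)
    }
  }
  if (is.null(best)) {
    stop("every candidate signature in the sweep was singular")
  }
  structure(list(values = best$values,
                 condition_number = best$condition_number,
                 n_per_type = best$n_per_type, g = g, G = G),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf(paste0("signature_matrix: %d features x %d cell types ",
                     "(n_per_type = %d of sweep %d..%d, condition number ",
                     "%.3f)\n"),
              nrow(x$values), ncol(x$values), x$n_per_type, x$g, x$G,
              x$condition_number))
  invisible(x)
}

#' Write a signature matrix (TSV + sidecar JSON)
#'
#' The TSV holds the feature-by-cell-type means; the JSON records the sweep
#' outcome: \code{n_per_type}, \code{condition_number}, \code{g}, \code{G},
#' \code{n_features}.
#'
#' @param signature a \code{signature_matrix}.
#' @param path TSV output path; the JSON goes to \code{paste0(path, ".json")}
#'   unless \code{json_path} is given.
#' @param json_path optional explicit sidecar path.
#' @return the TSV path, invisibly.
#' @export
write_signature <- function(signature, path, json_path = NULL) {
  write_intensity_table(signature$values, path)
  if (is.null(json_path)) json_path <- paste0(path, ".json")
  jsonlite::write_json(
    list(n_per_type = signature$n_per_type,
         condition_number = signature$condition_number,
         g = signature$g, G = signature$G,
         n_features = nrow(signature$values)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signature matrix TSV written by [write_signature()]
#'
#' The sidecar JSON is consulted when present; otherwise the metadata fields
#' are set to NA (a user-supplied marker matrix is acceptable as-is).
#'
#' @param path signature TSV path.
#' @return a \code{signature_matrix}.
#' @export
read_signature <- function(path) {
  values <- read_intensity_table(path)
  meta <- list(n_per_type = NA_integer_, condition_number = NA_real_,
               g = NA_integer_, G = NA_integer_)
  json_path <- paste0(path, ".json")
  if (file.exists(json_path)) {
    meta <- utils::modifyList(meta, jsonlite::read_json(json_path,
                                                        simplifyVector = TRUE))
  }
  structure(list(values = values,
                 condition_number = meta$condition_number,
                 n_per_type = meta$n_per_type, g = meta$g, G = meta$G),
            class = "signature_matrix")
}
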