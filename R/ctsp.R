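# Cell-type-specific peaks (CTSPs). A CTSP is an open-chromatin region (or
# gene) whose intensity is elevated in one cell type relative to EVERY other
# cell type. Specificity is assessed with an intersection-union test (IUT):
# the candidate type is the one with the highest mean intensity, a one-sided
# Welch t-test (candidate > other) is run against each remaining type, and
# the IUT p-value is the maximum of the component p-values — significant only
# when the candidate beats all of them. Ranking uses the pi-value,
# log2 fold change x (-log10 p), combining effect size and significance.

#' Test one feature for cell-type specificity (intersection-union test)
#'
#' @param profile a \code{reference_profile}; every cell type must have >= 2
#'   replicate samples.
#' @param feature_id feature to test.
#' @param pseudocount added to both means before the fold-change ratio, so
#'   silent peaks do not divide by zero.
#' @return one-row data.frame: \code{feature_id}, \code{cell_type} (candidate,
#'   the argmax-mean type), \code{log2_fc} (candidate over runner-up mean,
#'   pseudocounted), \code{p_iut}, \code{pi_value}.
#' @export
test_ctsp <- function(profile, feature_id, pseudocount = 1) {
  stopifnot(inherits(profile, "reference_profile"))
  if (!feature_id %in% rownames(profile$values)) {
    stop("unknown feature: ", feature_id)
  }
  check_replicates(profile)
  x <- profile$values[feature_id, ]
  groups <- split(unname(x), unname(profile$labels))
  ctsp_stat_one(feature_id, groups, pseudocount)
}

check_replicates <- function(profile) {
  n_rep <- table(profile$labels)
  thin <- names(n_rep)[n_rep < 2L]
  if (length(thin) > 0L) {
    stop("cell types with < 2 replicate samples (variance undefined): ",
         paste(thin, collapse = ", "))
  }
  invisible(NULL)
}

# groups: named list of replicate intensity vectors, one entry per cell type.
ctsp_stat_one <- function(feature_id, groups, pseudocount) {
  means <- vapply(groups, mean, 0)
  ord <- order(means, decreasing = TRUE)
  candidate <- names(means)[ord[1L]]
  runner_up_mean <- means[ord[2L]]
  log2_fc <- log2((means[ord[1L]] + pseudocount) /
                  (runner_up_mean + pseudocount))
  p_each <- vapply(names(means)[-match(candidate, names(means))], function(k) {
    x <- groups[[candidate]]; y <- groups[[k]]
    # both groups numerically constant (quantile normalization can produce
    # exact ties): the Welch statistic is undefined; fall back to comparing
    # the constants directly — certain separation or no evidence at all
    if (stats::var(x) + stats::var(y) <= .Machine$double.eps * mean(c(x, y))^2) {
      return(if (mean(x) > mean(y)) 0 else 1)
    }
    stats::t.test(x, y, alternative = "greater", var.equal = FALSE)$p.value
  }, 0)
  p_iut <- max(p_each)
  pi_value <- if (log2_fc > 0) {
    log2_fc * -log10(max(p_iut, .Machine$double.xmin))
  } else 0
  data.frame(feature_id = feature_id, cell_type = candidate,
             log2_fc = unname(log2_fc), p_iut = unname(p_iut),
             pi_value = unname(pi_value), stringsAsFactors = FALSE)
}

#' Call cell-type-specific peaks across all features
#'
#' Runs the intersection-union test on every feature and keeps, per cell type,
#' the features with \code{p_iut < max_p} and positive log2 fold change,
#' sorted by pi-value descending. Each feature is assigned to at most one
#' cell type (its argmax-mean candidate), so the groups partition the called
#' features.
#'
#' @param profile a \code{reference_profile} (normalized and filtered).
#' @param max_p IUT p-value cutoff in (0, 1]; default 0.05.
#' @param adjust if TRUE, Benjamini-Hochberg-adjust \code{p_iut} across
#'   features within each candidate cell type before thresholding.
#' @param pseudocount see [test_ctsp()].
#' @return data.frame of passing CTSPs (columns as [test_ctsp()]), ordered by
#'   cell type then pi-value descending. Cell types with zero passing CTSPs
#'   trigger a warning.
#' @export
call_ctsps <- function(profile, max_p = 0.05, adjust = FALSE,
                       pseudocount = 1) {
  stopifnot(inherits(profile, "reference_profile"))
  if (!(max_p > 0 && max_p <= 1)) stop("'max_p' must be in (0, 1]")
  check_replicates(profile)
  lab <- unname(profile$labels)
  groups_idx <- split(seq_along(lab), lab)
  vals <- profile$values
  stats_list <- lapply(rownames(vals), function(fid) {
    groups <- lapply(groups_idx, function(ix) vals[fid, ix])
    ctsp_stat_one(fid, groups, pseudocount)
  })
  all_stats <- do.call(rbind, stats_list)
  if (adjust) {
    all_stats$p_iut <- stats::ave(all_stats$p_iut, all_stats$cell_type,
                                  FUN = function(p) stats::p.adjust(p, "BH"))
    pos <- all_stats$log2_fc > 0
    all_stats$pi_value <- ifelse(
      pos,
      all_stats$log2_fc * -log10(pmax(all_stats$p_iut, .Machine$double.xmin)),
      0)
  }
  pass <- all_stats[all_stats$p_iut < max_p & all_stats$log2_fc > 0, ,
                    drop = FALSE]
  pass <- pass[order(pass$cell_type, -pass$pi_value), , drop = FALSE]
  rownames(pass) <- NULL
  empty <- setdiff(unique(lab), unique(pass$cell_type))
  if (length(empty) > 0L) {
    warning("cell types with no passing CTSPs: ", paste(empty, collapse = ", "))
  }
  pass
}

#' Write a CTSP table as TSV
#'
#' @param ctsps data.frame from [call_ctsps()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ctsp_table <- function(ctsps, path) {
  utils::write.table(ctsps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
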