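# Evaluation. When the true composition is known, agreement is summarized by
# RMSE and the Pearson correlation between estimated and true fractions.
# When it is not, goodness of fit is scored by the Wasserstein-1 distance
# between the value distributions of the observed mixture and its fitted
# reconstruction, calibrated into a p-value by Monte-Carlo sampling of
# random compositions from the uniform Dirichlet null.

#' Root-mean-square error between two vectors
#'
#' @param f_p,f_t equal-length numeric vectors (prediction, truth).
#' @return \code{sqrt(mean((f_p - f_t)^2))}.
#' @export
rmse <- function(f_p, f_t) {
  if (length(f_p) != length(f_t)) stop("length mismatch")
  sqrt(mean((f_p - f_t)^2))
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors, length >= 3.
#' @return the correlation, or NA (with a message) when either vector has
#'   zero variance.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("pcc undefined (zero variance); reporting NA")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Wasserstein-1 distance between two equal-length samples
#'
#' Order-free distance between the empirical value distributions: the mean
#' absolute difference of the sorted vectors (the exact 1-d Wasserstein-1
#' distance for equal-size samples).
#'
#' @param a,b equal-length numeric vectors.
#' @return nonnegative distance.
#' @export
wasserstein_distance <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  mean(abs(sort(a) - sort(b)))
}

#' Monte-Carlo Wasserstein p-value for a deconvolution fit
#'
#' The observed statistic is the Wasserstein-1 distance between the values of
#' the mixture column \code{m} and its fitted reconstruction \code{m_hat}
#' (both in transform space). The null pushes \code{n_draws} random
#' compositions \eqn{f_i \sim \mathrm{Dirichlet}(1, \ldots, 1)} through the
#' transformed signature, \eqn{\hat m_i = B_t f_i}, and computes the same
#' distance to \code{m}; the add-one estimator
#' \eqn{p = (1 + \#\{d_i \le d_{obs}\}) / (n_{draws} + 1)} is conservative
#' and never zero. Smaller distances (better fits) give smaller p-values.
#'
#' @param m observed mixture column (transform space).
#' @param m_hat fitted reconstruction \code{B_t f} (same length, same space).
#' @param signature transformed signature matrix \code{B_t} (features x cell
#'   types), the same one that produced \code{m_hat}.
#' @param n_draws Monte-Carlo draws, >= 99 (default 1000).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return list with \code{wasserstein_d} and \code{pvalue} (in
#'   \code{[1/(n_draws + 1), 1]}).
#' @export
wasserstein_pvalue <- function(m, m_hat, signature, n_draws = 1000L,
                               seed = 42L) {
  if (length(m) != length(m_hat)) stop("length mismatch")
  if (n_draws < 99L) stop("'n_draws' must be >= 99")
  B <- if (inherits(signature, "signature_matrix")) signature$values
       else as.matrix(signature)
  if (nrow(B) != length(m)) stop("signature rows must match length of m")
  d_obs <- wasserstein_distance(m, m_hat)
  k <- ncol(B)
  set.seed(seed)
  Fnull <- matrix(stats::rexp(k * n_draws), nrow = k)   # Dirichlet(1,...,1)
  Fnull <- sweep(Fnull, 2L, colSums(Fnull), "/")
  Mnull <- B %*% Fnull
  m_sorted <- sort(m)
  d_null <- apply(Mnull, 2L, function(col) mean(abs(sort(col) - m_sorted)))
  list(wasserstein_d = d_obs,
       pvalue = (1 + sum(d_null <= d_obs)) / (n_draws + 1))
}

#' Score a deconvolution run
#'
#' Per mixture: the Wasserstein goodness-of-fit distance and Monte-Carlo
#' p-value (skipped for degenerate estimates), and, when the true composition
#' is supplied, RMSE and Pearson correlation between estimated and true
#' fractions. Pooled: mean RMSE across mixtures and the Pearson correlation
#' over all (mixture, cell type) fraction pairs at once.
#'
#' @param result a \code{deconv_result} from [estimate_proportions()].
#' @param truth optional mixtures x cell-types matrix of true fractions;
#'   rows and columns are matched to the estimate by name when named.
#' @param n_draws,seed passed to [wasserstein_pvalue()]; draw i uses seed
#'   \code{seed + i - 1} so mixtures are independent but reproducible.
#' @return object of class \code{deconv_report}: list with
#'   \code{per_mixture} (data.frame: mixture_id, wasserstein_d, pvalue, and
#'   rmse/pcc when truth is known) and \code{pooled} (list: mean_rmse,
#'   pooled_pcc; NULL without truth).
#' @export
evaluate_deconvolution <- function(result, truth = NULL, n_draws = 1000L,
                                   seed = 42L) {
  stopifnot(inherits(result, "deconv_result"))
  props <- result$proportions
  n_mix <- nrow(props)
  if (!is.null(truth)) {
    truth <- as.matrix(truth)
    if (!is.null(rownames(truth)) && !is.null(rownames(props))) {
      truth <- truth[rownames(props), , drop = FALSE]
    }
    if (!is.null(colnames(truth))) {
      missing <- setdiff(colnames(props), colnames(truth))
      if (length(missing) > 0L) {
        stop("truth lacks cell types: ", paste(missing, collapse = ", "))
      }
      truth <- truth[, colnames(props), drop = FALSE]
    }
    stopifnot(dim(truth) == dim(props))
  }
  wd <- pv <- rep(NA_real_, n_mix)
  for (j in seq_len(n_mix)) {
    if (result$degenerate[j]) next      # all-zero estimate: p-value omitted
    w <- wasserstein_pvalue(result$mixture_transformed[, j],
                            result$fitted[, j],
                            result$signature_transformed,
                            n_draws = n_draws, seed = seed + j - 1L)
    wd[j] <- w$wasserstein_d
    pv[j] <- w$pvalue
  }
  per <- data.frame(mixture_id = rownames(props), wasserstein_d = wd,
                    pvalue = pv, stringsAsFactors = FALSE)
  pooled <- NULL
  if (!is.null(truth)) {
    per$rmse <- vapply(seq_len(n_mix),
                       function(j) rmse(props[j, ], truth[j, ]), 0)
    per$pcc <- vapply(seq_len(n_mix), function(j) {
      if (stats::sd(props[j, ]) == 0 || stats::sd(truth[j, ]) == 0) {
        NA_real_
      } else {
        stats::cor(props[j, ], truth[j, ])
      }
    }, 0)
    pooled <- list(mean_rmse = mean(per$rmse),
                   pooled_pcc = stats::cor(as.vector(props),
                                           as.vector(truth)))
  }
  structure(list(per_mixture = per, pooled = pooled),
            class = "deconv_report")
}

#' @export
print.deconv_report <- function(x, ...) {
  cat(sprintf("deconv_report: %d mixtures\n", nrow(x$per_mixture)))
  if (!is.null(x$pooled)) {
    cat(sprintf("  mean RMSE %.4f, pooled PCC %.4f\n",
                x$pooled$mean_rmse, x$pooled$pooled_pcc))
  }
  print(utils::head(x$per_mixture, 6L))
  invisible(x)
}
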