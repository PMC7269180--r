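# Deconvolution. The measurement model is m = B f: the mixture profile m is
# a nonnegative linear combination of the cell-type signature columns of B,
# weighted by the unknown proportion vector f. The regression is solved with
# SIMPLS (de Jong 1993), a partial-least-squares variant that extracts
# components directly from the predictor-response cross-product matrix and
# deflates that cross-product — at the full component count on well-
# conditioned predictors it coincides with least squares, while remaining
# stable when signature columns are near-collinear (lineage-adjacent cell
# types). Negative coefficients are clipped to zero and the remainder is
# renormalized to sum to one.

#' SIMPLS partial least squares regression
#'
#' De Jong's SIMPLS: columns of X and Y are mean-centered (no unit scaling —
#' intensity magnitudes carry signal); weight vectors are extracted from the
#' cross-product S = X'Y, which is deflated after each component by
#' projection onto the orthonormalized X-loadings. Deterministic for fixed
#' input.
#'
#' @param X n x p predictor matrix.
#' @param Y n x q response matrix (or length-n vector).
#' @param n_components number of components, 1..min(n-1, p); defaults to the
#'   rank-capped maximum. A request exceeding the rank of centered X is
#'   reduced with a warning.
#' @return p x q coefficient matrix mapping centered X to centered Y.
#' @references de Jong, S. (1993) SIMPLS: an alternative approach to partial
#'   least squares regression. Chemometrics and Intelligent Laboratory
#'   Systems 18, 251-263.
#' @export
simpls_fit <- function(X, Y, n_components = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (n < 2L) stop("need >= 2 observations")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (any(colSums(Xc^2) == 0)) {
    stop("zero-variance predictor column in X")
  }
  rank_x <- qr(Xc)$rank
  amax <- min(n - 1L, p, rank_x)
  if (is.null(n_components)) n_components <- amax
  if (n_components < 1L) stop("'n_components' must be >= 1")
  if (n_components > min(n - 1L, p)) {
    stop("'n_components' must be <= min(n - 1, p)")
  }
  if (n_components > amax) {
    warning("n_components reduced to the rank of centered X (", amax, ")")
    n_components <- amax
  }
  A <- n_components
  S <- crossprod(Xc, Yc)                       # p x q cross-product
  R <- matrix(0, p, A); P <- matrix(0, p, A)
  Q <- matrix(0, q, A); V <- matrix(0, p, A)
  for (a in seq_len(A)) {
    qa <- svd(S, nu = 0L, nv = 1L)$v[, 1L]     # dominant eigvec of S'S
    r <- S %*% qa                              # X weights
    t_score <- Xc %*% r
    t_score <- t_score - mean(t_score)
    normt <- sqrt(sum(t_score^2))
    if (normt < .Machine$double.eps^0.5) break # cross-product exhausted
    t_score <- t_score / normt
    r <- r / normt
    p_load <- crossprod(Xc, t_score)           # X loadings
    q_load <- crossprod(Yc, t_score)           # Y loadings
    v <- p_load
    if (a > 1L) {
      Vprev <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vprev %*% crossprod(Vprev, p_load)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)             # deflate the cross-product
    R[, a] <- r; P[, a] <- p_load; Q[, a] <- q_load; V[, a] <- v
  }
  coef <- R %*% t(Q)
  dimnames(coef) <- list(colnames(X), colnames(Y))
  coef
}

#' Estimate cell-type proportions in mixtures
#'
#' For each mixture column: restrict signature and mixture to their shared
#' features (exact feature-id match), transform both with the same chosen
#' transform (Box-Cox auto-selection by default, estimated from the pooled
#' mixture values), fit SIMPLS of the mixture on the signature columns, clip
#' negative coefficients to zero and renormalize to sum to one. Mixtures are
#' fit independently of one another.
#'
#' @param signature a \code{signature_matrix} or a plain features x cell-types
#'   matrix with rownames/colnames.
#' @param mixtures features x mixtures matrix (rownames required); a vector is
#'   treated as a single mixture.
#' @param transform a \code{transform_spec}, or a mode string passed to
#'   [transform_spec()] (default \code{"auto"}).
#' @param offset pseudocount for [transform_spec()] when \code{transform} is
#'   a mode string.
#' @param n_components SIMPLS components; default = number of cell types,
#'   capped at the rank of the transformed signature.
#' @return object of class \code{deconv_result}: list with
#'   \code{proportions} (mixtures x cell-types, rows sum to 1 unless
#'   degenerate), \code{raw_coefficients} (pre-clipping),
#'   \code{degenerate} (logical per mixture: all raw coefficients <= 0, in
#'   which case fractions are all zero), \code{transform} (finalized spec),
#'   \code{n_components}, \code{signature_transformed},
#'   \code{mixture_transformed}, and \code{fitted} (transform-space
#'   predictions B_t f per mixture).
#' @export
estimate_proportions <- function(signature, mixtures, transform = "auto",
                                 offset = 1, n_components = NULL) {
  B <- if (inherits(signature, "signature_matrix")) signature$values
       else as.matrix(signature)
  if (is.null(dim(mixtures))) {
    mixtures <- matrix(mixtures, ncol = 1L,
                       dimnames = list(names(mixtures), "mixture_1"))
  }
  mixtures <- as.matrix(mixtures)
  if (is.null(rownames(B)) || is.null(rownames(mixtures))) {
    stop("signature and mixtures need feature ids as rownames")
  }
  shared <- intersect(rownames(B), rownames(mixtures))
  k <- ncol(B)
  if (length(shared) == 0L) {
    stop("no features shared between signature and mixtures; check that the ",
         "two use the same id convention (e.g. 'chr1_100_600' peak ids or ",
         "identical gene symbols)")
  }
  if (length(shared) < k) {
    stop("only ", length(shared), " shared features for ", k,
         " cell types; proportions are unidentifiable")
  }
  spec <- if (inherits(transform, "transform_spec")) transform
          else transform_spec(transform, offset = offset)
  spec <- finalize_transform(spec, mixtures[shared, , drop = FALSE])
  Xt <- apply_transform(spec, B[shared, , drop = FALSE])
  Yt <- apply_transform(spec, mixtures[shared, , drop = FALSE])
  rank_x <- qr(scale(Xt, center = TRUE, scale = FALSE))$rank
  amax <- min(nrow(Xt) - 1L, k, rank_x)
  if (is.null(n_components)) {
    n_components <- amax          # number of cell types, rank-capped
  } else if (n_components > amax) {
    warning("n_components reduced to ", amax)
    n_components <- amax
  }
  n_mix <- ncol(Yt)
  props <- raw <- matrix(0, n_mix, k,
                         dimnames = list(colnames(Yt), colnames(Xt)))
  degenerate <- logical(n_mix)
  for (j in seq_len(n_mix)) {
    b <- drop(simpls_fit(Xt, Yt[, j, drop = FALSE], n_components))
    raw[j, ] <- b
    clipped <- pmax(b, 0)
    s <- sum(clipped)
    if (s <= 0) {
      degenerate[j] <- TRUE       # fractions left at zero, flagged
    } else {
      props[j, ] <- clipped / s
    }
  }
  structure(list(proportions = props, raw_coefficients = raw,
                 degenerate = degenerate, transform = spec,
                 n_components = n_components,
                 signature_transformed = Xt, mixture_transformed = Yt,
                 fitted = Xt %*% t(props)),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf(paste0("deconv_result: %d mixtures x %d cell types ",
                     "(transform = %s, %d SIMPLS components%s)\n"),
              nrow(x$proportions), ncol(x$proportions), x$transform$chosen,
              x$n_components,
              if (any(x$degenerate))
                sprintf(", %d degenerate", sum(x$degenerate)) else ""))
  print(utils::head(round(x$proportions, 4), 6L))
  invisible(x)
}

#' Write estimated proportions as TSV (mixtures in rows, cell types in columns)
#'
#' @param result a \code{deconv_result}.
#' @param path output path.
#' @param report optional \code{deconv_report} from [evaluate_deconvolution()];
#'   when given, its per-mixture \code{rmse}, \code{pvalue} columns are
#'   appended, along with the chosen transform.
#' @return the path, invisibly.
#' @export
write_proportions <- function(result, path, report = NULL) {
  df <- data.frame(mixture_id = rownames(result$proportions),
                   result$proportions, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(report)) {
    pm <- report$per_mixture
    stopifnot(identical(pm$mixture_id, df$mixture_id))
    if ("rmse" %in% names(pm)) df$rmse_fit <- pm$rmse
    df$pvalue <- pm$pvalue
  }
  df$chosen_transform <- result$transform$chosen
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
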