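# Automatic data transformation. Deconvolution quality depends on how close
# the intensity distribution is to normal; rather than fixing one scale, the
# Box-Cox profile likelihood estimates the power-transform parameter lambda
# from the mixture data and the estimate is snapped to the nearest of three
# scenarios: lambda = 0 (log2), lambda = 0.5 (square root), lambda = 1 (no
# transformation). The same chosen transform is applied to both the signature
# matrix and the mixtures so the linear model stays internally consistent.

#' Describe a transformation policy
#'
#' @param mode \code{"auto"} (estimate lambda from the mixture, then snap),
#'   or one of the fixed choices \code{"none"}, \code{"sqrt"}, \code{"log2"}.
#' @param offset pseudocount (> 0) added before lambda estimation and before
#'   the log2 transform; count-like intensities contain zeros.
#' @return a \code{transform_spec}: list with \code{mode}, \code{offset},
#'   \code{lambda_hat} (NA until estimated), \code{chosen} (NA until
#'   finalized when \code{mode = "auto"}).
#' @export
transform_spec <- function(mode = c("auto", "none", "sqrt", "log2"),
                           offset = 1) {
  mode <- match.arg(mode)
  stopifnot(offset > 0)
  structure(list(mode = mode, offset = offset, lambda_hat = NA_real_,
                 chosen = if (mode == "auto") NA_character_ else mode),
            class = "transform_spec")
}

#' Estimate the Box-Cox lambda by profile likelihood
#'
#' Maximizes the Box-Cox profile log-likelihood of an intercept-only model
#' over lambda in \eqn{[-2, 2]} (grid step 0.01, via \code{MASS::boxcox}).
#'
#' @param values strictly positive numeric vector, length >= 10.
#' @return the maximizing lambda.
#' @export
estimate_lambda <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 10L) stop("need >= 10 values to estimate lambda")
  if (any(values <= 0)) {
    stop("Box-Cox requires strictly positive values; add an offset first")
  }
  bc <- MASS::boxcox(values ~ 1, lambda = seq(-2, 2, by = 0.01),
                     plotit = FALSE)
  bc$x[which.max(bc$y)]
}

#' Snap an estimated lambda to one of the three supported transforms
#'
#' Nearest neighbor among lambda = 0 (log2), 0.5 (sqrt), 1 (none); the
#' midpoints 0.25 and 0.75 snap upward, toward linearity.
#'
#' @param lambda_hat estimated lambda.
#' @return \code{"log2"}, \code{"sqrt"} or \code{"none"}.
#' @export
snap_lambda <- function(lambda_hat) {
  if (lambda_hat < 0.25) "log2" else if (lambda_hat < 0.75) "sqrt" else "none"
}

#' Finalize a transform spec against observed data
#'
#' In \code{"auto"} mode, estimates lambda from the pooled values (plus the
#' offset) and snaps it; in fixed modes, returns the spec unchanged with
#' \code{chosen} already set.
#'
#' @param spec a \code{transform_spec}.
#' @param values nonnegative values to estimate from (the pooled mixture
#'   matrix, by convention).
#' @return the finalized \code{transform_spec} (\code{chosen} set).
#' @export
finalize_transform <- function(spec, values) {
  stopifnot(inherits(spec, "transform_spec"))
  if (spec$mode != "auto") return(spec)
  spec$lambda_hat <- estimate_lambda(as.numeric(values) + spec$offset)
  spec$chosen <- snap_lambda(spec$lambda_hat)
  spec
}

#' Apply a finalized transform to a nonnegative matrix
#'
#' \code{log2}: \eqn{x \mapsto \log_2(x + \mathrm{offset})}; \code{sqrt}:
#' \eqn{x \mapsto \sqrt{x}}; \code{none}: identity. All three are strictly
#' monotone, so within-column ranks are preserved.
#'
#' @param spec a finalized \code{transform_spec}.
#' @param m nonnegative numeric matrix (or vector).
#' @return the transformed matrix.
#' @export
apply_transform <- function(spec, m) {
  stopifnot(inherits(spec, "transform_spec"))
  if (is.na(spec$chosen)) {
    stop("transform_spec not finalized; call finalize_transform() first")
  }
  switch(spec$chosen,
         log2 = log2(m + spec$offset),
         sqrt = sqrt(m),
         none = m)
}
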