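# Intensity-level simulator. Generates labeled reference profiles and
# Dirichlet-weighted mixtures with the statistical structure the
# deconvolution model assumes: a lognormal background of peak intensities,
# per-cell-type marker peaks elevated by a known fold, multiplicative
# lognormal replicate noise, linear mixing of the true type-mean profiles,
# and optional blending of designated cell-type pairs to emulate
# lineage-adjacent (near-collinear) types. Everything is deterministic given
# the config seed, so ground truth is exact.

#' Simulation configuration
#'
#' @param n_cell_types number of cell types (>= 2).
#' @param n_features number of peaks/features.
#' @param n_markers_per_type planted marker peaks per type; marker blocks are
#'   disjoint, so \code{n_markers_per_type * n_cell_types <= n_features}.
#' @param n_replicates_per_type reference replicates per type (>= 2).
#' @param marker_fold elevation of marker peaks in their own type (> 1).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise on replicates and mixtures (>= 0; 0 means noiseless).
#' @param dirichlet_alpha Dirichlet concentration for mixture fractions:
#'   scalar (symmetric) or length-\code{n_cell_types} vector. The default 1
#'   is uniform over the simplex.
#' @param n_mixtures number of mixture samples.
#' @param collinearity optional list of \code{list(pair = c(a, b),
#'   weight = w)} entries, \code{w} in \eqn{[0, 1)}: type b's mean profile is
#'   blended toward type a's, \code{(1 - w) * mean_b + w * mean_a}. Types may
#'   be named or given as column indices.
#' @param n_present_types optionally restrict each mixture to this many
#'   randomly chosen cell types (others zeroed, fractions renormalized).
#' @param seed RNG seed (mandatory for reproducible truth).
#' @return a validated \code{simulation_config} list.
#' @export
simulation_config <- function(n_cell_types = 5L, n_features = 2000L,
                              n_markers_per_type = 100L,
                              n_replicates_per_type = 3L,
                              marker_fold = 10, noise_cv = 0.1,
                              dirichlet_alpha = 1, n_mixtures = 100L,
                              collinearity = NULL, n_present_types = NULL,
                              seed = 1L) {
  stopifnot(n_cell_types >= 2L, n_features >= 1L,
            n_replicates_per_type >= 2L, marker_fold > 1, noise_cv >= 0,
            n_mixtures >= 1L, all(dirichlet_alpha > 0))
  if (n_markers_per_type * n_cell_types > n_features) {
    stop("n_markers_per_type * n_cell_types must be <= n_features")
  }
  if (!length(dirichlet_alpha) %in% c(1L, n_cell_types)) {
    stop("dirichlet_alpha must be a scalar or one value per cell type")
  }
  if (!is.null(collinearity)) {
    for (cl in collinearity) {
      if (length(cl$pair) != 2L || is.null(cl$weight) || cl$weight < 0 ||
          cl$weight >= 1) {
        stop("each collinearity entry needs pair = c(a, b) and weight in [0, 1)")
      }
    }
  }
  if (!is.null(n_present_types)) {
    stopifnot(n_present_types >= 1L, n_present_types <= n_cell_types)
  }
  structure(list(n_cell_types = as.integer(n_cell_types),
                 n_features = as.integer(n_features),
                 n_markers_per_type = as.integer(n_markers_per_type),
                 n_replicates_per_type = as.integer(n_replicates_per_type),
                 marker_fold = marker_fold, noise_cv = noise_cv,
                 dirichlet_alpha = dirichlet_alpha,
                 n_mixtures = as.integer(n_mixtures),
                 collinearity = collinearity,
                 n_present_types = n_present_types,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Multiplicative lognormal noise factors with mean 1 and the requested CV.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a labeled reference profile with planted markers
#'
#' Base intensities are lognormal (meanlog 3, sdlog 1 — a count-like,
#' right-skewed background); each cell type's marker block is multiplied by
#' \code{marker_fold} in that type only; optional collinearity entries blend
#' type-pair mean profiles; replicates are the type mean times multiplicative
#' lognormal noise.
#'
#' @param config a \code{simulation_config}.
#' @param seed RNG seed; defaults to \code{config$seed}.
#' @return list with \code{profile} (a \code{reference_profile}),
#'   \code{marker_map} (named character: planted feature -> cell type) and
#'   \code{mean_profile} (the noiseless features x cell-types truth).
#' @export
simulate_reference <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  k <- config$n_cell_types
  types <- sprintf("CT%d", seq_len(k))
  feats <- sprintf("peak_%05d", seq_len(config$n_features))
  base <- stats::rlnorm(config$n_features, meanlog = 3, sdlog = 1)
  mean_profile <- matrix(base, nrow = config$n_features, ncol = k,
                         dimnames = list(feats, types))
  marker_map <- character(0)
  if (config$n_markers_per_type > 0L) {
    for (i in seq_len(k)) {
      block <- seq.int((i - 1L) * config$n_markers_per_type + 1L,
                       i * config$n_markers_per_type)
      mean_profile[block, i] <- mean_profile[block, i] * config$marker_fold
      marker_map[feats[block]] <- types[i]
    }
  }
  for (cl in config$collinearity) {
    a <- if (is.character(cl$pair[1L])) match(cl$pair[1L], types) else cl$pair[1L]
    b <- if (is.character(cl$pair[2L])) match(cl$pair[2L], types) else cl$pair[2L]
    mean_profile[, b] <- (1 - cl$weight) * mean_profile[, b] +
      cl$weight * mean_profile[, a]
  }
  n_rep <- config$n_replicates_per_type
  values <- matrix(0, config$n_features, k * n_rep)
  sample_ids <- character(k * n_rep)
  labels <- character(k * n_rep)
  col <- 0L
  for (i in seq_len(k)) {
    for (r in seq_len(n_rep)) {
      col <- col + 1L
      values[, col] <- mean_profile[, i] *
        lognormal_noise(config$n_features, config$noise_cv)
      sample_ids[col] <- sprintf("%s_rep%d", types[i], r)
      labels[col] <- types[i]
    }
  }
  dimnames(values) <- list(feats, sample_ids)
  list(profile = reference_profile(values,
                                   stats::setNames(labels, sample_ids)),
       marker_map = marker_map, mean_profile = mean_profile)
}

#' Simulate Dirichlet-weighted mixtures from a reference truth
#'
#' Per mixture j: draw \eqn{f_j \sim \mathrm{Dirichlet}(\alpha)} (optionally
#' restricted to \code{n_present_types} random types, renormalized); the
#' mixture column is \code{mean_profile \%*\% f_j} times multiplicative
#' lognormal noise.
#'
#' @param reference output of [simulate_reference()].
#' @param config the same \code{simulation_config}.
#' @param seed RNG seed; defaults to \code{config$seed + 1} so the mixture
#'   draws are decoupled from the reference draws.
#' @return list with \code{mixtures} (features x mixtures matrix) and
#'   \code{fractions} (mixtures x cell-types truth, rows summing to 1).
#' @export
simulate_mixtures <- function(reference, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  mean_profile <- reference$mean_profile
  k <- config$n_cell_types
  alpha <- rep(config$dirichlet_alpha, length.out = k)
  mix_ids <- sprintf("mix_%03d", seq_len(config$n_mixtures))
  fractions <- matrix(0, config$n_mixtures, k,
                      dimnames = list(mix_ids, colnames(mean_profile)))
  mixtures <- matrix(0, nrow(mean_profile), config$n_mixtures,
                     dimnames = list(rownames(mean_profile), mix_ids))
  for (j in seq_len(config$n_mixtures)) {
    f <- stats::rgamma(k, shape = alpha)
    if (!is.null(config$n_present_types) && config$n_present_types < k) {
      absent <- sample.int(k, k - config$n_present_types)
      f[absent] <- 0
    }
    f <- f / sum(f)
    fractions[j, ] <- f
    mixtures[, j] <- drop(mean_profile %*% f) *
      lognormal_noise(nrow(mean_profile), config$noise_cv)
  }
  list(mixtures = mixtures, fractions = fractions)
}

#' Simulate a complete truth-known dataset
#'
#' Convenience wrapper: [simulate_reference()] then [simulate_mixtures()].
#'
#' @param config a \code{simulation_config}.
#' @return list with \code{reference} (a \code{reference_profile}),
#'   \code{mixtures}, \code{fractions}, \code{marker_map},
#'   \code{mean_profile}, and the \code{config}.
#' @export
simulate_dataset <- function(config) {
  ref <- simulate_reference(config)
  mix <- simulate_mixtures(ref, config)
  list(reference = ref$profile, mixtures = mix$mixtures,
       fractions = mix$fractions, marker_map = ref$marker_map,
       mean_profile = ref$mean_profile, config = config)
}
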