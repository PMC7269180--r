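# Independent oracles and tiny fixture builders shared across the suite.
# Every oracle is deliberately brute-force / closed-form and shares no code
# with the implementation it checks.

make_peaks <- function(chrom, start, end, score, sample_id = "s1") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = paste0("p", seq_along(chrom)), score = score,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

# Brute-force greedy non-redundant selection: repeatedly take the top-scored
# remaining peak (ties: chrom, start) and delete everything overlapping it.
greedy_atlas_oracle <- function(peaks) {
  remaining <- peaks[order(-peaks$score, peaks$chrom, peaks$start), ,
                     drop = FALSE]
  kept <- remaining[0, ]
  while (nrow(remaining) > 0L) {
    top <- remaining[1L, ]
    kept <- rbind(kept, top)
    hit <- remaining$chrom == top$chrom &
      remaining$start < top$end & top$start < remaining$end
    remaining <- remaining[!hit, , drop = FALSE]
  }
  kept <- kept[order(kept$chrom, kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

# Rank-and-average quantile normalization (tie-free input only).
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2L, sort))
  out <- apply(m, 2L, function(col) ref[rank(col)])
  dimnames(out) <- dimnames(m)
  out
}

# One-sided Welch two-sample p-value (x > y), from the textbook formulas.
welch_p_greater <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  stats::pt(tstat, df, lower.tail = FALSE)
}

# 2-norm condition number via the eigenvalues of the Gram matrix.
cond_oracle <- function(m) {
  ev <- eigen(crossprod(as.matrix(m)), symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev) / min(ev))
}

# Centered ordinary least squares by the normal equations.
ols_oracle <- function(X, Y) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  solve(crossprod(Xc), crossprod(Xc, Yc))
}

# Box-Cox profile log-likelihood maximized over a grid.
boxcox_lambda_oracle <- function(y, grid = seq(-2, 2, by = 0.01)) {
  n <- length(y)
  sum_log_y <- sum(log(y))
  ll <- vapply(grid, function(l) {
    z <- if (abs(l) < 1e-12) log(y) else (y^l - 1) / l
    -n / 2 * log(mean((z - mean(z))^2)) + (l - 1) * sum_log_y
  }, 0)
  grid[which.max(ll)]
}

# Wasserstein-1 as a quantile-function integral on a fine midpoint grid;
# exact for equal-length samples when the grid size is a multiple of n.
wass_oracle <- function(a, b) {
  ngrid <- length(a) * 50L
  p <- (seq_len(ngrid) - 0.5) / ngrid
  mean(abs(stats::quantile(a, p, type = 1, names = FALSE) -
           stats::quantile(b, p, type = 1, names = FALSE)))
}

# Small labeled profile from an explicit matrix.
make_profile <- function(values, types_of_cols) {
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  rownames(values) <- paste0("f", seq_len(nrow(values)))
  reference_profile(values, stats::setNames(types_of_cols, colnames(values)))
}

rdirichlet1 <- function(k) {
  g <- stats::rexp(k)
  g / sum(g)
}
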