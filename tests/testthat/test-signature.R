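# Signature matrix: per-type means, condition number, g..G sweep.

test_that("celltype_means averages per group", {
  prof <- make_profile(matrix(c(2, 4, 6), 1, 3), c("A", "A", "B"))
  expect_equal(unname(celltype_means(prof, "f1")), cbind(3, 6),
               ignore_attr = TRUE)
  # single sample per type: means equal the sample columns
  one <- make_profile(matrix(1:4, 2, 2), c("A", "B"))
  expect_equal(unname(celltype_means(one)), matrix(1:4, 2, 2) * 1.0)
  expect_error(celltype_means(prof, "ghost"), "unknown features")
  # brute-force group means on a random 20 x 6 profile
  set.seed(2)
  v <- matrix(stats::runif(120, 0, 10), 20, 6)
  prof <- make_profile(v, rep(c("A", "B", "C"), times = 2))
  got <- celltype_means(prof)
  for (ct in c("A", "B", "C")) {
    cols <- which(rep(c("A", "B", "C"), times = 2) == ct)
    expect_equal(unname(got[, ct]), unname(rowMeans(v[, cols])))
  }
})

test_that("condition number follows the singular-value definition", {
  expect_equal(condition_number(diag(2)), 1.0)
  expect_equal(condition_number(diag(c(4, 1))), 4.0)
  m <- matrix(c(1, 1, 1, 1.0001), 2, 2)
  expect_equal(condition_number(m), cond_oracle(m), tolerance = 1e-6)
  set.seed(9)
  r <- matrix(stats::rnorm(50), 10, 5)
  expect_equal(condition_number(r), cond_oracle(r), tolerance = 1e-10)
  expect_identical(condition_number(matrix(c(1, 2, 2, 4), 2, 2)), Inf)
  expect_error(condition_number(matrix(0, 3, 3)), "all-zero")
})

# Small synthetic profile for sweep tests: 3 types, clear markers.
sweep_fixture <- function(seed = 4, n_markers = 20) {
  set.seed(seed)
  n_bg <- 40; k <- 3
  n <- n_bg + k * n_markers
  means <- matrix(stats::rlnorm(n, 3, 0.8), n, k)
  for (i in seq_len(k)) {
    means[(i - 1) * n_markers + seq_len(n_markers), i] <-
      means[(i - 1) * n_markers + seq_len(n_markers), i] * 8
  }
  values <- means[, rep(seq_len(k), each = 3)] *
    matrix(stats::rlnorm(n * 9, 0, 0.15), n, 9)
  make_profile(values, rep(c("A", "B", "C"), each = 3))
}

test_that("the sweep returns the minimum-condition-number candidate", {
  prof <- sweep_fixture()
  ctsps <- call_ctsps(prof, max_p = 0.05)
  sig <- build_signature(ctsps, prof, g = 5, G = 15)
  # independent exhaustive recomputation of every candidate in the sweep
  by_type <- split(ctsps, ctsps$cell_type)
  by_type <- lapply(by_type, function(d) d[order(-d$pi_value), ])
  kappas <- vapply(5:15, function(n) {
    feats <- unique(unlist(lapply(by_type, function(d) {
      d$feature_id[seq_len(min(n, nrow(d)))]
    })))
    B <- celltype_means(prof, feats)
    Z <- scale(B)
    cond_oracle(Z)
  }, 0)
  expect_equal(sig$condition_number, min(kappas), tolerance = 1e-10)
  expect_equal(sig$n_per_type, (5:15)[which.min(kappas)])
  # returned matrix is the raw means for the winning feature set
  expect_equal(sig$values,
               celltype_means(prof, rownames(sig$values)))
  expect_equal(qr(sig$values)$rank, 3L)  # identifiable
})

test_that("g = G evaluates exactly one candidate", {
  prof <- sweep_fixture(seed = 6)
  ctsps <- call_ctsps(prof, max_p = 0.05)
  sig <- build_signature(ctsps, prof, g = 8, G = 8)
  expect_equal(sig$n_per_type, 8L)
  expect_equal(nrow(sig$values), length(unique(unlist(lapply(
    split(ctsps, ctsps$cell_type),
    function(d) d$feature_id[seq_len(min(8, nrow(d)))])))))
})

test_that("scarce cell types contribute what they have, absent ones error", {
  prof <- sweep_fixture(seed = 7)
  ctsps <- call_ctsps(prof, max_p = 0.05)
  # truncate type A to 3 CTSPs, below g = 5
  scarce <- ctsps[!(ctsps$cell_type == "A" &
                    seq_len(nrow(ctsps)) %in%
                      which(ctsps$cell_type == "A")[-(1:3)]), ]
  expect_warning(sig <- build_signature(scarce, prof, g = 5, G = 6), "fewer")
  a_feats <- scarce$feature_id[scarce$cell_type == "A"]
  expect_length(intersect(rownames(sig$values), a_feats), 3L)
  none <- ctsps[ctsps$cell_type != "A", ]
  expect_error(build_signature(none, prof, g = 5, G = 6), "zero CTSPs")
})

test_that("signature columns track their own cell type best", {
  prof <- sweep_fixture(seed = 12)
  ctsps <- call_ctsps(prof, max_p = 0.05)
  sig <- build_signature(ctsps, prof, g = 10, G = 20)
  truth <- celltype_means(prof, rownames(sig$values))
  for (ct in colnames(sig$values)) {
    cors <- stats::cor(sig$values[, ct], truth)
    expect_equal(colnames(truth)[which.max(cors)], ct)
  }
})

test_that("signature TSV + JSON sidecar round-trips", {
  prof <- sweep_fixture(seed = 13)
  ctsps <- call_ctsps(prof, max_p = 0.05)
  sig <- build_signature(ctsps, prof, g = 5, G = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$values, sig$values, tolerance = 1e-12)
  expect_equal(back$n_per_type, sig$n_per_type)
  expect_equal(back$condition_number, sig$condition_number,
               tolerance = 1e-12)
})
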