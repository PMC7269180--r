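# peakdecon

Cell-type deconvolution of bulk chromatin-accessibility (ATAC-seq) — and,
more generally, gene-expression — mixtures.

Bulk assays average over the cell types in a tissue, and shifts in cell
composition confound almost every downstream comparison. `peakdecon`
estimates the composition directly: given purified reference samples of
known cell type, it models each mixture profile *m* as a nonnegative linear
combination of cell-type signatures,

```
m = B f,        f >= 0,  sum(f) = 1
```

where **B** is a signature matrix of cell-type-specific peaks (CTSPs)
built from the reference, and **f** is the vector of proportions to be
estimated. The pipeline:

1. merge per-sample peak calls into a non-redundant **peak atlas**
   (weak-peak and blacklist filtering, greedy score-ranked merging);
2. **quantile-normalize** the reference intensity table and drop peaks
   below the global median intensity;
3. call **CTSPs** with a one-vs-each Welch *t*-test combined as an
   intersection-union test (p = max of the component p-values), ranked by
   the pi-value `log2FC x (-log10 p)`;
4. build **B** by sweeping the per-type CTSP count from g to G and keeping
   the candidate whose z-scored matrix has the smallest condition number;
5. snap a Box–Cox lambda estimate to log2 / sqrt / identity and apply the
   same transform to signature and mixtures;
6. solve for **f** per mixture with **SIMPLS** partial least squares, clip
   negative coefficients to zero, renormalize to sum to one;
7. score the result: RMSE and Pearson correlation against known truth, and
   a Monte-Carlo **Wasserstein-distance p-value** for fit quality always.

It is written for genomicists who have reference peak/count data (or want
the built-in truth-known simulator) and need per-sample composition
estimates with honest uncertainty about fit quality.

## Worked example

Simulate a truth-known dataset (4 cell types, 1200 peaks, 80 planted
markers per type at 10x elevation, 10% multiplicative noise, 30 Dirichlet
mixtures), then run the full pipeline:

```r
library(peakdecon)

cfg <- simulation_config(n_cell_types = 4, n_features = 1200,
                         n_markers_per_type = 80, noise_cv = 0.1,
                         n_mixtures = 30, seed = 42)
sim  <- simulate_dataset(cfg)

prof  <- median_intensity_filter(quantile_normalize(sim$reference))
ctsps <- call_ctsps(prof, max_p = 0.05)
sig   <- build_signature(ctsps, prof, g = 30, G = 60)
sig
#> signature_matrix: 240 features x 4 cell types (n_per_type = 60 of sweep 30..60, condition number 1.097)

res <- estimate_proportions(sig, sim$mixtures, transform = "auto")
res
#> deconv_result: 30 mixtures x 4 cell types (transform = log2, 4 SIMPLS components)
#>            CT1    CT2    CT3    CT4
#> mix_001 0.1828 0.3836 0.2284 0.2052
#> mix_002 0.1846 0.0282 0.4337 0.3535
#> mix_003 0.4728 0.0000 0.1807 0.3464
#> ...

evaluate_deconvolution(res, truth = sim$fractions, n_draws = 999, seed = 43)
#> deconv_report: 30 mixtures
#>   mean RMSE 0.0319, pooled PCC 0.9858
#>   mixture_id wasserstein_d pvalue        rmse       pcc
#> 1    mix_001     0.7878291  0.256 0.003725464 0.9995272
#> 2    mix_002     0.7348922  0.616 0.038353377 0.9838178
#> ...
```

Reading the output: each row of `proportions` is one mixture's estimated
composition (nonnegative, summing to 1). The auto-transform selected log2,
as expected for lognormal intensities. Against the known truth the
estimates agree to a mean RMSE of 0.032 and pooled Pearson r of 0.986; the
per-mixture Wasserstein p-values are unremarkable (well above the minimum
1/1000), indicating the fitted reconstructions B·f reproduce the observed
intensity distributions about as well as the model allows.

The CTSP table itself is ordinary data:

```r
head(ctsps, 3)
#>   feature_id cell_type  log2_fc        p_iut pi_value
#> 1 peak_00077       CT1 3.089322 1.773525e-06 17.76719
#> 2 peak_00006       CT1 3.193067 1.630679e-05 15.28723
#> 3 peak_00012       CT1 3.416228 6.120229e-05 14.39336
```

## Command line

The same workflow is available as subcommands (thin wrappers over the
functions above; `inst/cli/peakdecon` is an executable Rscript):

```sh
peakdecon simulation    --n-cell-types 4 --n-mixtures 30 --seed 42 --outdir sim/
peakdecon findctsps     --pure sim/reference.tsv --phenotype sim/phenotype.tsv --outdir sig/
peakdecon deconvolution --mixture sim/mixtures.tsv --signature sig/signature.tsv \
                        --truth sim/truth.tsv --seed 7 --outdir out/
peakdecon preprocess    --peaks s1.narrowPeak,s2.narrowPeak --blacklist bl.bed --outdir atlas/
```

Every run writes a `manifest.json` (version, parameters, seed, input
checksums) sufficient to reproduce it exactly.

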