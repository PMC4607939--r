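# microtempo

Statistical machinery for asking how a long-term (press) disturbance
reshapes the temporal dynamics of a microbial community: does
composition turn over more slowly, is community assembly more
deterministic, and are species-to-species associations tighter? The
package targets bacterioplankton-style OTU time series — replicated
samples from two or more habitats over repeated cruises — but works on
any samples-by-OTUs count table.

## What it computes

Starting from an OTU count table, sample metadata (site, season,
sampling day, replicate) and an environmental table, `microtempo`
provides:

* **Table transforms** — rarefaction to even depth (without
  replacement), relative abundance, taxonomic aggregation, dominant-taxon
  (mean relative abundance > 1%) and core-OTU (present in > 50% of
  samples) screens.
* **Dissimilarity and diversity** — Bray–Curtis and Sørensen distance
  matrices (similarity = 1 − distance throughout), richness, Shannon H′
  and Pielou evenness.
* **Ordination and permutation statistics** — PCoA (Gower
  double-centering, negative eigenvalues reported), PERMANOVA with
  crossed factors and sequential sums of squares, ANOSIM, Mantel tests,
  and a distance-based linear model (DistLM) with marginal tests and
  forward selection.
* **Temporal turnover (TDR)** — the time-decay of similarity
  relationship: ordinary least squares of log10(mean similarity per lag)
  on log10(time interval). The turnover rate is the negated slope,
  `w = -d log10(s) / d log10(t)`. Permutation test of the slope against
  zero, sample-level bootstrap, two-group slope comparison, and
  within-group similarity contrasts.
* **Assembly partitioning** — a null model preserving each sample's
  richness, total count and abundance values, with occurrence-weighted
  taxon draws from the regional pool. The per-pair determinism fraction
  is `(s_obs - s_null) / s_obs`; group summaries report both a truncated
  ("determinacy %") and a symmetric aggregation.
* **Co-occurrence networks** — correlations over core-OTU profiles, a
  random-matrix-theory (RMT) threshold chosen where the nearest-neighbour
  spacing distribution of the thresholded spectrum turns Poisson,
  topology metrics (avgK, avgCC, geodesic distance, fast-greedy
  modularity, power-law fit, positive-edge fraction) and degree-preserving
  rewired baselines.
* **A synthetic community generator** — lognormal abundances with a
  mean-reverting (Ornstein–Uhlenbeck) latent process per site, tunable
  turnover rate, environmental filtering strength, site effects and
  planted taxon-correlation blocks, so every statistic above can be
  validated against a known ground truth.

## Worked example

```r
library(microtempo)

ds <- generate_dataset(sim_config(seed = 42))   # 2 sites x 6 days x 4 reps
ds$table
#> community_table: 500 OTUs x 48 samples
#>   taxonomy: absent
#>   per-sample totals: 3870 - 3870

D  <- distance_matrix(ds$table, metric = "bray_curtis")
pr <- similarity_lag_pairs(D, ds$meta, group = "control")
fit <- tdr_fit(pr$pairs)
fit
#> TDR fit (mean-per-lag): w = 0.0619, intercept = -0.4402, R2 = 0.532 (13 points)
slope_test_zero(fit, pr$pairs, n_boot = 999, seed = 1)$p
#> [1] 0.002
```

The control site's community similarity decays as a power law of the
time interval with turnover rate `w = 0.062` — similarity drops by a
factor `2^0.062 ≈ 4%` per doubling of the lag — and the decay is
significant under a permutation test (p = 0.002).

```r
meta <- ds$meta; meta$day_f <- factor(meta$day)
permanova(D, meta, ~ day_f * site, n_perm = 999, seed = 1)
#> PERMANOVA (sequential SS, 999 permutations)
#>        term df     ss pseudo_F     R2     p
#>       day_f  5  1.554    1.245 0.1070 0.054
#>        site  1  2.516   10.077 0.1732 0.001
#>  day_f:site  5  1.468    1.176 0.1011 0.111
#>    Residual 36  8.987       NA 0.6187    NA
#>       Total 47 14.525       NA 1.0000    NA
```

Sampling time and site partition the community variance (R² columns);
p-values come from free permutation of sample labels with the observed
statistic included (+1 convention).

The whole pipeline — rarefaction, ordination, PERMANOVA/ANOSIM/DistLM,
TDR, assembly partition, networks, dominant taxa — runs from one
configuration:

```r
res <- run_all(run_config(sim = sim_config(seed = 42), seed = 42), "out/")
```

which writes TSV tables, a JSON summary and a manifest to `out/`;
re-running the same configuration reproduces the numeric outputs
byte-for-byte. A thin command-line wrapper with `simulate` and
`run-all` subcommands lives in `inst/scripts/microtempo-pipeline.R`.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the underlying
models and their assumptions, the null-model and RMT numerical choices,
what the synthetic generator does and does not emulate, and known
limitations.
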