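---
title: "Methods: models, null expectations and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, null expectations and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`microtempo` bundles the statistics used to ask whether a sustained
("press") disturbance changes three properties of a microbial community
time series: the rate of temporal turnover, the balance of deterministic
versus stochastic assembly, and the tightness of species-to-species
associations. This vignette documents the models behind each component,
the parameters that matter, and the numerical decisions that were
genuinely open — so that results are interpretable and reproducible
without reading the source.

## Dissimilarity and similarity

All downstream statistics run on Bray–Curtis dissimilarity
(`1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`), with the incidence-based
Sørensen index available for sensitivity analyses. Similarity is
uniformly `1 - dissimilarity`. Phylogenetic metrics (UniFrac) are out of
scope: they require a tree, and every quantity the package reports is
well defined on the taxonomic table alone. Shannon diversity uses the
natural logarithm (a base option is provided); Pielou evenness is
defined as 1 for single-taxon samples, where `H'/ln(S)` is 0/0.

Dominance and prevalence screens both use strict inequalities: a
dominant taxon has mean relative abundance strictly greater than the
threshold (default 1%), and a core OTU is detected in strictly more than
the prevalence cutoff (default 50%) of samples. One consistent rule
avoids boundary ambiguity; "more than half" is the natural reading of a
core-community criterion.

## Distance-based inference

**PCoA.** Classical metric scaling: eigendecomposition of the
Gower-centered matrix of `-d^2/2`. Bray–Curtis is semimetric, so
negative eigenvalues occur; they are reported unchanged and excluded
from the `proportion_explained` denominator. No Lingoes/Cailliez
correction is applied by default — corrections change eigenvalue ratios
and are better applied deliberately.

**PERMANOVA.** The total sum of squares of a distance matrix,
`SS_total = (1/n) * sum_{i<j} d_ij^2`, equals the trace of the
Gower-centered matrix `G`; a model term's SS is the increment in
`trace(H G)` as the term's columns join the design's hat matrix `H`.
Terms are fitted sequentially (Type-I) in formula order, matching the
convention of the widely used `adonis` implementation, so the R² column
of a crossed `~ time * site` table reads as "variance constrained by the
factor, given those before it". Significance comes from free permutation
of sample labels. Sampled permutations use the +1 convention (the
observed statistic counts in numerator and denominator), which keeps
p-values off zero; with `permutations = "exact"` all `n!` relabellings
are enumerated (n ≤ 8) and the p-value is the exact tie-aware tail
share. The implementation is cross-checked in the test suite against
`vegan::adonis2` (sums of squares agree to 1e-10) and against classical
one-way ANOVA on 1-D Euclidean fixtures, where the pseudo-F is the
textbook F.

**ANOSIM and Mantel.** Rank-based ANOSIM R with average ranks for ties;
Mantel correlation (Pearson or Spearman) over lower triangles with
joint row/column permutation of the second matrix. Both match the vegan
reference implementations exactly on shared fixtures.

**DistLM.** Marginal tests fit each environmental variable alone
(`% variation = 100 * SS_var / SS_total` via the same trace form);
forward selection adds, at each step, the variable with the largest
conditional SS gain among those whose conditional permutation p ≤
`selection_alpha` (default 0.05), and stops — recording the reason —
when no candidate qualifies. The selection criterion is not uniquely
pinned down in the literature this mirrors; "largest admissible gain"
is the greedy choice that makes the sequential table monotone in
cumulative % variation. Conditional permutation tests use free
permutation of the Gower-centered matrix; zero-variance variables are
excluded with a warning.

## Temporal turnover (TDR)

The time-decay relationship is fit by ordinary least squares of
`log10(similarity)` on `log10(lag in days)`. By default similarities
are first averaged within each distinct lag ("mean-per-lag"), so the
regression runs on one point per time interval; an all-pairs option
exists. The turnover rate `w` is the negated slope, reported positive
for decaying similarity. Replicate (lag-0) pairs cannot enter the
log-log fit and are excluded from it, but they do enter within-group
similarity summaries, where all within-group pairs are pooled.

Two tests accompany the fit. The primary test of `slope = 0` is a
permutation test: similarity values are shuffled across lags, the
regression refit, and the two-sided p-value computed with the +1
convention. Secondarily, the package reports (a) a bootstrap
distribution of the slope obtained by resampling *samples* (not pairs)
with replacement and recomputing the pair set — pairs from a distance
matrix are not independent, and resampling at the sample level respects
that — and (b) a one-sample t test of the random-pairing null slopes
against the observed slope. The t-test construction is retained for
comparability with prior practice; it is statistically unusual (it
tests the null-slope distribution's mean, not the data), which is why
the permutation test is primary.

Between-group slope comparisons permute group membership at the sample
level and recompute both fits per permutation, which preserves each
group's internal pair structure under the null.

## Null-model assembly partition

The null model randomizes a community table under three constraints,
per sample: observed richness, observed total count, and the observed
multiset of positive abundance values. Taxon identities are drawn
without replacement from the regional pool (taxa occurring anywhere in
the table) with probability proportional to occurrence frequency;
abundance values are then assigned by random permutation across the
drawn taxa. This is a Raup–Crick-style null extended to abundances. An
unweighted (`"uniform"`) draw variant is provided.

For each within-group pair, the determinism fraction is
`(s_obs - s_null_mean) / s_obs`. Positive values mean the pair is more
similar than chance assembly predicts (deterministic convergence);
negative values mean deterministic divergence. Two group summaries are
emitted, because the field's conventional "determinacy %" is
asymmetric:

* **truncated**: `100 * mean(pmax(fraction, 0))`, with a companion
  stochasticity share `100 * mean(pmin(s_null/s_obs, 1))`. These need
  not sum to 100 — divergent pairs contribute zero determinism but full
  stochasticity — which reproduces the familiar pattern of determinacy
  and stochasticity percentages that do not add up.
* **symmetric**: `100 * mean(fraction)` untruncated, with stochasticity
  as its complement. The truncated summary is nonnegative by
  construction and therefore biased upward under the null; the
  symmetric summary is the one with a zero expectation under chance
  assembly, and the one used for calibration tests.

**Calibration.** Two properties anchor the method. First,
self-consistency: a table generated by the null model itself, when
partitioned against fresh randomizations, yields a symmetric determinism
share within Monte-Carlo error of zero (verified over 10 seeds with the
occurrence-weighted default; the uniform variant is *not*
self-consistent in this direction because a null draw shrinks the
realized pool). Second, sensitivity: the truncated determinism share
increases monotonically with the generator's environmental filtering
strength.

The neutral-calibration test deserves its caveat spelled out. A
similarity-based partition attributes to "determinism" *any* mechanism
that makes observed pairs more similar than random assembly from the
pool — including persistent taxon fitness differences (the same taxa
abundant everywhere) and temporal autocorrelation (drift legacy at
short lags), not only contemporary environmental filtering. The
package's neutral calibration therefore isolates the filtering signal:
it simulates with no persistent abundance structure (`base_sd = 0`), a
fast-mixing latent process, and evaluates positive-lag pairs with the
symmetric summary. Under the full default generator (persistent
lognormal structure, slow mixing), the partition reports substantial
determinism even at zero filtering — correctly, in the sense that
consistent fitness differences *are* deterministic, but users comparing
groups should rely on contrasts (site A vs site B) rather than absolute
percentages. The occurrence-weighted null is also mildly conservative
(it concentrates draws on common taxa, inflating null similarity by a
few percentage points in our simulations), which the uniform variant
avoids; contrasts are insensitive to this.

## Co-occurrence networks

Correlations are computed over core-OTU profiles after `log(x + 1)` of
relative abundances (Pearson by default; Spearman and a log-pseudocount
transform available). Zeros contribute the transform of zero rather
than missing values.

The similarity threshold is chosen by the random-matrix-theory
criterion: scan candidate thresholds, zero out sub-threshold entries,
and test the nearest-neighbour spacing distribution (NNSD) of the
unfolded eigenvalue spectrum against the Poisson form `exp(-s)`. Sparse
modular matrices have Poisson spacings; noisy dense ones follow
Wigner/GOE statistics. The chosen threshold is the smallest one whose
NNSD is Poisson-consistent (chi-square goodness of fit p > 0.05).
Numerical details the criterion needs pinned down: degenerate
eigenvalues are collapsed (tolerance 1e-8) before unfolding; unfolding
fits a degree-5 polynomial to the empirical cumulative spectral
density; at least 20 distinct eigenvalues are required for a spectrum
to be testable; the chi-square uses `ceiling(sqrt(#spacings))`
equal-probability bins under Exp(1). If no candidate passes, the scan
reports failure with per-threshold diagnostics and the caller may set
the threshold manually.

Topology follows the conventions of the molecular-ecological-network
literature: isolated nodes are dropped, so network size is the
connected size; average degree is `2L/n`; the clustering coefficient of
nodes with degree < 2 is 0; geodesic distance averages shortest paths
over connected pairs only; modularity comes from fast-greedy
agglomeration; the power-law R² is the least-squares fit of
log-frequency on log-degree over observed degrees. Random baselines
rewire by repeated double-edge swaps — two edges (a–b, c–d) become
(a–d, c–b) — rejecting self-loops and multi-edges, targeting 10
successful swaps per edge with an attempt cap for rigid graphs (a
clique cannot be rewired and correctly returns a zero-variance
baseline). The swap chain preserves the degree sequence exactly, which
the test suite verifies on every replicate.

## The synthetic community generator

The generator exists so that every statistic above can be validated
against a known ground truth; its defaults emulate a replicated
two-site seasonal design: 2 sites × 6 time points × 4 replicates,
3,870 reads per sample, sampling days 1, 6, 60, 66, 148, 153 (paired
cruises within three seasons, giving both ~5-day and ~2-season lags).

Per taxon `k` and site, log abundance is

```
latent_k(t) = base_k + z_k(t) + site_effect * pref_k
              - filter_strength * (optimum_k - env(t))^2
```

where `base_k ~ N(0, base_sd^2)` gives a lognormal rank-abundance
curve; `z_k(t)` is a stationary discrete-time Ornstein–Uhlenbeck
process with mean-reversion rate `turnover_theta` per day and
stationary SD `latent_sd`, sampled at the irregular cruise days (the
autocorrelation between days `t` and `t'` is
`exp(-turnover_theta * |t - t'|)`); the filtering term is a quadratic
match between a taxon optimum and a single seasonal environmental axis
(standardized declining temperature). Counts are multinomial draws of
the fixed depth from `exp(latent)` renormalized, with independent
per-replicate lognormal noise (`replicate_sd`) representing local
patchiness among replicate water samples. The environmental table
contains temperature (deterministically the latent axis), noisy
correlates (dissolved oxygen, chlorophyll a), a site-shifted nutrient,
and a pure-noise variable, so DistLM has both signal and decoys.

Default rates were chosen once, on realism grounds: `turnover_theta =
0.002/day`, `latent_sd = 1.5`, `base_sd = 1.5` and `replicate_sd = 1.5`
jointly give turnover rates near 0.06 per log10-day and within-site
mean similarities near 0.28 — the scales reported for coastal
bacterioplankton over seasonal windows. Without the replicate-noise
term, fixed-depth multinomial replicates would be unrealistically
similar (Bray–Curtis similarity ≈ 0.95), and all within-site similarity
would be temporal signal. The exact decay shape of the process is not
assumed power-law; tests compare fitted turnover rates *between*
parameterizations (ordering, recovery within Monte-Carlo error) rather
than against an analytic slope.

What the generator does **not** emulate: sequencing error, chimeras and
OTU-calling artifacts; phylogenetic structure (no tree, no taxonomy
strings); multi-year periodicity; spatial structure within a site
beyond exchangeable replicate noise; and taxon-taxon interactions
outside the planted correlation blocks. Passing tests therefore
demonstrate correctness of the statistical machinery on communities
with known generating processes, not robustness to upstream
bioinformatic noise.

Planted correlation blocks (`generate_blocked_taxa`) give each block a
shared latent factor so the expected within-block correlation is
`block_rho` and all other correlations are zero; latent values map
affinely to nonnegative integer abundances, preserving correlations.
These fixtures drive the network-recovery tests: at the RMT-chosen
threshold, connected components must equal the planted blocks exactly.

## Determinism, seeds and problem sizes

Every stochastic function takes a `seed`; a master seed deterministically
derives independent child streams for each stage, so a pipeline
configuration reproduces its numeric outputs byte-for-byte (stage
runtimes are logged to a separate file to keep outputs comparable).
The test suite sizes its simulations to run comfortably on one CPU:
type-I error calibration uses 500 null simulations per test at n = 12
samples with 99–199 permutations; turnover-ordering and
assembly-monotonicity checks use 20 seeds at 200–500-taxon pools;
the end-to-end determinism check runs the full default design twice.
These sizes are the package's chosen validation conditions; all
thresholds (3 binomial standard errors around the nominal level, 3
Monte-Carlo standard errors around zero) are stated in the tests
themselves.

## Known limitations

* The assembly partition is a similarity-based summary; it cannot
  separate environmental filtering from other convergence-inducing
  processes (see the calibration caveat above), and the truncated
  "determinacy %" is not a probability — only contrasts between groups
  are safely interpretable.
* The RMT criterion needs a reasonably large correlation matrix
  (≥ 30 core OTUs, in practice ≥ 20 distinct eigenvalues after
  thresholding); small matrices report failure rather than a threshold.
* Exact PERMANOVA enumeration is limited to n ≤ 8 samples (8! = 40,320
  relabellings); beyond that, sampled permutations with the +1
  convention apply.
* DistLM forward selection is greedy; like all stepwise procedures it
  does not guarantee the globally best variable subset, and its
  conditional permutation test uses free permutation rather than
  residual permutation.
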