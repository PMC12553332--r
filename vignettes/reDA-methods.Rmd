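---
title: "Methods: neighborhood abundance and differential-abundance testing in reDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neighborhood abundance and differential-abundance testing in reDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reDA)
```

## The problem

Multi-sample scATAC-seq experiments ask which *cell states* change in
frequency between conditions — disease versus healthy tissue, treated versus
untreated — rather than which individual peaks change accessibility. The
classical route (cluster, then count cells per cluster per sample) ties the
answer to an arbitrary clustering resolution and can miss shifts confined to
small or poorly separated subpopulations. reDA tests abundance at the
resolution of *single-cell neighborhoods* instead: every cell anchors a soft
neighborhood, every sample contributes a measurable amount of probability
mass to it, and neighborhoods whose per-sample mass covaries with the
phenotype are the differentially abundant cell states.

scATAC-seq adds two obstacles that shape the design: counts are extremely
sparse (roughly 1–10% of peaks detected per cell) and nearly binary, so all
distance computations happen in a TF-IDF/LSI embedding rather than on raw
counts, and the neighborhood definition must pool information across cells
aggressively without smearing genuinely local structure.

## The model

**Embedding and graph.** Counts are binarized (configurable), TF-IDF
weighted (`log(1 + TF·IDF·10^4)`, the Signac-style variant), and reduced by
truncated SVD. The first component tracks sequencing depth almost perfectly
in this assay, so by default a 30-component run keeps dimensions 2–30.
Cells are then joined in a shared-nearest-neighbor graph: edge weight
between two cells is the Jaccard overlap of their self-inclusive
k-nearest-neighbor sets (k = 20), pruned below 1/15 — the conventions of
the Seurat/Signac pipelines this stage mirrors. An externally corrected
embedding (e.g. after batch integration) can be supplied to bypass
preprocessing entirely; reDA does not implement batch correction itself.

**Neighborhoods by random walk with restart.** With adjacency `A` and
degree matrix `D`, the walk matrix is `W = D^-1 A`. A walker started at
cell i follows `W` but returns to its start with restart probability
`alpha` per step:

    r^s = (1 - alpha) W r^{s-1} + alpha I,   r^0 = I.

`r^s[i, i']` is the soft membership of cell i' in cell i's neighborhood:
the restart term anchors neighborhoods locally (the diagonal of `r^s` never
drops below `alpha`), while the walk term pools over the graph. The default
`alpha = 0.3` follows the reported robustness of the method around that
value; `alpha = 0` (no restart) and large `alpha` are available as
ablations — at `alpha = 0.9` the walk barely leaves its start cell and
detection collapses, which the benchmark harness reproduces.

**The neighborhood abundance matrix.** Summing walk mass over the cells of
each sample gives `R[n, i] = sum_{i' in sample n} r^s[i', i]`; normalizing
each row to 1 gives the NAM `Q`. Since each row of `r^s` is a probability
distribution, row n of `R` sums exactly to sample n's cell count — this
conservation law is asserted at runtime and in the tests. The pipeline
never materializes the M×M matrix `r^s`: because only `R = S^T r^s` is
needed (S the cell-by-sample indicator), the recursion is run on the N×M
matrix directly, `R_s = (1-alpha) R_{s-1} W + alpha S^T`, which is
algebraically identical (both equal `S^T p(W)` for the same matrix
polynomial) at O(N·edges) per step. The full walk is still available
(`keep_walk = TRUE`, `rwr_walk()`) and the equivalence is unit-tested.

**Choosing the walk length.** Longer walks make neighborhoods larger and
more sample-balanced; shorter walks keep them informative. Following the
kurtosis heuristic of covarying-neighborhood analysis, after each step the
kurtosis of each NAM column across samples is computed; walking stops at
the first step where the median kurtosis either fell by less than 3 (a
plateau) or is below 8. Two points deserve emphasis:

* The kurtosis *convention* is not fixed by the heuristic's description.
  reDA defaults to Fisher (excess) kurtosis and also offers Pearson
  (`kurt_type`); the thresholds 3 and 8 are applied to whichever is chosen.
* The absolute threshold (< 8) was calibrated on cohorts of ~18–19
  samples. Sample kurtosis over N values is bounded near N, so with ten or
  fewer samples the median excess kurtosis starts below 8 and the rule
  fires at s = 1 — the walk then reduces to one smoothing step over the
  SNN graph. This is the honest behavior of the published rule at small N,
  not a failure mode: neighborhoods in a well-mixed ten-sample design are
  already sample-balanced. The pathological opposite (per-sample cliques,
  where neighborhoods never mix) keeps kurtosis constant, and the plateau
  branch stops the walk rather than letting it run to `s_max`.

## The association test

The NAM is column-centered, residualized on sample covariates and batch
indicator columns by ordinary least squares when provided, and scaled to
unit column variance (columns annihilated by residualization stay at
zero). A thin SVD `Q~ = U S V^T` gives at most N−1 sample-level principal
components; component signs are fixed by making each component's
largest-magnitude cell loading positive, so results are deterministic.

**Global test.** For each candidate rank k the squared multiple
correlation `R²_k` between the centered phenotype and the first k score
columns is computed (score columns are centered and orthogonal, so `R²_k`
is a cumulative sum of squared correlations — verified against `lm()` in
the tests). Raw `R²_k` is monotone in k and saturates at 1 when k reaches
N−1, so it cannot select a rank by itself. Each rank is therefore scored
by the upper tail of its overall F statistic,
`F_k = (R²_k/k) / ((1−R²_k)/(N−1−k))`, mapped to −log tail probability so
ranks with different residual degrees of freedom are comparable (a plain
max over `F_k` would be dominated by the heaviest-tailed, largest-k
statistic). The observed statistic is the best rank's score; the identical
max-over-k selection is applied inside every phenotype permutation
(within batch strata when a batch is declared), so the reported p-value
`(1 + #{T_perm ≥ T_obs}) / (1 + n_perm)` is permutation-exact *including*
the selection. The parametric F tail is only a normalizing transform;
significance never relies on F's distributional assumptions.

**Local coefficients.** The coefficient of cell i is the correlation
across samples between the centered phenotype and NAM column i smoothed
through the selected k-PC subspace: `y_c^T P_k q~_i / (||y_c|| ||q~_i||)`.
Normalizing by the full column norm (rather than the norm of the
projection) matters: at k = 1 every projected column is proportional to
the first PC, so the projection-normalized variant would give every cell
an identical |coefficient| and reduce FDR thresholding to all-or-nothing.
With the full-column normalizer the coefficient is still bounded in
[−1, 1] (Cauchy–Schwarz), is zero for columns orthogonal to the retained
subspace, scales invariantly with y, and flips sign with y.

**Empirical FDR.** For each of `n_perm` phenotype permutations the entire
coefficient pipeline — rank selection, then local coefficients at the
selected rank — is re-run, giving null coefficient vectors. On a grid of
50 thresholds at equally spaced quantiles of the observed |coefficient|,
`FDR(t)` is the mean null exceedance count over the observed exceedance
count (floored at one so the top of the grid never divides by zero),
clipped to [0, 1] and made monotone non-increasing by running minimum.
The reported cell set is `|coefficient| ≥ t*` at the smallest threshold
with FDR ≤ 5%. When no threshold qualifies the set is empty and reported
as such — an expected outcome under the null, not an error.

## The synthetic benchmark

`simulate_dataset()` generates the study conditions used throughout the
tests: 2 conditions × 5 samples × 400 cells, 3000 peaks, 4 Gaussian
populations in a 10-dimensional latent space, the differentially abundant
population at 15% baseline weight and a 3-fold abundance effect in
condition 1, with per-sample log-normal jitter (sd 0.25) on the mixing
weights to mimic biological replicate variability. Accessibility follows a
logistic link `logit p = b0 + b_peak + L x` whose intercept is calibrated
by root-finding so the mean per-cell detection fraction hits the 5% target
(within the 1–10% range typical of the assay); counts are Bernoulli, i.e.
strictly binary, with optional Poisson bursts. Unstated parameters
(latent dimension 10, population-center scale 2, within-population spread
0.5, jitter 0.25) were chosen once for realistic separability and are not
tuned per experiment.

Two properties of this generator matter for interpreting results. First,
abundance is compositional: planting a 3× increase in one population
necessarily depresses every other population's *relative* abundance in
condition 1, so a correct test assigns non-zero (negative) coefficients to
non-planted populations too. Ground-truth scoring counts only the planted
population as positive, which places a ceiling on the achievable false
positive rate that is a property of the benchmark, not of the method.
Second, the generator draws samples exchangeably within condition, with no
batch structure or depth gradients; passing null calibration here shows
the permutation machinery is sound, not that the method is immune to real
batch effects (which the pipeline handles only through an externally
corrected embedding and/or a batch column).

With `da_effect = 1` nothing is planted and the pipeline's global p-value
is uniform — the test suite checks the rejection rate over 20 null
datasets against an exact binomial band, and the mean fraction of cells
passing FDR 5% against the nominal level.

## Numerical choices and degenerate inputs

* kNN is exact, with ties (including duplicated coordinates) broken by
  lower cell index; runs are reproducible by construction.
* A cell isolated by SNN pruning gets its strongest pre-prune edge back
  (with a warning) so the walk matrix stays defined; a zero-degree cell
  reaching `walk_matrix()` is an error.
* Constant phenotypes, designs with fewer than 2 samples, unknown sample
  references, and rank-deficient covariate designs are rejected with
  specific messages. NAM construction works from 2 samples; association
  testing requires at least 4 (permutations below that are meaningless).
* `lsi()` uses a randomized truncated SVD (irlba) above a small-matrix
  cutoff and exact `svd()` below it; the embedding is deterministic given
  the run seed, and all downstream distances are invariant to component
  sign flips.
* One run seed drives every stochastic stage through stage-name-derived
  substreams (`stage_seed()`), so changing `n_perm` never perturbs the
  simulated data or the embedding.

## Problem sizes

The test suite and the acceptance script run the full benchmark
configuration (4000 cells × 3000 peaks) for calibration and power checks
— 20 null datasets and a 20-replicate, 3-arm paired ablation benchmark —
and smaller configurations (600–900 cells) for unit-level pipeline
checks. These sizes were chosen so the complete suite runs in minutes on a
single core while leaving the study conditions (sample counts, effect
size, sparsity) exactly as stated above.

## Known limitations

* One phenotype at a time; multiple outcome conditions cannot be modeled
  jointly.
* No batch-effect correction of the embedding itself; only residualization
  and stratified permutation on a declared batch factor.
* The kurtosis stopping rule inherits its absolute thresholds from cohorts
  of ~18–19 samples and effectively selects one walk step for small-N
  designs (see above).
* Peak coordinates are carried as labels only; no peak unification across
  datasets is performed — a single consistent peak set is assumed.
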