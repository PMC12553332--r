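# reDA — cluster-free differential abundance testing for multi-sample scATAC-seq

reDA asks which *cell states* change in frequency between sample conditions
(disease vs. healthy, treated vs. untreated) in multi-sample single-cell
ATAC-seq — without first clustering the cells. It is aimed at analysts of
multi-sample scATAC-seq cohorts who have a peak-by-cell count matrix, a
sample assignment per cell, and a phenotype per sample, and want per-cell
evidence of phenotype-associated abundance shifts at a controlled false
discovery rate.

## Method at a glance

1. **Embedding.** TF-IDF (`log(1 + TF·IDF·10⁴)`, binarized counts) and
   truncated SVD; components 2–30 form the embedding (component 1 tracks
   sequencing depth). A batch-corrected embedding can be supplied instead.
2. **Graph.** Shared-nearest-neighbor graph over cells: edge weight =
   Jaccard overlap of self-inclusive k-NN sets (k = 20), pruned at 1/15.
3. **Neighborhoods.** Random walk with restart on `W = D⁻¹A`:

       rˢ = (1 − α) W rˢ⁻¹ + α I,  r⁰ = I,  α = 0.3

   `rˢ[i, i′]` is the soft membership of cell i′ in cell i's neighborhood.
   The walk length s is chosen automatically: walking stops once the median
   kurtosis (across samples) of the neighborhood abundance columns falls
   below 8 or plateaus (drops by < 3), i.e. once neighborhoods stop being
   dominated by a few samples.
4. **NAM.** `R[n, i] = Σ_{i′ ∈ sample n} rˢ[i′, i]`, row-normalized to the
   neighborhood abundance matrix `Q` (samples × cells).
5. **Association test.** NAM columns are centered, residualized on sample
   covariates/batch, and scaled; PCA across samples, a selection-aware
   permutation global test over NAM-PC ranks, per-cell neighborhood
   coefficients through the selected rank, and an empirical FDR computed by
   re-running the whole coefficient pipeline on phenotype permutations.
   Cells with `|coefficient| ≥ t*` at FDR 5% are the reported
   differentially abundant set.

A full account of the model, its assumptions, parameter defaults, and the
synthetic benchmark is in `vignettes/reDA-methods.Rmd`.

## Worked example

Simulate the package's standard benchmark (10 samples in two conditions,
400 cells each, 3000 peaks, one population planted at a 3-fold abundance
shift) and run the pipeline:

```r
library(reDA)

sim <- simulate_dataset(sim_config(da_effect = 3, seed = 1))
res <- reda_run(sim$counts, sim$samples, n_perm = 500, seed = 7)
res
#> reDA association result
#>   global p = 0.003992 (k = 1, s = 1, alpha = 0.30)
#>   245 / 4000 cells pass FDR 0.05 (|coef| >= 0.6284)

evaluate_calls(res$passing_cells, sim$truth)
#> $tpr
#> [1] 0.2274927
#>
#> $fpr
#> [1] 0.003370408
```

Reading the output: the global permutation test rejects the null of no
phenotype–abundance association (p ≈ 0.004); one NAM principal component
(k = 1) carries the association; the kurtosis rule selected a single walk
step (s = 1 — expected for a balanced 10-sample design, see the vignette);
245 cells exceed the coefficient threshold 0.628 at an empirical FDR of
5%, and those calls fall almost entirely inside the planted population
(FPR ≈ 0.3%). `write_results(res, "out/")` writes the per-cell
coefficients, the FDR table, and a JSON summary.

The command-line wrapper covers the same flow:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","reda.R",package="reDA"))') \
    simulate --out simdir --seed 1
Rscript .../reda.R run --mtx simdir/matrix.mtx --barcodes simdir/barcodes.tsv \
    --peaks simdir/peaks.bed --cells simdir/cells.csv \
    --samples simdir/samples.csv --seed 1 --out outdir
Rscript .../reda.R evaluate --results outdir --truth simdir/truth.tsv
```

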