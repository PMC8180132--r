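# fixbias

Diagnostics for methanol-fixation bias in single-cell RNA-seq.

Methanol fixation is a common way to preserve cells for scRNA-seq, but in
full-length (Smart-seq2-style) libraries it distorts the transcriptome in a
structured way: transcripts that are long and GC-rich are detected less, their
gene-body coverage collapses beyond ~1.5 kb from the 3' end, and — because TPM
renormalizes each cell to a fixed total — the surviving transcripts appear
*over*-expressed in fixed cells. `fixbias` packages the full diagnostic
battery for quantifying these effects in live-vs-fixed comparisons, together
with a generative model of the proposed mechanism so every diagnostic can be
validated on data with known ground truth.

## The model at the core

Reverse transcription of a fixed cell's molecule proceeds from the 3' end and
fails with constant per-base hazard once past a grace distance `d0`. For a
transcript with GC fraction `gc`, the probability that RT reaches at least
`x` bases from the 3' end is

    S(x) = exp(-lambda * max(0, x - d0)),
    lambda = lambda0 * (1 + gamma * (gc - 0.5))   (clipped at 0)

with defaults `d0 = 1500` bases, `lambda0 = 2e-4` per base, `gamma = 4`.
Fixation also lowers the per-molecule capture probability (`pi_live = 0.15`,
`pi_fixed = 0.10`). Under a full-length protocol a molecule is only counted if
RT survives to its 5' end (`S(L)`); under 3'-tag counting every captured
molecule keeps its 3' end, which is why tag protocols largely hide the effect.

## What the package provides

- **transcript catalogs** — length/GC annotation from FASTA, rank-order
  tables, deterministic equal-size binning and length x GC grids
  (`load_catalog`, `rank_order`, `bin_equal_size`, `quantile_grid`);
- **expression QC** — TPM/log2-TPM normalization, strict detected-gene cell
  filtering, pairwise cell correlation with clustering and a label-mixing
  statistic (`normalize_log_tpm`, `filter_cells`, `correlation_analysis`);
- **PCA diagnostics** — centered PCA with a deterministic sign convention,
  cycle-score regression, silhouette-based treatment separation, top-loading
  sets, and the length/GC threshold-sweep PCA (`run_pca`,
  `remove_cycle_effect`, `separation_score`, `threshold_sweep_pca`);
- **loading / dropout statistics** — live-vs-fixed mean comparisons with
  above/below-diagonal counts, CV-vs-mean, dropout threshold sweeps with
  Welch tests, abundance-class comparisons, loading-set length/GC t-tests;
- **coverage diagnostics** — samtools-depth ingestion, distance-from-3'
  coverage profiles per length/GC group, live-minus-fixed difference curves,
  per-transcript mapping-integrity ratios and the length x GC
  integrity-quotient grid;
- **end-bias emulation** — 3'- and 5'-terminal-window quantification from
  molecule records or depth, with side-by-side separation reports;
- **synthetic data** — `simulate_catalog`, `simulate_cells`,
  `simulate_depth` implementing the fixation model above;
- **pipeline** — `run_pipeline(pipeline_config(...), out_dir)` runs
  everything from one flat config and writes tables plus a machine-readable
  summary (a thin CLI wrapper lives in `inst/scripts/fixbias-pipeline.R`).

## Worked example

```r
library(fixbias)

cfg   <- sim_config(n_transcripts = 2000, n_cells = 100, n_cell_types = 1,
                    seed = 1)
cat   <- simulate_catalog(cfg, sequences = FALSE)
sim   <- simulate_experiment(cat, cfg, fixation_model())
em    <- normalize_log_tpm(sim$counts, cat, cell_data = sim$cell_data)

pca <- run_pca(em, k = 5)
align_component(pca, em$cell_data$treatment)   # which PC is the fixation PC
#> [1] 2
separation_score(pca, em$cell_data$treatment)
#> [1] 0.4251742

sweep <- threshold_sweep_pca(em, cat, k_bins = 5, top_n = 500)
sweep$summary[, c("tau", "n_transcripts", "separation_pc1",
                  "mean_length_top", "mean_gc_top")]
#>   tau n_transcripts separation_pc1 mean_length_top mean_gc_top
#> 1   0          2000     0.09762784        2094.570   0.5118609
#> 2   1          1279     0.23890828        2738.986   0.5432182
#> 3   2           726     0.64143998        3107.688   0.5665302
#> 4   3           312     0.85579798        3769.580   0.6004331
#> 5   4            79     0.87172709        5000.443   0.6451842
```

Read the sweep table as the package's headline diagnostic: at `tau = 0` (all
transcripts) PC1 carries the cell-cycle signal, so the live/fixed silhouette
on PC1 is near zero. As the sweep restricts the PCA to transcripts that are
long *and* GC-rich, PC1 becomes fixation-dominated: the treatment silhouette
rises to ~0.87 while the mean length and GC of the top-loading transcripts
climb — long, GC-rich transcripts are what separates fixed cells from live
ones.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the installed package end to end: it simulates the default synthetic
world at 2,000 transcripts x 200 cells, executes every pipeline stage
(normalization, correlation QC, PCA and cycle removal, loading and dropout
statistics, coverage and integrity diagnostics, end-bias emulation), writes
all stage tables under `results/pipeline_run/`, and emits the JSON target
file at `--out`.
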