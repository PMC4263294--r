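# oxomap

Genome-wide mapping of oxidative DNA damage (8-oxoguanine) from DIP-chip
microarray log-ratio signals.

## What this is for

8-oxoguanine (8-oxoG) is the most abundant oxidative DNA base lesion.
Measured genome-wide — by immunoprecipitating 8-oxoG-containing fragments
with a specific antibody and hybridizing IP and input DNA to a tiling
array — it yields a per-probe signal $y_i = \log_2(\mathrm{IP}_i /
\mathrm{input}_i)$ at roughly 6 kb resolution. `oxomap` is a tested,
reusable pipeline for the downstream analysis of such profiles, for
researchers in epigenomics and genome biology who want to relate damage
distribution to genome organisation:

* **Signal assembly & smoothing** — two-channel or log-ratio probe tables,
  replicate merging, per-probe sliding-window smoothing (mean over
  ±500 kb, i.e. a 1 Mb span) and fixed-step window tracks for
  chromosome-scale profiles.
* **Gene-density association** — non-overlapping 1 Mb bins, per-bin mean
  damage and strand-aware gene counts, Pearson correlation and box-plot
  summaries (damage rises in gene-poor bins and gene deserts).
* **Expression association** — mean damage over each gene's transcribed
  span, median and top/bottom-quantile expression splits, pooled-variance
  Student's *t* tests.
* **Assembly transfer** — a full reimplementation of UCSC chain-file
  interval remapping (liftOver semantics with the `minBlocks` minimum
  mapped-fraction criterion, default 0.1), so a lamin B1 DamID profile
  mapped on another assembly can be carried over to the damage assembly.
* **LAD association** — 200 kb fragment averaging of damage and lamin B1,
  a cutoff split at lamin = 0, group statistics, a 2-D density grid for
  contour plots, and a permutation test (default 1,000 relabellings of
  lamin values across fragments) summarised as a z-score with an add-one
  empirical p-value.
* **Synthetic data** — a generator for toy genomes with LAD architecture,
  bimodal lamin signal, planted damage effects, LAD-depleted gene
  placement, expression tables, and a paired assembly with indels, an
  inversion, chain files and per-tile mapped-coordinate ground truth.

The statistic at the centre of the LAD analysis is the observed group
difference $\Delta = \bar y_{\mathrm{lamin}>0} - \bar y_{\mathrm{lamin}\le
0}$ over fragments, with null moments $(\mu_0, \sigma_0)$ from random
reassignment of lamin values and $z = (\Delta - \mu_0)/\sigma_0$.

All coordinates are 0-based half-open throughout (BED/bedGraph/chain
native). See `vignettes/oxomap-methods.Rmd` for the modelling choices and
their rationale.

## Worked example

Simulate the default world (one 20 Mb chromosome, probes every ~6 kb,
LADs covering ~40% of the genome with a planted damage effect of +0.38
inside LADs, probe noise SD 0.5) and run the LAD analysis:

```r
library(oxomap)

sim   <- simulate_dataset(simulation_config(seed = 42))
frags <- fragment_profiles(sim$assembly, sim$probes, sim$lamin)  # 200 kb
sp    <- split_by_cutoff(frags, cutoff = 0)
group_stats(sp$positive, sp$negative)$comparison
#> student t-test: t = 17.042, df = 98.0, p = 4.57e-31
#>   group A: n = 40, mean = 0.3503
#>   group B: n = 60, mean = 0.0167

permutation_test(frags, n_iter = 1000, seed = 43)
#> Permutation test (mean_diff statistic, 1000 iterations, seed 43)
#>   groups: 40 positive / 60 negative fragments
#>   observed difference = 0.3337
#>   null mean = 0.0023, null sd = 0.0383
#>   z-score = 8.65, empirical p = 0.000999
```

The observed difference recovers the planted effect (0.33 vs 0.38; the
gap is diluted by fragments straddling LAD borders), and the permutation
z-score shows it far outside the null. The gene-density association on
the same world:

```r
bins <- make_bins(sim$assembly, 1e6)
bins <- mean_signal_per_bin(bins, sim$probes)
bins <- count_genes_per_bin(bins, sim$genes, rule = "tss")
density_association(bins)
#> Gene-density association over 20 bins
#>   Pearson r = -0.853 (P = 1.8e-06)
#>  gene_count label n_bins     median          q1        q3
#>           1     1      1 0.30912766  0.30912766 0.3091277
#>           5     5      1 0.32783638  0.32783638 0.3278364
#>           6     6      4 0.31994209  0.26281782 0.3804666
#>           7     7      1 0.34013158  0.34013158 0.3401316
#>          10  >=10     13 0.02973457 -0.02237515 0.1439684
```

Gene-poor megabase bins (here, LAD-dominated bins) carry visibly more
damage than gene-rich ones, the negative correlation the real assay
shows.

### Command line

```sh
# simulate a dataset + paired assembly/chain, then run every stage
Rscript -e 'oxomap::oxomap_cli()' all --seed 5 --out results/run1
# or stage by stage
Rscript -e 'oxomap::oxomap_cli()' liftover \
  --lamin lamin_foreign.bedgraph --chain toy.chain --out results/lift
```

Subcommands: `simulate`, `smooth`, `bins`, `expression`, `liftover`,
`lads`, `permtest`, `all`. Settings come from (lowest to highest
precedence) package defaults, a JSON config file (`--config cfg.json`),
and CLI flags. Every command writes a run-log JSON with the config hash,
seed, and all record/drop counts; exit codes are 0 (success), 1 (data
error), 2 (usage error). Re-running with the same seed reproduces every
output byte-for-byte.

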