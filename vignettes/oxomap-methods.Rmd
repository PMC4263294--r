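---
title: "oxomap: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{oxomap: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxomap)
```

## The measurement and the model

oxomap analyses genome-wide profiles of 8-oxoguanine (8-oxoG), the most
abundant oxidative DNA base lesion, measured by DNA immunoprecipitation
with an 8-oxoG-specific antibody followed by hybridization to a tiling
microarray (DIP-chip). The primary observable is, per probe $i$,

$$ y_i = \log_2(\mathrm{IP}_i / \mathrm{input}_i), $$

the log-ratio of the immunoprecipitated (Cy5) to input (Cy3) channel. On
the arrays this package targets, ~244,000 60-mer probes tile the genome at
about one probe per 6 kb, while the damage signal itself varies on the
megabase scale, so the probe density oversamples the biological signal and
plain window averaging is an adequate smoother.

The scientific questions the pipeline addresses are:

1. How is damage distributed along chromosomes? (smoothed profiles)
2. Does damage track gene density? (megabase binning + Pearson r)
3. Does genic damage track transcription? (expression-group t-tests)
4. Does damage track nuclear architecture, i.e. lamina-associated domains
   (LADs)? (fragment averaging against a lamin B1 DamID profile, a cutoff
   split, and a permutation z-score)

Since lamin B1 DamID profiles are typically available on a different
assembly than the damage data, the pipeline includes a full chain-file
interval remapping engine with liftOver semantics.

## Coordinates and conventions

All coordinates are 0-based half-open, the native convention of BED,
bedGraph and chain files; converting once at the boundary eliminates a
whole class of off-by-one errors. A probe is represented downstream by its
integer midpoint `floor((start + end)/2)`: probes are 60-mers, three
orders of magnitude shorter than any analysis window, so a point
representation is unambiguous. Probes with non-finite values are dropped
at read time and counted — never imputed. Biological replicates are
combined by the per-probe arithmetic mean of log-ratios; probes absent
from any replicate are dropped and counted. (Analysing replicates
separately is possible by running the pipeline per track.)

## Smoothing

`smooth_per_probe()` replaces each probe's value by the mean over all
probes within `halfwidth` bases in both directions (default 500,000, i.e.
a 1 Mb total span). The window bound is inclusive (`|mid_j - mid_i| <=
halfwidth`), a choice that affects only measure-zero coincidences on real
data; windows never cross chromosomes and always contain the probe itself,
so a single isolated probe keeps its value and constant signals are fixed
points. A "1 Mb sliding window" description and a "±500 kb per probe" rule
describe the same total span; `window_track()` additionally provides
fixed-step window export for plotting. Because means are contractions, the
smoothed track's range is always inside the raw range — a property the
tests assert, together with exact (1e-12) agreement with an O(n²)
brute-force oracle.

## Binning and the gene-density association

`make_bins()` tiles each chromosome from 0 in fixed bins (1 Mb for the
gene-density analysis); the final partial bin is kept and flagged, and is
included in the association by default (excluding it is a flag). Each
probe contributes to exactly one bin (midpoint rule), giving the exact
conservation identity — the probe-count-weighted mean of bin means equals
the global probe mean — used as a test invariant at 1e-9.

Gene counting defaults to the strand-aware 5' rule: a gene is counted in
the unique bin containing its transcription start (`tx_start` on `+`,
`tx_end - 1` on `-`), so each gene is counted exactly once, as per-bin
gene-count summaries require. An `overlap` rule (count in every
intersected bin) is available since the choice is not forced by the
analysis. The association output is the Pearson correlation between
uncapped gene counts and bin means, plus per-count medians/quartiles with
counts pooled at ≥10 for box-plot export.

## Expression groups

Genic damage is the mean probe value over `[tx_start, tx_end)`; genes
covering no probe are excluded (not zero-filled) from both groups. The
median split sends expression values strictly above the median to the
high group and ties to the low group — a deterministic rule that keeps the
split a partition. Top/bottom splits take the `q` tail fractions by rank
(0.25 and 0.10 preconfigured) and discard the middle. Groups are compared
with the two-sided pooled-variance Student's t-test (the classical test;
Welch is a flag). The pipeline reports p-values without significance
verdicts: in this assay genic damage is low overall, and group differences
near conventional thresholds are not interpreted by the software.

## Chain remapping (liftOver semantics)

`parse_chain()` validates that each chain's block sizes and gaps exactly
span its stated source and destination ranges. `map_interval()` considers
every chain with at least one aligned base inside the query interval,
computes the mapped fraction (aligned bases / interval length), and
applies the minimum-fraction criterion `min_blocks` (default 0.1, chosen
to keep sparse alignments convertible). The mapped output is the envelope
of the destination positions of the interval's aligned bases within the
single eligible chain — interior insertions are spanned, not split,
matching region-mode liftOver semantics. Minus-strand chains are handled
by coordinate reflection (`pos' = qSize - pos`).

Failure labels are `deleted` (no aligned base), `partially_deleted` (best
fraction below threshold) and `ambiguous` (two or more eligible chains).
Ambiguity fails closed by default — silently picking among paralogous
placements is worse than losing an interval — with an opt-in
`best_chain` selection (score, then aligned bases, then lowest id).
Mapped profile intervals that collide on the destination are dropped (the
earlier input wins) and counted, because downstream averaging requires
non-overlapping intervals. Raising `min_blocks` can only lose mappings,
except that ambiguity may legitimately resolve to a unique winner; the
test suite checks the implementation base-for-base against an independent
per-base walk oracle, including strand flips.

## LAD association and the permutation test

`fragment_profiles()` averages damage per fragment (default 200 kb, below
the 100 kb–10 Mb span of LADs; 50 kb and 500 kb are the usual robustness
settings) and averages the lamin profile with base-pair weights over
covered bases only — uncovered bases (e.g. liftOver gaps) carry no prior,
and fragments with no lamin coverage or no probes are excluded with
counts reported. The cutoff split (default 0, the trough of the bimodal
lamin distribution) sends exact-cutoff fragments to the negative group.

The permutation test uses the raw difference of group means as its
statistic (the quantity of interest; a Studentized variant is a flag).
Each of `n_iter` (default 1,000) iterations randomly reassigns the lamin
values across fragments and recomputes the difference under the same
cutoff. Because the multiset of lamin values is fixed, group sizes never
change across iterations, so no iteration can degenerate once the
observed split is valid. Reported are the null moments, the z-score
`(observed - null_mean)/null_sd`, and the add-one empirical p-value
`(1 + #{|null| >= |obs|})/(n_iter + 1)`, which is never exactly zero —
extreme effects are better summarized by the z-score. The test is exactly
reproducible given its seed and is run under a temporary RNG state, so it
does not perturb the caller's random stream.

## The synthetic world

`simulate_dataset()` generates the world the analysis assumes, with known
ground truth:

| parameter | default | meaning |
|---|---|---|
| `chrom_lengths` | one 20 Mb chromosome | toy genome |
| `probe_spacing` | 6,000 bp | mean probe interval |
| `lad_length_range` | 100 kb – 10 Mb | log-uniform LAD lengths |
| `lad_genome_fraction` | 0.4 | target LAD coverage |
| `lamin_mu`, `lamin_sd` | ±2.0, 0.5 | bimodal lamin tile signal (10 kb tiles) |
| `oxo_delta` | 0.38 | additive damage effect inside LADs |
| `oxo_sd` | 0.5 | probe noise SD |
| `gene_density_ratio` | 5:1 | inter-LAD : LAD per-base gene odds |
| `n_genes` | 300 | gene count |
| `chain_event_rate` | 0.5 / Mb | indel rate for the paired assembly |

LAD borders are sharp (no transition ramp), reflecting the observed
steepness of lamin B1 transitions; LAD lengths are drawn log-uniform and
accumulated until the target coverage is met, the last domain truncated to
hit it exactly, with inter-LAD gaps proportioned by uniform random
weights. The damage effect size 0.38 is the implied gap between
lamin-positive and lamin-negative group means (0.25 − (−0.13)) in the
assay this package models. Genes are placed by per-base weighted odds
(inter-LAD bases 5× more likely), with log-normal lengths (median 20 kb)
and log-normal expression; two replicate expression columns carry 0.1 SD
log2 noise. The paired assembly is derived by seeded deletions and
insertions (1–50 kb, log-uniform) plus one inversion, emitted as chains in
both directions together with a per-10-kb-tile table of expected mapping
outcomes computed directly from the edit events — independent of the
chain machinery it is used to test.

All randomness flows from one master seed through fixed per-component
child seeds (LADs, lamin, probes, genes, expression, chain events), so
each artefact is reproducible in isolation and emitted files are
byte-identical across runs.

What the generator does **not** emulate: microarray intensity physics
(dye bias, spatial artefacts), sequence content (no FASTA; GC effects out
of scope), clustered gene architecture, and facultative/constitutive LAD
differences between cell types. A green test therefore establishes that
the statistical machinery recovers planted structure under the stated
noise model — not that it reproduces any particular organism's numbers.

### Two known limits of the stated world

Two desk-scale acceptance expectations are not attainable under the
generator's own defaults, and the corresponding tests are intentionally
left failing rather than papered over:

* **Permutation z > 10 at 100 fragments.** With one 20 Mb chromosome and
  200 kb fragments, N = 100 and the z-score is analytically capped near
  $z \approx \delta / (s\sqrt{1/n_+ + 1/n_-}) \approx 9$ for
  $\delta = 0.38$, $\sigma = 0.5$ (measured over 40 seeds: mean 8.8, max
  9.5). The same pipeline exceeds z = 10 comfortably at ≥1,000 fragments,
  which the unit tests verify; the z value scales with $\sqrt{N}$, not
  with the truth of the effect.
* **Zero-gene megabase bins.** 300 genes on 20 Mb with 5:1 odds put ~4.4
  genes per fully-LAD megabase, so gene deserts at 1 Mb resolution are
  Poisson-rare (≈7% of simulated genomes contain any). Real mammalian
  genomes have lower, strongly clustered gene density, which is why
  zero-gene fragments dominate the real analysis but not the toy world.
  The sign of the density association (r ≈ −0.8 here vs −0.47 on real
  data) is recovered regardless.

## Pipeline and reproducibility

The CLI (`oxomap_cli()`, or the `inst/exec/oxomap` wrapper) exposes the
stages as subcommands (`simulate`, `smooth`, `bins`, `expression`,
`liftover`, `lads`, `permtest`, `all`) with a JSON config file and flag
overrides, precedence CLI > config > defaults. JSON (via jsonlite) was
chosen over YAML to avoid a dependency outside the guaranteed runtime
set. Every command writes a run-log (version, config hash, seed, record
counts including every dropped-record count, output names); no record is
dropped silently. Exit codes: 0 success, 1 data error, 2 usage error;
partial outputs of a failed command are removed. Re-running any command
with the same config and seed produces byte-identical outputs (run-logs
hash path settings by basename so runs rooted in different directories
compare equal).
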