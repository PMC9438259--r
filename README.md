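# ladr — LAD calling and nuclear-lamina interaction analysis

`ladr` is an R package for the computational analysis of genome–nuclear
lamina (NL) interaction maps produced by DamID and pA-DamID. It is written
for chromatin biologists who have mapped NL contacts (e.g. LaminB1-tethered
Dam with a free-Dam accessibility control) across conditions — typically
acute protein depletions — and want to call lamina-associated domains
(LADs), characterize their borders, and quantify how NL interactions change.

## What it computes

**Signal.** Reads at GATC fragment ends are counted in 10-kb bins,
normalized to counts per million, and expressed per bin as

    log2((LaminB1_cpm + 1) / (Dam_cpm + 1))

then converted to z-scores (genome-wide mean/sd) to correct for
dynamic-range differences between experiments, and averaged across
biological replicates.

**Segmentation.** LADs are called with a two-state hidden Markov model on
the averaged z track — Baum–Welch fitting (Student-t or Gaussian emissions,
missing-data aware, one model shared across chromosomes) and Viterbi
decoding; the higher-emission state is the LAD state. Condition-specific
calls are merged into a union consensus so new LADs are scored everywhere.

**Borders.** A border is a CTCF border if a CTCF site lies within 20 kb
just outside the LAD; borders within 10 kb of an active gene (FPKM > 1) are
flagged; CTCF motif orientation is classified inward/outward/ambiguous.
Oriented meta-profiles (mean ± 95% CI), signal changes just outside
borders, and signed border-shift distributions against a reference
segmentation (100-kb censoring) quantify border behavior.

**Detachment.** Each intra-LAD CTCF site (≥100 kb from active genes and
borders) gets a detachment score — mean z at 50–100 kb flanks minus mean z
within 10 kb of the site; positive = locally detached from the NL — and a
loop-anchor class (no anchor, partner in LAD, partner in iLAD).

**LAD dynamics.** Per-LAD mean z changes are classified against an
empirical null (0.1%/99.9% quantiles of a control delta distribution) and
correlated (Spearman + BH) with LAD features: size, CTCF/active-gene
density, histone-mark levels, local LAD density in the surrounding 30 Mb,
distance to chromosome ends, chromosome size.

**Synthetic data.** A seeded generator builds genomes, LAD/CTCF/gene/loop
ground truth, expected z profiles (logistic borders, Gaussian dips at CTCF
sites and active genes) and negative-binomial read sets at GATC cuts, so
the whole pipeline is validated by parameter recovery.

## Worked example

```r
library(ladr)

res <- run_pipeline(pipeline_config(), seed = 1)

nrow(res$lad_sets$control)        # 7 LADs called in the control
head(res$borders[, c("chrom", "pos", "side", "n_ctcf",
                     "orientation_class")], 4)
#>   chrom     pos  side n_ctcf orientation_class
#> 1  chr1 2310000  left      0              none
#> 2  chr1 2490000 right      0              none
#> 3  chr1 7140000  left      1           outward
#> 4  chr1 7840000 right      0              none

sh <- res$shifts$shifts
median(sh$ref_distance[!sh$censored])
#> [1] 20000
```

The default configuration simulates a 2 × 10-Mb genome with two replicates
per channel and a "depleted" condition that removes the focal CTCF-site
dips and pushes every LAD border 20 kb into the iLAD. The example shows the
control segmentation (7 LADs, 13 interior borders, 5 of them CTCF borders),
the per-border CTCF classification, and the recovered median border shift —
exactly the simulated 20 kb, positive meaning displaced toward the iLAD.
Detachment scores for the filtered intra-LAD CTCF sites are in
`res$detachment` (mean 0.22 z here; with only a handful of qualifying sites
at this genome size the per-run mean is noisy), and per-LAD scores per
condition in `res$lad_scores`.

Pass `outdir = "out/"` to write all tracks and tables (bedGraph, BED, TSV);
two runs with the same config and seed are byte-identical.

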