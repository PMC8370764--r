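# tcrshare

Clonal overlap analysis for paired-site TCRβ repertoires.

## What it is for

After an antigen is delivered to two separate draining lymph nodes (e.g.
both hind footpads of a mouse), bulk TCRβ sequencing of the germinal
centers of the left and right node yields two clonotype tables. The
biological question — do the two nodes expand the *same* T follicular
helper clones, or does each run an independent clonal selection? — becomes
a question about two frequency distributions: how similar are they, which
clonotypes are shared, and is the sharing concentrated in the dominant
clones?

`tcrshare` is an R package for immunologists and computational biologists
analysing such paired-site (or paired-timepoint) repertoire designs. It
covers:

* **I/O** — AIRR rearrangement TSVs, legacy clonotype-table dialects,
  sample manifests; segment-level gene-name normalization.
* **Filtering** — productivity + copy-number ≥ 2 ("annotation") filter,
  then a strict per-sample above-median abundance filter, with full
  provenance logging.
* **Overlap statistics** — Morisita–Horn similarity, shared-clonotype
  dot-plot tables with regression fits, top-N relative intersection,
  cross-mouse sharing spectra with TRBV breakdown, Venn decomposition,
  group-level Mann–Whitney / Kruskal–Wallis summaries.
* **Segment usage** — TRBV/TRBJ usage tables (read- or
  clonotype-weighted) under per-strain gene panels (including
  deletion-bearing strains), compared between groups with Sidak
  family-wise correction.
* **Simulation** — a seeded generator of paired repertoires with a shared
  dominant clonotype block, heavy-tailed background, public clonotype
  pool, antigen-specific TRBV enrichment, and temporal decay of dominant
  clones; ground truth for every statistic above.
* **Pipeline** — `run_pipeline()` drives manifest → filtered repertoires →
  all statistics → TSV/JSON report bundle; `demo_synthetic()` is a
  one-command end-to-end demonstration.

## The core statistic

For clonotype relative-frequency vectors *p*, *q* of two repertoires over
the union of their clonotypes,

    MHI = 2 Σᵢ pᵢqᵢ / (Σᵢ pᵢ² + Σᵢ qᵢ²)  ∈ [0, 1]

the Morisita–Horn index: 0 for disjoint repertoires, 1 for identical
frequency distributions. It is quadratic in frequencies, hence dominated
by the most expanded clones — the right sensitivity for asking whether
the dominant clonotypes of two sites coincide. It is complemented by the
presence/absence *relative intersection* of the top-N clonotypes, which
detects persistence of dominant clones even after their frequencies decay.

## Worked example

```r
library(tcrshare)

# one antigen-like mouse, paired left/right nodes, default generator scale
cfg <- synth_config(seed = 42, n_mice = 1, group = "Ag_like")
samples <- simulate_sequencing(sample_clone_universe(cfg))
reps <- lapply(samples, function(s)
  filter_repertoire(aggregate_repertoire(s$records, meta = s$meta)))

reps[[1]]
#> TCRbeta repertoire 'Ag_like_m1_left_w4' (key: nt_vj)
#>   clonotypes: 1508   total reads: 913850
#>   filter annotation(min_count=2): 3179 -> 3020 clonotypes
#>   filter above_median(median=64): 3020 -> 1508 clonotypes

pair_overlap(reps[[1]], reps[[2]])
#> Pair overlap Ag_like_m1_left_w4 vs Ag_like_m1_right_w4
#>   MHI: 0.8856   shared clonotypes: 72
#>   top-20 shared: 20 (100.0%)
#>   regression (percent_linear): slope 0.871, r^2 0.780
```

Reading the output: of 3179 observed clonotypes, 3020 survive the
in-frame/copy-number filter and 1508 the above-median filter; the two
nodes of this simulated antigen-exposed mouse share 72 filtered
clonotypes whose abundances agree closely (MHI 0.89), and all 20 of the
left node's most expanded clonotypes are present in the right node — the
paired-site synchronization signature. A control (`PBS_like`) mouse
yields MHI near 0 with no top-20 sharing.

For the full study emulation (antigen + control groups, early + late
timepoints, report bundle on disk):

```r
demo_synthetic(master_seed = 1, dir = "demo_out")
```

A thin CLI wrapper with `demo` / `simulate` / `run` subcommands is at
`inst/scripts/tcrshare-cli.R`.

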