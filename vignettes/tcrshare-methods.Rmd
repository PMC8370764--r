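---
title: "Methods: paired-site TCRβ repertoire overlap analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-site TCRβ repertoire overlap analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question the package addresses

When an antigen drains to two separate lymph nodes — say the left and right
popliteal nodes after a footpad injection into both hind feet — do the
germinal centers of the two nodes recruit the *same* T follicular helper
(Tfh) clones, or does each node run an independent clonal lottery?
Bulk TCRβ sequencing of the two sites turns this into a statistical
question about two clonotype frequency distributions: how similar are they,
which clonotypes are shared, and is the sharing concentrated in the
dominant (most expanded) clones?

`tcrshare` implements the full analysis chain for this design: reading
clonotype tables, the filtering rules, abundance-weighted similarity,
dominant-clone intersection, cross-individual sharing spectra, and V/J
segment-usage comparison — plus a generative model of paired repertoires
that provides ground truth for every statistic.

## Data model and filtering

A *clonotype* is keyed, by default, on the CDR3 nucleotide sequence
together with the V and J segment calls (`nt_vj`); amino-acid-level
(`aa_vj`) and CDR3-only (`nt_only`) keys are available. Gene calls are
normalized to segment level on ingest (allele suffixes after `*` are
stripped): every analysis here operates at segment resolution, so allele
information would only create spurious clonotype splits.

Two filters are applied per sample, in this order:

1. **Annotation filter** — keep clonotypes that are in-frame (productive)
   and supported by at least 2 reads. Singletons are overwhelmingly PCR or
   sequencing artifacts in bulk TCRβ libraries.
2. **Above-median abundance filter** — compute the median clonotype read
   count of the sample and keep clonotypes *strictly above* it. "Above" is
   read literally: a sample whose counts are all equal empties out, with a
   warning rather than an error, because a legitimately flat sample is not
   a data defect. The even-count median uses the midpoint convention. The
   two filters are deliberately not interchangeable: the median is computed
   over annotated clonotypes only.

Counts rather than relative abundances feed the median; the two are
equivalent under a per-sample constant read total, and integer counts avoid
floating-point median artifacts. `median_abundance_filter()` is not
idempotent (reapplying it would keep halving the repertoire), so the
pipeline applies it exactly once; this is pinned by tests.

An empty *filtered* repertoire propagates as an empty repertoire object
with a logged warning. Any attempt to compute a similarity on it raises an
error — returning 0 would fabricate "no overlap" out of a filtering
artifact.

## Statistics

**Morisita–Horn index.** For relative frequency vectors $p$ and $q$ over
the union of clonotypes,

$$\mathrm{MHI} = \frac{2\sum_i p_i q_i}{\sum_i p_i^2 + \sum_i q_i^2}
\in [0, 1].$$

The index is quadratic in frequencies and therefore dominated by the most
expanded clones — exactly the right sensitivity profile for asking whether
the *dominant* clonotypes of two sites coincide. It is 1 iff the frequency
vectors agree on the union and 0 iff the supports are disjoint. The
implementation is index-matching-based and is validated against a naive
per-clonotype scan oracle to within $10^{-12}$ on hundreds of random
repertoire pairs of up to $10^3$ clonotypes.

**Overlap table and regression.** The shared clonotypes of a pair, with
frequencies in percent, ordered descending by the first sample's frequency
(ties broken lexicographically by key). An OLS fit of `freq_b` on `freq_a`
summarizes the dot plot; both the percent-linear and the log10 transform
are offered because published dot-plot axis conventions are often
ambiguous. The transform used is recorded in the result.

**Top-N relative intersection.** The percentage of one sample's N most
frequent clonotypes (N = 20 by default) found anywhere in another
repertoire. This presence/absence statistic is deliberately insensitive to
frequency decay: a clone that dropped 10-fold but persists still counts.
Ties at rank N are broken lexicographically so results are deterministic.

**Sharing spectrum.** Given one clonotype set per individual (for paired
designs, the union of the individual's two samples), the number of distinct
clonotypes present in exactly $k$ of $n$ individuals, with a per-$k$ TRBV
breakdown. Presence/absence only, per the field's sharing-index
convention. A 7-region Venn decomposition is available for $n = 3$.

**Group tests.** Similarity values are compared between groups with the
Mann–Whitney U test (exact when both groups have ≤ 8 untied values — the
relevant regime, since group sizes here are 3–10 — tie-corrected normal
approximation otherwise) or Kruskal–Wallis for ≥ 3 groups. Note the exact
3-vs-3 two-sided floor is $p = 0.1$: with three pairs per arm no rank test
can reach 0.05, which the package reports honestly rather than papering
over.

**Segment usage.** Per-sample TRBV/TRBJ usage is computed either
read-weighted (summed clonotype frequency per segment; the default, since
clonal dominance is the phenomenon of interest) or clonotype-weighted.
Gene panels are closed per-strain vocabularies: the bundled SJL-like panel
omits the TRBV families deleted from that strain's germline, and observed
off-panel segments warn instead of silently joining the family. Group
comparison is per-segment with Sidak family-wise correction
$p_{\mathrm{adj}} = 1 - (1-p)^m$, where $m$ counts only testable in-panel
segments — deleted or zero-variance segments must not dilute the
correction. Three test modes exist:

* `wilcox` (default): exact Mann–Whitney per segment. Assumption-free, but
  at 6 samples per group its exact floor is $2/924 \approx 0.0022$, which
  after Sidak over a dozen segments (~0.026) demands *complete* group
  separation. Read-weighted usage is noisy — a single top clone can carry
  ~10% of a sample's mass — so this mode is underpowered at small $n$.
* `t`: per-segment Welch tests.
* `anova`: a two-way group-by-segment fixed-effects fit whose per-segment
  group contrasts share a pooled error term — the classic "two-way ANOVA
  with Sidak's multiple comparisons" layout of graphing software. This is
  the mode the package's own enrichment-recovery validation uses, at the
  generator's default effect size.

## The generative model

`synth_config()` + `sample_clone_universe()` + `simulate_sequencing()`
emulate the clonal structure such a study observes. Per mouse:

* **One global power law.** Clone sizes follow a Zipf law. In the
  antigen-like condition the top $D$ ranks of that law form the *dominant
  block* (default $D = 20$), shared between the mouse's left and right
  samples with total mass $s$ per side (default 0.5); the background
  occupies the ranks below ($D{+}1, D{+}2, \dots$), renormalized. The rank
  offset is what guarantees scale separation: the largest *private*
  background clone is smaller than the smallest *shared* dominant clone,
  so the measured top-20 is the shared block — the structure in which
  "over 90% of the dominant clonotypes are shared" between paired nodes.
  Within the dominant block a flatter exponent (0.5) spreads the block
  over roughly one order of magnitude, matching the typical span of a
  dominant-clone dot plot.
* **Left/right correlation.** Each dominant clone has one latent size;
  each side multiplies it by independent log-normal jitter with log-sd
  $0.8(1 - \rho)$, $\rho$ = `left_right_dominant_correlation` (default
  0.5). $\rho = 1$ gives identical frequencies.
* **Background.** Default 3000 clones per sample, mostly private; each
  background clone is drawn from a cross-mouse public pool (500 clones)
  with probability 0.1, producing the nonzero baseline overlap that real
  control repertoires show. Clone identity is decoupled from clone size by
  randomly permuting rank assignments.
* **V/J usage.** Segments are drawn from per-strain panels; the
  antigen-like dominant block is TRBV3-enriched (weight 0.5) and mildly
  TRBJ2-5-enriched, emulating antigen-specific convergent selection.
* **Decoys.** A configurable fraction of unique clones (default 5%) are
  out-of-frame decoys with small total mass, plus optional post-sequencing
  productive singletons; these exist to exercise the annotation filter.
* **Sequencing.** Multinomial read sampling at the configured depth
  (default $10^6$ reads), so unseen clones are absent and observed
  frequencies carry binomial noise.
* **Time decay.** `apply_time_decay()` multiplies the dominant mass by
  `decay_factor` (default 0.3), keeps the early dominants present at
  reduced frequency, and gives the freed mass half to newly drawn
  late-emerging dominants *private to each side* and half to the
  background. This reproduces the observed asymmetry: the early top-20 is
  still found in late samples, while the late top-20 is largely absent
  early.

Every (mouse, side, block, timepoint) draws from its own RNG stream
derived from the master seed by a stable string hash (`derive_seed()`), so
identical configurations are bit-identical and adding mice or timepoints
never perturbs existing samples.

Scale defaults (3000 background clones, depth $10^6$, $D = 20$, groups of
3 mice) mirror the per-sample unique-clonotype counts (order $3 \times
10^3$) and read depths (order $10^6$) typical of laser-captured
germinal-center Tfh sequencing, which keeps a full two-group, two-timepoint
study generatable in seconds.

### What the generator does *not* emulate

* **Absolute similarity magnitudes.** The model omits PCR amplification
  bias, germinal-center subsampling (only 4–6 GCs per node are captured in
  the motivating design), and inter-animal variance in expansion kinetics.
  Left/right MHI at the defaults is therefore higher (~0.85) than typical
  real-data values (~0.5); the generator is calibrated to reproduce the
  *contrasts* — antigen ≫ control, early > late, top-20 sharing > 90% —
  not absolute indices. Passing tests show the statistics recover the
  structure that was put in, not that real data will look like this.
* **Cross-mouse convergence of dominant clones.** Dominant clones are
  private per mouse; group-level sharing spectra differ between conditions
  only through the public pool. The real phenomenon of identical
  TRBV3-bearing clonotypes across littermates (convergent recombination)
  is not modeled, so the synthetic sharing spectra of antigen and control
  groups are similar.
* **Sequence realism.** CDR3s are random in-frame strings (canonical
  C…F motif, 11–17 aa, synonymous random back-translation); no VDJ
  recombination model, no indel/error profile, no UMI structure.

## Numerical and design choices

* Strict "above median" (`>` not `≥`), midpoint convention for even
  counts; boundary behavior `{5,4,3,2,2} → 2 survivors`, `{2,2,2} → 0` is
  test-pinned.
* Deterministic ordering everywhere: clonotypes by descending count then
  key; overlap tables by descending `freq_a` then key. Reruns are
  byte-identical.
* Aggregation is a commutative, associative reduction; record streams can
  be split and merged (`merge_repertoires()`) with identical results.
* Mixed productive flags within one clonotype are carried as `NA` by
  aggregation and rejected by the annotation filter with the clonotype
  named — a data inconsistency, not a filterable condition.
* Validation problem sizes: the oracle equivalence suite uses 200 random
  pairs of up to $10^3$ clonotypes; generator properties use 50–200
  seeded replicates per setting at the full default scale; enrichment
  recovery uses 20 replicate studies of 3 mice per arm. These sizes give
  stable Monte-Carlo estimates while keeping the whole suite in the
  low minutes.

## Worked example

```r
library(tcrshare)

# one antigen-like mouse, paired nodes, defaults
cfg <- synth_config(seed = 42, n_mice = 1, group = "Ag_like")
samples <- simulate_sequencing(sample_clone_universe(cfg))
reps <- lapply(samples, function(s)
  filter_repertoire(aggregate_repertoire(s$records, meta = s$meta)))

pair_overlap(reps[[1]], reps[[2]])   # MHI, shared table, top-20 stats

# the full two-group, two-timepoint study with report bundle:
res <- demo_synthetic(master_seed = 42, dir = tempfile())
```

## Known limitations

* Single-chain (β) bulk data only; no paired αβ, no single-cell barcodes.
* No diversity indices (Shannon, Chao) or rarefaction — out of scope for
  the overlap question.
* The bundled gene panels are curated approximations suitable for
  simulation and panel-logic testing, not an authoritative germline
  reference; users with real data should supply their strain's panel TSV.
* Upstream clonotype calling (CDR3 assembly, error-cluster merging) is
  assumed done; the package consumes its table outputs.
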