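---
title: "Methods: ATAC-seq quality metrics, defined-FRiP simulation and functional-bias statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ATAC-seq quality metrics, defined-FRiP simulation and functional-bias statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and data model

`atacqc` operates downstream of alignment. Its unit of data is the
*fragment library*: properly-paired, MAPQ-filtered fragments given as
BED-like records (0-based, half-open) on a declared genome layout with
a designated mitochondrial chromosome. The two per-mate read spans are
reconstructed from the fragment ends and a fixed read length
(default 75 bases — 76 bp sequencing with one 3' base trimmed):
`[start, min(start + readlen, end))` and
`[max(end - readlen, start), end)`. Mates never extend past the
opposite fragment end, and fragments longer than 2000 bases (the
mapping pipeline's maximum insert) are rejected on input.

Duplicates are defined as identical `(chrom, start, end)` triples, the
first record in file order being kept. Standard duplicate markers key
on both mates' 5' positions; for proper pairs the two definitions
coincide. The library always retains its *pre*-deduplication read
counts because %mito is defined before duplicate removal, while every
other metric uses the deduplicated nuclear view.

Interval arithmetic (merge, overlap, coverage) is delegated to
`IRanges`/`GenomicRanges` behind the package's 0-based surfaces.
"Overlap" always means at least one shared base under half-open
arithmetic: `[100,200)` and `[199,300)` merge, `[100,200)` and
`[200,300)` do not.

# The five quality metrics

**FRiP.** Fraction of deduplicated nuclear *reads* (mate intervals,
two per fragment) overlapping a merged reference peak set. Counting
reads rather than fragments mirrors intersecting read records with
peaks with "report once" semantics; a documented switch
(`frip(..., by = "fragment")`) counts whole inserts instead and is off
by default. An empty reference yields 0; an empty library is an
explicit undefined-metric error, never a silent zero.

**TSS enrichment.** Per-base read-span depth is aggregated over a
4000 bp window centered on each TSS, strand-flipped so negative
offsets are always upstream; the profile is divided by the mean of the
100 outermost bases at each end (200 bases total); the score is the
maximum normalized depth at offsets −200..−1. Some pipelines take the
maximum in a symmetric window around the TSS instead; both conventions
are supported (`mode = "upstream200"` (default) vs `"centered200"`)
because published per-sample tables do not always say which was used.
A zero flank mean raises an undefined-metric error: with no reads near
the window edges the normalization is meaningless, and coercing it to
zero would corrupt cross-condition medians.

The TSS reference is built from GTF by taking the most upstream base
of each transcript (start for `+`, last covered base for `-`),
retaining transcripts whose gene type AND transcript type are in the
coding/lncRNA/immune-receptor whitelist, and excluding transcripts
tagged `readthrough_transcript` or `PAR`. GTF attributes are parsed
in-package: a transcript may carry several `tag` attributes and all of
them must be inspected, which off-the-shelf GTF importers collapse to
a single value.

**Sub-nucleosomal score.** `max(count below 150 bp) / max(count at
>= 150 bp)` on the 1 bp-binned deduplicated insert-size histogram. The
149/150 boundary is inclusive on the nucleosomal side.

**%mito.** `100 x mito reads / total reads`, both pre-deduplication.
Whether one counts reads or pairs cancels in the ratio; the package
counts reads in its logged denominators.

**Estimated complexity.** The Lander–Waterman saturation model:
observed `unique` distinct fragments among `total` sequenced implies a
latent pool of size `X` with `unique = X (1 - exp(-total/X))`. The
root is found on the substituted variable `r = total/X` (where
`(1-e^(-r))/r` is monotone on a known bracket) via `uniroot` at
tolerance 1e-13, then polished with Newton steps to a relative
tolerance of 1e-9. `unique == total` returns `Inf` — the estimate is
genuinely unbounded when no duplicates were observed. Units are unique
*fragments* (pairs), matching conventional duplicate-marker output.

# The desk-scale peak caller

The caller reproduces the *procedure* of the fixed-window invocation
used for ATAC data (no fragment model; every read contributes a
200 bp window centered on its 5' insertion site — equivalent to
shifting by −100 and extending 200):

1. per-base pileup = number of windows covering the base;
2. per-base Poisson rate `lambda = max(global rate, local rate)`,
   where the global rate is `reads x 200 / nuclear genome size` and
   the local rate is the window mass of reads within ±5 kb divided by
   10 kb;
3. upper-tail p-value `P(Pois(lambda) >= pileup)` per base;
4. Benjamini–Hochberg across all nuclear bases — computed exactly but
   on constant runs of the (pileup, lambda) decomposition with
   base-count weights, which is algebraically identical to per-base
   `p.adjust` and keeps the computation linear in the number of
   breakpoints;
5. significant bases (`q < 0.05`) fused across gaps of at most 30
   bases; regions shorter than 200 bases dropped; the summit is the
   pileup argmax within each region.

This is an explicit stand-in, not a bit-exact reimplementation of the
published caller; narrowPeak files from real callers drop in anywhere
a peak set is consumed. Records are used as given ("keep duplicates"
semantics), so calling on deduplicated or raw libraries is the
caller's input choice, and the dedup/no-dedup comparison utility
partitions the merged union of two call sets into shared and unique
intervals.

# The defined-FRiP simulation

Deduplicated nuclear pairs are partitioned against a master peak set
at *mate* level: a pair with at least one read interval overlapping a
peak is signal, a pair with neither is background. A synthetic library
at defined FRiP `t` and depth `d` reads draws `round(t * d/2)` signal
pairs and the complement from background, without replacement, pairs
intact, seeded. "Reads" in depth accounting means mates (1M reads =
500k pairs).

The sweep (`simulation_grid()` + `run_grid()`) records, per cell and
replicate: the number of peaks called on the synthetic library, the
subsample FRiP (against its own calls), the aggregate FRiP (against
the master set), optionally an external-reference FRiP and TSS
enrichment, and the sub-nucleosomal score, summarized as mean and
min–max per cell. Default levels are 10–90% in 10% steps with three
replicates. The default depth grid is desk scale (0.2M–2M reads);
`full_scale = TRUE` switches to 10M–50M reads in 5M steps, the design
used on deep real libraries, which is deliberately not the default:
the package's tests and scripts are sized for a single CPU and
minutes, not hours, and the robustness phenomena of interest
(reference-based FRiP is depth-invariant; subsample FRiP is
depth-driven because peak-calling power is) are already visible at
desk scale. Per-cell seeds are derived deterministically from the grid
seed and the (level, depth, replicate) coordinates, so identical grids
reproduce bit-identically and cells never share a random stream.

# Functional-bias statistics

**Condition table.** Per-condition peak sets are concatenated and
merged; each master interval carries the set of conditions with at
least one overlapping peak. A peak is *reproducible* if seen in at
least 3 conditions, and *missing* for condition `c` if seen in at
least 3 conditions other than `c` but not in `c`. With fewer than four
conditions the definition is degenerate and the workflow warns.

**Missing-peak enrichment.** With `B` reproducible background peaks,
`K` of them overlapping a ChIP peak set, and `n` missing peaks of
which `k` overlap, the p-value is the upper tail *including* `k`
(`phyper(k - 1, K, B - K, n, lower.tail = FALSE)` — the convention is
fixed explicitly because "P(X >= k)" is ambiguous in some toolkits),
and fold enrichment is `(k/n)/(K/B)`. `n = 0` or `K = 0` marks the
result untestable rather than feigning a p-value. BH adjustment is
applied per condition across factors, matching how such screens group
their reported tables.

**FRiP-ChIP / FRiP-TF.** FRiP-ChIP is the fraction of deduplicated
nuclear reads in the merged union of all ChIP peak sets. FRiP-TF for a
factor divides that factor's overlapping reads by the reads in *any*
ChIP peak — a composition measure, robust to depth. Row-wise z-scores
use the sample standard deviation (n−1); the ±1.5 cap applies only to
the exported display copy, never to stored values. The MAD is the raw
`median(|x - median(x)|)` without the 1.4826 consistency constant,
because it is used as a descriptive variability summary, not a sigma
estimate.

**Segmentation annotation.** Each deduplicated nuclear read is
assigned by the single base at its 5' end to at most one of the seven
segmentation classes (TSS, E, WE, CTCF, R, T, PF); class fractions
divide by all deduplicated reads, so unannotated gaps make fractions
sum below one. Segments of different classes must not overlap — a
segmentation that does not partition the genome is rejected rather
than double-counted.

# The synthetic-data generator

The generator emulates exactly the structure the analyses assume:

- a two-chromosome 10 Mb nuclear genome plus a 16,571 bp
  mitochondrial chromosome (configurable);
- 500 disjoint accessibility peaks, widths uniform on 300–700 bp,
  at least 1 kb apart, with per-peak intensity weights drawn
  Gamma(shape 4) — heterogeneous enough that peak-calling power grows
  visibly with depth (weak peaks exist) while a deep library still
  recovers essentially all planted peak bases;
- a TSS planted inside 30% of peaks (random strand), those peaks
  upweighted by `1 + tss_strength` (default 3x total);
- ChIP peak sets per factor: a sensitivity-thinned copy (90%) of the
  factor's assigned peak class plus 20% decoy intervals placed clear
  of all accessibility peaks;
- a seven-class segmentation tiling every nuclear base exactly once;
- fragment libraries drawn with replacement from a latent pool of
  `complexity` distinct nuclear fragments (plus a proportionally
  sized mitochondrial pool), so duplicates arise naturally and the
  Lander–Waterman model is *exactly* the right recovery model for the
  pool size;
- insert sizes from a truncated tri-modal mixture: sub-nucleosomal
  (30 + Gamma(4, scale 18), capped below 150), mono-nucleosome
  (Normal(200, 35) on [150, 290]) and di-nucleosome
  (Normal(380, 45) on [291, 700]); default weights 0.62/0.28/0.10
  give a sub-nucleosomal score near 2, typical of good native
  libraries. The weight-ratio-to-score mapping is documented as
  approximate rather than inverted exactly;
- a mitochondrial fraction of 0.24, the median of good native
  libraries; fixed-nuclei protocols run far higher and the dial is
  per-library;
- signal placement: a fragment assigned to a peak lies fully inside
  it whenever it fits (uniform over feasible starts) and is centered
  with symmetric overhang otherwise; background fragments are
  rejection-sampled to be entirely clear of peaks. This makes the
  defined-FRiP construction exact at read level — the signal/noise
  partition and the generator agree about what "in peaks" means —
  at the cost of not modeling shoulder reads that straddle real peak
  boundaries;
- per-condition class multipliers scale the sampling weight of
  factor-annotated peak classes, emulating protocol-induced coverage
  biases (e.g. a buffer that under-covers CTCF sites).

All randomness flows from one seed through named substreams
(annotation, sizes, placement, duplication, per-condition), and the
global RNG state of the session is saved and restored around every
seeded operation.

What the generator does *not* emulate — and what passing tests
therefore do not establish about real data: sequence content (no
Tn5 insertion bias, no GC bias), chromatin shoulder structure around
peaks, correlated duplicates from optical clusters, inter-replicate
biological variability, and real peak-width/intensity joint
distributions. Conclusions about metric *definitions* and pipeline
*correctness* transfer; absolute values of, e.g., TSS enrichment on
synthetic data are higher than typical real libraries because planted
peaks are cleaner than real ones.

# Numerical choices and degenerate inputs

- Undefined metrics (zero denominators, empty flanks, empty
  histogram halves) are typed errors carried as explicit `NA` with a
  reason in `qc_report()`; medians over panels use `na.rm`.
- BH over the genome is computed on value runs with base weights;
  ties and monotonicity behave exactly as `p.adjust(method = "BH")`.
- The complexity root uses a monotone bracket, so bisection-grade
  robustness with Newton-grade precision; the estimator is monotone
  in `unique` and always at least `unique`.
- Duplicate tie-break: first record in file order survives.
- Subsampling and defined-FRiP construction require even read
  counts; pairs are never split.
- Seeds are 32-bit; derived seeds are reduced modulo 2^31 - 1.

# Problem sizes

The shipped tests run the full pipeline at: libraries of 6k–100k
fragments for unit tests; one 1.05M-fragment library for the
simulation-recovery check (aggregate FRiP within one percentage point
at every level of the 10–90% grid at 1M reads); four-condition panels
of 60k fragments for the planted-bias recovery; 1000 label
permutations over a 20k-interval condition table for the null
calibration of the hypergeometric test. The calibration table is
sized so the discrete p-value lattice is fine enough for the nominal
level to be attainable: with a few thousand missing peaks the
achievable sizes straddle 0.05 closely, whereas a small table would
make the test conservative by discreteness alone, which would be a
property of the lattice, not of the method.

# Known limitations

- The peak caller is a stand-in: absolute peak counts will not match
  a production caller's output on real data, only the qualitative
  depth/FRiP response.
- Complexity estimates at low duplication are upward-noisy (the
  saturation curve is almost linear there); this is a property of the
  model, not the solver.
- The hypergeometric test treats peaks as exchangeable units; no
  width or GC matching of background is attempted.
- Published per-sample supplements are not redistributable with the
  package, so the recomputation of printed medians runs only when the
  user supplies those files locally.
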