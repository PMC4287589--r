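---
title: "Methods: how mscportrait characterises an MSC transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how mscportrait characterises an MSC transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscportrait)
```

`mscportrait` chains six analyses that together portray a cell type from
bulk RNA-seq: expression-footprint calling, gene-set enrichment, a
consensus TF-binding-site (TFBS) over-representation engine, methylation
Beta-value profiling, a two-engine differential-expression (DE)
consensus, and TF-network assembly. This vignette explains each model,
its assumptions, the tunable parameters, the numerical choices, and what
the synthetic-data module does and does not emulate.

## Expression footprint

FPKM values are summarised per gene as `log2` of the per-tissue FPKM sum
(used in scatter and marker reports) and `log2` of the mean FPKM across
all samples (used for thresholding). A gene is "expressed" when its log2
mean FPKM reaches a threshold, boundary inclusive.

Two thresholding modes exist. The fixed default of 2 corresponds to 4
FPKM — about one transcript per cell in bulk RNA-seq calibrations — and
is the scientifically motivated choice. The `"auto"` mode instead takes
the lower-tail `q`-quantile (default `q = 0.05`) of the log2 means,
computed **only over genes with positive log2 means** (mean FPKM > 1):
the positive restriction isolates the expressed component of the bimodal
FPKM density, and the quantile then trims its lowest 5%. Quantiles use
linear interpolation between order statistics (R type 7); ties at the
threshold are included. Both conventions matter at the margin and the
data source is silent on them, so they are fixed here once.

Zero aggregates have no log2 representation; they are mapped to an `NA`
"not detected" sentinel and excluded from densities and quantiles rather
than carried as `-Inf`, which would distort interpolation.

## Gene-set enrichment

Over-representation of a reference set in the footprint is the upper
tail `P(X >= k)` of `Hypergeometric(N, K, n)` with `N` the annotated
universe, `K` the footprint, `n` the set, `k` the overlap. The universe
is **always the supplied annotation**, never an implicit genome-size
constant: this makes every p-value reproducible from the inputs and is
recorded in the output row. Identifiers outside the universe are dropped
with a count. Raw p-values are reported alongside BH-adjusted values
across sets, since single-set inspection and multi-set screening need
different error control. Between-category expression comparisons use
two-sided Wilcoxon rank-sum tests (exact when the sample permits, normal
approximation with tie correction otherwise, as `stats::wilcox.test`
decides).

## The meta-regulator engine

The engine answers: which expressed TFs have binding sites
over-represented in the promoters of the expressed genes, and — second
pass — in the promoters of the expressed TF genes themselves?

**Scanning.** Motifs are JASPAR-style count matrices converted to
log-odds with background-proportional pseudocounts (total mass 1 per
column). Log-odds are quantized to 0.01 log2 units, and the exact pmf of
the score of a random background word is computed by dynamic programming
over motif positions on that grid; quantizing the scanner to the same
grid makes the `alpha` threshold exact rather than approximate. A window
is a hit when `P(score >= s) <= alpha` with `alpha = 1e-4` by default —
roughly one false site per 10 kb per strand, the usual operating point
for promoter scanning. Both strands are scanned (reverse strand = scan
of the reverse complement, reported at forward coordinates); windows
containing N are skipped.

**Promoter windows.** Three presets relative to the TSS: (-2000, -1),
(-5000, -800) and (-5000, +200). Coordinates are 1-based and inclusive;
the TSS itself is position +1 and there is no position 0. Minus-strand
genes take the mirrored genomic range, reverse-complemented. Windows
running off a contig are truncated with a warning.

**Enrichment and voting.** A gene counts once per matrix (presence/
absence of any hit), matching hypergeometric set-counting; hit counts
per promoter would need a different null. Within each scanning
configuration, matrices are BH-corrected and flagged at `q < 0.05`; a TF
is significant if any of its matrices is (the matrix-to-TF map is an
explicit input), and NA when it has no matrix. The consensus score is
the number of significant configurations minus 1 if the TF is
significant on **any** random reference set — `rrs_runs = 10` fresh
uniform gene sets of the target's size, evaluated on the first
configuration; the penalty is applied once however many runs fire. TFs
with score >= 2 are selected, preserving "2 of 3 methods" voting
semantics with a single engine run under three window configurations
(the original multi-tool setup is not bit-reproducible, and only the
voting layer is defined independently of the tools). The second pass
reruns enrichment with the expressed-TF promoters as target; the
meta-regulators are the intersection of both passes' selections. The
number of configurations is a free parameter (a list of promoter sets),
since how many search setups feed the vote is a user decision.

In simulations, planted motifs concentrate in expressed-gene promoters,
so an RRS draw that randomly over-samples expressed genes fires the
penalty for all planted TFs at once; selected regulators then typically
carry score 2 (3 significant configurations - 1). This is the intended
behaviour of the penalty, not a defect, and the score >= 2 rule absorbs
it.

## Methylation

Beta values follow the Illumina offset formula `M / (M + U + 100)`,
bounded in [0, 1). CpGs with detection p > 0.01 in any array are
removed (the boundary value is kept). The median Beta across arrays per
CpG (even counts: mean of the central pair) feeds all comparisons. The
target TF set is compared against `n_random = 3` control sets drawn
without replacement from a TF universe, overall and per island
sub-region. Two control modes exist because the natural universe is
ambiguous: TFs *not expressed* in the cell type (the stricter contrast,
the default in the pipeline) or any TFs. Inputs are assumed normalized;
array preprocessing and probe chemistry are out of scope. Structural
ties in intensity-derived medians make the exact rank-sum unavailable,
so the normal approximation with tie correction is always used here.

## Differential expression consensus

Two engines with independent error modes are intersected.

The **FPKM engine** runs a per-gene Welch t test on
`log2(FPKM + pseudo)` and reports `log2fc` from the group means of
`FPKM + pseudo` (second group over first). The pseudocount bounds fold
changes of near-zero genes. Its default is 0.25 FPKM, the detection
floor scale: a full pseudo-unit of 1 FPKM measurably attenuates
down-regulated genes in the expressed component (signed bias ~0.26 at a
planted |log2fc| of 3 with 3 vs 3 replicates, versus ~0.09 at 0.25),
because the shrunken side of a down-regulated gene is the one the
pseudocount dominates.

The **count engine** is a negative-binomial test: size factors by
median-of-ratios (genes with any zero excluded from the geometric-mean
reference), per-gene dispersion by method of moments on normalized
counts pooled across the two groups (floored at 1e-8), and an
exact-style two-sided tail — twice the smaller NB tail of the group A
count sum under the pooled rate, capped at 1, reducing to Poisson when
the moment estimate is at the floor. With discrete counts this tail is
conservative for weakly expressed genes, so calibration is assessed on
the expressed component, where the empirical type-I error sits near
0.04 at nominal 0.05; over all genes the test is conservative, never
anti-conservative.

The consensus keeps genes significant in both engines at asymmetric
thresholds (`q < 0.05` FPKM engine, `q < 0.001` count engine — the count
engine is far less stringent, so its cut-off is tightened to control
false positives). Direction is taken from the FPKM engine; sign
disagreements between engines are flagged but retained. Isoform-overlap
statistics are pure set intersections, with the footprint as denominator
for the footprint overlap and the consensus set for the signature
overlap.

## TF network

Edges are restricted to pairs with both endpoints in the admitted TF
list; duplicate evidence rows per unordered pair are summed into an
integer evidence weight (an edge represents merged experimental
evidence, not one edge per experiment). Nodes are the endpoints of
retained edges; unconnected TFs that are paralogs of a connected node
can be added as flagged isolated nodes, without edges. Exports: SIF and
GraphML (evidence as edge attribute).

## The synthetic-data module

`gen_expression()` draws per-gene mean log2 FPKM from two Gaussian
components — unexpressed at -3 (sd 1), expressed at +5 (sd 1.5) — with
replicate noise sd 0.25. The component locations put more than 4 sd
between the classes so the lower-tail quantile rule behaves as it does
on real bimodal FPKM densities; FPKM below 2^-6 is floored to zero to
create "not detected" sentinels. DE genes get a signed `de_log2fc` shift
in the second tissue group. Counts derive from FPKM via fixed per-gene
lengths (uniform 0.5–10 kb, recorded in the annotation) and per-sample
library sizes (uniform 20–50 million reads): no length distribution is
stated for the real data, so one plausible range is fixed once.
`gen_promoters()` uses i.i.d. uniform background bases and plants sites
sampled from each regulator's PSSM (re-drawn until they clear the scan
threshold) at recorded positions/strands in a configurable fraction of
target promoters, resolving overlaps by position re-draw.
`gen_methylation()` solves intensities from the Beta formula at fixed
total intensity `M + U = 2000`, so each record's recomputed Beta equals
its drawn target; detection failures are *generated* (~1% of CpGs), not
derived from control probes. `gen_ppi()` is an Erdős–Rényi edge model
with `1 + Poisson(1.5)` evidence counts.

What this does **not** emulate: read-level noise and alignment artifacts
(FPKM is drawn, not assembled), isoform structure, correlated genes,
GC/length biases, array probe chemistry, realistic genomic coordinates,
or hub structure in the PPI graph. Passing recovery tests therefore show
that the statistical machinery is correct under its stated model — not
that the pipeline is robust to real-data pathologies upstream of it.

All generators are deterministic given `seed` (drawn through isolated
RNG streams with fixed per-generator offsets, so they also do not
disturb the caller's RNG).

## Numerical choices and degenerate inputs

- Score discretization 0.01 log2 units; hit comparisons use a 1e-9
  slack so grid points at the threshold are included.
- `alpha = 1` returns the minimum attainable score; an `alpha` below the
  full-match probability yields an unattainable threshold and no hits.
- Empty footprints, empty edge lists, empty methylation tables and
  zero-CpG requests flow through and return empty results, not errors;
  an empty universe, no positive log2 means, or control pools smaller
  than the target set are hard errors.
- Zero-variance genes in the FPKM engine get df 1 and p = 1 when the
  means also agree (p near 0 otherwise).
- Welch df uses the Satterthwaite formula; BH is `stats::p.adjust`.

## Test problem sizes

The suite runs everything at desk scale, chosen so the full run stays in
the minutes range while keeping statistical room: oracle-equivalence
checks at enumeration-feasible sizes (hypergeometric universes up to 25,
exhaustive 4^w score distributions at w <= 6, 10 kb scan oracles, 1e4
BH inputs, 3 vs 3 rank-sum labelings); regulator-recovery over 20
seeded replicates of 200-gene / 12-TF worlds with 500 bp promoters;
DE recovery and null calibration on 2,000–3,000-gene matrices; and
methylation separation with ~240 CpGs per side.

## Known limitations

- The consensus engine's three configurations share one scanner; real
  multi-tool setups add algorithmic diversity the package cannot
  emulate, only the voting layer is reproduced.
- The count engine's moment dispersion has no shrinkage across genes;
  at 3 vs 3 replicates its dispersion estimates are noisy, which the
  doubled-tail test absorbs by being conservative.
- Gene-level Beta uses the median over a gene's CpGs when a per-gene
  value is needed; no weighting by region or probe type.
- The second-pass meta-regulator query inherits the small-target low
  power of any set-enrichment on a few dozen genes; with uniform
  planting the correct second-pass answer is "none", and detecting
  TF-promoter-specific regulators needs `targets_by_tf` planting.
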