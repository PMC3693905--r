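---
title: "Methods: linkage mapping and map integration in allotetraploid white clover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linkage mapping and map integration in allotetraploid white clover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clovermap)
```

# The problem

White clover is an allotetraploid (2n = 4x = 32) with eight homoeologous
chromosome pairs and strictly disomic inheritance: each chromosome pairs
only with its own homologue, never with its homoeologue.  Outbred,
highly heterozygous parents crossed in a double pseudo-testcross design
give an F1 family in which each parent's heterozygous loci segregate as in
a testcross, so a separate map can be estimated per parent and then merged.

Integrating maps from *two unrelated* populations adds a twist specific to
polyploids: population A's linkage group for, say, chromosome 5 homoeologue
"-1" must be matched to the correct one of the two chromosome-5 groups in
population B before any merging by shared markers makes sense.  The package
implements the full chain — marker discovery statistics, per-population
linkage analysis, homoeologue matching, integration, distortion scanning,
and reference-genome synteny — with a synthetic data generator that makes
each stage testable against known truth.

# SSR mining

`find_ssr_arrays()` reports maximal perfect tandem repeats of di- to
hexanucleotide motifs.  Class thresholds default to at least six repeats
for dinucleotides and five for the other classes.  Choices worth noting:

* **Perfect repeats only.** No mismatch or compound-array tolerance; an
  `N` (or any non-ACGT character) terminates an array.
* **Coordinates** are 0-based, half-open, and `end − start` always equals
  `repeats × motif length`: a trailing partial repeat is excluded and the
  array anchors at the leftmost base of the maximal perfect region.
* **Shortest-period rule.** A candidate whose motif is itself a repetition
  of a shorter unit (`ATAT`, or a mononucleotide run seen at period 2) is
  reported once, under the shortest period.  Arrays of different minimal
  periods may overlap and are then all reported.
* **Primer feasibility** replaces thermodynamic primer design: an array
  passes when both flanks can host a 27 nt primer and some amplicon
  containing the array fits 95–395 bp.  The amplicon convention includes
  both primers; with a minimum primer length of 20 the achievable lengths
  are `array + 40` up to `array + flanks`.  Melting temperature (60 °C) is
  carried as metadata and never evaluated.
* **Quality filter.** The phred-score filter is interpreted as a
  per-sequence arithmetic mean with a default threshold of 50; the
  aggregation and threshold are configurable because per-base and
  windowed interpretations are equally defensible.

These operations are verified against brute-force oracles (exhaustive
(position, period) enumeration; exhaustive primer-window enumeration) in
the test suite.

# Two-point CP linkage analysis

For each parent, `transmission_matrix()` infers which of the parent's two
alleles each progeny received, by enumerating the four gamete unions of
the locus and matching the observed visible allele pattern; progeny whose
pattern is compatible with both alleles (e.g. the heterozygous class of an
ab×ab locus) are uninformative.  Null alleles are handled uniformly by the
same enumeration — they simply make more patterns collapse.

`estimate_rf()` counts recombinants between two transmission vectors under
both phase assignments and keeps the phase with the higher likelihood
(ties break toward coupling).  With `n` informative meioses and `k`
recombinants, `r̂ = k/n` and

    LOD = (n − k) log10(2(1 − r̂)) + k log10(2 r̂).

Pairs with fewer than 10 shared informative meioses are flagged
low-confidence and excluded from grouping; the default keeps a LOD 8
threshold meaningful at the smaller family size (n = 92).  Grouping is the
connected components of the LOD ≥ 8 graph (via igraph).

## Ordering

Group ordering is a heuristic seriation.  Two candidate orders are built —
greedy insertion seeded with the strongest pair, and the first principal
coordinate of the pairwise distance matrix (classical MDS) — then each is
polished by local search (adjacent swaps, single-locus relocation, and
segment reversal) under the cost

    sum over pairs of LOD_ij (d_ij − |pos_i − pos_j|)^2,

and the lower-cost order wins.  Three numerical choices matter:

* The *cost* uses **Haldane** distances, which are additive under a
  no-interference crossover model, so with exact inputs the true order has
  cost zero.  Kosambi distances are not additive under that model, and
  using them in the cost systematically rewards wrong insertions.
  The *reported positions* are cumulative **Kosambi** distances between
  adjacent loci, the reporting convention of the field; at the small
  adjacent fractions that define positions the two functions differ by
  well under 5%.
* Pairs below LOD 3 carry no weight in the cost and `r̂` is capped at 0.45
  before conversion, so noisy estimates near `r = 0.5` (whose mapped
  distances diverge) cannot outvote local structure.
* Segment reversal in the polish is what rescues a weakly linked
  chromosome arm whose internal order is right but whose orientation
  flipped across a marker gap — the characteristic failure of purely
  adjacent moves.

Orientation of a finished group is arbitrary; it is canonicalised by
placing the lexicographically smaller terminal locus first, which makes
reversed solutions compare equal.  A locus sharing no informative pair
with the rest of its group raises a "disconnected evidence" error rather
than being placed arbitrarily.

## Parental consensus

The maternal and paternal maps of one population are merged through bridge
loci (loci informative in both parents) with the same joining-locus merge
used for inter-population integration, at equal weights.  Merging is
agglomerative: any two groups sharing at least two bridge loci merge,
repeatedly, so a chromosome that fragmented in one parent's map (common at
n = 92) is reunited through the other parent.  A locus whose fragment
never merges is kept in the largest group containing it, and fragments
with no usable bridges are passed through with a warning.

# Homoeologue matching

`designate_slhs()` applies the single-locus homoeologue-specific rule: a
marker is SL-HS when no individual in the diversity panel shows more than
two alleles.  A dual-homoeolocus marker betrays itself as soon as any
panel individual amplifies three or more distinct sizes; null alleles can
mask this, which is why SL-HS designation is evidence, not proof.

`assign_pairing()` decides between the two possible pairings of a
homoeologous group pair across populations:

1. SL-HS joining markers nominate a pairing directly; markers nominating
   *both* pairings are an internal conflict and leave the pair unresolved.
2. Otherwise allele-size evidence decides by maximising
   `matches − mismatches`; a tie with no SL-HS support is unresolved.
3. If SL-HS and net allele-size evidence disagree — a case the original
   study never met — the pair is left unresolved rather than guessed.

Allele-size evidence for a locus is `match` when its alleles fall in the
same non-overlapping homoeolocus size range in both populations,
`mismatch` when they fall in different ranges, and `ambiguous` when the
two ranges overlap or the alleles span both or neither (missing sizes are
ambiguous with a warning).  At the marker level the package forms, for
each candidate pairing, the hulls of the paired ranges across populations
and asks which pairing renders the two hulls disjoint; if both or neither
do, the marker is ambiguous.  "Range" means the closed interval
`[min, max]` of observed parental allele sizes per homoeolocus per
population.  Accepting one pairing fixes the sister groups' pairing by
elimination, and an accepted pairing resting on a single SL-HS locus is
flagged `accepted_single_slhs`.

Homoeologous pairs within one population are reconstructed from
dual-locus markers; at least two independent dual markers must support a
pair so that small unmerged fragments cannot masquerade as homoeologues.
A joining-locus density warning fires at over 50 cM per joining locus.

# Map integration

`combine_groups()` merges two maps of the same chromosome:

1. Joining loci (at least two) anchor the merge.  Between populations,
   anchors are matched by *marker identity* (a joining marker with exactly
   one locus in each paired group), because configuration suffixes differ
   between populations; between the two parents of one population, locus
   ids match directly.
2. Orientation is fixed by the rank correlation of anchor positions
   (group orientation is arbitrary).  Remaining order conflicts are an
   error by default; pipeline callers use `on_conflict = "demote"`, which
   keeps the largest order-consistent anchor subset and places the
   demoted loci like ordinary loci, with a warning — estimated maps carry
   ordering noise, and discarding a whole chromosome over one locally
   swapped anchor would be worse than demoting the anchor.
3. Consensus anchor positions are the population-size-weighted means of
   the source positions after a 1-D affine (Procrustes-style) alignment,
   iterated to convergence (tolerance 1e-10; with two anchors or
   identical maps this is exactly the plain weighted mean).
4. Non-anchor loci interpolate piecewise-linearly between their flanking
   anchors.  Beyond the terminal anchors the source map's overall affine
   slope extrapolates: a local terminal-segment slope is numerically
   fragile when two anchors happen to sit close together, and a single
   noisy segment would then fling distal loci far off the map.
5. The merged group starts at 0 and is canonically oriented, making the
   merge symmetric in its arguments.

Because every source enters through a monotone map, the relative order of
loci co-occurring in a source is preserved — the hard invariant of the
integration, tested exhaustively on small maps.  Weights default to the
two family sizes (184 vs 92).

`map_statistics()` reports, per group, the locus count `m`, observed
length (largest position), Method-4 expected length
`L̂ = L_obs (m + 1)/(m − 1)`, and density `L_obs/m`; totals, means and
standard errors over groups; coverage `ΣL_obs / ΣL̂` (Sekino–Hara, on
summed totals rather than per-group averages); and overall density both
as the mean of per-group densities and as total length over total loci.
Saturation uses the Fishman formula `c = 1 − exp(−2dn/G)`, checked in the
tests against Monte-Carlo dropping of loci on a circle.

The packaged reference table (`clover_map_summary()`) documents two quirks
of the published per-group summary: the expected-length entries of groups
2-1/2-2 and 6-1/6-2 appear interchanged relative to a direct Method-4
computation from the same rows, and the first population's per-group
expected column cannot be recovered from its observed column by Method 4
(only its printed total is used downstream).  The package always computes
expected lengths from observed data and keeps the printed column purely
as reference.

# Segregation distortion

`distortion_scan()` tests each locus per parental origin: the two
transmitted-allele counts against 1:1, chi-square with one degree of
freedom.  Class-ratio tests for arbitrary configurations (e.g. 1:2:1 for
ab×ab observable classes) are available through `segregation_chisq()`,
which switches to an exact multinomial test when any expected count drops
below 1 (enumeration up to n = 40, Monte-Carlo beyond).  Signed profiles
follow the convention of distortion figures in this literature:
`−log₁₀P` (positive) for female-derived alleles, `log₁₀P` (negative) for
male-derived alleles, plotted against position as a proportion of group
length.  Distorted loci (P < 0.05) are retained for mapping; a flagged
locus is additionally marked *removable* when both flanking loci are
non-distorted and its `|signed log₁₀P|` exceeds both flanks' by more than
2 — an explicit operationalisation of "incongruous with flanking loci",
which the source literature leaves qualitative.

# Synteny against a reference genome

Homology hits arrive as 12-column BLAST tabular text.  `filter_hits()`
applies the E ≤ 1e-20 exclusion, caps at five hits per query, and keeps
the single strongest (ties by bit score, then input order) — a function
only of the (query, E, bit score) triples.  `conflate_homoeologues()`
maps the 16 groups onto eight axes, each locus at its own homoeologue's
proportional position; homoeoloci are plotted separately rather than
averaged, so homoeologue disagreements stay visible.  Reference positions
use the hit midpoint as a proportion of chromosome length; strand is
metadata.

`colinearity_fraction()` fits a repeated-median (Siegel) line per
(group, dominant chromosome) block and counts records within a residual
band (default 0.1 of normalized length).  The published "fraction on a
linear pattern" was assessed by inspection; the robust-line-plus-band
criterion is a reproducible stand-in with the threshold exposed.  Hits to
non-dominant chromosomes and blocks of fewer than three records count
against co-linearity.  The repeated-median fit has a 50% breakdown point
and is sign-free, so the measure is invariant to reversing either axis.

`detect_translocation()` segments one group's ordered chromosome labels
with at most three change points by dynamic programming, minimising hits
that disagree with their segment's majority label (ties prefer fewer
segments; the DP is verified against exhaustive breakpoint enumeration in
the tests).  A secondary-chromosome segment must be supported by at least
three hits — the smallest support observed for a real translocated
segment in this system — and be internally coherent (majority share at
least 0.75); otherwise it merges into its neighbour, so interleaved
labels collapse to a single low-purity segment instead of spurious
breakpoints.  Breakpoints are reported at the midpoint between flanking
hits.

# The synthetic allotetraploid cross

`sim_config()` fixes the study conditions; `simulate_cross()` generates a
shared marker scaffold, two F1 populations, and a diversity panel under
one seed (bitwise reproducible).

* **Genome**: 8 homoeologous pairs, 80 cM per homoeologue.
* **Families**: n = 92 and n = 184 — the two population sizes of the
  mapping design this package targets.
* **Markers**: 20 loci per linkage group per population; marker positions
  are uniform draws per chromosome.  A marker amplifies both homoeoloci
  with probability 0.35 (dual markers are what link homoeologues within a
  population); 25% of each group's markers are joining markers typed in
  both populations, the rest split evenly between them.
* **Allele sizes** are integers (base pairs): each marker draws a base
  size, homoeolocus 2 is offset by 40 bp, and alleles sit on 2 bp steps
  within a 12 bp range — so homoeolocus ranges are disjoint by default
  and deliberately overlapping when the offset is set below the spread.
* **Segregation configurations** are drawn per locus with both-parent
  types at 45% (ab×cd 0.18, ab×ac 0.15, ab×ab 0.12) and single-parent
  types at 55%, mirroring the roughly 36/37/27 split of
  both/maternal/paternal-informative loci reported for this kind of
  population.  Null alleles replace parental alleles at 3% and whole
  calls go missing at 2% — free parameters, as no rates are published;
  both are low-single-digit values typical of SSR genotyping.
* **Meiosis** is a Poisson (no-interference) crossover process with
  expectation `length/100` per chromosome and strict disomic inheritance.
  The closed-form Haldane expectation this implies is the oracle for the
  recombination tests.  Kosambi is used only where maps are reported.
* **Distortion** is gametic selection: viability weights on a parent's
  two haplotypes at a position, enforced by rejection sampling (bounded
  attempts; impossible weights raise an error).  Zygotic selection is not
  modelled.
* **Panel**: 16 unrelated genotypes drawn uniformly from each
  homoeolocus's allele pool, reporting the union of visible alleles per
  marker — exactly the observable the SL-HS screen uses.

What the generator does **not** emulate: genotyping error (miscalled
sizes), segregating paralogues outside the homoeologous pair, stutter or
size-binning artefacts, population structure in the panel, crossover
interference, and any sequence-level realism.  Passing recovery tests
therefore demonstrate correctness of the analysis logic under a clean
co-dominant model, not robustness to every artefact of real
capillary-electrophoresis data.

# Test problem sizes

The recovery tests run the full pipeline at the default study conditions
(8 × 2 groups, 20 markers per group, n = 92/184) over 20 seeds and check:
truth-equal grouping partitions in at least 95% of seeds; within-group
order Spearman |ρ| ≥ 0.95 for at least 90% of (seed, group) pairs;
homoeologue pairing equal to truth for every pairing supported by two or
more SL-HS loci; and mean per-group integrated-position |ρ| ≥ 0.97 in
every seed.  The distortion type-I rate is pooled over 50 seeds of a
single-pair, 10-marker, n = 184 null simulation and required to sit
within 2 percentage points of the nominal 5%.  Brute-force oracle
comparisons use sequences up to 2 kb (SSR), 30 hits (segmentation), and
Monte-Carlo saturation at a few hundred replicates — sizes at which the
oracles are exact or their error is far below the tolerance tested.

# Known limitations

* Two-point analysis only: no multipoint likelihood, no interference
  estimation, and distances come from adjacent pairs, so marker-dense
  noisy regions can locally compress or stretch.
* The ordering heuristic is a local search; order accuracy across a long
  gap with little shared information is intrinsically weak, and such a
  flip shows up as a low order-|ρ| group rather than an error.
* The integration algorithm is a documented substitute for the original
  commercial software's internals, judged by simulation recovery, not by
  equality with that software's output.
* Homoeologue assignment to progenitor genomes (*T. occidentale* /
  *T. pallescens*) is out of scope; the -1/-2 labels are arbitrary.
* The synteny stage consumes tabular homology hits; it does not align
  sequences.
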