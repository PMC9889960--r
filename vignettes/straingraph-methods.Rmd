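---
title: "Strain-aware de Bruijn graph assembly: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-aware de Bruijn graph assembly: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(straingraph)
```

## The assembly model

`straingraph` assembles shotgun metagenomic reads through a canonical
k-mer de Bruijn graph. Every k-length window of every read (windows
containing `N` are skipped) is stored under its *canonical* form — the
lexicographic minimum of the k-mer and its reverse complement — so both
strands of the community collapse onto one node set. Each node carries

* a **coverage** count: the number of read windows that produced it,
  a proxy for the abundance of the sequence it came from; and
* two 4-bit **edge masks**: the outgoing nucleotides observed when the
  node is read in its canonical orientation and in the reverse
  complement orientation (bits A=1, C=2, G=4, T=8). Every edge is
  recorded symmetrically on both endpoints.

k must be odd. An even-length k-mer can equal its own reverse
complement, which would make the stored orientation of a node
ambiguous; `straingraph` rejects even k with an explanatory error
rather than special-casing palindromes. The practical range is
3–191, with 31 the shipped default — large enough to be specific in
mixed communities, small enough that moderate-coverage data still
connects.

Coverage counts every window occurrence, not per-read presence: a
k-mer appearing twice in one read (e.g. across a short inverted
repeat) contributes two units. This is the convention under which the
conservation law *total node coverage = number of valid read windows*
holds exactly, which the test suite asserts.

## Pruning

Sequencing errors produce two graph artefacts: isolated low-coverage
nodes and short dead-end spurs ("tips") hanging off real paths.
`prune_graph()` removes them in that order — the coverage filter
first, because deleting low-coverage nodes exposes further tips — with
defaults of minimum coverage 2 and tip length up to 100 nodes.

The tip rule is *fork-competitive*: at every node with two or more
outgoing edges on one side, each branch is chased along its simple
chain. A branch that dead-ends within the length bound (every chain
node having in-degree 1 and out-degree ≤ 1) is a clippable tip. If the
fork also has a branch that continues — past the bound, or into
further structure — all tips at that fork are clipped; if *every*
branch is a dead end (as at the end of a linear replicon that happens
to carry an error spur), the best branch is kept, ranked by mean
coverage, then length, then first k-mer. Clipping iterates to a fixed
point. A naive "remove every short dead-end chain attached to a
branching node" rule is not usable: the two genuine ends of a chain
A–B–C with a side tip D at B are themselves short dead-end chains off
B, and the naive rule would eat the whole chain down to B. The
fork-competitive rule removes D and keeps A, B, C.

One practical consequence at desk scale: a genuine strain flank
shorter than the tip bound that competes at a fork with a longer
continuation *will* be clipped. Test fixtures with 60-node flanks
therefore prune with a 10-node bound; the 100-node default is sized
for real genomes, where genuine dead ends are chromosome/contig ends
thousands of nodes long.

## The consensus traversal (MC)

Each connected component of size ≥ 2 is walked once, starting from its
highest-coverage node (ties: smallest k-mer) and extending in both
directions. At a fork the branch whose target node has the highest
coverage wins, provided it meets the coverage floor — with one
exception, the **collective-coverage bubble rule**: if two branches
rejoin at a common node within the lookahead horizon (default 64
nodes; each branch followed by a greedy highest-coverage walk), and
their combined mean branch coverage exceeds every other single
branch's mean, the walk routes through the bubble via the
higher-coverage member of the pair. The scenario is two strains whose
summed abundance exceeds a third sequence sharing the same junction:
the strains' common path is the better consensus even though neither
allele alone outweighs the competitor.

The branch means for the pair test are taken over the branch-specific
nodes (the lookahead walk up to, excluding, the rejoin node), which
makes the metric insensitive to how much shared sequence lies beyond
the rejoin; a competing straight branch is summarized by the mean of
its full lookahead walk. Ties anywhere are broken in nucleotide order
A<C<G<T, so runs are reproducible.

A walk terminates at a dead end, when the chosen branch leads to a
node already in the path (repeats, cycles — the cycle is emitted once),
or when no branch meets the floor. Afterwards the component is
consumed: by default entirely (one contig per component), or — with
`multiple_contigs = TRUE`, for graphs where shared k-mers fuse many
species into one giant component — only the path's own nodes, so the
remainder is re-seeded and each component can yield several contigs.

### Local variants as sequence graphs

For GFA2/FASTG output, the consensus path is re-traversed: at every
node, each off-path branch meeting the floor is followed depth-first
(greedy highest coverage, cycle-safe, bounded at 500 nodes). A walk
returning to the path at a strictly *later* position is a local
variant — the other allele of a SNP or small indel — and is recorded
as an alternative segment anchored to the consensus segment by two
junction edges with exactly k−1 bases of overlap; scanning then
resumes from the rejoin position. Re-entry at or before the branch
point is rejected, so an inversion cannot masquerade as a bubble.
Branches are explored in the path's walk orientation only: the same
bubble seen from the opposite strand is the reverse complement of an
alternative already found, and exploring both directions would emit
every variant twice.

The GFA2 document carries one `S` line per segment (mean coverage as a
`DP:f:` tag), `E` lines with 0-based, end-exclusive overlap
coordinates (`$`-suffixed at segment ends, per the format), and one
`O` group per walk; a `ks:i:` header tag records k so the file
round-trips. FASTG output uses the v1.0 draft's colon/comma adjacency
headers with variation carried by distinct records, mirroring the GFA2
representation. Both writers are byte-deterministic, and
`read_gfa2()` inverts `write_gfa2()` exactly — the tests assert file-level
identity.

## The subtractive walk (SW)

The consensus walk writes one sequence per region; the subtractive
walk aims to write one per *variant*. It relies on a simple signal:
along a path through a single variant, adjacent nodes have similar
coverage, while entering a region shared with another variant roughly
doubles it. The normalized coverage change

$$\delta = \frac{c_{current} - c_{previous}}{\max(c_{current},\, c_{previous})} \in [-1, 1]$$

measures that transition independent of absolute depth.

Each round extracts the maximum-coverage path (greedy at every fork;
bubbles deliberately disregarded — the point is to separate variants,
not to merge them), then estimates how many variants cover each node.
The path's minimal-coverage node is anchored at one variant; when
several nodes tie at the minimum, the one closest to the path end is
used. Walking outward from the anchor in both directions ("previous"
always meaning the node visited at the preceding step of that walk), a
sharp rise `delta > delta_sw` increments the count and a sharp drop
`delta < -delta_sw` decrements it, floored at one; comparisons are
strict, so `delta == delta_sw` exactly changes nothing.

Two sign pairings of this rule are conceivable — rise-adds or
drop-adds. Starting from the minimum (by construction a low-coverage,
single-variant node), only *rise-adds* assigns extra variants to
high-coverage shared cores, which is the configuration in which
subtraction leaves shared nodes with residual coverage and zeroes
variant-specific ones; that is the default. The opposite pairing is
preserved behind `as_printed = TRUE` so the divergence is observable —
on the worked profile `[10, 10, 30, 30, 10, 8]` with threshold 0.4 the
default yields counts `[1, 1, 2, 2, 1, 1]`, the alternative
`[2, 2, 1, 1, 1, 1]`.

Subtraction then updates the graph in place: single-variant nodes are
zeroed; multi-variant nodes lose an amount linearly interpolated, by
path index, between the coverages of the nearest single-variant
positions on either side (one-sided constant extrapolation if a side
has none; the anchor guarantees at least one exists). On
`[10, 10, 30, 30, 10, 8]` the shared mid-section loses 10, leaving
`[0, 0, 20, 20, 0, 0]`. Coverages are clamped at zero and may become
fractional; all subsequent floor comparisons work on the real values.

The loop repeats — deterministic sorted node order, a budget-bounded
component scan (default 1 000 nodes) locating each round's locally
maximal seed — until no node meets the floor. Every round zeroes at
least its path's anchor node, a previously positive node, so the
number of rounds is bounded by the node count and termination needs no
further guard; an internal invariant additionally asserts that total
coverage strictly decreases. A re-walk of a residual shared core can
reproduce an earlier contig verbatim; such duplicates (up to reverse
complement) are subtracted but not re-emitted.

## The strain walk

Given a consensus-plus-alternatives sequence graph and a score table
mapping (segment, strain) to mapping identity and query cover — in
practice produced by aligning segments against reference genomes —
`walk_strain()` re-threads the backbone for one strain: at every
junction the candidate branch (alternative segment vs the backbone's
own continuation) with the highest score, identity × query cover, is
taken. A tie, or the absence of any scored candidate, keeps the
backbone branch, the conservative choice. Alternatives are resolved
greedily in walk order; an alternative starting inside a chosen
alternative's span is passed over. Missing table entries are treated
as "no mapping", never as a zero score, so sparse tables degrade
towards the consensus rather than towards arbitrary branches.

`score_segments()` provides an offline scorer for fixtures: exact
substring occurrence (either strand) scores 1 × 1; otherwise the best
local alignment (both strands) supplies percent identity and aligned
query fraction.

## The synthetic community generator

`simulated_community()`/`simulate_reads()` emulate a multi-strain
shotgun experiment: reference genomes, derived strains with per-base
SNP (uniform over the three alternatives) and indel (1–3 bp,
insert/delete equiprobable) events recorded as ground-truth edit
lists, per-sequence abundance weights, and reads of fixed length with
`ceiling(depth × length / read_length)` count per sequence, uniform
start/strand, and per-base substitution errors. One master seed fans
out derivably to per-sequence generators, so adding a genome never
perturbs another genome's reads.

Two read layouts are provided. `"uniform"` draws starts uniformly —
realistic, but a linear genome's terminal k-mer is then covered by
only the reads starting at exactly one position (an expected ~0.2
reads at 30×/150 bp over 2 kb), so exact end-to-end reconstruction is
a matter of luck, not correctness. `"tiling"` spaces starts evenly
with both ends included, the idealised read set under which a clean
graph spells the genome back exactly; the perfect-reconstruction
checks use it, with no pruning and a coverage floor of 1, because
error-free reads leave nothing to prune and terminal coverage
legitimately falls to 1. What the generator does *not* emulate:
sequencing indel errors (substitutions suffice to exercise pruning),
quality scores, chimeras, GC bias, or platform error profiles — so a
green test suite demonstrates algorithmic correctness on idealised
data, not performance on a real instrument's reads.

`evaluate_assembly()` is likewise alignment-free: genome fraction is
the percentage of reference positions overlapped by at least one
canonical k-mer shared with any contig, and N50 the usual
length-weighted median. On error-free fixtures this is exact and
strand-insensitive; on errorful data it is *not* numerically
comparable to aligner-based evaluation, since one substitution
interrupts k consecutive k-mers.

## Numerical and design choices

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 31 | odd k-mer length (3–191) |
| `min_coverage` | 2 | floor for nodes, seeds and branches |
| `tip_length` | 100 | maximum tip length, in nodes |
| `delta_sw` | 0.8 | variant-count threshold; 0.4 for diverse communities |
| `lookahead` | 64 | bubble-detection horizon, nodes |
| `max_alt_length` | 500 | variant-exploration bound, nodes |
| `min_component` | 2 | smallest component traversed |
| `search_budget` | 1000 | component-scan bound for SW seeding |
| `min_contig_length` | 100 | FASTA emission floor (500 is the usual evaluation convention) |

Other fixed choices: all string ordering uses radix (C-locale) sort,
so node order, contig numbering and output bytes are independent of
the session locale; branch ties resolve A<C<G<T; path positions and
indices are 1-based throughout the R API; contigs are written longest
first with a full-sequence tie-break; FASTA wraps at 80 columns;
coverage statistics print at two decimals. The graph serialization is
a versioned binary container (magic `SFDBG`, version byte, k, node
count, then k-mer text, double coverage and two edge-mask bytes per
node); merging summed-coverage/unioned-edge graphs of equal k
reproduces the single-pass build exactly. Reads with characters
outside `{A,C,G,T,N}` are mapped to `N` (excluded from k-mers) rather
than rejected; FASTQ structure is validated up front so malformed
records fail with their line number.

The test suite runs the algorithms at deliberately small problem
sizes — 2 kb genomes for exact reconstruction, 2.5 kb two-strain
mixtures at 50×, 200 random ≤ 12-node graphs for the greedy-walk
oracle, k = 15 for structural fixtures — chosen so the full suite
completes in about a minute while still exercising every rule. k = 5
and 7 are used only in hand-built literals: their canonical spaces
(512 and 8 192 k-mers) are small enough that random fixtures collide
and manufacture spurious forks, a pitfall worth knowing when building
one's own toy graphs.

## Known limitations

Single-threaded, pure R, designed for method development and
desk-scale experiments rather than multi-gigabase runs. Pairing
information is carried only as provenance — no paired-end repeat
resolution or scaffolding. Coloured (multi-sample) graphs are out of
scope, as is compatibility with other assemblers' binary graph
formats. The strain walk assumes a single-segment backbone with
simple (non-nested) bubbles, matching what the consensus traversal
emits; alternatives spanning other alternatives are resolved greedily.
Even k is rejected by design. The subtractive walk's variant counts
are a heuristic on coverage ratios: regions of low sequence
complexity, or abundance ratios near 1 between more than two strains,
can under- or over-count variants, which is why `delta_sw` is exposed
as the primary tuning knob.
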