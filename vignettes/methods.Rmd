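---
title: "How nanomapr maps error-prone long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How nanomapr maps error-prone long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

nanomapr is a read mapper built for long reads whose error rates (10--35%,
dominated by indels) defeat the seed-and-extend heuristics of short-read
mappers.  Its design premise is *read funneling*: a cascade of five cheap,
conservative stages, each of which narrows the set of candidate locations
using a progressively more detailed model of the read-to-reference
alignment, so that the expensive final alignment runs on (usually) a single
candidate region.  This vignette explains each stage, the parameters that
matter, what the bundled read simulator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## Stage I: gapped spaced seeds and Hough voting

Exact kmer seeds of useful length are almost absent from a read with 30%
errors.  nanomapr instead uses *gapped spaced seeds*: a shape such as
`1111110111111` (the 6-1-6 shape) reads twelve inclusive bases and skips a
"don't care" (DC) base in the middle.  The reference is indexed once per
shape under keys built from the inclusive bases only.  At lookup time each
DC position contributes three alternative layouts -- mismatch (skip the DC
base), deletion (do not skip it, consuming one fewer base) and insertion
(skip it and the following base) -- so a shape with $d$ DC positions
produces up to $3^d$ distinct keys, and a single 1 bp indel under a DC
position still retrieves the true location.  Two complementary weight-12
shapes are used by default (`1111110111111` and `11110111101111`); searching
for an optimal shape under the Levenshtein metric is intractable and out of
scope.  Keys occurring more than `max_postings` (default 500) times in the
index are skipped during lookup: they contribute little locational
information but a great deal of vote noise.

A seed hit is a point $(q, t)$ of read and reference positions.  Hits from
the true location are collinear on a slope-1 line $t = q + c$, so only the
intercept $c = t - q$ must be recovered -- a one-dimensional Hough
transform.  The intercept axis is rasterized into bins of width $L/3$ for
read length $L$ (so at least one bin is fully covered by the read), votes
are accumulated per (reference, strand), and bins with more than 75% of the
maximum count are kept.  Two practical additions: a hit lying within $L/6$
of its bin's lower edge also casts a *boundary vote* into the next-lower bin
(protecting reads whose true intercept straddles a bin edge; switchable via
`bin_smear`), and boundary votes are tracked separately so that primary
votes remain one-per-hit.  A selected bin covering intercepts
$[bw, (b+1)w)$ corresponds to reads occupying up to $(b+1)w + L$ on the
reference; expanding that footprint by one read length on each side gives
the candidate *region* $[bw - L, (b+1)w + 2L)$.  Overlapping selected bins
merge into one region; on circular references regions may run across the
origin, including a merge of the two fragments a wrapped read produces on
either side of it.

## Stage II: the kmer mapping graph

Within each region the read's kmers (default $k = 6$, comparable to the
signal-level kmer of nanopore base callers) become graph vertices, with
repeated kmers kept as distinct vertices.  Each vertex has $l$ outbound
edges (default 9) to the following $l$ read kmers.  Region kmers are
streamed left to right; each hit either extends the best existing walk
ending within the last $l$ read kmers -- "best" meaning the longest covered
walk, with ties preferring the smallest read gap and then the earliest
origin -- or starts a new walk.  The edges let a walk jump over kmers
poisoned by errors, which is what makes anchoring work at nanopore error
densities.  An extension must also advance between 1 and $l$ positions on
the region; without that reference-side constraint walks teleport across
repeats.  Covered length is accounted with kmer advances clipped at $k$, so
overlapping kmers are not double counted.

Walks shorter than 12 covered bases (smaller than the stage-I seeds) are
discarded.  A walk may bridge an indel and thereby shift diagonal; because
every downstream consumer (chaining, L1 fitting, anchored alignment)
expects exact co-linear segments, each surviving walk is split at its
diagonal shifts into maximal co-linear segments, and these segments are the
*anchors*.  Anchors are exact at their sampled kmers; bases between sampled
kmers inside a segment may mismatch (a bridged substitution) but never
shift the diagonal.

## Stage III: variable-length LCSk chaining

Repeats make the anchor set non-monotone.  The chain stage selects the
subset of anchors, strictly increasing in both read and region start
coordinates, that maximizes total covered length -- the longest common
subsequence in $k$-length substrings, relaxed so each "substring" has its
anchor's length.  Partially overlapping monotone anchors are both kept,
with the later anchor's credit reduced by the larger of its read- and
region-side overlaps (never below zero), so no matched base is counted
twice.  Because this overlap credit is a pairwise function of predecessor
and successor, the usual events-with-prefix-maxima sweep cannot represent
the objective exactly; the chain is therefore computed with an exact
$O(n^2)$ dynamic programme in C++.  Anchor counts per region are at most a
few thousand, where the quadratic programme costs milliseconds; an
exhaustive-subset oracle backs it in the test suite.  Ties are broken
toward the smaller region span and then the earlier anchors, making the
chain deterministic under input permutation.

## Stage IV: L1 refinement and region scoring

Chained anchors should lie on a 45-degree line in read-region space;
deviations are indel noise, and LCSk alone places no constraint on the
distance between consecutive anchors, so outliers survive it.  The
least-absolute-deviation fit with fixed slope 1 reduces to the weighted
median of anchor intercepts (weights = credited lengths).  Anchors farther
than $eT$ from the line in reference coordinates -- perpendicular distance
$eT/\sqrt2$ -- are dropped, where $e$ is the expected error rate
(conservatively 0.45 by default) and $T$ the read length.  A confidence
half-width $3\sqrt{\overline{d_i^2}}$ (the constant 3 mimicking a
3-sigma rule) then re-admits anchors close to the line, and LCSk runs once
more to close gaps the filtering opened.

Five scores summarize the refined chain: covered kmers $n_{kmers}$, the
standard deviation $\sigma$ of anchors around the line, the matched query
span $m_{len}$, anchor-covered bases $n_{cb}$, and the read length.  The
printed forms of the four normalizations are not available in the source
material, so the package fixes them as

$$norm_{mlen} = \min(1, m_{len}/T), \qquad
  norm_{ncb} = \min(1, n_{cb}/\max(1, m_{len})),$$
$$norm_\sigma = \max(0, 1 - \sigma/(eT)), \qquad
  norm_{readlen} = T/(T + \min(Q, 10^4)),$$

with $Q$ the length of the region's reference sequence, and the region
quality $f$ is their product.  Each factor is monotone in the evidence it
measures and bounded in $[0,1]$; the $10^4$ cap keeps $f$ from vanishing on
large references.  Since $f$ only ranks regions *of the same read*,
cross-read comparability is not required.  Note $f < 1$ even for a perfect
match -- only its ordering matters.  $n_{kmers}$ is deliberately excluded
from the product: it is the currency of the ambiguity rule below.

## Stage V: final alignment, MAPQ and E-value

Regions are sorted by $f$ and the best is aligned (ties: more covered
kmers, then smaller reference coordinate).  Three aligners are available:

* **myers** (default): semi-global edit-distance alignment (whole read,
  free region end gaps).  Myers' bit-vector algorithm -- the block-based
  formulation with carry propagation, tracking the score of the last query
  row -- locates the optimal window and distance in $O(nm/64)$; the CIGAR
  is then rebuilt by a banded dynamic programme whose band slack equals
  that distance plus one, which provably contains the optimal path, so the
  reported alignment is an exact optimum, not an approximation.
* **gotoh**: affine-gap semi-global alignment (gap of length $g$ costs
  $open + g \cdot extend$), full-matrix with traceback; memory-hungry on
  long regions and intended for moderate problem sizes.
* **anchor**: anchors of the chain are clustered; a neighbour joins a
  cluster when its read/region gaps agree, $|\Delta q - \Delta t| /
  \max(\Delta q, \Delta t) < e/2$.  Discordances of at most 20 bases never
  split a cluster: they are ordinary sequencing indels (the same constant
  the SV caller uses to separate errors from events), and splitting on
  them would fragment every cluster.  Clusters covering fewer than
  $\max(30, 0.02T)$ bases are discarded.  Anchor bodies are emitted by
  direct comparison; inter-anchor and inter-cluster gaps are aligned with
  the banded edit-distance kernel -- a reference-only gap becomes one long
  `D` run, which is how a spanning deletion surfaces in the CIGAR -- and
  read-end extensions are soft-clipped.  If every cluster is discarded the
  whole region falls back to the semi-global aligner.

Mapping quality derives from the ambiguity count $N_a$: regions with
$n_{kmers} \ge (1 - F)\, n_{kmers,best}$ (where $n_{kmers,best}$ belongs to
the best-$f$ region and $F \in [0,1]$ is the ambiguity factor) are
near-equivalent candidates.  With $p = \max(1 - 1/N_a, 10^{-4})$ the
reported quality is $\mathrm{round}(-10\log_{10} p)$ capped at 40: a unique
candidate scores 40, two candidates score 3.  With $F > 0$ the other
qualifying regions are emitted as secondary records.  Every mapped record
also carries a BLAST-like E-value in the `ZE` tag: the alignment is
rescored with match $+5$, mismatch $-4$, gap open $-8$ and gap extend $-6$
per gap base, converted to a bit score with Gumbel parameters
$\lambda = 0.192$, $K = 0.176$ (configurable; the defaults are conventional
values for this scoring scheme), and $ZE = mn\,2^{-bits}$.  Alignments
with `ZE` above the `-z` cutoff are reported unmapped.

## The read simulator

`simulate_reads()` draws read start positions and strands uniformly and
generates each emitted base by an i.i.d. draw over match / mismatch /
insertion / deletion.  The two presets mirror the two nanopore read
classes: `2D` (both-strand consensus reads) uses 5% mismatch, 4% insertion,
8% deletion; `1D` (single-strand reads) uses 10%, 5%, 15%.  These match the
published accuracy bands of the respective read types (roughly 83% and 70%
of template bases unaltered).  Each read carries a per-event edit string
from which the exact source coordinate of every base is reconstructed
(`truth_base_map()`), which is what the evaluation criteria consume.

What the generator deliberately does **not** emulate: homopolymer-biased
deletions and bursty, quality-correlated error clusters of real nanopore
signals; PBSIM-style model-based indel length distributions; chimeric
reads.  Error placement being i.i.d. makes the per-base placement task
measurably *easier* than on real reads -- an edit-optimal aligner recovers
about 79% of base placements under the 1D preset, where real-profile
simulations in the literature report about 70% -- so passing base-accuracy
checks here bounds behaviour on i.i.d. noise, not on real flowcell data.
Location-level metrics are much less sensitive to this difference.

`mutate_reference()` (SNP rate $6\times10^{-4}$, indel rate $0.0067$, sizes
truncated-geometric capped at 10) reproduces the divergence of a draft
nanopore-only assembly; `inject_svs()` plants the benchmark set of 20
structural variants (10 insertions and 10 deletions of 100 bp to 4 kbp).

## Evaluation procedures

* **Location**: a read is correctly mapped if its clip-adjusted start
  (reported position minus leading clipped bases) is within 50 bp of the
  simulated origin on the matching strand.  Precision divides by mapped
  reads, recall by all simulated reads.
* **Per-base**: a read base is correctly aligned if placed at exactly its
  simulated coordinate.  Clipped portions and unmapped reads are excluded;
  all other read bases (including insertions, which have no true
  coordinate) form the precision denominator.
* **Consensus** (`consensus_call()`): simple majority vote per position
  over A/C/G/T/deletion with plurality ties resolved to the reference
  base; positions under 20x coverage are not called; an insertion is
  emitted when more than half of the covering reads report one, voting
  over (length, sequence) pairs.
* **Structural variants** (`sv_call()`): indel CIGAR runs of at least 20
  bases vote per position (deletions over their interval, insertions over
  a half-size window around their junction); maximal windows with more
  than 15% supporting fraction and at least five supporting reads are
  called, windows closer than the larger window length are merged, the
  size estimate is the per-read median after re-aggregating split runs,
  and a call matches a true event when its size and both breakpoints agree
  within 25% of the event size.

## Benchmark scales and design choices worth knowing

The bundled benchmarks run at desk scale, chosen to exercise every stage
while completing in minutes on one core: mapping benchmarks use a 1 Mbp
uniform-random genome with 200 reads per error preset (1--5 kbp); the SV
benchmark plants the 20-event set on 1 Mbp and maps 2D-like reads at 30x
coverage.  For the SV experiment the read length is set to 6--12 kbp,
emulating the long genomic 2D libraries used for such analyses; this is
also a structural requirement, since the stage-IV band filter retains
anchors offset by at most $eT$, so only reads longer than
$4\,\mathrm{kbp}/0.45 \approx 9\,\mathrm{kbp}$ can span the largest events
natively.  A uniform random genome contains no repeat families; the
repeat-confusion benchmark used for the chaining ablation therefore plants
25 copies of a 2 kb motif at 2% divergence, where disabling LCSk chaining
measurably degrades both location precision and recall.

Degenerate inputs are handled conservatively: reads shorter than the seed
span, reads with no hits, regions with no surviving chain, and reads whose
every candidate scores $f = 0$ are reported unmapped rather than
force-aligned.  All coordinates are 0-based half-open internally; SAM
output is 1-based, collapses `=`/`X` to `M` by default, and reports `NM`,
`AS` and `ZE` tags.  The pipeline is deterministic: no stage draws random
numbers, so identical inputs give byte-identical SAM bodies regardless of
the `--threads` setting.

Known limitations: memory for the seed index grows with $4^{weight}$ for
the direct-offset table (weight 12 costs ~67 MB per shape; heavier shapes
fall back to binary search); the Gotoh mode stores a full traceback matrix;
the graph walk keeps at most four live states per read position, which can
in principle drop a best predecessor in extremely repetitive reads; and
`ZE` values use fixed Gumbel parameters rather than sequence-composition
estimates.
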