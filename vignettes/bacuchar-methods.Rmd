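---
title: "Methods: baculovirus genome characterization with bacuchar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: baculovirus genome characterization with bacuchar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacuchar)
```

# Scope and data model

`bacuchar` characterizes circular baculovirus genomes (ORFs, hr/dr repeat
regions, variants) and compares genome pairs (homology blocks, orthologs
and gene parity, K2P distances). The central container is the `genome`:
an uppercase A/C/G/T/N sequence with a topology. All coordinates are
1-based and inclusive, the convention of published baculovirus ORF tables,
where an ORF running from `start` to `end` (stop codon included) encodes
`(end − start + 1)/3 − 1` amino acids. Spans crossing the circular origin
carry a `wraps` flag and cover `start..L` then `1..end`.

Upstream steps that depend on external resources are consumed as inputs,
not re-run: homology and ab-initio coding support arrives as a per-ORF
evidence table (TSV), and variant calls arrive as a TSV or minimal VCF.
This keeps every analysis deterministic and network-free.

# ORF annotation

`enumerate_orfs()` reports, per strand and frame, the maximal open frame
from the first ATG after the upstream in-frame stop; start codons are ATG
only and stops TAA/TAG/TGA (standard code). Circularity is handled by
scanning the doubled sequence, keeping ORFs whose canonical start lies in
the first copy and whose extent does not exceed one genome length, and
deduplicating by stop codon position; enumeration therefore commutes with
genome rotation, which the test suite checks explicitly.

`apply_annotation_rules()` implements the conventional filter: ORFs with
homology evidence are always annotated; ORFs without it must (a) avoid
repeat regions entirely, (b) overlap every longer annotated ORF by at most
75 bp — the boundary is inclusive, 75 bp survives and 76 bp does not — and
(c) carry ab-initio coding support. Candidates are processed in decreasing
amino-acid length so that larger ORFs take precedence; equal lengths are
ordered by start coordinate, a deterministic tie-break the convention
leaves unstated. Overlap is measured in genomic bp regardless of strand.
`number_orfs()` then rotates the genome so the anchor ORF (polyhedrin or
granulin, by field convention) starts at position 1 and numbers annotated
ORFs by ascending start. The anchor must be plus-strand; assemblies where
it reads the other way should be reverse-complemented first, which we
prefer over silently flipping the sequence.

# Repeat regions

Two detector families replace interactive repeat-finding tools.

**hr regions** are clusters of ~44 bp imperfect palindromic units sharing
a genome-wide consensus. `find_repeat_units()` scans both orientations
(and across the origin) for ungapped windows within Hamming identity
`min_identity = 0.75` of a probe consensus. Ungapped matching is a
deliberate simplification: hr units in this family are length-conserved,
and it makes the identity threshold exact. The 0.75 default lets a
consensus — itself an average of imperfect units — recruit units diverged
by 15% or more with margin to spare; it is a visible parameter. A de-novo
mode (repeated 14-mer seeds, extension to unit length, similarity
grouping, re-scan with each group consensus) covers genomes without a
known probe. `cluster_into_hrs()` merges hits separated by at most 500 bp
and discards singleton "clusters" (≥ 2 units required); regions are named
hr1, hr2, ... in genome order. Per-unit palindrome scores — the fraction
of positions complementary to their mirror position — are recorded; the
44 bp consensus used as the generator default scores 0.5, i.e. palindromic
at half its positions, which is what "imperfect palindrome" means
quantitatively here.

**dr regions** are intergenic tandem arrays. `find_tandem_direct_repeats()`
compares the genome to itself at every candidate period p in 8–100 bp and
scores the lag-p match profile +1/−1. Maximal-scoring segments of that
profile (a tandem array matches itself at most positions and climbs
steadily; random sequence matches at ~1/4 and drifts downward) become
candidate arrays: units are phased from the array start, terminal units
recruited from random flanks are trimmed (a terminal unit is dropped when
it is both below the identity floor and a clear outlier against the
array's own units), and arrays must reach 4 copies with mean unit identity
≥ 0.8 to their majority consensus. Among overlapping candidates the period
explaining the most copies wins (a 2p reading halves the copy count), then
the longest self-match run, then the smaller period. Arrays equally well
explained at period 1 or 2 (homopolymers, dinucleotide wobble) are
excluded as low-complexity rather than reported as biological drs.
Consensus building is column-wise majority with ties broken in fixed base
order A < C < G < T, so results are platform-independent.

Regions of both kinds report span, unit length, copy number, per-unit
identities and the consensus; when both detectors fire on the same locus
the dr interpretation wins, since a tandem array recruited by a unit probe
is better explained as a dr.

# Cross-genome comparison

`find_homology_blocks()` anchors on exact shared 16-mers — effectively
unique at the 100 kb scale of these genomes; k-mers occurring more than
10 times in either genome are dropped as low-complexity — chains anchors
greedily by colinearity (anchor gap ≤ 500 bp, diagonal drift ≤ 20 bp),
extends chains outward by ungapped X-drop extension (+1/−2, drop 12), and
realigns each chained interval: Hamming when the chain is gap-free, global
alignment otherwise. Blocks need ≥ 200 bp and ≥ 0.8 identity; overlapping
blocks are resolved by match count. Percent identity counts gap and N
columns as mismatches — a conservative convention recorded in the output,
since published identity figures rarely state theirs. Both orientations
are scanned; inverted blocks are reported with an orientation flag.

Ortholog assignment is reciprocal best hit under global protein alignment
with identity scoring (match +1, mismatch −1, gap open 10, extend 0.5);
identity is identical residue pairs over alignment columns, and pairs must
reach 0.25 identity with 0.5 mutual coverage. Gene parity points place
each ortholog pair at its ordinal coordinates and each unmatched ORF on
the axis of the genome containing it, the standard synteny visualization
for these genomes. `compare_genomes()` additionally flags which annotated
ORFs each homology block overlaps and whether the block boundary truncates
them — the diagnostic pattern of a recent interspecies transfer is a
near-identical block whose edges cut genes.

# Distances and demarcation

`count_substitutions()` uses pairwise deletion (columns with gaps or N are
excluded) and splits differences into transitions (A↔G, C↔T) and
transversions. `k2p()` applies the Kimura two-parameter correction
`d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)`; saturated comparisons raise a
typed error (`k2p_saturation`) rather than returning NaN or infinity, so
pipelines fail loudly. `k2p_gamma()` implements the Jin–Nei gamma form
`d = (a/2)(1 − 2P − Q)^{−1/a} + (a/4)(1 − 2Q)^{−1/a} − 3a/4`; it converges
to plain K2P as the shape grows and increases monotonically as the shape
shrinks. The shape is a user input with no default applied — the plain
K2P distance is the default because shape estimates belong to the
alignment at hand. The test suite validates the gamma form against a
Monte-Carlo rate-mixture oracle and plain K2P against an independent
implementation (`ape::dist.dna`, model K80). `demarcate_species()` applies
the 0.05 substitutions/site criterion for baculovirus species demarcation
at conserved loci, with the boundary value itself classed "same" (strict
inequality; reported inter-species distances sit far above the line, so
the boundary convention is cosmetic but documented).

# Variants

`filter_variants()` keeps records with frequency ≥ 0.10 — inclusive, so a
variant at exactly 10% survives. Context classification gives ORFs
precedence over repeat regions, then intergenic; coding effects are
computed by translating the affected codon with reference and alternate
base on the coding strand (minus-strand ORFs via reverse complement), with
indels returning "na". Coding effect is invariant under genome rotation,
which is tested.

# The synthetic-data generator

`generate_genome()` emits genomes whose defaults emulate the architecture
of an alphabaculovirus isolate: 120 kb circular sequence, 39% GC
background, ORFs of 60–400 codons, ten hr regions of two-to-seven 44 bp
units around a fixed consensus, and five dr arrays with six to twelve
copies. Features are laid out in a deterministically shuffled order with
at least 600 bp of background between them, so planted repeat regions can
never merge under the default clustering gap; every generator is a pure
function of its spec and seed, and the caller's RNG state is left
untouched.

Two mutation regimes are used deliberately. Unit divergence inside planted
hr/dr regions applies an *exact count* of mutated positions per unit
(`round(rate × length)`, each to a different base), so a unit planted at
10% divergence has identity exactly 40/44 — recovery tests can then assert
exact counts instead of probabilistic ones. The recombination transfer
(`plant_recombination()`) instead mutates per base (Bernoulli), because
the binomial spread of realized identity around 1 − rate is itself the
property of interest. `evolve_pair()` plants transition/transversion
differences site-wise with the requested probabilities and returns
realized counts as truth, which makes distance-recovery tests exact about
their own generating process.

What the generator does **not** emulate: codon usage and dinucleotide
composition (background is i.i.d.; planted ORFs raise realized GC a point
or two above the background target), gene density of real genomes (tests
plant fewer, well-separated features), indel variation inside repeat
units, and sequencing error. Passing tests therefore demonstrate that the
detectors recover the stated feature classes under controlled divergence —
not that thresholds are optimal for any particular real isolate.

# Numerical and design choices

* Problem sizes in tests and the acceptance script are scaled to the
  signal being measured: 60 kb genomes for repeat recovery (10 + 5
  regions), 30 kb pairs for block rediscovery, 1.5 kb alignments × 100
  replicates for distance recovery. These sizes make the checks sharp
  while keeping the full suite around a minute.
* Acceptance-style recovery of the planted recombination scenario (1516 bp
  at 2.5% mutation) lands at one block whose mean identity is ~0.975 with
  boundaries within a few bases; chance-matching flank bases may extend a
  block a handful of positions beyond the planted segment, which is real
  homology and not clipped.
* Ties everywhere (consensus columns, equal-length ORFs, equal-run
  periods) have fixed documented tie-breaks; no result depends on hash or
  platform ordering.
* Degenerate inputs are rejected with typed or descriptive errors: empty
  genomes, non-IUPAC symbols (with offset), saturated distances,
  frequencies outside (0, 1], linear-genome rotation, spans out of range.

# Known limitations

* Ungapped repeat matching will under-recruit hr units with indels;
  gapped matching is deferred.
* Homology-block chaining is greedy single-pass; heavily rearranged or
  highly repetitive genome pairs may fragment blocks that a DP chainer
  would join. Blocks wrapping the circular origin are reported as two
  blocks (one per end).
* The GenBank reader ingests sequence and CDS locations only (no joins,
  no qualifiers beyond the location line); it is an ingest convenience,
  not a general parser.
* RBH ortholog assignment is quadratic in proteome size; it is intended
  for the ~130-ORF proteomes of this family, not metagenome-scale input.
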