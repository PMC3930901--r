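---
title: "Developing SSR markers from genome assemblies with ssrforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing SSR markers from genome assemblies with ssrforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrforge)
```

## The problem

Simple sequence repeats (SSRs, microsatellites) are tandem repetitions of
1-6 bp motifs whose allele length mutates quickly by replication slippage.
They remain the workhorse codominant marker for diversity studies, linkage
mapping and marker-assisted breeding in crops where dense genotyping is
not routine. Developing *useful* SSR markers from a reference assembly
involves more than finding repeats: the locus must be single-copy so a
primer pair amplifies one product; it should be polymorphic between the
genotypes of interest, which can be screened in silico when alternate
assemblies exist; and a primer pair must amplify a product in a size
window the genotyping platform resolves. ssrforge implements this whole
chain, plus the downstream statistics used to characterize the resulting
markers (PIC, transferability, Nei DA distances with neighbor-joining
trees, and a physical map).

## Tract detection

`scan_sequence()` reports every maximal perfect tandem run whose repeat
count reaches its class threshold. The defaults target high-repeat-number
tracts, which are the ones most likely to be polymorphic:

| class | unit (bp) | min repeats | min tract (bp) |
|-------|-----------|-------------|----------------|
| Mono  | 1         | 20          | 20             |
| Di    | 2         | 8           | 16             |
| Tri   | 3         | 8           | 24             |
| Tetra | 4         | 8           | 32             |
| Penta | 5         | 6           | 30             |
| Hexa  | 6         | 6           | 36             |

Per-sequence overrides (`overrides = list(Chr6 = c(Di = 5))`) exist
because marker panels sometimes relax one chromosome's threshold to even
out marker density; the override mechanism reproduces such exceptions
without hard-coding them.

Conventions that needed a decision, and what was chosen:

* **Perfect repeats only.** Compound or interrupted SSRs appear as
  separate adjacent loci when each segment passes its own threshold.
  Alignment-style approximate repeat finding is out of scope.
* **Primitivity.** A run is assigned to the smallest unit that generates
  it: poly-A is Mono, never Di "AA"; `ATATAT` is Di, never Tetra
  `ATAT`.
* **Leftmost phase.** A periodic region read as `...ATATAT...` can be
  phrased as AT or TA; the leftmost full unit defines the reported motif
  and coordinates, which also guarantees no two reported loci of one
  family overlap.
* **Families are strand-specific.** The family is the lexicographically
  smallest cyclic rotation of the motif (AG and GA group together), but
  reverse complements are *not* merged - AG/GA and CT/TC are distinct
  families, matching how SSR composition is conventionally reported per
  strand.
* **N breaks a run**; tracts never span an N. Coordinates are 1-based
  inclusive throughout, for GFF3 compatibility.
* **Coding context** (`classify_genomic_context()`) uses a >= 1 bp
  overlap rule with the supplied coding intervals - the simplest testable
  convention.

The scanner is validated against a brute-force oracle that tries every
primitive motif of length 1-6 at every position of seeded random
sequences.

## Single-copy filtering

A fragment (tract plus 200 bp flanks by default) is kept when its best
genome-wide alignment scores at least five-fold higher than the second
best (`single_copy_test()`; the boundary is inclusive, and a tie at the
top is multi-copy). Production use feeds standard 12-column tabular hit
files from an external aligner (`read_hit_table()`; the bitscore column
is used - the score basis is not otherwise interpreted). For
self-contained runs, `naive_search()` provides a deliberately simple
desk-scale stand-in: exact 15-mer seeds, ungapped extension scoring
+1/-1, best interval per seeded diagonal, reported at score >= 30. The
self-hit stays in the score list, so "single copy" means the self-hit
dominates everything else. Loci with zero hits cannot be confirmed
single-copy and are dropped (logged distinctly as `no-hit`).

## Polymorphism calls against alternate assemblies

Rather than whole-genome alignment, `compare_loci()` anchors each locus's
immediate 50 bp flanks in the alternate assembly (exact match first, then
best match with at most 2 mismatches; both anchors must be unique, on one
sequence, in order), then re-measures the longest run of the locus's
family between the anchors. This flank-anchoring design replaces
general-purpose variant comparison tools with an operation whose behavior
on known inputs is fully specifiable: on synthetic assemblies with
planted repeat-count changes and intact flanks, exactly the mutated loci
are called polymorphic and every length delta is recovered exactly.
Anchoring failures (deleted or duplicated flanks, assembly gaps,
anchors on different contigs) yield `unresolved`, never a wrong call.

The default polymorphism threshold is `min_diff = 1` bp - any length
difference counts. Gel-resolved genotyping in practice needs >= 2 bp, so
the threshold is configurable. Summary percentages are always recomputed
from the integer counts in the same row and rounded half-up to one
decimal, the convention used in published marker tables.

## Primer design

`design_pair()` replaces a thermodynamic designer with a deterministic,
fully specified selector. Defaults: primer length 18-24 nt, Wallace-rule
Tm (2(A+T) + 4(G+C)) in 55-62 °C, GC 0.40-0.60, homopolymer <= 4, Tm
difference <= 3 °C, product 100-300 bp. Only the product window is
dictated by the genotyping platform; the rest follow common primer-design
practice. Every candidate window pair flanking the tract is enumerated
and scored with

```
penalty = |tm_f - 60| + |tm_r - 60| + |tm_f - tm_r| + 0.01 |product - 200|
```

and the minimum-penalty pair wins, ties broken by smaller forward start
then smaller product. The Wallace rule was chosen over nearest-neighbor
thermodynamics deliberately: it is integer-valued and exactly
reproducible without parameter tables, which makes the selector testable
against an independent exhaustive enumeration (a documented deviation
from typical tools - the Tm values are rough). Every returned pair is
additionally verified by exact in-silico PCR to amplify exactly one
product of the declared size containing the whole tract.

## Marker statistics

* **PIC** (`pic()`): Botstein's polymorphism information content,
  `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`, computed from allele
  frequencies where a heterozygous call contributes 1/2 to each allele.
  PIC is the standard meaning of marker informativeness; other diversity
  statistics are out of scope.
* **Transferability** (`transferability()`): the percentage of markers
  with at least one non-missing call in a target accession group.
  "Amplifies" is operationalized as a non-missing call, not as
  polymorphism - the natural reading of transfer rates across related
  species.
* **Nei DA distance** (`nei_da()`, 1983):
  `1 - (1/L) sum_loci sum_alleles sqrt(x_a y_a)`. Missing data are
  handled by pairwise deletion (per-pair shared loci) by default,
  matching common SSR practice; complete deletion is available. DA
  satisfies symmetry and identity but is not guaranteed metric, so no
  triangle-inequality property is asserted anywhere.
* **Neighbor joining** (`neighbor_joining()`): Saitou-Nei with the
  standard Q-criterion. Determinism conventions: ties in Q break by the
  smallest index pair; negative branch lengths are clamped to 0 with the
  deficit not redistributed (the simplest documented convention); n = 2
  splits the single edge equally. Trees are emitted as Newick with
  6-decimal branch lengths and round-trip through the package's own
  parser. On additive matrices NJ provably recovers the generating tree;
  the tests verify path-length equality to 1e-9 and topology agreement
  with an independent implementation.

## The physical map

`build_map()` orders markers by tract start within each sequence and
reports gaps to the previous marker in Kb. Marker position is the SSR
tract start, not the primer position, so coordinates are stable when
primers are redesigned. The global mean gap averages within-sequence
adjacent pairs only - distances across chromosome boundaries are
meaningless.

## What the synthetic data emulate - and what they do not

`generate_genome()` plants specified SSR tracts into uniform-random ACGT
background that is re-sampled (rejection, not masking) until no
*unplanted* tract passes the scan thresholds, so the truth table is exact
by construction. Planted tracts must be >= 200 bp apart to keep flanks
anchorable. `derive_genotype()` emulates a resequenced-and-assembled
alternate accession: per-locus repeat-count deltas plus flank
substitutions at a configurable rate (default 0.005/bp), with a 60 bp
window adjacent to each tract kept SNP-free so anchors stay findable -
a stress flag allows mutating anchors to exercise the unresolved path.
`simulate_genotype_matrix()` emulates a genotyped accession panel: the
default groups (8 landraces, 10 cultivars, 10 wild accessions; 28 in
all) mirror a realistic diversity panel; allele counts per marker default
to 2 + Binomial(14, 0.36), giving the 2-16 range with median near 7
that characterized SSR panels of this kind; group divergence mixes a
shared Dirichlet-drawn base frequency profile with a group-specific draw
using a single weight (0 = identical groups, 1 = independent), and calls
are homozygous, matching an inbreeding species.

These generators do **not** model realistic microsatellite evolution
(no stepwise mutation dynamics, no homoplasy), chimeric assemblies,
sequencing error, or linkage between markers. A green planted-truth test
therefore establishes that the pipeline recovers what the generators
encode - not that it would handle every artifact of real assemblies. The
cluster-recovery property uses 733 markers (a full developed-panel size)
at divergence 0.8 ("strongly diverged groups"); with tens of markers the
group signal of single-individual accessions is too weak for reliable
monophyly, which is itself a faithful reflection of how many markers
such panels need.

## Numerical choices

* Percentages: half-up rounding to 1 decimal (`round_half_up()`), the
  convention of published marker tables; 0-of-0 cells are blank (NA).
* PIC validates that frequencies sum to 1 within 1e-6; allele-frequency
  estimates themselves always sum to 1 within 1e-9.
* The lower median is used for even marker counts in the allele-count
  distribution.
* All generators take explicit seeds and restore the caller's RNG state;
  identical seeds give byte-identical outputs.

## Known limitations

* The built-in aligner is ungapped with exact seeds; an indel in a
  repeated flank can hide a second copy. External hit tables are the
  production path.
* Flank anchoring requires both 50 bp anchors intact and unique; highly
  fragmented or repeat-dense assemblies will yield many `unresolved`
  loci (reported, never silently dropped).
* Wallace Tm is a rough approximation; designed primers should be
  re-checked thermodynamically before synthesis.
* No dimer/hairpin screening; genome-wide primer specificity is
  delegated to the single-copy filter on fragments.
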