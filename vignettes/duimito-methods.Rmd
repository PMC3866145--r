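---
title: "Methods: comparative analysis of gender-associated mitogenomes"
author: "duimito"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of gender-associated mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duimito)
```

# Scope

Freshwater mussels (and a few other bivalve lineages) transmit two deeply
divergent mitochondrial genomes under doubly uniparental inheritance (DUI):
a maternally inherited F genome and a paternally inherited M genome.
`duimito` implements the comparative analyses this system calls for:
genome architecture (overlaps, unassigned regions, start/stop codon usage,
the male *cox2* 3' extension), strand-asymmetry skews and per-partition
base composition, codon usage with RSCU, codon-aware F/M divergence
(p-distances, bootstrap standard errors, NG86 Ka/Ks), Fickett TESTCODE
coding-potential scores for the gender-specific open reading frames,
control-region identification from tandem repeats with stem-loop potential,
signed gene-order comparison, and a light neighbor-joining surface for
reciprocal-monophyly checks. A deterministic genome simulator provides the
package's test surface; its defaults encode the architecture of a
unionoid F/M mitogenome pair.

# Data model and conventions

A genome is a `mito_genome`: the deposited light-strand (L) sequence of a
circular molecule plus an ordered feature table. Coordinates are 0-based
and half-open on the L strand; a feature spanning the sequencing origin
keeps `wraps_origin = TRUE` rather than being split. GenBank's 1-based
closed coordinates (including origin-spanning `join()` locations) are
converted at the I/O boundary, and a plain TSV feature table
(`label`, `kind`, `start`, `end`, `strand`, `wraps_origin`) is supported
alongside FASTA for fully transparent fixtures.

Gene labels are canonicalized (`cox1..3`, `nad1..6`, `nad4L`, `atp6`,
`atp8`, `cob`, `rrnS`, `rrnL`, `trnX` with `S1/S2`, `L1/L2`
anticodon-based disambiguation, `FORF`/`MORF`) so that orders and gene
tables are comparable across records. All translation uses the
invertebrate mitochondrial code (translation table 5); the first codon of
a CDS is rendered as methionine regardless of the (possibly alternative)
initiation triplet. Mitogenomes annotate both "13 protein-coding genes"
and the gender-specific ORF; reports expose both groupings — architecture
tables include the ORF (14 coding rows), while composition and
concatenated-divergence partitions default to the 13 typical PCGs with an
`include_orf` switch.

Half-open abutting genes do **not** overlap; an overlap requires at least
one shared base. Intergenic (unassigned) regions are the maximal
feature-free arcs of the circle, so their count and lengths — and every
other architecture statistic — are invariant under rotation of the origin
(a property the test suite exercises directly).

# Composition and strand skews

Skews follow the standard definitions `AT skew = (A - T)/(A + T)` and
`GC skew = (G - C)/(G + C)`. Ambiguity codes are excluded from numerators
and denominators rather than fractionally allocated; `n_effective` records
the bases used. The partition table reports the whole genome on the L
strand as deposited, and rRNA/PCG/tRNA partitions on strand-corrected
(sense) sequences — this reproduces the characteristic sign structure of
DUI mitogenomes, where the coding strand of the protein genes shows
negative AT skew and positive GC skew while the whole L strand shows the
opposite signs. Codon-position partitions are taken per gene in reading
frame and then pooled, so frames never slip across gene boundaries.
Percentages are conventionally displayed to one decimal and skews to two;
full precision is retained in every returned object.

RSCU is computed per synonymous family as count over family mean, so a
fully observed family averages to exactly 1; stop codons are counted but
flagged and excluded from most/least-frequent summaries (ties broken
lexicographically).

# Divergence estimation

Each shared protein-coding gene is compared by a codon-aware pipeline:

1. terminal stop codons are stripped and the CDS translated (internal
   stops are errors, not warnings — they indicate mis-annotation);
2. peptides are aligned globally by Needleman–Wunsch under BLOSUM62 with
   affine gap penalties (opening 10, extension 1). For a two-sequence
   comparison this is the exact optimum a progressive multiple aligner
   approximates, which removes an external binary at the cost of possible
   last-digit differences from published values computed with other
   aligners;
3. the amino-acid alignment is imposed back onto the codons
   (retro-alignment): each residue becomes its source codon, each residue
   gap a 3-base gap, so nucleotide columns stay in frame.

p-distances use pairwise deletion of gap/ambiguous columns (whole-codon
masking for the codon statistics). Standard errors come from a
site-resampling bootstrap (default 1000 replicates, default seed 42);
columns are resampled with replacement and the statistic recomputed, which
matches the binomial closed form on iid sites.

Ka/Ks follows the classic NG86 formulation with equal pathway weighting:
per-codon synonymous site fractions are averaged over the two sequences
(changes that would create a stop codon count as nonsynonymous, which
keeps `S + N = 3 × codons` exactly); for each differing codon pair the
synonymous/nonsynonymous difference counts are averaged over all
minimal-substitution pathways, excluding pathways through stop codons
(falling back to all pathways only if every one is blocked). `ps = Sd/S`
and `pn = Nd/N` are corrected with Jukes–Cantor,
`d = -(3/4) ln(1 - (4/3) p)`. Saturation (`p >= 3/4`) is an error, not a
clamped value, and `Ks = 0` yields an undefined (NA) ratio rather than 0.
The per-gene table wraps the estimator so saturated genes are reported as
NA while their p-distances remain. The "all proteins" row is computed on
the concatenation of the shared typical PCGs (gender-specific ORFs
excluded), not as an average of per-gene values; `concat_and_mask()`
also produces the third-position-masked matrix (two thirds of the
columns) with a partition map in 1-based inclusive column ranges.

# TESTCODE

The Fickett TESTCODE statistic combines, for each base, a positional
asymmetry parameter `max(n1, n2, n3) / (min(n1, n2, n3) + 1)` over the
three phases and a content parameter (base frequency), each mapped through
the published probability lookup tables and combined with the published
weights (tables embedded as versioned constants, v1982). Verdicts use the
published thresholds: noncoding below 0.74, no-opinion between 0.74 and
0.95, coding above 0.95. The reported probability-of-coding is a monotone
linear calibration anchored at those thresholds (it reproduces the
conventional readings of ~92% near a score of 1.0 and 100% above ~1.2);
it approximates the original calibration curve and should be read as a
guide, not a posterior. Whether an annotated ORF's stop codon was included
in published scores is typically unstated, so both modes are exposed
(`include_stop`); the default strips a terminal stop. Scores on sequences
below 200 nt are flagged low-confidence.

# Tandem repeats, hairpins and control-region ranking

The repeat detector is seed-and-extend: candidate periods are the
distances at which exact k-mers (default k = 12, adapted downward for
short inputs) recur; for each candidate period the lag-match profile is
segmented into runs, runs are merged while overall identity stays above
the threshold (default 0.85), merged ends are trimmed while a terminal
window falls below the threshold, and overlapping reports are reduced to
divisor-minimal periods (smaller period preferred, then higher identity,
then leftmost). Copy numbers are reported fractionally (`span / period`)
and rounded only in summaries; a printed count of "8 repeats" corresponds
to a fractional estimate in [7.5, 8.5). The detector compares successive
copies by substitution only — indel-divergent copies would fragment an
array — which matches the near-perfect arrays the simulator plants and the
~100 bp control-region elements this analysis targets.

Stem-loop potential is assessed by combinatorial base-pair maximization
(the Nussinov recursion) with Watson–Crick and G–U pairs and a minimum
loop of 3, rather than thermodynamic minimum-free-energy folding: free
energy parameter sets are deliberately out of scope, so criterion (iii)
below tests *stem-loop potential*, not ΔG. The traceback prefers pairing
the outermost compatible bases, yielding maximal contiguous helices with
deterministic (5'-most) tie-breaking; the reported stem is the longest
contiguous helix of the optimum, with its subtended loop.

Control-region candidates are the unassigned regions scored on the three
classic criteria — (i) length, (ii) AT content, (iii) a tandem repeat
whose unit folds into a hairpin with at least `min_stem` (default 6)
contiguous pairs. The composite score is the minimal-assumption equal
weighting `z(length) + z(AT%) + indicator(qualifying repeat)`, computed
across the genome's unassigned regions, ties broken by length. The
z-scoring makes the ranking rotation-invariant and scale-free; the
indicator contributes exactly +1, so adding a qualifying repeat can never
demote a candidate.

# Gene orders

Orders are signed circular permutations (sign = strand), canonicalized to
start at `cox1`; reflections are *not* identified with each other because
strand annotation fixes the orientation of a mitogenome. Two scopes are
exposed: the 13 typical PCGs + 2 rRNAs (the classic rearrangement marker
set) and all genes including tRNAs (where most mitogenome plasticity
lives). An adjacency is an oriented neighbor pair, equal to its
reverse-complement reading; the breakpoint distance is the number of
adjacencies of one order absent from the other. Segment inversions of any
internal length cost exactly 2, single-gene transpositions 3 — properties
the suite checks against an independent adjacency-scanning oracle.
Clade-diagnostic (synapomorphic) adjacencies are those present in every
group member and absent from every non-member.

# Neighbor joining and monophyly

`nj_tree()` is the Saitou–Nei algorithm with deterministic lowest-index
tie-breaking on the Q matrix; negative branch lengths are clamped to zero
with a message (standard practice). It recovers additive matrices exactly
and is cross-checked against an independent NJ implementation in the test
suite. Monophyly of a taxon set on an unrooted tree is decided by edge
bipartitions, so a set and its complement are equivalent — the form in
which reciprocal F/M monophyly is asserted.

# The synthetic generator

`unionoid_genome_spec()` and `simulate_genome()` realize an annotated
circular genome exactly from a roster: gene labels, kinds, lengths,
strands, start/stop codons, gaps and overlaps. The defaults are the study
conditions of a unionoid F/M pair: F 16716 bp with 27 unassigned regions,
2 overlaps (1–8 bp) and a 1049 bp control region carrying 8 × 101 bp
repeats between *nad5* and *trnQ*; M 17102 bp with 23 unassigned regions,
6 overlaps (1–168 bp, including the 168 bp *nad6/nad4* and 8 bp
*cox3/cox1* overlaps) and an 848 bp control region with 7 × 102 bp
repeats between *trnH* and *trnQ*; published per-gene lengths and
start/stop codons throughout; the typical PCG+rRNA order
*cox1-cox2-nad3-nad2-rrnS-rrnL-cob-nad5-nad1-nad6-nad4-nad4L-atp8-atp6-cox3*
for M, with the *nad2/nad3* relative inversion distinguishing the F order
(the precise F arrangement between *cox2* and *rrnS* is not printed in
the study's text, so the inversion is realized as *cox2-nad2-nad3-rrnS*);
*trnH* transposed and the *trnD–atp8* segment inverted between the sexes.
Per-gene strand assignments are only partially published (the tRNAs other
than *trnH*/*trnD* and both rRNAs are light-strand); the remaining
assignment is fixed but arbitrary, with *nad6* and *nad4* on opposite
strands in M so that the planted stop codon of one 168 bp-overlap partner
cannot fall in frame inside the other.

Composition planting solves strand-specific base probabilities in closed
form from (AT%, AT skew, GC skew) per partition — codon positions 1/2/3
for coding bodies, per-rRNA, tRNA, control region and background targets.
Non-coding features use exact-count sampling (largest-remainder rounding
of the target probabilities, then shuffling), which matters for the
control region: its repeat array replicates one unit many times, so a
single multinomial draw's noise would be amplified across the whole
region. The repeat unit is built hairpin-capable (arm, loop,
reverse-complement arm, filler), which necessarily dilutes the planted GC
skew of the control region toward zero over the arm halves — the strong
negative sign survives, the printed magnitude does not. Whole-genome
skews are likewise emergent mixtures of strand-corrected partitions under
the arbitrary strand assignment, so tests assert their signs rather than
printed magnitudes. Coding bodies are stop-free by construction; planted
start/stop codons are written last, and a repair pass reconciles
overlapping reading frames by re-sampling offending codons under the
constraint that no covering frame gains an internal stop and no planted
codon is touched. An in-frame stop is planted immediately upstream of
each gender-specific ORF so that ORF scans recover the annotated extent.

Codon evolution (`evolve_codon_sequences()`) is a proposal/acceptance
process, not a full codon-model matrix: uniform single-nucleotide
proposals at a rate tuned to the synonymous-divergence target
(`proposals = Ks × 3 × codons`, exploiting that the per-proposal
synonymous probability equals `S/3n`), synonymous changes always
accepted, nonsynonymous accepted with probability ω, stop-creating
proposals rejected. NG86 recovers ω from these simulations to within 20%
at 3000 codons, with the neutral limit inside [0.9, 1.1]; the small
downward bias comes from stop-adjacent sites that NG86 counts as
nonsynonymous but the process never substitutes. `unionoid_pair()`
derives the M genes from the F genes under published per-gene (ω, Ks)
targets, appending or trimming 3' codons to the M lengths — which is
precisely how the 543 bp (79.7%) male *cox2* extension arises. Two
refinements apply only to this derivation: proposals are drawn from the
M-genome positional base distributions with a Metropolis–Hastings
correction (so divergence does not erode the planted AT-richness), and
the proposal budget is scaled by the expected Hastings acceptance so
realized divergences stay on target. Synonymous targets above 1.8 are
capped at 1.8: the Jukes–Cantor correction is undefined at `p >= 3/4`,
and an uncapped near-saturating target would put a non-trivial fraction
of replicates outside the estimator's domain. The two most saturated
genes therefore sit slightly below their published Ks, and the
concatenated nucleotide p-distance lands near, but a little under, the
published ~0.40.

What the generator does **not** emulate: indel evolution (alignments of
equal-length cores are gap-free apart from the planted 3'
extensions), realistic tRNA cloverleafs, among-site rate variation,
base-by-base identity with any deposited record, and real codon usage
beyond positional composition (TESTCODE scores of the synthetic ORFs
fall near the no-opinion band rather than at published values). Passing
tests therefore demonstrate that the estimators recover what was planted
under realistic sizes and compositions — not that any particular real
accession is reproduced digit for digit; analyses of real records go
through the same `load_genome()` path.

# Numerical choices and problem sizes

Determinism is end-to-end: every stochastic routine takes a seed, RNG
state is saved and restored around internal use, and identical
config+seed report runs emit byte-identical JSON summaries. Default
thresholds: repeat identity 0.85, minimum period 20 bp, minimum 2 copies;
hairpin minimum loop 3 with G–U allowed, qualifying stem 6 pairs;
control-region length criterion 500 bp; bootstrap 1000 replicates, seed
42. Test and acceptance runs use the sizes at which the properties are
informative yet quick: 3000-codon alignments with 5–8 replicates for ω
recovery, exhaustive folding oracles at 8–18 nt, 5–8 taxon additive
matrices for NJ recovery, and the full 16.7/17.1 kb genome pair for all
architecture, composition, control-region and divergence checks.

# Known limitations

Annotation is taken as given (no de-novo tRNA or rRNA inference; rRNA
ends in the source records were themselves assumed to extend to flanking
genes). The GenBank reader covers single-record flat files with simple
and origin-spanning locations, not multi-contig or heavily qualified
records. The repeat detector will fragment indel-divergent arrays. The
hairpin model maximizes pairs, so it overestimates the stability of
AT-rich stems relative to a thermodynamic model. ML/Bayesian phylogenetics
and codon-model (ML) dN/dS are intentionally out of scope; the NJ surface
exists for topology-level properties only.
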