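---
title: "Methods: comparative mitogenomics of doubly uniparental inheritance"
author: "mitorfan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenomics of doubly uniparental inheritance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorfan)
```

## The biological problem

Freshwater mussels (Bivalvia: Unionida) and several other bivalve
lineages transmit mitochondria through both sexes: a female-transmitted
F mtDNA passes through eggs while a distinct male-transmitted M mtDNA
passes through sperm — doubly uniparental inheritance (DUI). The two
molecules of one species can differ by roughly 40% at the nucleotide
level, carry lineage-specific open reading frames with no recognizable
homologs (ORFans: F-orf in F, M-orf in M, H-orf in the F-derived
molecule of hermaphrodites that lost DUI), show an in-frame 3'
elongation of *cox2* in the M molecule, and differ in gene order
through tandem duplication–random loss (TDRL) rearrangements whose
decayed pseudogene leftovers persist in unassigned regions.

`mitorfan` implements the comparative toolkit this biology calls for:
an ORF census of the unassigned regions under the invertebrate
mitochondrial genetic code, counting-method dN/dS, gene-order algebra
with a single-step TDRL test, repeat and pseudogene-fragment scanners,
and a topological classifier of the transmission pattern
(gender-joining versus taxon-joining). A deterministic simulator
produces mitogenomes with known planted truth so the whole pipeline is
testable without any sequence download.

## Coordinate and data model

All coordinates are 0-based half-open on the forward strand; a feature
on a circular molecule may wrap the origin (encoded as `end` greater
than the genome length). GenBank's 1-based inclusive convention exists
only inside `read_genbank()`/`write_genbank()`. Unassigned regions
(URs) are the maximal intervals covered by no annotated feature —
overlapping genes are allowed, and a base belongs to a UR only when no
feature covers it. UR number 1 is the UR whose end lies nearest
upstream of *cox1* on the forward strand, and numbering proceeds
clockwise; this makes the numbering invariant under rotation of the
sequence origin, which the test suite checks explicitly.

## ORF census

An ORF runs from an initiation codon of NCBI translation table 5
(ATG, ATA, ATT, ATC, GTG, TTG) to the nearest in-frame stop, with both
ends inside the UR; the minimum is 10 encoded amino acids plus the
stop, i.e. 33 nt. When several start codons share a stop only the
longest ORF is reported. Because the start-to-stop definition is a
policy rather than a fact about the data, `find_orfs()` also offers a
stop-to-stop mode behind the `mode` argument; the default is the
start-to-stop rule. Two protein translations accompany every call:
`as_coded` (an alternative initiation codon contributes its ordinary
amino acid) and `force_met` (the first residue is always written as
methionine). Codons containing `N` translate to `X`, and a candidate
whose ambiguous codon could resolve to a stop is rejected outright
rather than reported with an uncertain boundary.

The homology screen mirrors a profile-search ladder with local
alignment: each ORF protein is compared against (1) the genomes' 13
standard proteins, (2) known F/M/H-ORF proteins, and finally (3) the
ORF set itself, with the per-step best hit (or an explicit miss)
recorded. Alignment uses Smith–Waterman (BLOSUM62, gap open 11, extend
1, a gap of length L costing `open + ext * L`) through
`Biostrings::pairwiseAlignment()`; the acceptance score of 40 was
chosen so that random 30-residue proteins hit the reference set in
fewer than 5% of simulations, a proxy for the E-value cutoffs of
profile-search tools, and the suite verifies exactly that property.

## Divergence statistics

`p_distance()` is the proportion of differing sites among compared
columns, with pairwise deletion of gap/`N` columns (for two sequences
this equals complete deletion — the alignment program setting most
counting tools default to).

`nei_gojobori()` implements the counting estimator. Synonymous site
fractions per codon come from enumerating all nine single-nucleotide
changes; changes to stop codons are counted as nonsynonymous so that
every codon contributes exactly 3 sites and `S + N = 3 × codons` holds
as an invariant. Observed differences at multi-hit codons are averaged
over all orderings of the single changes with equal weights, excluding
pathways that pass through a stop codon (if every pathway is blocked —
possible only for a handful of codon pairs — all pathways are used and
steps through stops count as nonsynonymous). The Jukes–Cantor
correction `d = -3/4 log(1 - 4/3 p)` is applied by default and flagged
undefined at `p >= 3/4`; `omega = dN/dS` is flagged undefined when
`dS = 0`. The implementation is verified against an independent
pathway-enumeration oracle over the full 60 × 60 sense-codon table of
the invertebrate mitochondrial code.

For the F-versus-M report, codon alignments are built by aligning the
two protein sequences globally (Needleman–Wunsch, BLOSUM62, 11/1) and
threading codons through the protein alignment; gapped codon columns
are excluded from the counts. The headline statistic is computed on
the concatenation of the 13 per-gene codon alignments (per-gene rows
are also emitted, since averaging per gene is the other reasonable
reading of an "overall" value); rRNA genes contribute nucleotide
p-distances only.

## Alignment masks

Masking programs disagree, so the package represents each program's
output as a per-column keep/drop vector and combines them by a k-of-n
vote: a column survives `combine_masks(masks, k = 3)` with four masks
iff at least three of the four keep it. `k = 1` is the union, `k = n`
the intersection, and raising `k` can only remove columns — all three
facts are tested. Two built-in maskers (gap fraction at most 0.5;
column Shannon entropy over residues at most 1.5 bits) exist so the
consensus machinery is exercisable without external programs; they are
simple column filters, not re-implementations of any published masker.

## Gene-order analysis

Gene orders are signed circular token sequences read off the feature
table. The breakpoint distance counts signed adjacencies of one order
absent from the other, identifying `(x, y)` with `(-y, -x)`, after
restriction to the shared gene set.

`tdrl_feasible()` decides whether one tandem duplication–random loss
step explains a rearrangement: a contiguous block is duplicated in
tandem and one copy of each duplicated gene is lost, so the surviving
genes read as the first-copy survivors in source order followed by the
second-copy survivors in source order. Outside some contiguous block
the two orders must agree, and inside it the target must split into a
prefix and a suffix that are each increasing in source order. Note
that this is strictly stronger than being a merge of two increasing
subsequences (the permutation `2 1 4 3` of `1 2 3 4` splits into two
increasing subsequences but is not reachable by one TDRL); the
implementation is therefore validated against a brute-force oracle
that enumerates every duplication block and every loss assignment,
exhaustively for up to six genes and on a thousand random ten-gene
instances. Circularity is handled by trying all rotations of both
orders. TDRL does not invert genes, so any strand disagreement is
infeasible by definition, with the offending genes named. Every
feasible result carries a witness (block, per-gene retained copy)
whose replay must reproduce the target exactly.

Pseudogene fragments are found by scanning a UR with each reference
gene on both strands (match +1, mismatch −1, gap −2 per position).
Decayed duplicates are recognizable against the genome's *own* intact
paralogue — not against a 40%-diverged orthologue from the other
lineage — so the pipeline scans each genome's URs with that genome's
gene set. The default score threshold of 16 is calibrated by
simulation: composition-matched random 300-bp URs produce a hit in
under 5% of scans, while fragments with 15% simulated decay are still
detected reliably.

The tandem-repeat scanner compares the sequence with itself at every
candidate period (50–500 bp by default), merges windows whose
match fraction reaches the identity threshold (0.8) into maximal
regions, and reports the smallest period when harmonics describe the
same region. Planted-repeat unit lengths are recovered within 10%.

## Transmission-pattern classification

Trees are built by neighbor joining (`ape::nj()` behind
`neighbor_joining()`, with negative branch lengths clamped to zero
with a warning) from pairwise distances of the concatenated
protein-coding supermatrix (*atp8* excluded as too variable to align
reliably; genes truncated to the shortest copy, which removes the M
*cox2* extension). At ~40% divergence raw p-distances saturate and
lose additivity, so tree building uses Jukes–Cantor-corrected
distances (`p_distance_matrix(..., correction = "jukes_cantor")`).

Classification is purely topological, since the pattern definitions
are topological: *gender-joining* iff some edge bipartition separates
all M tips from all F and H tips (H molecules are F-derived and group
with F); *taxon-joining* iff each species' F and M tips form a cherry.
The bipartition test runs first, so the (degenerate) trees satisfying
both are called gender-joining. The cherry criterion is this package's
operationalization of "clustering by species", which the literature
leaves informal; the classifier's evidence string names the separating
edge or the violating species. Branch lengths and support values are
ignored throughout.

## The simulator and what it does (not) show

`sim_config()` holds the study conditions as defaults: circular
genomes of about 16–17 kb carrying the standard 37 genes in a fixed
synthetic gene order (an F-like template with a large
control-region-like UR immediately upstream of *cox1*), AT content
65%, intraspecific F–M divergence 0.40 with dN/dS 0.33, a 501-bp
in-frame 3' extension of the M *cox2*, M-orf between *nad4L* and
tRNA-Asp (second M-orf between tRNA-Asp and *atp8* in one species),
F-orf upstream of *nad2*, one TDRL of the tRNA-Asp–*atp8*–*nad6*
block with 15% pseudogene decay, and a 320-bp tandem repeat in three
copies with 5% per-copy decay. The `mini` scale shrinks gene lengths
(≈6 kb total) for fast tests without changing any of the biology.

Sequence evolution is a seeded single-nucleotide substitution process:
transition/transversion proposal ratio 2, no indels (so orthologous
genes stay aligned by construction), stop-creating proposals rejected,
start/stop codons immutable. dN/dS is controlled by accept/reject:
nonsynonymous proposals are accepted with probability `min(1, a)` and
synonymous ones with `min(1, 1/a)`, where `a` is computed from the
ancestor so that the realized rate ratio per Nei–Gojobori site equals
the target under the kappa-weighted proposal process. The recovery
property — estimated omega within 0.1 of targets 0.1, 0.33 and 1.0 on
a 10,000-codon gene — is tested at p = 0.25; at substantially higher
divergence the synonymous proportion approaches the Jukes–Cantor
singularity for small omega and the estimate (like any counting
estimate) degrades.

Branch targets compose through the Jukes–Cantor model: to realize an
intraspecific F–M p-distance of 0.40 with 0.03 tip branches, the M
stem is evolved to `p(jc(0.40) - 2 jc(0.03))`. Under the
gender-joining truth the M lineage diverges once at the root; under
the taxon-joining truth each species' M derives independently from
that species' F. Taxon-joining is simulated at divergence 0.20: the
pattern arises in nature from recent masculinization and is therefore
shallow, and at 0.40 the two independently evolved M lineages converge
(the same constrained sites saturate in both) until no distance method
can see the species-wise pairing — a genuine identifiability limit,
not an implementation artifact.

What passing tests show: every algorithm agrees with an independent
brute-force oracle on its domain, and every planted signal (ORF
inventory, TDRL witness, repeat, fragment, pattern) is recovered
end-to-end through GenBank round trips. What they do not show: the
generator has no indels, no rate heterogeneity, no composition bias in
the substitution process (the ancestor's 65% AT drifts toward ~60%
over a 0.4-divergence branch), no realistic tRNA/rRNA structure, and
chance ORFs in random URs are genuine ORFs — so absolute ORF counts on
real data depend on real UR composition and are not predicted by the
simulator.

## Numerical choices and degenerate inputs

* Codon columns containing a gap or `N` in either sequence are dropped
  before Nei–Gojobori counting; an alignment reduced to zero codons
  yields `NaN` proportions rather than an error.
* `rscu()` gives an unused codon family RSCU 0 for all members and
  lists the family in an attribute.
* `combine_masks()` with `k` above the number of masks keeps nothing,
  with a warning; length mismatches are errors.
* `find_orfs()` on a UR shorter than 33 nt returns an empty frame.
* The repeat scanner reports the smallest period on harmonic ties and
  discards candidates overlapping a kept call by more than half.
* `tdrl_feasible()` between identical orders is feasible with an
  empty-block witness.
* All simulator entry points take a seed and restore the caller's RNG
  state; identical configurations produce byte-identical files.

## Problem sizes

The shipped test suite simulates at the `mini` scale (≈6 kb genomes,
five genomes per study) and runs in a few minutes; exhaustive oracles
cover all sense-codon pairs, all permutations of up to six genes, and
all unrooted 4–6-taxon topologies. The acceptance script runs the full
pipeline at the default study scale (≈17 kb genomes) in well under a
minute. These sizes are the package's own validation design; all
thresholds above are stated once here and used unchanged everywhere.
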