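---
title: "Methods: comparative plastome structure and gene-loss analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome structure and gene-loss analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
```

This vignette is the package's own account of its methods: the models
and procedures each stage implements, the tunable parameters and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and the numerical choices made where the design
was genuinely open.

## The quadripartite model and IR detection

A plastome is modelled as a circular string over {A,C,G,T,N} carrying a
quadripartite partition LSC | IRa | SSC | IRb with IRb the reverse
complement of IRa up to a small number of mismatches. The partition is
valid only if the four arcs tile the circle exactly, the arms have equal
length, and LSC ≥ SSC; the composition identity
`LSC + SSC + 2·IR = genome length` is checked for every structure and
every published component table the package summarises. Published tables
occasionally violate the identity by a few bp; `summarize_structures()`
therefore warns and flags rather than errors.

**Sequence-based detection.** `find_inverted_repeat()` seeks the
maximal-length pair of disjoint arcs such that one arc equals the
reverse complement of the other with at most `max_mismatch_frac × len`
mismatches. The search anchors exact 21-mers shared between the doubled
sequence and its reverse complement (doubling makes arcs that wrap the
origin visible), then scans every anchored anti-diagonal for the longest
window within the mismatch budget. For `min_len ≥ 50` and a mismatch
fraction ≤ 0.02 any qualifying repeat must contain an exact 21-mer
(pigeonhole over the mismatch positions), so the anchored search finds
exactly what an exhaustive scan over all anti-diagonals finds; the test
suite asserts this equivalence against a brute-force oracle on random
sequences up to 2 kb. Ties on length resolve to the pair whose first arc
starts at the smallest coordinate. K-mers occurring more than 16 times
are dropped from anchoring to bound the join on low-complexity input.

Two defaults deserve comment. The arm mismatch tolerance is 0.5%
(`max_mismatch_frac = 0.005`): real arms are homogenised by gene
conversion and are "virtually identical", but no published threshold
exists, so a small non-zero budget absorbs assembly noise. Because the
reported pair is *maximal under the budget*, arms can over-extend past
the biological junction by roughly `budget / 0.75` bp of random flank
(~0.7% of the arm length); every downstream step that depends on
junctions (gene region assignment, expansion attribution) uses
majority-overlap and gene-anchor rules precisely so that this bounded
jitter is immaterial. With a budget of 0 detection is exact, which the
simulator tests exploit.

**Coverage-based detection.** Reads from the two identical arms pile on
either copy, so the repeat shows ~2× the single-copy depth.
`detect_ir_from_coverage()` smooths the per-base track with a centred
rolling median (`window`, default 200 bp — long enough to flatten
Poisson noise at typical 40× depth, short enough to resolve junctions),
normalises by the genome-wide median depth, and reports maximal runs
with a ratio in `[1.7, 2.5]`. The band is deliberately generous because
"approximately two times" has no published quantification. The method
assumes the single-copy regions hold the majority of positions, so that
the genome-wide median tracks the single-copy depth; in genomes whose
repeat approaches half the sequence (heavily expanded plastomes) the
median drifts between the two depth modes and the ratio band can miss.
The package tests the detector on unexpanded quadripartite proportions,
where the assumption holds; on heavily expanded genomes the
sequence-based detector is authoritative. An all-zero track is an error
("no coverage"), a uniform track returns no calls, and runs shorter
than the window are discarded.

**Degenerate partitions.** If the two single-copy arcs tie in length the
LSC label goes to the arc containing coordinate 0, with a warning —
an arbitrary but deterministic rule. A genome with no qualifying pair
returns a distinct "not found" result rather than an error, since
losing one repeat copy is a real biological outcome.

## Expansion mapping against the outgroup

Homology is by gene name, not sequence alignment: the analysis reasons
gene-wise, all species share an annotation vocabulary, and whole-genome
alignment is out of scope. A target gene inside the target repeat whose
outgroup namesake is LSC-resident (resp. SSC-resident) counts as
recruited from that region; genes already duplicated in the outgroup
repeat contribute nothing, because only originally single-copy genes
witness expansion.

Repeat bp are attributed on one arm. Runs of consecutively recruited
genes are bounded, at each edge, by the midpoint of the intergenic gap
between the outermost recruited gene and its nearest non-recruited
neighbour, clipped to the arm. The midpoint rule is symmetric and
deterministic; no published rule exists for attributing junction bp
between genes, and the midpoint makes the attribution error at each
edge at most half the intergenic gap — exactly the resolution the
simulator records in its truth ledger, and the tolerance the recovery
tests use. Recruited runs not adjacent to the junction facing their
source region are flagged `non_contiguous`: they are internally
relocated blocks, reported gene-wise rather than given a separate bp
class, because bp attribution for a relocated block is ambiguous.
The raw arm-length difference versus the outgroup is reported separately
(`ir_len_diff`) and is *not* forced to equal the from-LSC + from-SSC
total: the two quantities measure different things and published tables
disagree between them for some species.

## Pseudogene calling

Each target coding sequence is aligned globally to the outgroup copy
under affine gaps (match +2, mismatch −3, gap open −8, gap extend −2;
a gap of length L costs `−8 − 2L`). The scoring favours a compact
mutation model: one substitution (−3 vs +2) is much cheaper than a gap
(−10), so isolated planted edits align as planted. The implementation is
a compiled Gotoh three-state dynamic program with fully deterministic
tie-breaking: mismatch preferred over gap, gap-in-target preferred over
gap-in-reference, and equal-scoring gaps placed leftmost (the standard
normalisation, so a deletion inside a homopolymer always reports the
first equivalent position). Scores are checked against an independent
full-DP oracle in the tests. The pairwise-versus-outgroup design (rather
than a multiple alignment) makes "the same position" well-defined:
every mutation carries a reference-anchored nucleotide position, and
cross-species identity is decided on that anchor.

Frameshift scanning walks alignment columns maintaining the cumulative
net indel length d; each maximal indel run with length ≢ 0 (mod 3)
emits one FS anchored at the reference codon of the run start. The
frame is restored wherever d returns to 0 mod 3. Stop scanning
translates the *target in its own running frame*; any stop strictly
before the reference terminal stop is premature. A stop at a site where
d ≢ 0 (mod 3) is `frameshift_induced`: it still argues for
pseudogene status, but it is downstream fallout of the indel, not an
independent mutation, so induced stops are excluded from shared-event
matching. A stop aligned at or beyond the reference terminus is never
premature. Amino-acid positions are reported both reference-anchored
(`aa_ref`) and in the target's own codon numbering (`aa_target`),
because the two drift apart after indels and published positions follow
species-local numbering.

Status precedence is absent → partial → potential_pseudogene → intact.
A gene is `absent` below 20% reference coverage, `partial` when one
exon is essentially missing (< 20% exon coverage) while another is
essentially present (> 80%), and `potential_pseudogene` with one or
more frameshifts or premature stops. The 0.20/0.80 thresholds are
configuration defaults chosen to separate "exon deleted" from
"alignment ragged end" cleanly at these gene sizes; no published
criterion exists. Loss of the start codon is recorded nowhere as an
inactivating class — it is not part of the FS/SC model — and a gene
truncated only at its 3′ end is handled by the coverage thresholds.

## Shared events and Dollo placement

Mutations from all species against the one reference are grouped by
(gene, kind, reference position, exact change descriptor). Groups with
two or more species and byte-identical descriptors are `identical`
events — the operative definition of "the same mutation" is the
identical nucleotide change, not the amino-acid number, which drifts
with upstream indels. Mutations hitting the same reference codon with
different descriptors are `convergent_same_site`: independent events at
one amino-acid position. Exact-position identity is the default;
a codon-window relaxation exists in the grouping key (the convergent
class) but nothing looser, since widening identity would manufacture
shared ancestry.

Placement is Dollo: an event shared by a species set maps to the stem
branch of the set's MRCA; single-species events sit on their terminal
branch; an event whose set does not equal the subtree's full leaf set
is flagged inconsistent (homoplasy) and reported under the MRCA, never
silently split into multiple origins — the convergence classification
already happened upstream. The species tree is an input (Newick,
branches named by child nodes); tree inference is a different artifact.

## The synthetic-data generator

The simulator is the oracle for every stage: it builds an ancestral
quadripartite genome, evolves it along a named-branch tree, and records
everything it did in a truth ledger. Defaults are 1/10-scale regions
(LSC 8,000 bp, SSC 1,800 bp, IR 2,600 bp — the canonical 85/18/26 kb
proportions scaled so the full pipeline runs in seconds), 25 genes in
the field's three classes distributed over all three region classes
(including a two-exon gene and the junction-flanking gene block), a
Jukes–Cantor-type substitution probability of 0.01 per site per branch,
and a six-leaf tree with a five-event schedule emulating the study
design: a shared LSC-side expansion in the parasite clade, an SSC-side
expansion recruiting `ycf1` in the obligate clade, a shared 1-bp
frameshift on the sister-pair stem, a terminal stop-gain, and a
terminal exon loss. Scale, roster, tree, events and rates are all
configurable; region lengths that cannot hold their genes raise an
"infeasible packing" error.

Three deliberate idealisations keep the ledger a *complete* mutation
inventory, which is what a parameter-recovery oracle needs:

* The repeat is evolved as a single arm and re-duplicated at assembly —
  concerted evolution taken to its limit, so arm mismatch stays 0 and
  detection tolerances are not consumed by simulated drift.
* Random substitutions are rejection-sampled so they never create or
  destroy a stop codon in any gene's reference frame, never touch start
  or terminal codons, and never fall within ±6 nt of an engineered
  mutation site (in any lineage). Without the window, a chance
  substitution beside a planted indel could change which equivalent gap
  placement is optimal and shift the reported position by a base.
* Planted indel positions are left-normalised with the same
  slide-left string rule the aligner's tie-break realises, so ledger
  positions and recovered positions are comparable exactly.

Boundary shifts snap to the midpoint of the nearest intergenic gap
(genes are never split), and the ledger records half the gap width at
each engineered junction as the anchor resolution — the exact tolerance
recovery can achieve under gene-anchored attribution. The four bases
adjacent to the planted arm junctions are chosen non-complementary to
their pairing partners so the planted arms are exactly maximal and
zero-budget detection recovers them bit-for-bit. Coverage tracks draw
per-base depths from Poisson(base depth) in single-copy regions and
Poisson(2× base depth) in the arms, with base depth 40× by default.

What the simulator does **not** emulate — and hence what green tests do
not certify about real data: realistic indel length spectra, partial
gene conversion between arms, SSC orientation flipping (real plastomes
carry both orientations at ~50:50), rate heterogeneity across sites and
branches, annotation error, and assembly artefacts. The simulator
validates the detection logic, not evolutionary realism.

## Problem sizes and determinism

The test suite runs the pipeline end-to-end on twenty replicate
six-leaf simulations at 1/10 scale, compares the repeat finder with a
brute-force oracle on a hundred random sequences up to 2 kb, the
aligner with an exhaustive DP oracle on fifty pairs up to 60 nt, scans
a planted-indel grid of lengths 1–6 across codons 2–50, and checks
coverage recovery on twenty Poisson tracks — sizes chosen so the whole
suite completes in a few minutes on one CPU while every stage is
exercised at full fidelity. All simulation outputs are pure functions
of the configuration seed; the pipeline itself is deterministic, and
rerunning it on the same inputs reproduces every report byte for byte.

## Known limitations

* Homology by gene name assumes consistent annotation vocabularies;
  diverged or renamed annotations would need reconciliation first.
* The coverage detector's median baseline assumes single-copy majority
  (see above).
* The maximal-under-budget repeat definition over-extends junctions by
  a bounded amount when the mismatch budget is non-zero; junction-exact
  boundaries require a zero budget or downstream anchor-based rules
  (both provided).
* Orientation isomers of the SSC are not resolved; the reported SSC
  strand is whatever the assembly presents.
* The Dollo model never re-splits inconsistent events; genuinely
  recurrent mutations appear as flagged homoplasy, by design.
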