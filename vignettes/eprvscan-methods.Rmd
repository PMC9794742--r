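---
title: "Mining genome assemblies for recent endogenous pararetroviruses: methods and design"
author: "eprvscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining genome assemblies for recent endogenous pararetroviruses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Endogenous pararetroviruses (EPRVs) are copies of plant dsDNA
reverse-transcribing viruses (family *Caulimoviridae*) integrated into
host nuclear genomes.  Integration is not part of the viral replication
cycle, so once inserted a copy evolves as host DNA: it accumulates point
mutations, stops, frameshifts and rearrangements.  This has a useful
consequence for paleovirology: a copy whose reverse-transcriptase (RT)
domain is still long, uninterrupted and well conserved was almost
certainly inserted *recently*, and groups of 100% identical copies in
one genome indicate amplification after insertion.

`eprvscan` implements the complete discovery-and-classification pipeline
for such recent insertions: a translated homology search of genome
assemblies with a library of labelled RT domains, screening down to
intact non-redundant Caulimoviridae-class loci, identity clustering,
distance-based classification into operational taxonomic units (OTUs),
minimum insertion-age inference from host divergence times, and
annotation of element architecture (including the diagnostic rule for
the Wendovirus-like four-ORF organisation with two aspartic
proteinases).  Because no practical gold standard exists for real
assemblies, the package ships a first-class synthetic-genome simulator
whose planted-element ledger lets every stage be scored against known
truth.

## The search model

The search is a self-contained tBLASTn surrogate.  Each contig is
translated in all six frames (codons containing `N` become `X`, stops
become `*`); each frame translation is cut at stop codons into stop-free
segments, and query/segment pairs are aligned locally
(Smith--Waterman via `Biostrings::pairwiseAlignment`) under BLOSUM62
with gap open 11 / extend 1 -- the tBLASTn defaults, which the source
analysis used unchanged.  Segments shorter than `min_seg_aa` (default
60 aa) are skipped: genuine hits must eventually exceed 300 aa, while a
stop-free run of 60 codons is already rare in random translation.  A
cheap exact 4-mer seed pre-filter decides which query/segment pairs are
aligned at all; `exhaustive = TRUE` disables it, and the test suite
verifies that the seeded engine and a quadratic dynamic-programming
oracle agree on the optimal scores of small instances.

E-values use Karlin--Altschul statistics with the published gapped
BLOSUM62 parameters (lambda = 0.267, K = 0.041) and search space
*m* x *n* = query length x total translated length.  We do not claim
agreement with NCBI's edge-corrected E-values; the quantity only plays
its functional role of a stringent hit threshold (default 1e-10).
Alignments are strictly single-frame: a frameshifted element can only
appear as two partial hits, which is exactly what the downstream
intactness screen is designed to reject.

## Screening rules

Three rules, applied in a fixed order:

1. **Intactness** (`filter_intact`): the genomic peptide must be at
   least 300 aa, contain no stop, and the alignment must carry no gap
   in either row within a single frame (the operational reading of
   "no frameshifts").
2. **Proximity dedup** (`dedup_proximity`): hits less than 1500 bp
   apart (strict inter-interval gap, strand-agnostic) are chained
   transitively; each chain keeps its best bit score (ties: leftmost).
   This collapses tandem/nested arrays of any size to one
   representative, and guarantees no two survivors are closer than the
   window.
3. **Lineage triage** (`triage_lineage`): each surviving peptide is
   scored by global alignment against every library reference; hits
   closer to Ty3/Gypsy retroelement references than to Caulimoviridae
   are removed.  An exact inter-class tie falls back to the higher
   summed top-3 score per class -- a documented tie-break chosen for
   determinism, since nothing in the selection logic otherwise orders
   exact ties.

The composition is idempotent, which the tests assert directly.

## Clustering and amplification

`greedy_cluster` reimplements CD-HIT's greedy incremental semantics
exactly rather than delegating to the binary: sequences sorted by
decreasing length (ties lexicographic), each sequence joins the first
cluster whose *representative* it matches at or above the threshold,
identity being identical aligned positions divided by the length of the
shorter sequence over a global alignment.  CD-HIT's word-filter
acceleration (bandwidth, length-skip) is a heuristic for scale we do
not need at these problem sizes; every comparison here is an exact
alignment.  Thresholds 0.60 and 1.00 reproduce the cluster60/cluster100
analyses; at 1.00 the tests check equivalence with plain string-equality
grouping.  `find_amplification` clusters per genome at 1.00 and reports
only clusters of at least 10 copies -- the deliberately restrictive
criterion for very recent amplification.

## Classification, trees and ages

Distances are Poisson-corrected amino-acid distances,
d = -ln(1 - p), with p the mismatch fraction over gap-free columns of a
pairwise global alignment; p >= 0.95 is clamped with a warning.  The
correction matters little at the low divergences of interest but keeps
deeper reference-to-candidate distances roughly additive.  Trees are
standard Saitou--Nei neighbor joining (`ape::nj`; negative edges clamped
to zero); bootstrap support resamples columns of a reference-anchored
alignment (every sequence projected onto the longest), and externally
computed alignments can be supplied instead.  The anchored alignment is
a deliberate simplification: it drops insertions relative to the
anchor, which is adequate for well-conserved RT domains but would be
lossy for highly gapped families.

OTU assignment defaults to nearest reference: the candidate takes the
OTU of the reference at minimal distance, with support margin
(d2 - d1)/d2 between the two best distinct-OTU distances, and falls
back to `unclassified` beyond a distance ceiling (default 1.0, about
63% observed mismatch -- far beyond anything a genuine Caulimoviridae RT
shows against the library).  A clade-based method (smallest OTU-pure
enclosing clade on the NJ tree) is provided as an alternative; nearest
reference is the default because it is deterministic, cheap, and
exactly recovers the planted labels in simulation.

The minimum insertion age of a cluster is the divergence time of its
most distantly related pair of host taxa, looked up in a local
divergence-time table (genus rank preferred, since published maximum
ages are quoted between genera); a single-taxon cluster has age 0, the
first maximizing pair in sorted order is reported, and pairs missing
from the table are surfaced as a condition -- never silently treated as
zero.

## Element architecture and the Wendovirus rule

`find_orfs` scans the three forward frames (elements are oriented with
the RT forward) for ATG-initiated ORFs of at least 100 aa, first ATG
after each stop, stop codon included in the interval -- the conventions
of a standard ORF finder.  Domain presence uses packaged
position-constrained motifs: fixed-width patterns whose matches are
scored by BLOSUM62 similarity to the motif consensus with a per-motif
threshold at ~70% of the consensus self-score.  These are deliberate
surrogates for profile HMMs: they assert presence and order of the six
diagnostic domains (zinc finger, movement protein, two aspartic
proteinase families, RT, RNase H), not calibrated homology scores, and
the two proteinase patterns are treated interchangeably in the
architecture rule for that reason.

An element is `wendovirus_like` iff it has >= 4 ORFs, a
zinc-finger-bearing ORF, an ORF with movement protein plus a
proteinase, a distinct downstream ORF with proteinase followed by RT
then RNase H, and at least two proteinase-bearing ORFs overall.
Elements with the full domain repertoire in a different arrangement
(e.g. the RT ORF split in two) are `unresolved` rather than forced into
either call.  `simulate_wendovirus_element` builds a ~7.7 kb positive
control with four genuinely overlapping ORFs: consecutive ORFs share an
11 bp junction cassette that reads stop in the upstream frame and
start in the downstream frame.

## The simulator and what passing means

The generator's defaults are the package's reference validation
conditions: 2 Mb of i.i.d. background at GC 0.36 over 5 contigs with a
light sprinkling of N runs, a simulated reference library (star
phylogeny: OTU ancestors ~30% diverged from a common root, members ~10%
from their ancestor, retroelement decoy families ~45% from the root,
with the RT catalytic box held invariant), and implants comprising 20
intact dispersed copies at 0--10% divergence, 10 internal-stop copies,
10 frameshifted copies, 10 decoys, one 12-copy identical burst and one
5-copy tandem array with 200 bp gaps.  Divergences are realised by
exact-count codon substitution (never creating stops), so targets are
met to within 1/n.  Dispersed implants keep a 2 kb exclusion zone so
that the 1500 bp dedup rule can only ever merge the *tandem* array.
Frameshift deletions are placed in the middle 60% of the element: both
in-frame pieces then stay <= ~256 aa, so the class is guaranteed to
fail the 300-aa intactness criterion even allowing for short
chance read-through extensions of a local alignment (at the 80% band
the larger piece can reach ~288 aa, and we observed occasional
extensions crossing 300 aa).

Passing the recovery suite on this simulator shows the pipeline's
selection logic is correct under its own assumptions.  It does not show
performance on real assemblies: real host DNA is repetitive and
structured, real EPRVs fragment and nest in ways richer than our two
degeneration modes, real Ty3/Gypsy elements are a diverse superfamily
rather than diverged copies of one root, and codon usage is not
uniform.  Those factors affect sensitivity in the field, not the
correctness of the rules tested here.

## Numerical and design choices

* Alignment parameters are fixed package-wide (BLOSUM62, 11/1) so
  search, triage, clustering and distances are mutually consistent.
* Greedy clustering ties (equal lengths) break lexicographically by id;
  dedup ties by leftmost locus; triage inter-class ties by summed top-3
  scores -- all chosen for determinism and stated in the docs.
* The pipeline run id is derived from the seed only, so identical
  configurations give byte-identical tabular outputs.
* Problem sizes in the tests (2 Mb scenario, 100-replicate bootstraps,
  oracle instances of <= 60 aa x 2 kb, enumeration oracles at n <= 6--8)
  are the package's chosen desk-scale validation sizes; they keep the
  whole suite in the minutes range while still exercising every rule.
* Default probes are one reference per Caulimoviridae OTU
  (`queries_per_otu = 1`), mirroring the representative-probe strategy
  of the source analysis; the probe set is configurable because no
  definitive list is fixed by the method itself.

## Known limitations

* The anchored multiple alignment underestimates alignment uncertainty
  for gappy or highly diverged sets; import an external MSA for serious
  bootstrap work.
* E-values are uncorrected Karlin--Altschul estimates.
* Degenerate-element recovery is out of scope by design: the method
  deliberately targets recent, intact copies, and old fragmented EPRVs
  are invisible to it.
* The published per-genus totals of the transcribed cluster60 table are
  internally inconsistent for three genera; the consistency checker
  reports both numbers and takes no side.
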