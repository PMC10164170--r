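---
title: "Detecting non-reference ERV-LTR insertions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting non-reference ERV-LTR insertions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrscout)
```

## The problem

Endogenous retroviruses (ERVs) are remnants of germline retroviral
integrations. Most detectable young ERV remnants are solo long terminal
repeats (LTRs) left behind by recombination, and many of them are
*non-reference*: carried by some individuals but absent from the species'
reference assembly. Because integration duplicates 4-8 bp of host sequence
on both sides of the provirus (the target site duplication, TSD), a genuine
non-reference insertion leaves a precise, verifiable signature in short-read
data: read pairs that straddle the insertion map discordantly, mates that
fall inside the inserted LTR go unmapped (singletons), and reads crossing a
junction are soft-clipped there, with the 5'- and 3'-side junction reads
overlapping on the reference by exactly the TSD length.

`ltrscout` turns that signature into a reusable pipeline: read-pair
classification, anchor discovery against an LTR query library, breakpoint
clustering and filtering, automatic TSD detection, local contig assembly
with insertion-sequence deduction, classification by local alignment, and a
comparative layer (presence/absence matrices, Venn partitions,
binary-distance clustering, gene overlap with GO enrichment) plus per-locus
LTR sequence analysis (alignment, substitution counting, U3/R/U5
segmentation, EAV mosaic typing, K2P/NJ phylogenies).

Real studies of this kind start from tens of whole genomes at ~30x
coverage. Those inputs are far beyond what a package check should download
or process, so the package carries a first-class cohort simulator that
generates every input the pipeline consumes, together with machine-readable
truth. Every claim the test suite makes is a claim about this synthetic
cohort.

## The cohort simulator

`simulate_cohort()` builds an insertion-free random reference (uniform
i.i.d. bases), places germline insertion events on the branches of a
user-supplied species tree, and splices each event into the genomes of all
individuals below that branch. The default tree,
`(((red,gray),ceylon),green);`, mirrors the four-species junglefowl design:
one red-junglefowl-like ingroup, two successively deeper relatives, and a
basal outgroup. Branches include a root stem, so some loci are fixed in the
whole cohort.

Coordinate convention: an event at 0-based reference position `p` with TSD
length `L` duplicates the reference slice `[p-L, p)`; the carrier genome is
`ref[0,p) + LTR + TSD + ref[p,...)`. The same convention is used by the
truth tables and (implicitly) by the detector, which reports the TSD as a
reference interval - a representation that is convention-free.

Key defaults and why:

* **read length 100 bp, ~30x coverage** - the sequencing design the
  pipeline targets;
* **fragment length ~ Normal(400, 40)**, truncated below at the read length
  and above at mean + 4 sd - a minimal Illumina-like model; the upper
  truncation bounds how far discordant evidence can scatter, which in turn
  bounds the anchor clustering window;
* **TSD length uniform on 4-8 bp** - the biologically observed range for
  these elements;
* **minimum spacing 4 x fragment mean between planted elements** - keeps the
  evidence clusters of neighbouring loci disjoint; the generator refuses
  configurations it cannot place;
* **insertion rate: 10 events per branch** in the study-scale configuration;
  real per-branch rates are unknown, so this is a free parameter chosen to
  give every branch enough loci for tree reconstruction, not an estimate;
* **reference-resident decoys** (default 2 per chromosome): LTR copies
  planted directly into the reference background, carried by everyone and
  invisible to the discordant-read signal; they exist to exercise the
  200 bp flank-exclusion stage;
* **per-base substitution error rate, default 0** - the acceptance checks
  run error-free by design (they test the logic, not robustness); the error
  model is exercised separately.

`emit_truth_alignments()` projects simulated reads onto the reference
through the insertion map rather than running an aligner. One modelling
choice matters: a read crossing the 3' junction carries a copy of the TSD
immediately before downstream reference sequence, and a real aligner will
extend its alignment leftwards through that TSD copy. The projector
reproduces this, which is exactly what creates the 1-10 bp overlap between
left- and right-clipped junction reads that the TSD detector measures.
Mates that fall entirely inside an insertion are emitted unmapped (the
singleton path) rather than being assigned to the library, and mapped
stretches shorter than 20 bp are also emitted unmapped, since no aligner
would place them confidently.

What the simulator deliberately does not model: SNP/indel background
variation between individuals, base-quality profiles, GC or mappability
bias, repetitive reference context, and somatic insertions. Passing tests
therefore demonstrate the pipeline's logic under clean mapping signatures;
they do not demonstrate robustness to the repeat-rich regions where real
ERVs accumulate, and real-data use would reintroduce an aligner (e.g.
BWA-MEM) upstream.

## Detection

**Pair taxonomy.** Each pair is assigned exactly one of five classes, with
precedence `unmapped_pair > singleton > split > proper > discordant`. A
pair is proper when both mates map on opposite strands with an inferred
insert inside limits estimated as mean +/- 4 sd from a sample of
proper-orientation pairs (the data themselves define "expected"); a split
pair carries a soft-clip of at least 10 bp.

**Anchors.** For each non-proper pair the free end - the unmapped mate, the
distant mate, or the clipped tail - is matched against the LTR library by
exact 15-mer seeding plus ungapped extension at >= 90% identity, on both
strands. The anchor's side records its orientation relative to the
insertion: forward-strand anchors and right-clips face it from 5', the
mirror cases from 3'. Anchors require mapping quality >= 20; the identity
and seed length are exposed parameters, as no published threshold exists
for this matching step.

**Calls.** Anchors within one clustering window (default: the fragment
mean) form a call. Split junctions take priority for the position: the
midpoint between the rightmost 5'-side junction and the leftmost 3'-side
junction, which differ by the TSD length at a true locus - hence reported
positions sit ~L/2 bp to the left of the splice point, within the +-5 bp
tolerance used throughout. Per-call evidence is capped at 10,000 reads.

**Confidence ladder.** Support filtering uses two thresholds: at least 10
supporting reads, and a confidence level of at least 7 on an eight-rung
ladder (one rung each for two-sided evidence, >= 3 reads per side, >= 10
total, single library family, consistent two-sided geometry, any split
read, and split reads on both sides). The ladder is a documented surrogate
for an opaque per-call level scheme in the tooling this pipeline emulates:
it preserves the semantics that the passing threshold demands two-sided
evidence with split support, reaches its maximum only with splits on both
sides, and is monotone in every evidence count. Calls within 500 bp of a
stronger passing call are merged away (keep-best rather than discard-both:
discarding both sides of a duplicate pair would delete true loci).

**TSD detection.** Let `R5` be the rightmost reference coordinate reached
by right-clipped junction reads near the call and `L3` the leftmost start
of left-clipped junction reads; the TSD is `[L3, R5)` when the overlap is
1-10 bp. A blunt junction (overlap 0) yields no TSD: the quoted working
definition of these events requires a strictly positive overlap, and a
zero-length "duplication" would be indistinguishable from a clean break.

## Assembly, deduction, classification

Reads mapped within 150 bp of the TSD (plus their mates) feed a greedy
overlap-layout-consensus assembler: repeatedly merge the pair of contigs
with the best suffix-prefix overlap (>= 30 bp at >= 95% identity, both
orientations), consensus by majority read count, ties broken by
lexicographic read id so the result is independent of input order.
Candidate overlap lengths come from exact 12-mer seeds taken from the first
24 bases of the incoming contig; at the identity levels involved a true
overlap cannot evade both seed windows. For desk-scale read sets (tens of
reads per locus; the pipeline subsamples to 60, keeping clipped and
unmapped records preferentially) greedy OLC is adequate and dependency-free.

The inserted sequence is deduced from the contig by locating the TSD at
both junctions; when the TSD is shorter than 6 bp it anchors poorly, so the
6 bp reference flanks immediately 5' and 3' of it are used as delimiters
instead and the TSD copies are stripped from the delimited region. A
delimiter occurring more often than expected makes the locus ambiguous and
deduction returns nothing (with a warning) rather than guessing. This is a
real, accepted cost: a 6 bp word recurs in a ~650 bp contig often enough
that roughly 10-15% of loci are abandoned as ambiguous; the acceptance
metrics therefore report the deduction *yield* separately from the
byte-identity of what is deduced, which is 100% on error-free data.

Classification aligns the contig (or deduced insertion) locally against
every library entry on both strands - Smith-Waterman scoring +1/-2 with gap
open 5 / extend 2 - and converts scores to an e-value-like quantity
`E = K m n exp(-lambda S)` with the exact ungapped Karlin-Altschul lambda
for this scoring and a fixed `K = 0.1`. The statistic is used only to rank
entries ("lowest e-value wins") and as a single tunable threshold
(default 1e-5); it is not calibrated against any external database
statistic. The 200 bp reference flanks of every breakpoint are classified
the same way; a hit on either side marks the locus as explained by a
reference-resident ERV and excludes it.

## Comparative layer

Per-individual pass calls are merged across the cohort with the same
500 bp single-linkage rule used within a genome (the cross-individual
application is the natural extension needed for cohort comparison; merging
happens first, group assignment second). The resulting 0/1 matrix feeds:

* `venn_counts()` - disjoint presence cells over up to 6 groups;
* `binary_distance()` - Jaccard similarity `s` on carried-locus sets with
  the classical `sqrt(1 - s)` transform by default (the first method of the
  standard binary-distance families; plain `1 - s` is available);
* `hierarchical_tree()` - agglomerative clustering, average linkage by
  default (the common choice for presence/absence element data; complete
  and single linkage are exposed);
* `annotate_gene_overlap()` - genes whose span (+-5 kb by default; "near a
  gene" has no canonical width, so the window is a parameter) contains the
  locus point;
* `go_enrichment()` - upper-tail hypergeometric tests per term with
  Benjamini-Hochberg adjustment, no GO-graph propagation.

## LTR sequence analysis

Per-locus copies are aligned with a progressive aligner (pairwise
Needleman-Wunsch distances -> UPGMA guide tree -> profile-profile merges
with sum-of-pairs scores; match +1, mismatch -1, linear gap -2).
Substitutions are counted as alignment columns containing two or more
distinct bases, ignoring gap-only differences.

U3/R/U5 segmentation globally aligns a query to an annotated prototype and
projects the prototype's boundary columns onto the query; insertions
sitting exactly on a boundary are assigned to the upstream region (a
tie-break that keeps the three intervals a partition). Segmentation
requires >= 60% alignment identity - below that the prototype is simply
wrong. EAV mosaic typing assigns each region to the prototype with the
highest identity, requiring >= 80% per region; the (U3, R+U5) type pair
maps to the four mosaic letters (I,I)->A, (I,II)->B, (II,II)->C,
(III,I)->D, and anything else - including a region below the gate - is
`novel`, by construction never a wrong letter. Both gates are package
decisions; no published values exist.

Sequence phylogenies use Kimura two-parameter distances,
`d = -ln((1-2P-Q) sqrt(1-2Q)) / 2`, over columns where both sequences have
bases, and canonical neighbor joining with labels pre-sorted for
deterministic tie-breaks and negative branch lengths clamped to zero. NJ on
K2P replaces a maximum-likelihood tree search deliberately: it is exact,
fast, dependency-free and deterministic at package-check scale, and for the
near-clonal within-locus divergences involved the two approaches agree on
topology; the API accepts any distance matrix, so a likelihood backend can
be substituted.

One numerical choice deserves mention: pairwise global alignments between
equal-length sequences take a gap-free fast path when the ungapped identity
is >= 90% (where gap-free is provably optimal under this scoring) or
<= 40% (far below every decision gate, where only the identity value is
consumed); the 40-90% band always runs the exact dynamic program.

## Problem sizes and determinism

The study-scale configuration used by the acceptance checks is 2
chromosomes x 70 kb, 7 branches x 10 insertions (70 loci), 4 decoys, 4
individuals at 30x - about 90,000 reads in total. These sizes were chosen
so that every locus has dozens of supporting reads (the regime the
thresholds target) while a full end-to-end run remains a few minutes of
desk-scale compute. All randomness flows from a single integer seed per
run; the simulator, assembler, aligner and tree builders are deterministic
given their inputs.

## Known limitations

* Truth alignments substitute for a real aligner; mapping artefacts
  (mismapping in repeats, chimeric alignments) are out of scope.
* The caller detects presence-in-sample only; reference-present,
  absent-in-sample deletions and genotype likelihoods are not modelled.
* Deduction abandons delimiter-ambiguous loci (~10-15% at these contig
  sizes) rather than guessing.
* The e-value statistic is a ranking device, not a calibrated significance
  measure.
* Short reads cannot reconstruct full-length proviruses; the pipeline
  targets solo-LTR-scale insertions.
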