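---
title: "Annotating germline IG and TCR loci with vdjgermline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating germline IG and TCR loci with vdjgermline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdjgermline)
```

## The problem

Immunoglobulin (IGH, IGK, IGL) and T cell receptor (TRA, TRB, TRG,
TRD) loci are arrays of V, D and J gene segments interleaved with
regulatory elements. Annotating them in a genome assembly requires
locating the locus, placing every known or novel segment, judging
whether each segment could participate in expression and V(D)J
rearrangement, and characterizing the recombination signal sequences
(RSS) and germline CDR1/CDR2. This vignette documents the models,
parameters and design choices behind each step, and what the packaged
synthetic validation does and does not demonstrate.

## Locus extraction

Each locus is delimited by two conserved flanking genes supplied as a
`region_spec`. Anchors are placed by the same seed-and-extend aligner
used for segments, with a minimum identity of 0.85 — low enough to
tolerate cross-species divergence of conserved genes, high enough to
reject paralogues. Two decisions were genuinely open:

* **Anchor-inclusive boundaries.** The reported region spans the outer
  edges of the two anchors. Terminal J or V segments often sit within
  a few hundred bp of an anchor; inclusive boundaries guarantee they
  are never clipped. The cost — a few extra kb of non-receptor
  sequence — is harmless.
* **Multiple placements.** Segmental duplications can place an anchor
  more than once. We pair the highest-identity placements that lie on
  one contig, in a consistent orientation, within `max_region_length`
  (default 5 Mb).

Minus-strand loci are reverse-complemented into locus-forward
orientation, so downstream coordinates are orientation-invariant: a
region extracted from an assembly and from its reverse complement is
byte-identical (this is tested).

Fragmented loci can be scaffolded against a reference region:
each contig is anchored by its exact unique shared k-mers (k = 21),
ordered by the median reference position of those anchors, oriented by
majority anchor strand, and joined with 100 N characters. Contigs
without unique anchors are excluded with a warning. Scaffolded regions
are flagged, since a scaffold cannot prove segment content between its
joins.

## Segment placement and allele calling

Placement is seeded by exact 11-mers (non-overlapping across the
query, plus the final window) and extended by an affine-gap
query-global alignment of the whole allele against a padded local
window (match +1, mismatch −1, gap open −2, extend −1; window padding
capped at 0.2 × allele length and tightened by the observed seed
diagonal spread). These scores mimic megablast-like behaviour on
high-identity germline alleles. Identity thresholds are 0.90 for V/J
and 0.94 for D with a minimum aligned length of 8 bp: D segments are
short enough that a single mismatch is usually decisive, and at these
thresholds D records under 16 bp reduce to exhaustive exact search.
Hits truncated by a region edge are kept but flagged and excluded from
novelty calling.

Overlaps are resolved greedily by descending score, keeping a hit only
if it overlaps every already-kept hit by at most 10 bp; ties break by
identity, then length, then start, then allele name, so results are
reproducible to the byte. Greedy selection can differ from the
exhaustive-optimal compatible subset on adversarial inputs; the test
suite checks compatibility and maximality always, and agreement with
brute-force enumeration on a majority of random cases.

A placed segment identical to a library allele (exact string equality
after uppercasing, coding orientation) is that allele. Everything else
is novel, with provisional name `gene*x<hash8>` — the first eight hex
digits of an FNV-1a hash of the observed sequence. Content hashing
makes novel-allele names stable across samples, runs and platforms,
which is what makes cohort-level confirmation counting possible.
Novelty is library-relative by construction: re-annotating with a
library extended by a previously-novel sequence converts it to a known
call at identical coordinates.

## Functionality classification

Criteria are organised in two tiers; any failed pseudogene-tier
criterion gives *pseudogene*, otherwise any failed ORF-tier criterion
gives *ORF*, otherwise *functional*. The tier rule itself is a pure
function (`functionality_from_criteria`) and is tested exhaustively
against a truth-table oracle over all 2^9 combinations.

**V** (pseudogene tier): leader identified; length a multiple of 3;
start codon present; no in-frame stop in the spliced
L-PART1 + L-PART2 + V product; functional 3′ RSS. (ORF tier): donor
GT; acceptor AG; at least two cysteines in the V translation; and an
optional "stop codon at the end of the sequence" check. That last
criterion is ambiguous for a germline V, which does not normally end
in a stop; it ships disabled (`check_end_stop = FALSE`) behind a
configuration switch rather than guessing a semantics. "In-frame" is
evaluated on the spliced product in the ATG frame, following the
practice of evaluating the spliced ORF; the cysteine count is over the
V translation alone.

**Leader search**: 400 bp upstream (configurable), L-PART1 26–70 bp
and ATG-initiated, intron ≥ 60 bp bounded by GT..AG, L-PART2 8–13 bp
flush against the V start, L-PART1 + L-PART2 a multiple of 3. These
ranges are plausible genomic bounds; none is dictated by the
annotation model itself, so all are parameters. Among candidates the
fewest violated splice sub-criteria win, then the shortest intron,
then the ATG closest to the segment — a deterministic order.

**D**: functional iff both flanking RSS pass. **J**: no premature stop
in the motif frame, donor GT immediately 3′ of the segment, functional
5′ RSS (pseudogene tier); the [FW]G.G amino-acid motif (ORF tier).
Codons containing N count as neither stop nor cysteine and set a
contains-N note in the evidence.

## RSS models and refinement

An RSS is heptamer + spacer + nonamer with the heptamer abutting the
coding end; spacers follow the 12/23 rule, tabulated per
locus/class/side in `default_spacer_table()` (editable). V segments
carry a 3′ RSS, J a 5′ RSS, D both. Before any model exists the
heptamer is taken at offset 0 with the tabulated spacer length; once
models exist, offsets 0–3 bp and spacer lengths ±1 bp are scanned and
the best-scoring combination kept.

Heptamer and nonamer are modelled separately as position weight
matrices per (locus, class, side) stratum, trained on the segments
preliminarily classified functional with duplicate (allele, RSS)
combinations collapsed; strata with fewer than 3 training sequences
fall back to a pooled per-locus model, and if that is also too small
the RSS check is skipped with a `no-model` flag rather than failed.
Scores are log-odds in bits against a uniform background. P-values are
exact: full enumeration when `4^L <= 65536` (heptamers), otherwise a
discretized dynamic program over positions with bin width 0.001 bits.
The binned p-value is provably bracketed by the exact p-values at
thresholds shifted by ±L·bin, which is the tolerance the tests assert.
An RSS passes when both element p-values are at or below `rss_alpha`
(default 1e−3, configurable — scoring elements jointly or picking a
different threshold are reasonable alternatives we did not take) and
the spacer length is within tolerance.

Refinement is two-pass: classify with the RSS criterion held open,
train, re-extract and rescore, reclassify. Labels can only be demoted
by this step. On consistent data the second pass is a fixpoint — the
third pass reproduces it byte-for-byte (tested). D segments without
full RSS support, and all TRDD segments (whose short length makes
placement intrinsically unreliable), are flagged low-confidence.

## CDR1/CDR2

CDR coordinates are supplied as a sidecar TSV of reference alleles
(amino-acid sequence plus 0-based half-open CDR windows) rather than
fetched from a service, which keeps the package testable offline. The
V translation is globally aligned to the CDR-bearing reference of the
same gene (else the closest by amino-acid edit distance; conflicts
resolved deterministically), reference CDR columns are mapped through
the alignment, and the query window is back-projected to region
nucleotides. The transfer returns nothing when the V is frameshifted
or when gaps cover at least half a CDR. Summaries align the unique CDR
sequences per locus by sequence-to-profile progressive alignment with
a deterministic guide order (length, then sequence) — at CDR scale
(3–10 residues for CDR2) a full guide tree adds nothing.

## Cohort aggregation

Unique alleles are distinct observed sequences per class; novel
alleles are those absent from the library. Support for a novel
sequence counts distinct *individuals* (both haplotypes of one person
count once); confirmation sets are reported at thresholds 2 and 4,
reflecting the two confirmation stringencies relevant in practice
(lenient multi-individual support versus the stricter standard
appropriate for cell-line-derived assemblies). Zygosity calls an
individual homozygous at a locus iff both haplotypes carry identical
ordered allele content, and identical-haplotype groups use the same
order-sensitive key. Concordance between two annotation sets counts a
pair concordant when same-class intervals overlap by at least 1 bp,
matched greedily by overlap length, each annotation used at most once.

## The synthetic generator, and what the tests show

`generate_library` / `generate_locus` / `generate_cohort` invert the
annotation model into a generator with planted truth: anchors,
leaders, segments, RSS and inter-segment background are laid down
explicitly, and every supported lesion (`no-ATG`, `frameshift`,
`inframe-stop`, `one-cysteine`, `donor-break`, `acceptor-break`,
`rss-break-5/3`, `J-motif-break`) is designed to violate exactly one
classification criterion. Expected labels come from the lesion plan
through an independent rule table, never from the classifier under
test.

Guaranteeing the one-lesion/one-criterion mapping requires
restrictions a real genome does not have, and they are worth stating
plainly:

* L-PART1 interiors are T-free, intron interiors avoid AG/GT, and each
  leader search window contains exactly one ATG, so the planted leader
  is the unique zero-violation candidate and removing its ATG removes
  all candidates. Real loci contain decoy ATGs and cryptic splice
  sites; on real data the leader search reports the best-scoring
  candidate, which may legitimately differ from the annotated leader.
* RSS are planted at consensus (`CACAGTG` / `ACAAAAACC`, noise rate
  0): truth labels must follow from the lesion plan alone, and motif
  noise would decouple them. Real RSS vary by position; the adaptive
  PWM route exists precisely for that, but the synthetic cohort does
  not exercise graded motif degradation.
* V bodies avoid stop and cysteine codons except the two planted
  cysteines; J bodies avoid F/W codons outside the planted motif and
  are rejection-sampled so no alternative frame contains one.
* Inter-segment spacing (420–520 bp) keeps each leader window inside
  plain background; background GC is 0.42 for reproducibility.

Passing the synthetic suite therefore shows that the pipeline inverts
its own generative model exactly — coordinates, allele identity,
novelty, leader geometry, RSS pass/fail and labels — at cohort scale,
under strand flips, fragmentation and library updates. It does not
show robustness to assembly error, somatic rearrangement in
cell-line-derived assemblies, segmental duplications, or diverged
leaders/RSS in distant species; those need curated references.

Problem sizes used throughout (the package's own choices): synthetic
cohorts of 5 individuals × 2 haplotypes × 3 loci (IGH 30 V/6 D/9 J
records, IGK 33/0/12, TRB 29/4/12, one in five V genes with a second
allele), V alleles of 94–103 codons, D of 10–25 bp, J of 45–63 bp;
PWM validation over 20 random matrices with enumeration over all
16 384 heptamer words.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 output is 1-based
  inclusive.
* Edit distance for nearest-allele search is unit-cost Levenshtein
  (`utils::adist`), with ties broken by identity, then length
  difference, then name — novelty calls are reproducible.
* Empty libraries, empty hit sets, empty cohorts and merges of empty
  libraries are all defined (errors only where the operation is
  meaningless, e.g. `closest_allele` on an empty class).
* All generator randomness flows from one explicit integer seed;
  generated truth files record the seed.

## Known limitations

Constant (C) genes, rearranged-repertoire reads, split/chimeric
segments and transcriptome-informed functionality are out of scope.
Functionality labels are genomic predictions, not experimental
classifications — deviations from curated assignments concentrate in
the ORF category, where curation uses expression evidence no
sequence-only rule can see.
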