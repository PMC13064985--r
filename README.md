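# vdjgermline

Germline annotation of immunoglobulin (IG) and T cell receptor (TCR)
loci in genome assemblies.

The antigen-receptor loci (IGH, IGK, IGL, TRA, TRB, TRG, TRD) are built
from arrays of V, D and J gene segments that somatically rearrange
during B- and T-cell development. Annotating these regions in an
assembly means answering four questions for every segment: *where is
it* (locus extraction and segment placement), *what allele is it*
(known vs novel relative to a reference library), *can it work*
(functional / ORF / pseudogene from genomic criteria), and *what are
its regulatory and antigen-binding features* (recombination signal
sequences, CDR1/CDR2). `vdjgermline` implements this workflow
end-to-end for single assemblies and multi-sample cohorts, plus a
deterministic synthetic-locus generator with planted truth so the whole
pipeline can be validated without any external download.

## Method overview

- **Locus extraction.** Conserved flanking genes anchor each locus; all
  anchor placements on both strands with identity ≥ 0.85 are found by
  seed-and-extend alignment, and the region spanning the anchors' outer
  edges is reported in locus-forward orientation. Fragmented regions
  can be scaffolded against a reference by unique shared k-mer anchors
  (contigs ordered by reference midpoint, oriented by anchor strand,
  joined with N gaps).
- **Segment placement.** Every library allele is placed by exact k-mer
  seeding (k = 11) and affine glocal alignment (match +1, mismatch −1,
  gap open −2, extend −1); D segments shorter than 16 bp are scanned
  exhaustively. Overlaps are resolved greedily by score with fully
  deterministic tie-breaking.
- **Allele calling.** A placed segment identical to a library allele is
  that allele; anything else is novel and named
  `gene*x<hash8>`, where `hash8` is a stable content hash of the
  observed sequence, so the same novel allele gets the same name in
  every sample — the prerequisite for cohort confirmation counts.
- **Functionality.** V segments require a leader (ATG-initiated
  L-PART1, GT..AG intron, L-PART2), an intact reading frame, no
  in-frame stop in the spliced product, and a functional RSS
  (pseudogene tier); splice-site details and a two-cysteine check
  demote to ORF. J segments require the [FW]G.G motif (ORF tier), no
  premature stop, a GT donor and a functional RSS; D segments stand or
  fall with their two RSS.
- **Adaptive RSS models.** Heptamer and nonamer position weight
  matrices are trained per locus/class/side from the segments
  preliminarily classified functional (unique allele/RSS combinations
  only), every RSS is rescored with exact log-odds p-values
  (enumeration for 7-mers, discretized dynamic programming for
  9-mers), and labels are refined; the train/rescan/classify cycle is a
  fixpoint after two passes.
- **CDR1/CDR2.** Transferred from CDR-bearing reference alleles by
  global amino-acid alignment and back-projected to genomic
  coordinates.
- **Cohorts.** Per-class totals, unique and novel allele counts,
  novel-allele confirmation across individuals (support counts
  individuals, not haplotypes), zygosity, identical-haplotype groups,
  and concordance between annotation sets under the
  overlapping-or-identical-coordinates rule.

## Worked example

```r
library(vdjgermline)

# a synthetic IGH library (30 V, 6 D, 9 J records) and a locus carrying
# one planted in-frame stop
gl <- generate_library(11, "IGH", c(v = 30L, d = 6L, j = 9L))
lo <- generate_locus(gl$library, "IGH", seed = 12,
                     lesions = c(IGHV8 = "inframe-stop"))

reg <- extract_region(lo$assembly, lo$spec)
reg
#> Extracted region IGH (|): contig1:200-31930 (+), 31730 bp, complete=TRUE, scaffolded=FALSE

ra <- annotate_region(reg, gl$library, cdr_refs = gl$cdr_refs)
ra
#> Region annotation IGH: 39 segments (D=6, J=9, V=24); 1 novel
#>              class
#> functionality  D  J  V
#>    functional  6  9 23
#>    pseudogene  0  0  1

subset(ra$annotations, novel,
       select = c(gene, allele_call, functionality, failed_criteria))
#>    gene     allele_call functionality failed_criteria
#> 8 IGHV8 IGHV8*xac3dbd06    pseudogene    inframe-stop
```

The lesioned V is recovered at its planted coordinates, called novel
(its sequence is one codon away from the library allele), given a
stable content-hash name, and classified pseudogene with the violated
criterion recorded. The remaining 38 segments are exact matches to
library alleles, placed at identity 1.0 and classified functional.

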