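Package: vdjgermline
Title: Germline Annotation of Immunoglobulin and T Cell Receptor Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts immunoglobulin (IG) and T cell receptor (TCR) loci from
    genome assemblies using conserved flanking-gene anchors, annotates known
    and novel V, D and J gene segments against an allele library by
    seed-and-extend alignment, classifies segment functionality
    (functional/ORF/pseudogene) from genomic criteria including leader
    sequences, characterizes recombination signal sequences with adaptive
    position weight matrix models and exact log-odds p-values, transfers
    germline CDR1/CDR2 coordinates from reference alleles, aggregates
    multi-sample cohorts (novel-allele confirmation, zygosity, haplotype
    identity, concordance), and ships a deterministic synthetic-locus
    generator with planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
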