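# Cohort aggregation, novel-allele confirmation, concordance and
# haplotype identity.

.mk_ann <- function(sample_id, haplotype, locus, class, gene, seq,
                    novel = FALSE, start = 0L, complete = TRUE) {
  data.frame(sample_id = sample_id, haplotype = haplotype, locus = locus,
             segment_class = class, gene = gene, observed_sequence = seq,
             novel = novel, allele_call = paste0(gene, "*01"),
             provisional_name = ifelse(novel, paste0(gene, "*xdeadbeef"),
                                       NA_character_),
             start = start, end = start + nchar(seq), complete = complete,
             stringsAsFactors = FALSE)
}

test_that("cohort aggregation counts classes, unique and novel alleles", {
  ann <- rbind(
    .mk_ann("I1", "1", "IGH", "V", "IGHV1", "AAAA"),
    .mk_ann("I1", "2", "IGH", "V", "IGHV1", "AAAA"),
    .mk_ann("I1", "1", "IGH", "J", "IGHJ1", "CCCC"),
    .mk_ann("I1", "2", "IGH", "J", "IGHJ1", "CCCC"),
    .mk_ann("I2", "1", "IGH", "V", "IGHV1", "AAAT", novel = TRUE),
    .mk_ann("I2", "1", "TRB", "V", "TRBV1", "GGGG"))
  s <- aggregate_cohort(ann)
  pc <- s$per_class_counts
  expect_equal(pc$n[pc$locus_group == "IG" & pc$segment_class == "V"], 3L)
  expect_equal(unname(s$unique_alleles["V"]), 3L)
  expect_equal(unname(s$novel_alleles["V"]), 1L)
  expect_equal(unname(s$novel_alleles["J"]), 0L)
  # row totals equal the sum of class cells
  expect_equal(sum(pc$n), nrow(ann))
  z <- s$zygosity
  expect_equal(z$zygosity[z$individual == "I1" & z$locus == "IGH"],
               "homozygous")
  expect_equal(z$zygosity[z$individual == "I2" & z$locus == "TRB"],
               "single-haplotype")
  # empty cohort
  s0 <- aggregate_cohort(NULL)
  expect_equal(sum(s0$unique_alleles), 0L)
})

test_that("novel confirmation counts individuals, not haplotypes", {
  novel_seq <- "ACGTACGTAA"
  ann <- rbind(
    do.call(rbind, lapply(1:4, function(i)
      .mk_ann(paste0("I", i), "1", "IGH", "V", "IGHV2", novel_seq,
              novel = TRUE))),
    .mk_ann("I9", "1", "IGH", "V", "IGHV3", "TTTTGGGGCC", novel = TRUE),
    .mk_ann("I9", "2", "IGH", "V", "IGHV3", "TTTTGGGGCC", novel = TRUE),
    .mk_ann("I5", "1", "IGH", "V", "IGHV4", "GGGGCCCCAA", novel = TRUE))
  cn <- confirm_novel(ann, thresholds = c(2L, 4L))
  sup <- cn$support
  expect_equal(sup$support[sup$sequence == novel_seq], 4L)
  # both haplotypes of one individual count once
  expect_equal(sup$support[sup$sequence == "TTTTGGGGCC"], 1L)
  expect_equal(sup$support[sup$sequence == "GGGGCCCCAA"], 1L)
  expect_true(novel_seq %in% cn$confirmed_at[["4"]]$sequence)
  expect_true(novel_seq %in% cn$confirmed_at[["2"]]$sequence)
  expect_false("TTTTGGGGCC" %in% cn$confirmed_at[["2"]]$sequence)
  # monotone: confirmed_at(4) is a subset of confirmed_at(2)
  expect_true(all(cn$confirmed_at[["4"]]$sequence %in%
                  cn$confirmed_at[["2"]]$sequence))
})

test_that("concordance uses 1 bp overlap with greedy unique matching", {
  mk_iv <- function(class, start, end)
    data.frame(segment_class = class, start = start, end = end,
               stringsAsFactors = FALSE)
  a <- rbind(mk_iv("V", 100, 400), mk_iv("J", 1000, 1060))
  # self-comparison: everything matches
  r <- compare_annotations(a, a)
  expect_equal(r$matched, 2L)
  expect_equal(r$tool_only, 0L)
  expect_equal(r$reference_only, 0L)
  # a single base of overlap is concordant
  r <- compare_annotations(mk_iv("V", 100, 400), mk_iv("V", 399, 600))
  expect_equal(r$matched, 1L)
  # disjoint intervals are not
  expect_warning(
    r <- compare_annotations(mk_iv("V", 100, 400), mk_iv("V", 500, 600)))
  expect_equal(r$matched, 0L)
  expect_equal(r$tool_only, 1L)
  expect_equal(r$reference_only, 1L)
  # class mismatch never matches; count identities hold
  r <- compare_annotations(mk_iv("V", 100, 400),
                           rbind(mk_iv("D", 100, 400),
                                 mk_iv("V", 300, 500)))
  expect_equal(r$matched + r$tool_only, 1L)
  expect_equal(r$matched + r$reference_only, 2L)
})

test_that("haplotype identity groups identical ordered allele vectors", {
  h <- function(ind, hap, seqs, starts = seq(0, by = 500,
                                             length.out = length(seqs))) {
    do.call(rbind, Map(function(s, st, i)
      .mk_ann(ind, hap, "TRB", "V", paste0("TRBV", i), s, start = st),
      seqs, starts, seq_along(seqs)))
  }
  ann <- rbind(h("I1", "1", c("AAAA", "CCCC")),
               h("I1", "2", c("AAAA", "CCCC")),
               h("I2", "1", c("CCCC", "AAAA")),   # same alleles, other order
               h("I3", "1", c("GGGG", "TTTT")))
  g <- haplotype_identity(ann, "TRB")
  expect_length(g, 1L)
  expect_setequal(g[[1]], c("I1#1", "I1#2"))
  # order sensitivity: I2 not grouped with I1 despite same allele set
  expect_false(any(grepl("I2", unlist(g))))
  # all distinct: no groups
  g2 <- haplotype_identity(ann[ann$sample_id != "I1", ], "TRB")
  expect_length(g2, 0L)
})
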