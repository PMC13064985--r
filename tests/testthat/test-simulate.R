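# Synthetic generator: determinism, construction constraints, planted
# truth consistency.

test_that("generation is deterministic under the seed", {
  a <- generate_library(7, "IGH", c(v = 5L, d = 3L, j = 4L))
  b <- generate_library(7, "IGH", c(v = 5L, d = 3L, j = 4L))
  expect_identical(as.data.frame(a$library), as.data.frame(b$library))
  expect_identical(a$cdr_refs, b$cdr_refs)
  la <- generate_locus(a$library, "IGH", seed = 9)
  lb <- generate_locus(b$library, "IGH", seed = 9)
  expect_identical(la$assembly, lb$assembly)
  expect_identical(la$truth, lb$truth)
  # and distinct seeds give distinct sequences
  lc <- generate_locus(a$library, "IGH", seed = 10, anchors = la$anchors)
  expect_false(identical(la$assembly, lc$assembly))
})

test_that("library record counts and composition match the request", {
  gl <- generate_library(3, "IGH", c(v = 5L, d = 3L, j = 4L))
  expect_equal(nrow(gl$library), 12L)
  expect_equal(as.integer(table(gl$library$segment_class)[c("V", "D", "J")]),
               c(5L, 3L, 4L))
  # V records carry at least two in-frame cysteine codons
  vs <- gl$library$sequence[gl$library$segment_class == "V"]
  for (s in vs) {
    aa <- as.character(translate_dna(s))
    expect_gte(lengths(regmatches(aa, gregexpr("C", aa))), 2L)
    expect_false(grepl("*", aa, fixed = TRUE))
    expect_equal(nchar(s) %% 3L, 0L)
  }
  # J records contain the [FW]G.G motif in frame 0 only
  js <- gl$library$sequence[gl$library$segment_class == "J"]
  for (s in js) {
    expect_match(as.character(translate_dna(s, 0)), "[FW]G.G")
    expect_no_match(as.character(translate_dna(s, 1)), "[FW]G.G")
    expect_no_match(as.character(translate_dna(s, 2)), "[FW]G.G")
  }
})

test_that("a lesion-free locus annotates as entirely functional", {
  gl <- generate_library(15, "IGK", c(v = 5L, d = 0L, j = 3L))
  lo <- generate_locus(gl$library, "IGK", seed = 16)
  expect_true(all(lo$truth$expected_label == "functional"))
  reg <- extract_region(lo$assembly, lo$spec)
  ann <- annotate_region(reg, gl$library)$annotations
  expect_equal(nrow(ann), nrow(lo$truth))
  expect_true(all(ann$functionality == "functional"))
  expect_true(all(!ann$novel))
})

test_that("truth labels derive from the lesion plan, independent of the classifier", {
  tl <- tiny_locus()
  truth <- tl$locus$truth
  expect_equal(truth$expected_label[which(truth$lesion == "inframe-stop")],
               "pseudogene")
  expect_equal(truth$expected_failed[which(truth$lesion == "inframe-stop")],
               "inframe-stop")
  expect_equal(truth$expected_label[which(truth$lesion == "J-motif-break")],
               "ORF")
  expect_equal(truth$expected_label[which(truth$lesion == "rss-break-5")],
               "pseudogene")
  expect_true(all(truth$expected_label[is.na(truth$lesion)] == "functional"))
  # sequence-changing lesions are flagged novel in truth
  expect_true(truth$novel[which(truth$lesion == "inframe-stop")])
  expect_false(truth$novel[which(truth$lesion == "no-ATG")])
})

test_that("cohort truth records carrier support and zygosity", {
  co <- generate_cohort(77, n_individuals = 3L, loci = "IGH",
                        n_per_class = list(IGH = c(v = 10L, d = 3L, j = 5L)))
  expect_length(co$assemblies, 6L)
  np <- co$truth$novel_plan
  nt <- co$truth$novel
  for (i in seq_len(nrow(np))) {
    carr <- length(strsplit(np$carriers[i], ",")[[1]])
    expect_equal(nt$expected_support[nt$sequence == np$sequence[i]], carr)
  }
  # planted novels appear once per carrier individual in the segments
  seg <- co$truth$segments
  for (i in seq_len(nrow(np))) {
    inds <- unique(seg$sample_id[seg$sequence == np$sequence[i]])
    expect_length(inds, length(strsplit(np$carriers[i], ",")[[1]]))
  }
  expect_true(all(co$truth$zygosity$zygosity %in%
                  c("homozygous", "heterozygous")))
})

test_that("locus truth files are written as GFF3 and TSV", {
  tl <- tiny_locus()
  gff <- tempfile(fileext = ".gff3"); tsv <- tempfile(fileext = ".tsv")
  write_locus_truth(tl$locus, gff3 = gff, tsv = tsv)
  lines <- readLines(gff)
  expect_equal(lines[1], "##gff-version 3")
  expect_equal(sum(grepl("gene_segment", lines)), nrow(tl$locus$truth))
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(tl$locus$truth))
  expect_equal(back$start, tl$locus$truth$start)
})
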