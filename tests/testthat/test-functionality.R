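# Leader detection and functional / ORF / pseudogene classification.

test_that("planted leaders are found at exact coordinates", {
  tl <- tiny_locus(); gl <- tiny_library()
  ra <- tiny_annotation()
  ann <- ra$annotations
  truth <- tl$locus$truth
  clean_v <- truth[truth$segment_class == "V" & is.na(truth$lesion), ]
  for (i in seq_len(nrow(clean_v))) {
    j <- which(ann$start == clean_v$start[i] & ann$segment_class == "V")
    ld <- ra$leaders[[ann$ann_id[j]]]
    expect_false(is.null(ld))
    expect_equal(ld$lpart1[1], clean_v$leader_l1_start[i])
    expect_equal(ld$lpart1[2], clean_v$leader_l1_end[i])
    expect_equal(ld$lpart2[2], clean_v$start[i])
    expect_true(ld$donor_gt && ld$acceptor_ag && ld$has_start_codon)
  }
})

test_that("leader lesions are detected as designed", {
  tl <- tiny_locus()
  ra <- tiny_annotation()
  ann <- ra$annotations
  truth <- tl$locus$truth
  # ATG removed: no leader at all -> pseudogene
  no_atg <- truth[which(truth$lesion == "no-ATG"), ]
  j <- which(ann$start == no_atg$start)
  expect_null(ra$leaders[[ann$ann_id[j]]])
  expect_equal(ann$functionality[j], "pseudogene")
  expect_match(ann$failed_criteria[j], "leader")
  # donor GT broken but ATG intact: leader found, donor flag FALSE -> ORF
  db <- truth[which(truth$lesion == "donor-break"), ]
  j <- which(ann$start == db$start)
  ld <- ra$leaders[[ann$ann_id[j]]]
  expect_false(is.null(ld))
  expect_false(ld$donor_gt)
  expect_true(ld$acceptor_ag)
  expect_equal(ann$functionality[j], "ORF")
})

test_that("V classification follows the criterion table", {
  leader_ok <- list(lpart1 = c(0, 45), intron = c(45, 115),
                    lpart2 = c(115, 124), has_start_codon = TRUE,
                    donor_gt = TRUE, acceptor_ag = TRUE, truncated = FALSE,
                    lpart1_seq = paste0("ATG", strrep("GCA", 14)),
                    lpart2_seq = strrep("CCA", 3))
  v_ok <- paste(c("TGT", rep("GCA", 30), "TGC"), collapse = "")
  expect_equal(classify_v(v_ok, leader_ok, rss_ok = TRUE)$label,
               "functional")
  # planted in-frame TAA -> pseudogene with the criterion recorded
  v_stop <- v_ok
  substr(v_stop, 46, 48) <- "TAA"
  fc <- classify_v(v_stop, leader_ok, rss_ok = TRUE)
  expect_equal(fc$label, "pseudogene")
  expect_true("inframe-stop" %in% fc$failed_criteria)
  # exactly one cysteine, everything else passing -> ORF
  v_onecys <- paste(c("TGT", rep("GCA", 31)), collapse = "")
  fc <- classify_v(v_onecys, leader_ok, rss_ok = TRUE)
  expect_equal(fc$label, "ORF")
  expect_true("two-cys" %in% fc$failed_criteria)
  # length not a multiple of 3 -> pseudogene
  fc <- classify_v(substr(v_ok, 1, nchar(v_ok) - 1), leader_ok, TRUE)
  expect_equal(fc$label, "pseudogene")
  expect_true("v-frame" %in% fc$failed_criteria)
  # failed RSS -> pseudogene
  expect_equal(classify_v(v_ok, leader_ok, rss_ok = FALSE)$label,
               "pseudogene")
})

test_that("D classification requires both flanking RSS", {
  expect_equal(classify_d(TRUE, TRUE)$label, "functional")
  fc <- classify_d(FALSE, TRUE)
  expect_equal(fc$label, "pseudogene")
  expect_equal(fc$failed_criteria, "rss-5")
  fc <- classify_d(FALSE, FALSE)
  expect_equal(fc$label, "pseudogene")
  expect_equal(fc$failed_criteria, c("rss-5", "rss-3"))
})

test_that("J classification follows the criterion table", {
  j_ok <- paste(c(rep("GCA", 10), "TTT", "GGC", "CAG", "GGA", "GCA"),
                collapse = "")  # ...FGQG...
  expect_equal(classify_j(j_ok, "GT", TRUE)$label, "functional")
  # motif broken (LGQG) -> ORF
  j_lg <- j_ok
  substr(j_lg, 31, 33) <- "CTT"
  fc <- classify_j(j_lg, "GT", TRUE)
  expect_equal(fc$label, "ORF")
  expect_equal(fc$failed_criteria, "j-motif")
  # premature stop in the motif frame -> pseudogene
  j_stop <- j_ok
  substr(j_stop, 4, 6) <- "TAG"
  fc <- classify_j(j_stop, "GT", TRUE)
  expect_equal(fc$label, "pseudogene")
  expect_true("premature-stop" %in% fc$failed_criteria)
  # missing donor or failed RSS -> pseudogene
  expect_equal(classify_j(j_ok, "GA", TRUE)$label, "pseudogene")
  expect_equal(classify_j(j_ok, "GT", FALSE)$label, "pseudogene")
})

test_that("classification is a pure function of its inputs", {
  tl <- tiny_locus(); gl <- tiny_library()
  a1 <- annotate_region(tl$region, gl$library)$annotations
  a2 <- annotate_region(tl$region, gl$library)$annotations
  expect_identical(a1, a2)
})
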