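# RSS extraction, PWM building/scoring and exact p-values.

test_that("RSS extraction returns the planted elements per side", {
  tl <- tiny_locus()
  ra <- tiny_annotation()
  ann <- ra$annotations
  rss <- ra$rss
  truth <- tl$locus$truth
  # clean V: one 3' RSS with consensus heptamer/nonamer at offset 0
  v <- truth[truth$segment_class == "V" & is.na(truth$lesion), ][1, ]
  id <- ann$ann_id[ann$start == v$start]
  r <- rss[rss$ann_id == id, ]
  expect_equal(r$side, "3prime")
  expect_equal(r$heptamer, "CACAGTG")
  expect_equal(r$nonamer, "ACAAAAACC")
  expect_equal(r$start, v$rss3_start)
  expect_equal(r$spacer_len, 23L)
  # D: exactly two records, both sides
  d <- truth[truth$segment_class == "D" & is.na(truth$lesion), ][1, ]
  id <- ann$ann_id[ann$start == d$start & ann$segment_class == "D"]
  r <- rss[rss$ann_id == id, ]
  expect_setequal(r$side, c("5prime", "3prime"))
  expect_equal(r$heptamer, c("CACAGTG", "CACAGTG"))
  # J: one 5' RSS
  jt <- truth[truth$segment_class == "J" & is.na(truth$lesion), ][1, ]
  id <- ann$ann_id[ann$start == jt$start & ann$segment_class == "J"]
  expect_equal(rss$side[rss$ann_id == id], "5prime")
})

test_that("segments too close to the region edge get truncated-flank records", {
  region <- structure(list(sample_id = "", haplotype = "", locus = "IGH",
                           contig = "c", start = 0L, end = 400L,
                           strand = "+", sequence = rand_dna(400, seed = 3),
                           complete = FALSE, scaffolded = FALSE),
                      class = "extracted_region")
  ann <- data.frame(ann_id = "x", locus = "IGH", segment_class = "V",
                    start = 350L, end = 390L, strand = "+",
                    stringsAsFactors = FALSE)
  r <- extract_rss(region, ann)
  expect_false(r$pass)
  expect_match(r$flags, "truncated-flank")
})

test_that("PWM estimation matches its closed forms", {
  # single sequence, pseudocount 0: indicator columns, 14-bit consensus
  m <- build_pwm("CACAGTG", pseudocount = 0)
  expect_equal(unname(m$probs[1, ]), c(0, 1, 0, 0))
  expect_equal(as.numeric(score_pwm(m, "CACAGTG")), 7 * log2(4))
  # two sequences differing only at position 3
  m2 <- build_pwm(c("CACAGTG", "CATAGTG"), pseudocount = 0)
  expect_equal(unname(m2$probs[3, c("C", "T")]), c(0.5, 0.5))
  expect_equal(sum(m2$probs[3, ]), 1)
  # any pseudocount keeps columns normalized
  m3 <- build_pwm(c("ACGTACG", "ACGTACG", "TTTTTTT"), pseudocount = 0.1)
  expect_equal(unname(rowSums(m3$probs)), rep(1, 7), tolerance = 1e-9)
  # sequences containing N are excluded and counted
  m4 <- build_pwm(c("ACGTACG", "ACNTACG"))
  expect_equal(m4$n_training, 1L)
  expect_equal(m4$n_excluded, 1L)
  expect_error(build_pwm(character(0)), "no training RSS")
})

test_that("consensus maximality and degenerate models behave", {
  set.seed(41)
  m <- build_pwm(replicate(10, rand_dna(7)), pseudocount = 0.5)
  dist <- pwm_score_distribution(m)
  cons <- pwm_consensus(m)
  expect_equal(as.numeric(score_pwm(m, cons)), max(dist$scores),
               tolerance = 1e-9)
  # uniform PWM: score 0 and p-value 1 for every sequence
  u <- build_pwm(c("AAAAAAA", "CCCCCCC", "GGGGGGG", "TTTTTTT"),
                 pseudocount = 0)
  expect_equal(as.numeric(score_pwm(u, "ACGTACG")), 0)
  expect_equal(scan_score(u, "GATTACA")$p_value, 1)
})

test_that("7-mer p-values equal the exhaustive word-count oracle", {
  set.seed(43)
  bases <- c("A", "C", "G", "T")
  words <- do.call(paste0, expand.grid(rep(list(bases), 7),
                                       stringsAsFactors = FALSE))
  expect_equal(length(words), 16384L)
  for (rep in 1:3) {
    m <- build_pwm(replicate(8, rand_dna(7)), pseudocount = 0.3)
    # independent oracle: score every word directly from the probabilities
    lo <- log2(m$probs / 0.25)
    wmat <- do.call(rbind, strsplit(words, ""))
    wscores <- rowSums(matrix(lo[cbind(rep(1:7, each = nrow(wmat)),
                                       match(as.vector(wmat), bases))],
                              ncol = 7))
    for (q in c("CACAGTG", "GATTACA", pwm_consensus(m))) {
      p <- scan_score(m, q)$p_value
      s <- as.numeric(score_pwm(m, q))
      expect_equal(p, mean(wscores >= s - 1e-9), tolerance = 1e-9)
    }
  }
})

test_that("DP p-values are bracketed by enumeration at shifted thresholds", {
  set.seed(47)
  bin <- 0.001
  for (rep in 1:3) {
    m <- build_pwm(replicate(6, rand_dna(7)), pseudocount = 0.4)
    d_en <- pwm_score_distribution(m, method = "enumerate")
    d_dp <- pwm_score_distribution(m, method = "dp", bin = bin)
    slack <- 7 * bin  # max total binning displacement
    for (q in replicate(10, rand_dna(7))) {
      s <- as.numeric(score_pwm(m, q))
      p_dp <- sum(d_dp$probs[d_dp$scores >= s - slack / 2 - 1e-9])
      p_lo <- sum(d_en$probs[d_en$scores >= s + slack])
      p_hi <- sum(d_en$probs[d_en$scores >= s - slack])
      expect_gte(p_dp, p_lo - 1e-9)
      expect_lte(p_dp, p_hi + 1e-9)
    }
  }
})

test_that("p-values are monotone in score with p(min) = 1", {
  set.seed(53)
  m <- build_pwm(replicate(5, rand_dna(9)), pseudocount = 0.5)
  dist <- pwm_score_distribution(m)
  seqs <- replicate(30, rand_dna(9))
  sc <- vapply(seqs, function(q) as.numeric(score_pwm(m, q)), 0)
  pv <- vapply(seqs, function(q) scan_score(m, q)$p_value, 0)
  ord <- order(sc)
  expect_true(all(diff(pv[ord]) <= 1e-9))
  worst <- paste(c("A", "C", "G", "T")[apply(m$probs, 1, which.min)],
                 collapse = "")
  expect_equal(scan_score(m, worst)$p_value, 1)
})

test_that("training deduplicates allele/RSS combinations and refinement
           downgrades scrambled heptamers", {
  gl <- tiny_library()
  lo <- generate_locus(gl$library, "IGH", seed = 505,
                       lesions = c(IGHV3 = "rss-break-3"))
  reg <- extract_region(lo$assembly, lo$spec)
  ra <- annotate_region(reg, gl$library)
  ann <- ra$annotations
  broken <- lo$truth[which(lo$truth$lesion == "rss-break-3"), ]
  j <- which(ann$start == broken$start & ann$segment_class == "V")
  expect_equal(ann$functionality[j], "pseudogene")
  expect_match(ann$failed_criteria[j], "rss")
  rss_j <- ra$rss[ra$rss$ann_id == ann$ann_id[j], ]
  expect_false(rss_j$pass)
  expect_gt(rss_j$p_hep, 1e-3)
  # all intact planted RSS keep their labels
  clean <- lo$truth[is.na(lo$truth$lesion), ]
  for (i in seq_len(nrow(clean))) {
    jj <- which(ann$start == clean$start[i] &
                ann$segment_class == clean$segment_class[i])
    expect_equal(ann$functionality[jj], "functional")
  }
  # dedup: training set size counts unique allele/RSS pairs
  tr_ann <- ann[ann$segment_class == "V" &
                ann$functionality == "functional", ]
  models <- train_rss_models(ann, ra$rss)
  mh <- models[["IGH|V|3prime|heptamer"]]
  expect_lte(mh$n_training, nrow(unique(cbind(tr_ann$observed_sequence))))
})
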