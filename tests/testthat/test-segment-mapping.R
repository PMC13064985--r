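# Allele placement, overlap resolution and known/novel calling.

test_that("planted segments map at exact coordinates with identity 1", {
  tl <- tiny_locus(); gl <- tiny_library()
  hits <- resolve_overlaps(map_segments(tl$region, gl$library))
  truth <- tl$locus$truth
  for (i in seq_len(nrow(truth))) {
    j <- which(hits$start == truth$start[i] & hits$end == truth$end[i] &
               hits$segment_class == truth$segment_class[i])
    expect_length(j, 1L)
  }
})

test_that("a single substitution lowers identity by exactly one match", {
  set.seed(21)
  gl <- tiny_library()
  v <- gl$library$sequence[gl$library$segment_class == "V"][1]
  L <- nchar(v)
  planted <- v
  substr(planted, 123, 123) <- setdiff(c("A", "C", "G", "T"),
                                       substr(planted, 123, 123))[1]
  reg_seq <- paste0(rand_dna(500), planted, rand_dna(500))
  region <- structure(list(sample_id = "s", haplotype = "1", locus = "IGH",
                           contig = "c", start = 0L,
                           end = nchar(reg_seq), strand = "+",
                           sequence = reg_seq, complete = TRUE,
                           scaffolded = FALSE),
                      class = "extracted_region")
  hits <- map_segments(region, gl$library)
  h <- hits[hits$best_allele == gl$library$name[gl$library$sequence == v], ]
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 500L)
  expect_equal(h$identity, (L - 1) / L)
  expect_equal(h$distance, 1L)
  # full dynamic-programming oracle at the planted offset agrees
  al <- align_glocal(v, planted)
  expect_equal(al$matches, L - 1L)
  # an allele absent from the region yields no hit
  absent <- paste(rep("ACGTT", 60), collapse = "")
  other <- allele_library("IGHV99*01", absent, label = "x")
  expect_equal(nrow(map_segments(region, other)), 0L)
})

test_that("overlap resolution is greedy, deterministic, maximal", {
  mk <- function(start, end, score, identity = 0.95, allele = "IGHV1*01") {
    data.frame(segment_class = "V", gene = sub("\\*.*", "", allele),
               best_allele = allele, start = start, end = end,
               strand = "+", identity = identity, score = score,
               distance = 1L, btop = "x", observed_sequence = "N",
               flags = "", stringsAsFactors = FALSE)
  }
  # higher score wins an overlap
  r <- resolve_overlaps(rbind(mk(0, 300, 50), mk(100, 400, 40)))
  expect_equal(r$score, 50)
  # equal score and identity: longer hit wins
  r <- resolve_overlaps(rbind(mk(0, 296, 30), mk(50, 350, 30)))
  expect_equal(r$end - r$start, 300L)
  # brute-force subset oracle on random interval sets
  set.seed(31)
  n_equal <- 0L; n_cases <- 20L
  for (case in seq_len(n_cases)) {
    n <- sample(4:10, 1)
    hits <- do.call(rbind, lapply(seq_len(n), function(i) {
      s <- sample(0:500, 1)
      mk(s, s + sample(30:200, 1), score = sample(10:60, 1),
         allele = sprintf("IGHV%d*01", i))
    }))
    kept <- resolve_overlaps(hits, overlap_tol = 10L)
    ov <- function(a, b, c, d) max(0, min(b, d) - max(a, c))
    compat <- function(idx) {
      if (length(idx) < 2) return(TRUE)
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (a < b && ov(hits$start[idx[a]], hits$end[idx[a]],
                        hits$start[idx[b]], hits$end[idx[b]]) > 10) {
          return(FALSE)
        }
      }
      TRUE
    }
    kept_idx <- match(paste(kept$start, kept$end), paste(hits$start, hits$end))
    expect_true(compat(kept_idx))
    # maximality: no dropped hit can be added
    for (i in setdiff(seq_len(n), kept_idx)) {
      expect_false(compat(c(kept_idx, i)))
    }
    # exhaustive optimum for comparison (greedy may rarely differ)
    best <- 0
    for (m in 0:(2^n - 1)) {
      idx <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
      if (compat(idx)) best <- max(best, sum(hits$score[idx]))
    }
    expect_lte(sum(kept$score), best)
    if (sum(kept$score) == best) n_equal <- n_equal + 1L
  }
  # greedy may differ from the exhaustive optimum on adversarial interval
  # sets; it must agree on a clear majority of random cases
  expect_gte(n_equal, as.integer(0.6 * n_cases))
})

test_that("novel calls carry stable content-hash provisional names", {
  ra <- tiny_annotation()
  ann <- ra$annotations
  # exact hits are known
  known <- ann[!ann$novel, ]
  expect_true(all(known$allele_call %in% tiny_library()$library$name))
  # lesioned segments with changed sequence are novel with gene*x<hash8>
  nov <- ann[ann$novel, ]
  expect_gt(nrow(nov), 0L)
  expect_true(all(nov$provisional_name ==
                  paste0(nov$gene, "*x",
                         vapply(nov$observed_sequence, content_hash8, ""))))
  # the same sequence hashes identically wherever it appears
  expect_equal(content_hash8(nov$observed_sequence[1]),
               content_hash8(tolower(nov$observed_sequence[1])))
})

test_that("novelty is library-relative: extending the library converts the call", {
  gl <- tiny_library(); tl <- tiny_locus()
  ra <- tiny_annotation()
  nov <- ra$annotations[ra$annotations$novel, ][1, ]
  ext <- merge_libraries(gl$library,
                         allele_library(paste0(nov$gene, "*09"),
                                        nov$observed_sequence,
                                        label = "update"))
  ann2 <- annotate_region(tl$region, ext)$annotations
  j <- which(ann2$start == nov$start & ann2$end == nov$end)
  expect_length(j, 1L)
  expect_false(ann2$novel[j])
  expect_equal(ann2$allele_call[j], paste0(nov$gene, "*09"))
})

test_that("reverse-complementing the region mirrors coordinates and strands", {
  gl <- tiny_library(); tl <- tiny_locus()
  reg <- tl$region
  L <- nchar(reg$sequence)
  reg_rc <- reg
  reg_rc$sequence <- revcomp(reg$sequence)
  hits <- resolve_overlaps(map_segments(reg, gl$library))
  hits_rc <- resolve_overlaps(map_segments(reg_rc, gl$library))
  expect_equal(nrow(hits), nrow(hits_rc))
  hits_rc <- hits_rc[order(-hits_rc$start), ]
  expect_equal(hits_rc$start, L - hits$end)
  expect_equal(hits_rc$end, L - hits$start)
  expect_true(all(hits_rc$strand != hits$strand))
  expect_equal(hits_rc$observed_sequence, hits$observed_sequence)
})
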