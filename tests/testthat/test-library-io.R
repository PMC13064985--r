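# Allele library parsing, merging and nearest-allele search.

test_that("FASTA parsing handles header dialects, rejects bad records", {
  f <- write_tmp_fasta(c(
    "IGHV1-2*02|Homo sapiens|F" = "acgtacgtacgt",
    "IGHJ4*01|Homo sapiens|P" = "TTTTGGCCAGGG",
    "TRBV2*01" = "CCCCAAAATTTT",
    "not_an_allele_header" = "ACGT",
    "IGHV9-9*01|Homo sapiens|F" = "ACGTXACGT"))
  expect_message(lib <- parse_library(f, "test"), "unparseable")
  expect_equal(nrow(lib), 3L)
  expect_setequal(lib$segment_class, c("V", "J"))
  expect_equal(lib$sequence[lib$name == "IGHV1-2*02"], "ACGTACGTACGT")
  expect_equal(lib$locus[lib$name == "TRBV2*01"], "TRB")
  expect_equal(lib$functionality[lib$name == "IGHJ4*01"], "pseudogene")
  expect_equal(lib$functionality[lib$name == "TRBV2*01"], "unknown")
  expect_equal(attr(lib, "n_skipped"), 1L)
  expect_equal(attr(lib, "rejected")$name, "IGHV9-9*01")
})

test_that("identical sequences under different names share a dup group", {
  f <- write_tmp_fasta(c("IGHV1*01" = "ACGTACGTAC",
                         "IGHV2*01" = "ACGTACGTAC",
                         "IGHV3*01" = "TTTTACGTAC"))
  lib <- parse_library(f, "dups")
  # oracle: exact string comparison over all pairs
  same <- outer(lib$sequence, lib$sequence, "==")
  for (i in 1:3) for (j in 1:3) {
    expect_equal(lib$dup_group[i] == lib$dup_group[j], same[i, j])
  }
})

test_that("empty library files are rejected", {
  f <- tempfile(fileext = ".fasta")
  file.create(f)
  expect_error(parse_library(f), "empty library")
})

test_that("merge obeys the size law and is idempotent and symmetric", {
  set.seed(42)
  pool <- replicate(40, rand_dna(30))
  for (rep in 1:10) {
    na <- sample(5:20, 1); nb <- sample(5:20, 1)
    sa <- sample(pool, na); sb <- sample(pool, nb)
    a <- allele_library(sprintf("IGHV%d*01", seq_len(na)), sa, label = "A")
    b <- allele_library(sprintf("IGHV%d*01", seq_len(nb)), sb, label = "B")
    m <- merge_libraries(a, b)
    shared <- length(intersect(unique(sa), unique(sb)))
    # size law relative to unique sequence classes
    expect_equal(nrow(m),
                 length(unique(sa)) + length(unique(sb)) - shared)
    # sequence sets commute
    m2 <- merge_libraries(b, a)
    expect_setequal(m$sequence, m2$sequence)
    # representative priority: shared classes keep the a-side record
    for (s in intersect(sa, sb)) {
      expect_equal(m$name[m$sequence == s], a$name[a$sequence == s][1])
      expect_match(m$source[m$sequence == s], "A.*B")
    }
    expect_equal(nrow(merge_libraries(a, a)), length(unique(sa)))
  }
  # disjoint 3 + 2 = 5
  d1 <- allele_library(c("IGHV1*01", "IGHV2*01", "IGHV3*01"),
                       c("AAAA", "CCCC", "GGGG"), label = "x")
  d2 <- allele_library(c("IGHJ1*01", "IGHJ2*01"), c("TTTT", "ATAT"),
                       label = "y")
  expect_equal(nrow(merge_libraries(d1, d2)), 5L)
})

test_that("closest_allele minimizes edit distance with deterministic ties", {
  gl <- tiny_library()
  lib <- gl$library
  vseqs <- lib$sequence[lib$segment_class == "V"]
  # exact query returns that record at distance 0
  r <- closest_allele(vseqs[2], lib, "V")
  expect_equal(r$record$sequence, vseqs[2])
  expect_equal(r$transcript$distance, 0L)
  # one substitution: oracle is exhaustive pairwise edit distance
  q <- vseqs[3]
  substr(q, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                               substr(q, 50, 50))[1]
  r <- closest_allele(q, lib, "V")
  d_all <- drop(utils::adist(q, lib$sequence[lib$segment_class == "V"]))
  expect_equal(r$transcript$distance, min(d_all))
  expect_equal(r$transcript$distance, 1L)
  ops <- parse_btop(r$transcript$btop)
  expect_equal(sum(ops$op == "sub"), 1L)
  expect_equal(sum(ops$op %in% c("ins", "del")), 0L)
  # tie broken by lexicographically smallest name
  s <- rand_dna(60, seed = 7)
  sA <- s; substr(sA, 10, 10) <- "A"; substr(sA, 10, 10) <- if (substr(s, 10, 10) == "A") "C" else "A"
  sZ <- s; substr(sZ, 40, 40) <- if (substr(s, 40, 40) == "A") "C" else "A"
  tie_lib <- allele_library(c("IGHV9*01", "IGHV1*01"), c(sZ, sA),
                            label = "tie")
  r <- closest_allele(s, tie_lib, "V")
  # enumeration confirms the tie
  expect_equal(drop(utils::adist(s, c(sZ, sA))), c(1L, 1L))
  expect_equal(r$record$name, "IGHV1*01")
  expect_error(closest_allele("ACGT", tie_lib, "D"), "empty class")
})

test_that("edit transcripts replay to reconstruct the query", {
  set.seed(99)
  for (i in 1:25) {
    target <- rand_dna(sample(20:80, 1))
    q <- target
    # random mutations: substitutions, insertion, deletion
    p <- sample(nchar(q) - 2, 1)
    substr(q, p, p) <- sample(c("A", "C", "G", "T"), 1)
    if (i %% 2 == 0) q <- paste0(substr(q, 1, p), "A",
                                 substr(q, p + 1, nchar(q)))
    if (i %% 3 == 0) q <- paste0(substr(q, 1, 3),
                                 substr(q, 5, nchar(q)))
    tr <- edit_transcript(q, target)
    expect_equal(replay_btop(tr$btop, target), q)
    expect_equal(tr$distance, tr$columns - tr$matches)
  }
})

test_that("closest_allele distance is zero iff the sequence is in the library", {
  gl <- tiny_library()
  lib <- gl$library
  for (i in seq_len(nrow(lib))) {
    r <- closest_allele(lib$sequence[i], lib, lib$segment_class[i])
    expect_equal(r$transcript$distance, 0L)
  }
  q <- paste0(lib$sequence[1], "ACGT")
  expect_gt(closest_allele(q, lib)$transcript$distance, 0L)
})
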