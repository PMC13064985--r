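# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small IGH library + CDR sidecar
tiny_library <- function() fixture("tiny_library", function() {
  generate_library(101, "IGH", c(v = 6L, d = 3L, j = 4L))
})

# one lesioned IGH locus with truth, plus its extracted region
tiny_locus <- function() fixture("tiny_locus", function() {
  gl <- tiny_library()
  lo <- generate_locus(gl$library, "IGH", seed = 202,
                       lesions = c(IGHV2 = "inframe-stop",
                                   IGHV3 = "no-ATG",
                                   IGHV4 = "donor-break",
                                   IGHD2 = "rss-break-5",
                                   IGHJ2 = "J-motif-break"))
  reg <- extract_region(lo$assembly, lo$spec, sample_id = "S1",
                        haplotype = "1")
  list(locus = lo, region = reg)
})

tiny_annotation <- function() fixture("tiny_annotation", function() {
  gl <- tiny_library()
  tl <- tiny_locus()
  annotate_region(tl$region, gl$library, cdr_refs = gl$cdr_refs)
})

# random DNA helper for tests
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# write a FASTA tempfile from a named vector
write_tmp_fasta <- function(seqs) {
  f <- tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  f
}

# independent brute-force: all exact occurrences of q in s (both strands)
brute_exact_placements <- function(q, s) {
  L <- nchar(q)
  out <- NULL
  for (st in c("+", "-")) {
    pat <- if (st == "-") revcomp(q) else q
    for (p in seq_len(nchar(s) - L + 1)) {
      if (substr(s, p, p + L - 1) == pat)
        out <- rbind(out, data.frame(start = p - 1L, end = p - 1L + L,
                                     strand = st))
    }
  }
  out
}
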