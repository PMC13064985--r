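# Deterministic synthetic-data generator: allele libraries, single loci
# and multi-sample cohorts with full planted truth. The generator is the
# inverse of the annotation model: it lays down anchor genes, leaders,
# segments and RSS so that, absent lesions, every planted segment
# satisfies every functionality criterion, and each supported lesion
# breaks exactly one criterion. Expected labels are computed from the
# lesion plan by an independent rule table, never by the classifier
# under test.
#
# Alphabet restrictions that make the lesion -> criterion map exact:
#  - L-PART1 is ATG plus a T-free tail, the intron interior is drawn from
#    {C,A} without AG, and L-PART2 from {C,A,G} without AG: the planted
#    leader is then the unique zero-violation candidate in the search
#    window, and alternative splice geometries cannot introduce stops.
#  - every ATG in a V leader search window other than the initiator is
#    scrubbed, so removing the initiator removes all leader candidates.
#  - V bodies avoid stop and cysteine codons except the two planted
#    cysteines; J bodies avoid F/W codons outside the planted [FW]G.G
#    motif and are rejection-sampled so no other frame contains a motif.
#  - RSS are planted at consensus (noise_rate 0): truth labels derive
#    from the lesion plan alone.

STOP_CODONS <- c("TAA", "TAG", "TGA")
CYS_CODONS <- c("TGT", "TGC")
FW_CODONS <- c("TTT", "TTC", "TGG")
RSS_SCRAMBLED_HEPTAMER <- "TGACTAC"  # differs from consensus at all 7

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.rand_dna <- function(n, gc = 0.42) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

.all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

.rand_codons <- function(n, exclude) {
  pool <- setdiff(.all_codons(), exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# constrained sampler: alphabet subset, no "AG" dinucleotide; the first
# character can additionally exclude G so that no AG can form across the
# junction with a preceding piece ending in A
.rand_no_ag <- function(n, alphabet = c("C", "A", "G"),
                        ban_first_g = FALSE) {
  out <- character(n)
  prev <- ""
  for (i in seq_len(n)) {
    pool <- if (prev == "A" || (i == 1L && ban_first_g))
      setdiff(alphabet, "G") else alphabet
    out[i] <- sample(pool, 1L)
    prev <- out[i]
  }
  paste(out, collapse = "")
}

.leader_template <- function(intron_len = 70L) {
  lpart1 <- paste0("ATG", paste(sample(c("A", "C", "G"), 42L,
                                       replace = TRUE), collapse = ""))
  intron <- paste0("GT", .rand_no_ag(intron_len - 4L, c("C", "A")), "AG")
  lpart2 <- .rand_no_ag(9L, ban_first_g = TRUE)
  list(lpart1 = lpart1, intron = intron, lpart2 = lpart2)
}

.make_v_sequence <- function(n_codons) {
  safe <- setdiff(.all_codons(), c(STOP_CODONS, CYS_CODONS))
  codons <- sample(safe, n_codons, replace = TRUE)
  codons[22] <- "TGT"
  codons[n_codons - 6L] <- "TGC"
  paste(codons, collapse = "")
}

.make_j_sequence <- function(n_codons) {
  safe <- setdiff(.all_codons(), c(STOP_CODONS, FW_CODONS))
  motif_at <- n_codons - 5L  # 0-based codon index of the F
  repeat {
    codons <- sample(safe, n_codons, replace = TRUE)
    codons[motif_at + 1L + 0:3] <- c("TTT", "GGC", "CAG", "GGA")  # F G Q G
    s <- paste(codons, collapse = "")
    aa <- vapply(0:2, function(f) as.character(translate_dna(s, f)), "")
    ok <- length(gregexpr("[FW]G.G", aa[1])[[1]]) == 1L &&
      gregexpr("[FW]G.G", aa[1])[[1]][1] != -1L &&
      !grepl("*", aa[1], fixed = TRUE) &&
      !grepl("[FW]G.G", aa[2]) && !grepl("[FW]G.G", aa[3])
    # also require the lesioned form (F -> L) to be motif-free everywhere
    codons2 <- codons
    codons2[motif_at + 1L] <- "CTT"
    s2 <- paste(codons2, collapse = "")
    aa2 <- vapply(0:2, function(f) as.character(translate_dna(s2, f)), "")
    ok2 <- !any(grepl("[FW]G.G", aa2)) && !grepl("*", aa2[1], fixed = TRUE)
    if (ok && ok2) return(s)
  }
}

#' Generate a synthetic allele library with CDR references
#'
#' V alleles are 94-103 codons with two planted cysteines and recorded
#' CDR1/CDR2 windows; roughly one V gene in five carries a second allele
#' (*02, three codon substitutions). D alleles are 10-25 bp, J alleles
#' 45-63 bp with a planted [FW]G.G motif. Deterministic under the seed.
#'
#' @param seed integer seed
#' @param locus locus name (determines allele name prefixes)
#' @param n_per_class named integer vector c(v =, d =, j =): number of
#'   records per class
#' @return list: library (\code{allele_library}), cdr_refs (data.frame)
#' @export
generate_library <- function(seed, locus = "IGH",
                             n_per_class = c(v = 25L, d = 6L, j = 9L)) {
  .with_seed(seed, {
    names(n_per_class) <- tolower(names(n_per_class))
    n_v <- n_per_class[["v"]]; n_d <- n_per_class[["d"]]
    n_j <- n_per_class[["j"]]
    names <- character(0); seqs <- character(0)
    cdr <- list()
    n_alt <- max(0L, n_v %/% 5L)
    n_genes_v <- n_v - n_alt
    safe <- setdiff(.all_codons(), c(STOP_CODONS, CYS_CODONS))
    for (g in seq_len(n_genes_v)) {
      ncod <- sample(94:103, 1L)
      s <- .make_v_sequence(ncod)
      gene <- sprintf("%sV%d", locus, g)
      cdr2_len <- sample(3:10, 1L)
      add_allele <- function(name, s) {
        names <<- c(names, name); seqs <<- c(seqs, s)
        cdr[[length(cdr) + 1L]] <<- data.frame(
          allele = name, aa_sequence = as.character(translate_dna(s, 0L)),
          cdr1_start = 26L, cdr1_end = 34L,
          cdr2_start = 50L, cdr2_end = 50L + cdr2_len,
          stringsAsFactors = FALSE)
      }
      add_allele(paste0(gene, "*01"), s)
      if (g <= n_alt) {
        codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
        idx <- sample(setdiff(seq_along(codons), c(22L, ncod - 6L)), 3L)
        for (i in idx) codons[i] <- sample(setdiff(safe, codons[i]), 1L)
        add_allele(paste0(gene, "*02"), paste(codons, collapse = ""))
      }
    }
    for (g in seq_len(n_d)) {
      repeat {
        s <- .rand_dna(sample(10:25, 1L))
        if (!s %in% seqs) break
      }
      names <- c(names, sprintf("%sD%d*01", locus, g))
      seqs <- c(seqs, s)
    }
    for (g in seq_len(n_j)) {
      s <- .make_j_sequence(sample(15:21, 1L))
      names <- c(names, sprintf("%sJ%d*01", locus, g))
      seqs <- c(seqs, s)
    }
    lib <- allele_library(names, seqs, functionality = "functional",
                          label = paste0("synthetic-", locus))
    cdr_refs <- do.call(rbind, cdr)
    list(library = lib, cdr_refs = cdr_refs)
  })
}

# independent truth rules: lesion -> (expected label, expected failed
# criterion). Derived from the classification rule table, not from the
# classifier implementation.
.truth_for_lesion <- function(class, lesion) {
  if (is.na(lesion) || lesion == "") {
    return(list(label = "functional", failed = ""))
  }
  map <- list(
    "V.no-ATG" = list("pseudogene", "leader"),
    "V.frameshift" = list("pseudogene", "v-frame"),
    "V.inframe-stop" = list("pseudogene", "inframe-stop"),
    "V.one-cysteine" = list("ORF", "two-cys"),
    "V.donor-break" = list("ORF", "donor-gt"),
    "V.acceptor-break" = list("ORF", "acceptor-ag"),
    "V.rss-break-3" = list("pseudogene", "rss"),
    "D.rss-break-5" = list("pseudogene", "rss-5"),
    "D.rss-break-3" = list("pseudogene", "rss-3"),
    "J.J-motif-break" = list("ORF", "j-motif"),
    "J.rss-break-5" = list("pseudogene", "rss"))
  key <- paste(class, lesion, sep = ".")
  if (is.null(map[[key]])) stop("unsupported lesion for class: ", key)
  list(label = map[[key]][[1]], failed = map[[key]][[2]])
}

.apply_v_lesion <- function(s, lesion) {
  if (is.na(lesion)) return(s)
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  if (lesion == "frameshift") {
    return(paste0(substr(s, 1, 29), substr(s, 31, nchar(s))))
  }
  if (lesion == "inframe-stop") { codons[40] <- "TAA" }
  if (lesion == "one-cysteine") { codons[22] <- "TCT" }
  paste(codons, collapse = "")
}

.scrub_window_atg <- function(seq, w0, w1, protect0) {
  # mutate every ATG whose start lies in [w0, w1) except at protect0
  repeat {
    win <- slice0(seq, w0, w1)
    hits <- gregexpr("ATG", win, fixed = TRUE)[[1]]
    if (hits[1] == -1L) break
    pos <- w0 + as.integer(hits) - 1L   # 0-based starts in seq
    pos <- pos[pos != protect0]
    if (!length(pos)) break
    for (p in pos) {
      substr(seq, p + 2L, p + 2L) <- "C"  # ATG -> ACG
    }
  }
  seq
}

#' Generate a synthetic locus with planted truth
#'
#' Lays down an upstream anchor gene, V units (leader + V + 3' RSS), D
#' units (5' RSS + D + 3' RSS), J units (5' RSS + J + donor GT) and a
#' downstream anchor, separated by random background. Lesions break
#' exactly one functionality criterion each; truth labels come from the
#' lesion plan (see \code{.truth_for_lesion}).
#'
#' @param library \code{allele_library} (only records of \code{locus} are
#'   used)
#' @param locus locus to build
#' @param seed integer seed
#' @param lesions named character vector: gene -> lesion
#' @param allele_choice named character vector: gene -> allele name
#'   (default *01)
#' @param overrides named list: gene -> list(name =, sequence =) planting
#'   a non-library (novel) sequence at that gene's slot
#' @param spacing_range inter-unit background length range (bp)
#' @param intron_len leader intron length
#' @param strand place the locus on "+" or "-" of the emitted contig
#' @param anchors optional list(up = c(name, seq), down = c(name, seq));
#'   generated when NULL
#' @param contig contig name
#' @param spacer_table 12/23 table
#' @param gc background GC fraction
#' @return list: assembly (named contig vector), truth (data.frame of
#'   planted segments, region-forward coordinates relative to the
#'   anchored region), spec (\code{region_spec}), anchors, region_offset
#' @export
generate_locus <- function(library, locus, seed, lesions = character(0),
                           allele_choice = character(0),
                           overrides = list(),
                           spacing_range = c(420L, 520L),
                           intron_len = 70L, strand = "+",
                           anchors = NULL, contig = "contig1",
                           spacer_table = default_spacer_table(),
                           gc = 0.42) {
  .with_seed(seed, {
    df <- as.data.frame(library)
    df <- df[df$locus == locus, ]
    genes <- unique(df$gene)
    cls_of <- df$segment_class[match(genes, df$gene)]
    genes <- genes[order(match(cls_of, c("V", "D", "J")),
                         match(genes, unique(df$gene)))]
    pre_pad <- .rand_dna(200L, gc); post_pad <- .rand_dna(200L, gc)
    if (is.null(anchors)) {
      anchors <- list(
        up = c(name = paste0("UP-", locus), seq = .rand_dna(400L, gc)),
        down = c(name = paste0("DOWN-", locus), seq = .rand_dna(400L, gc)))
    }
    parts <- character(0)
    cursor <- 0L
    add <- function(piece) {
      parts[[length(parts) + 1L]] <<- piece
      start <- cursor
      cursor <<- cursor + nchar(piece)
      start
    }
    spacing <- function() add(.rand_dna(sample(spacing_range[1]:
                                               spacing_range[2], 1L), gc))
    anchor_up_start <- add(anchors$up[["seq"]])
    region_offset <- anchor_up_start  # region starts at anchor outer edge
    truth <- list()
    scrub_jobs <- list()  # (w0, w1, protect) region-relative, filled per V
    for (g in genes) {
      cls <- df$segment_class[match(g, df$gene)]
      lesion <- if (g %in% names(lesions)) lesions[[g]] else NA_character_
      if (g %in% names(overrides)) {
        seg_name <- overrides[[g]]$name
        seg_seq <- toupper(overrides[[g]]$sequence)
        is_novel <- TRUE
      } else {
        an <- if (g %in% names(allele_choice)) allele_choice[[g]]
              else paste0(g, "*01")
        seg_seq <- df$sequence[df$name == an]
        if (!length(seg_seq)) stop("allele not in library: ", an)
        seg_name <- an
        is_novel <- FALSE
      }
      spacing()
      row <- list(locus = locus, segment_class = cls, gene = g,
                  allele_name = seg_name, lesion = lesion)
      if (cls == "V") {
        ld <- .leader_template(intron_len)
        if (!is.na(lesion) && lesion == "no-ATG")
          ld$lpart1 <- paste0("CTG", substr(ld$lpart1, 4, nchar(ld$lpart1)))
        if (!is.na(lesion) && lesion == "donor-break")
          ld$intron <- paste0("GG", substr(ld$intron, 3, nchar(ld$intron)))
        if (!is.na(lesion) && lesion == "acceptor-break")
          ld$intron <- paste0(substr(ld$intron, 1, nchar(ld$intron) - 2L),
                              "AA")
        seg_seq2 <- .apply_v_lesion(seg_seq, lesion)
        if (!identical(seg_seq2, seg_seq)) is_novel <- TRUE
        l1_start <- add(ld$lpart1)
        in_start <- add(ld$intron)
        l2_start <- add(ld$lpart2)
        v_start <- add(seg_seq2)
        sp <- .spacer_for(spacer_table, locus, "V", "3prime")
        hep <- if (!is.na(lesion) && lesion == "rss-break-3")
          RSS_SCRAMBLED_HEPTAMER else RSS_HEPTAMER_CONSENSUS
        rss_start <- add(paste0(hep, .rand_dna(sp, gc),
                                RSS_NONAMER_CONSENSUS))
        row <- c(row, list(start = v_start, end = cursor0 <- v_start +
                             nchar(seg_seq2),
                           leader_l1_start = l1_start,
                           leader_l1_end = in_start,
                           leader_intron_start = in_start,
                           leader_intron_end = l2_start,
                           leader_l2_start = l2_start,
                           leader_l2_end = v_start,
                           rss3_start = rss_start,
                           rss3_end = rss_start + 16L + sp,
                           rss5_start = NA_integer_,
                           rss5_end = NA_integer_))
        scrub_jobs[[length(scrub_jobs) + 1L]] <-
          list(w0 = v_start - 400L, w1 = v_start,
               protect = if (!is.na(lesion) && lesion == "no-ATG") -1L
                         else l1_start)
      } else if (cls == "D") {
        sp5 <- .spacer_for(spacer_table, locus, "D", "5prime")
        sp3 <- .spacer_for(spacer_table, locus, "D", "3prime")
        hep5 <- if (!is.na(lesion) && lesion == "rss-break-5")
          RSS_SCRAMBLED_HEPTAMER else RSS_HEPTAMER_CONSENSUS
        hep3 <- if (!is.na(lesion) && lesion == "rss-break-3")
          RSS_SCRAMBLED_HEPTAMER else RSS_HEPTAMER_CONSENSUS
        r5_start <- add(revcomp(paste0(hep5, .rand_dna(sp5, gc),
                                       RSS_NONAMER_CONSENSUS)))
        d_start <- add(seg_seq)
        r3_start <- add(paste0(hep3, .rand_dna(sp3, gc),
                               RSS_NONAMER_CONSENSUS))
        row <- c(row, list(start = d_start, end = d_start + nchar(seg_seq),
                           leader_l1_start = NA_integer_,
                           leader_l1_end = NA_integer_,
                           leader_intron_start = NA_integer_,
                           leader_intron_end = NA_integer_,
                           leader_l2_start = NA_integer_,
                           leader_l2_end = NA_integer_,
                           rss3_start = r3_start,
                           rss3_end = r3_start + 16L + sp3,
                           rss5_start = r5_start,
                           rss5_end = r5_start + 16L + sp5))
      } else {  # J
        sp5 <- .spacer_for(spacer_table, locus, "J", "5prime")
        hep5 <- if (!is.na(lesion) && lesion == "rss-break-5")
          RSS_SCRAMBLED_HEPTAMER else RSS_HEPTAMER_CONSENSUS
        if (!is.na(lesion) && lesion == "J-motif-break") {
          ncod <- nchar(seg_seq) %/% 3L
          motif_at <- ncod - 5L
          substr(seg_seq, motif_at * 3L + 1L, motif_at * 3L + 3L) <- "CTT"
          is_novel <- TRUE
        }
        r5_start <- add(revcomp(paste0(hep5, .rand_dna(sp5, gc),
                                       RSS_NONAMER_CONSENSUS)))
        j_start <- add(seg_seq)
        add("GT")   # donor splice site immediately 3' of the J
        row <- c(row, list(start = j_start, end = j_start + nchar(seg_seq),
                           leader_l1_start = NA_integer_,
                           leader_l1_end = NA_integer_,
                           leader_intron_start = NA_integer_,
                           leader_intron_end = NA_integer_,
                           leader_l2_start = NA_integer_,
                           leader_l2_end = NA_integer_,
                           rss3_start = NA_integer_,
                           rss3_end = NA_integer_,
                           rss5_start = r5_start,
                           rss5_end = r5_start + 16L + sp5))
      }
      tl <- .truth_for_lesion(cls, row$lesion)
      row$expected_label <- tl$label
      row$expected_failed <- tl$failed
      row$novel <- is_novel
      row$sequence <- if (cls == "V") .apply_v_lesion(seg_seq, lesion)
                      else if (cls == "J" && !is.na(lesion) &&
                               lesion == "J-motif-break") seg_seq
                      else seg_seq
      truth[[length(truth) + 1L]] <- row
    }
    spacing()
    add(anchors$down[["seq"]])
    region_end <- cursor
    contig_seq <- paste0(pre_pad, paste(parts, collapse = ""), post_pad)
    # scrub stray ATGs in each V leader window (contig coordinates:
    # region coordinate + nchar(pre_pad))
    off <- nchar(pre_pad)
    for (job in scrub_jobs) {
      w0 <- max(0L, job$w0) + off
      w1 <- job$w1 + off
      protect <- if (job$protect < 0L) -1L else job$protect + off
      contig_seq <- .scrub_window_atg(contig_seq, w0, w1, protect)
    }
    truth_df <- do.call(rbind, lapply(truth, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    # region coordinates are relative to the anchored region start
    coord_cols <- c("start", "end", "leader_l1_start", "leader_l1_end",
                    "leader_intron_start", "leader_intron_end",
                    "leader_l2_start", "leader_l2_end",
                    "rss3_start", "rss3_end", "rss5_start", "rss5_end")
    for (cc in coord_cols)
      truth_df[[cc]] <- truth_df[[cc]] - region_offset
    truth_df$strand <- "+"
    if (strand == "-") contig_seq <- revcomp(contig_seq)
    assembly <- stats::setNames(contig_seq, contig)
    spec <- region_spec(locus,
                        upstream_gene = c(name = anchors$up[["name"]],
                                          seq = anchors$up[["seq"]]),
                        downstream_gene = c(name = anchors$down[["name"]],
                                            seq = anchors$down[["seq"]]))
    list(assembly = assembly, truth = truth_df, spec = spec,
         anchors = anchors, region_offset = region_offset,
         region_length = region_end - region_offset, seed = seed)
  })
}

#' Write locus truth as GFF3 and TSV
#' @param locus_obj result of \code{\link{generate_locus}}
#' @param gff3,tsv output paths (NULL to skip)
#' @return invisibly, the truth data.frame
#' @export
write_locus_truth <- function(locus_obj, gff3 = NULL, tsv = NULL) {
  truth <- locus_obj$truth
  if (!is.null(tsv))
    utils::write.table(truth, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(gff3)) {
    con <- file(gff3, "w")
    on.exit(close(con))
    writeLines(c("##gff-version 3",
                 sprintf("# synthetic locus %s seed=%d",
                         truth$locus[1], locus_obj$seed)), con)
    writeLines(sprintf(
      "%s\tsynthetic\t%s_gene_segment\t%d\t%d\t.\t%s\t.\tID=%s;functionality=%s",
      truth$locus, truth$segment_class, truth$start + 1L, truth$end,
      truth$strand, truth$allele_name, truth$expected_label), con)
  }
  invisible(truth)
}

.default_lesion_plan <- function(library, locus) {
  df <- as.data.frame(library)
  df <- df[df$locus == locus, ]
  v_genes <- unique(df$gene[df$segment_class == "V"])
  d_genes <- unique(df$gene[df$segment_class == "D"])
  j_genes <- unique(df$gene[df$segment_class == "J"])
  n_alt <- sum(grepl("\\*02$", df$name))
  plan <- character(0)
  v_lesions <- c("no-ATG", "frameshift", "inframe-stop", "one-cysteine",
                 "donor-break", "acceptor-break", "rss-break-3")
  # reserve the last three V genes for planted novel variants
  n_les <- max(0L, min(length(v_lesions), length(v_genes) - n_alt - 3L))
  vs <- v_genes[seq(n_alt + 1L, length.out = n_les)]
  plan[vs] <- v_lesions[seq_along(vs)]
  if (length(d_genes) >= 2L) plan[d_genes[2L]] <- "rss-break-5"
  if (length(j_genes) >= 3L) {
    plan[j_genes[2L]] <- "J-motif-break"
    plan[j_genes[3L]] <- "rss-break-5"
  }
  plan
}

.mutate_one_codon_safe <- function(seq, codon_idx) {
  # single-nucleotide substitution in codon codon_idx (1-based), keeping
  # the codon outside stop/cys codons; deterministic given RNG state
  p0 <- (codon_idx - 1L) * 3L
  codon <- slice0(seq, p0, p0 + 3L)
  safe <- setdiff(.all_codons(), c(STOP_CODONS, CYS_CODONS))
  cand <- character(0)
  for (i in 1:3) for (b in c("A", "C", "G", "T")) {
    nc <- codon
    substr(nc, i, i) <- b
    if (nc != codon && nc %in% safe) cand <- c(cand, nc)
  }
  nc <- sample(cand, 1L)
  paste0(slice0(seq, 0L, p0), nc, slice0(seq, p0 + 3L, nchar(seq)))
}

#' Generate a multi-individual synthetic cohort with planted truth
#'
#' Two haplotypes per individual across several loci. Haplotypes vary by
#' random allele choice at multi-allele V genes; a default lesion plan
#' (shared by all haplotypes, i.e. germline) exercises every supported
#' functionality lesion; novel single-substitution V/J variants are
#' planted in configured carrier individuals. One individual is forced
#' homozygous at the last locus. Haplotype-2 contigs are emitted reverse
#' complemented to exercise orientation normalization.
#'
#' @param seed integer seed
#' @param n_individuals number of individuals (2 haplotypes each)
#' @param loci loci to simulate
#' @param n_per_class named list: locus -> c(v =, d =, j =)
#' @param novel_plan data.frame(locus, gene_index, carriers) where
#'   carriers is a comma-joined list of individual indices; NULL for the
#'   default plan (carrier sets of sizes 4, 2 and 1 on the first locus)
#' @param force_homozygous individual index made homozygous at the last
#'   locus (0 disables)
#' @return list: assemblies (named list "I<ind>#<hap>" of contig
#'   vectors), specs, library, cdr_refs, truth (segments, novel,
#'   zygosity), seed
#' @export
generate_cohort <- function(seed, n_individuals = 5L,
                            loci = c("IGH", "IGK", "TRB"),
                            n_per_class = NULL, novel_plan = NULL,
                            force_homozygous = 1L) {
  .with_seed(seed, {
    if (is.null(n_per_class)) {
      n_per_class <- list(IGH = c(v = 30L, d = 6L, j = 9L),
                          IGK = c(v = 33L, d = 0L, j = 12L),
                          TRB = c(v = 29L, d = 4L, j = 12L))
      n_per_class <- n_per_class[loci[loci %in% names(n_per_class)]]
      for (l in setdiff(loci, names(n_per_class)))
        n_per_class[[l]] <- c(v = 25L, d = 4L, j = 10L)
    }
    lib_seeds <- sample.int(1e6, length(loci))
    locus_seeds <- matrix(sample.int(1e7, 2L * n_individuals * length(loci)),
                          nrow = length(loci))
    libs <- list(); cdrs <- list()
    for (i in seq_along(loci)) {
      gl <- generate_library(lib_seeds[i], loci[i], n_per_class[[loci[i]]])
      libs[[i]] <- gl$library
      cdrs[[i]] <- gl$cdr_refs
    }
    library <- Reduce(function(a, b) {
      m <- rbind(as.data.frame(a), as.data.frame(b))
      .new_allele_library(m, "synthetic-cohort")
    }, libs)
    cdr_refs <- do.call(rbind, cdrs)
    lesion_plans <- lapply(loci, function(l)
      .default_lesion_plan(library, l))
    names(lesion_plans) <- loci
    # novel plan: default on first locus
    df <- as.data.frame(library)
    if (is.null(novel_plan)) {
      l1 <- loci[1]
      v_genes <- unique(df$gene[df$locus == l1 & df$segment_class == "V"])
      carriers <- list(seq_len(min(4L, n_individuals)),
                       seq_len(min(2L, n_individuals)), 1L)
      # the default lesion plan reserves the last three V genes
      nv <- length(v_genes)
      j_genes <- unique(df$gene[df$locus == l1 & df$segment_class == "J"])
      novel_plan <- data.frame(
        locus = l1,
        gene = c(v_genes[nv - 2:0],
                 j_genes[min(4L, length(j_genes))]),
        carriers = c(vapply(carriers, paste, "", collapse = ","),
                     paste(unique(pmin(c(2L, 3L), n_individuals)),
                           collapse = ",")),
        stringsAsFactors = FALSE)
    }
    # build novel variant sequences
    novel_plan$name <- NA_character_
    novel_plan$sequence <- NA_character_
    for (i in seq_len(nrow(novel_plan))) {
      g <- novel_plan$gene[i]
      base <- df$sequence[df$name == paste0(g, "*01")]
      cls <- df$segment_class[df$name == paste0(g, "*01")]
      j_ok <- function(s) {
        aa <- vapply(0:2, function(f) as.character(translate_dna(s, f)), "")
        m0 <- gregexpr("[FW]G.G", aa[1])[[1]]
        sum(m0 != -1L) == 1L && !grepl("*", aa[1], fixed = TRUE) &&
          !grepl("[FW]G.G", aa[2]) && !grepl("[FW]G.G", aa[3])
      }
      repeat {
        s <- .mutate_one_codon_safe(base, if (cls == "V") 30L else 2L)
        if (!s %in% df$sequence && (cls != "J" || j_ok(s))) break
      }
      novel_plan$sequence[i] <- s
      novel_plan$name[i] <- paste0(g, "*x", content_hash8(s))
    }
    # per-haplotype allele choices
    assemblies <- list(); specs <- list(); truth_rows <- list()
    anchors_by_locus <- list()
    hap_blueprints <- list()
    for (ind in seq_len(n_individuals)) for (hap in 1:2) {
      hap_id <- sprintf("I%d#%d", ind, hap)
      contigs <- character(0)
      for (li in seq_along(loci)) {
        loc <- loci[li]
        dfl <- df[df$locus == loc, ]
        alt_genes <- unique(sub("\\*02$", "",
                                dfl$name[grepl("\\*02$", dfl$name)]))
        lesioned <- names(lesion_plans[[loc]])
        choice <- character(0)
        for (g in setdiff(alt_genes, lesioned)) {
          choice[g] <- paste0(g, sample(c("*01", "*02"), 1L))
        }
        overrides <- list()
        forced <- force_homozygous > 0L && ind == force_homozygous &&
          loc == loci[length(loci)]
        np <- novel_plan[novel_plan$locus == loc, , drop = FALSE]
        for (i in seq_len(nrow(np))) {
          carr <- as.integer(strsplit(np$carriers[i], ",")[[1]])
          plant <- if (length(carr) == 1L) {
            ind %in% carr            # single carrier: both haplotypes
          } else {
            # forced-homozygous individuals plant on haplotype 1 so the
            # copied haplotype carries the variant too
            hap_target <- if (forced) 1L else 1L + (ind %% 2L)
            ind %in% carr && hap == hap_target
          }
          if (plant)
            overrides[[np$gene[i]]] <- list(name = np$name[i],
                                            sequence = np$sequence[i])
        }
        if (forced && hap == 2L) {
          bp <- hap_blueprints[[sprintf("I%d#1|%s", ind, loc)]]
          choice <- bp$choice; overrides <- bp$overrides
          lseed <- bp$seed
        } else {
          lseed <- locus_seeds[li, (ind - 1L) * 2L + hap]
        }
        hap_blueprints[[paste(hap_id, loc, sep = "|")]] <-
          list(choice = choice, overrides = overrides, seed = lseed)
        lo <- generate_locus(library, loc, seed = lseed,
                             lesions = lesion_plans[[loc]],
                             allele_choice = choice,
                             overrides = overrides,
                             strand = if (hap == 2L) "-" else "+",
                             anchors = anchors_by_locus[[loc]],
                             contig = paste0("chr_", loc))
        anchors_by_locus[[loc]] <- lo$anchors
        specs[[loc]] <- lo$spec
        contigs[paste0("chr_", loc)] <- lo$assembly[[1]]
        tr <- lo$truth
        tr$sample_id <- sprintf("I%d", ind)
        tr$haplotype <- as.character(hap)
        truth_rows[[length(truth_rows) + 1L]] <- tr
      }
      assemblies[[hap_id]] <- contigs
    }
    segments <- do.call(rbind, truth_rows)
    # expected support per novel sequence (distinct individuals)
    novel_truth <- unique(segments[segments$novel,
                                   c("locus", "segment_class", "gene",
                                     "sequence")])
    novel_truth$expected_support <- vapply(novel_truth$sequence,
      function(s) length(unique(segments$sample_id[segments$sequence == s])),
      0L)
    rownames(novel_truth) <- NULL
    # expected zygosity from blueprints
    zyg <- list()
    for (ind in seq_len(n_individuals)) for (loc in loci) {
      k1 <- sprintf("I%d#1|%s", ind, loc); k2 <- sprintf("I%d#2|%s", ind, loc)
      key <- function(k) {
        bp <- hap_blueprints[[k]]
        paste(paste(names(bp$choice), bp$choice, collapse = ";"),
              paste(names(bp$overrides), collapse = ";"))
      }
      zyg[[length(zyg) + 1L]] <- data.frame(
        individual = sprintf("I%d", ind), locus = loc,
        zygosity = if (identical(key(k1), key(k2))) "homozygous"
                   else "heterozygous", stringsAsFactors = FALSE)
    }
    list(assemblies = assemblies, specs = specs, library = library,
         cdr_refs = cdr_refs,
         truth = list(segments = segments, novel = novel_truth,
                      zygosity = do.call(rbind, zyg),
                      lesion_plans = lesion_plans,
                      novel_plan = novel_plan),
         seed = seed)
  })
}
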