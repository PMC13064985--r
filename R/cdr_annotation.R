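# Germline CDR1/CDR2 annotation by coordinate transfer from reference
# alleles with known CDR boundaries. References are supplied as a sidecar
# TSV (allele, aa_sequence, cdr1_start, cdr1_end, cdr2_start, cdr2_end;
# amino-acid coordinates, 0-based half-open) rather than fetched from any
# service.

#' Read a CDR reference sidecar TSV
#' @param path TSV with columns allele, aa_sequence, cdr1_start, cdr1_end,
#'   cdr2_start, cdr2_end
#' @return data.frame
#' @export
read_cdr_references <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("allele", "aa_sequence", "cdr1_start", "cdr1_end",
            "cdr2_start", "cdr2_end")
  if (!all(need %in% names(df))) stop("malformed CDR reference table")
  df
}

#' Write a CDR reference sidecar TSV
#' @param refs data.frame as in \code{\link{read_cdr_references}}
#' @param path output file
#' @export
write_cdr_references <- function(refs, path) {
  utils::write.table(refs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Transfer CDR1/CDR2 coordinates from a reference allele to a V segment
#'
#' The V translation is globally aligned to the reference amino-acid
#' sequence (match +1, mismatch -1, gap open -4, extend -1); reference
#' CDR columns are mapped through the alignment to query positions and
#' back-projected to region nucleotide coordinates. Returns NULL when the
#' V is untranslatable (frameshift), when no CDR-bearing reference exists,
#' or when the alignment places gaps across at least half of a CDR.
#'
#' @param v_annotation one-row V annotation
#' @param refs CDR reference data.frame; the reference is the CDR-bearing
#'   entry of the same gene, else the closest by amino-acid edit distance
#' @param params \code{\link{vdj_params}}
#' @return one-row data.frame (ann_id, cdr1_aa, cdr2_aa, nt coordinates,
#'   source_reference) or NULL
#' @export
transfer_cdr <- function(v_annotation, refs, params = vdj_params()) {
  v_seq <- toupper(v_annotation$observed_sequence)
  if (nchar(v_seq) %% 3L != 0L) return(NULL)  # untranslatable: no-frame
  v_aa <- as.character(translate_dna(v_seq, 0L))
  cand <- refs[!is.na(refs$cdr1_start), , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  ref_gene <- sub("\\*.*$", "", cand$allele)
  same <- cand[ref_gene == v_annotation$gene, , drop = FALSE]
  pool <- if (nrow(same)) same else cand
  d <- drop(utils::adist(v_aa, pool$aa_sequence))
  ref <- pool[order(d, pool$allele)[1L], ]
  al <- align_global(v_aa, ref$aa_sequence, match = 1, mismatch = -1,
                     gap_open = -4, gap_ext = -1)
  qa <- strsplit(al$a_aln, "")[[1]]; ra <- strsplit(al$b_aln, "")[[1]]
  qpos <- cumsum(qa != "-") - 1L   # query aa index at each column
  rpos <- cumsum(ra != "-") - 1L
  get_span <- function(rs, re) {
    cols <- which(rpos >= rs & rpos < re & ra != "-")
    gaps <- sum(qa[cols] == "-")
    if (gaps >= ceiling((re - rs) / 2)) return(NULL)
    qcols <- cols[qa[cols] != "-"]
    if (!length(qcols)) return(NULL)
    c(qpos[qcols[1]], qpos[qcols[length(qcols)]] + 1L)
  }
  s1 <- get_span(ref$cdr1_start, ref$cdr1_end)
  s2 <- get_span(ref$cdr2_start, ref$cdr2_end)
  if (is.null(s1) || is.null(s2)) return(NULL)
  aa_sub <- function(sp) substr(v_aa, sp[1] + 1L, sp[2])
  nt_region <- function(sp) {
    if (v_annotation$strand == "+") {
      c(v_annotation$start + 3L * sp[1], v_annotation$start + 3L * sp[2])
    } else {
      c(v_annotation$end - 3L * sp[2], v_annotation$end - 3L * sp[1])
    }
  }
  n1 <- nt_region(s1); n2 <- nt_region(s2)
  data.frame(ann_id = v_annotation$ann_id, locus = v_annotation$locus,
             gene = v_annotation$gene,
             cdr1_aa = aa_sub(s1), cdr2_aa = aa_sub(s2),
             cdr1_nt_start = n1[1], cdr1_nt_end = n1[2],
             cdr2_nt_start = n2[1], cdr2_nt_end = n2[2],
             source_reference = ref$allele, stringsAsFactors = FALSE)
}

#' Transfer CDRs for every eligible V annotation of a region
#' @param ann annotation data.frame
#' @param refs CDR references
#' @param region the \code{extracted_region} (unused; kept for signature
#'   stability)
#' @param params \code{\link{vdj_params}}
#' @return data.frame of CDR annotations (possibly empty)
#' @export
transfer_cdr_all <- function(ann, refs, region = NULL,
                             params = vdj_params()) {
  out <- list()
  for (i in which(ann$segment_class == "V")) {
    r <- transfer_cdr(ann[i, ], refs, params)
    if (!is.null(r)) out[[length(out) + 1L]] <- r
  }
  if (!length(out)) {
    return(data.frame(ann_id = character(0), locus = character(0),
                      gene = character(0), cdr1_aa = character(0),
                      cdr2_aa = character(0), cdr1_nt_start = integer(0),
                      cdr1_nt_end = integer(0), cdr2_nt_start = integer(0),
                      cdr2_nt_end = integer(0),
                      source_reference = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# --- progressive profile alignment of short peptides ---------------------

.profile_align <- function(seqs) {
  # seqs already ordered; returns character vector of aligned strings
  prof <- strsplit(seqs[1], "")[[1]]
  aligned <- list(prof)
  consensus <- function(rows) {
    L <- length(rows[[1]])
    vapply(seq_len(L), function(j) {
      col <- vapply(rows, `[[`, "", j)
      col_ng <- col[col != "-"]
      if (!length(col_ng)) return("-")
      tb <- table(col_ng)
      names(tb)[which.max(tb)]
    }, "")
  }
  for (s in seqs[-1]) {
    cons <- paste(consensus(aligned), collapse = "")
    al <- align_global(s, cons, match = 1, mismatch = -1,
                       gap_open = -4, gap_ext = -1)
    sa <- strsplit(al$a_aln, "")[[1]]
    ca <- strsplit(al$b_aln, "")[[1]]
    # columns where the profile consensus gained a gap -> insert gap
    # columns into every existing aligned row
    newrows <- lapply(aligned, function(row) {
      out <- character(length(ca)); k <- 0L
      for (j in seq_along(ca)) {
        if (ca[j] == "-") out[j] <- "-"
        else { k <- k + 1L; out[j] <- row[k] }
      }
      out
    })
    newrows[[length(newrows) + 1L]] <- sa
    aligned <- newrows
  }
  vapply(aligned, paste, "", collapse = "")
}

#' Summarize CDR sequences per locus
#'
#' Unique CDR amino-acid sequences per locus and CDR are progressively
#' aligned (guide order: length, then sequence) and summarized as
#' per-column residue frequency matrices plus length distributions.
#'
#' @param cdr_annotations data.frame from \code{\link{transfer_cdr_all}}
#' @return nested list: [[locus]][[cdr1|cdr2]] with elements sequences,
#'   alignment, freq (residues x columns), lengths
#' @export
summarize_cdr <- function(cdr_annotations) {
  stopifnot(nrow(cdr_annotations) >= 1L)
  out <- list()
  for (loc in unique(cdr_annotations$locus)) {
    sub <- cdr_annotations[cdr_annotations$locus == loc, ]
    for (which_cdr in c("cdr1_aa", "cdr2_aa")) {
      seqs <- unique(sub[[which_cdr]])
      seqs <- seqs[nzchar(seqs)]
      if (!length(seqs)) next
      seqs <- seqs[order(nchar(seqs), seqs)]
      aligned <- .profile_align(seqs)
      mat <- do.call(rbind, strsplit(aligned, ""))
      residues <- sort(unique(as.vector(mat)))
      freq <- vapply(seq_len(ncol(mat)), function(j) {
        tab <- table(factor(mat[, j], levels = residues))
        as.numeric(tab) / nrow(mat)
      }, numeric(length(residues)))
      freq <- matrix(freq, nrow = length(residues),
                     dimnames = list(residues, NULL))
      out[[loc]][[sub("_aa$", "", which_cdr)]] <-
        list(sequences = seqs, alignment = aligned, freq = freq,
             lengths = nchar(seqs))
    }
  }
  out
}
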