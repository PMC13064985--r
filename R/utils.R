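# Small shared helpers. Coordinates are 0-based half-open throughout the
# package internals; GFF3 output converts to 1-based inclusive.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Slice a sequence by 0-based half-open coordinates
#' @param s character scalar (DNA/AA string)
#' @param start,end 0-based half-open interval
#' @return substring
#' @keywords internal
slice0 <- function(s, start, end) substr(s, start + 1L, end)

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case preserved as
#'   uppercase on output is not forced; input is complemented as-is).
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || nchar(s) == 0L) return(s)
    intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", s))))
  }, character(1), USE.NAMES = FALSE)
}

.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

#' Translate a DNA string (standard nuclear code)
#'
#' Trailing partial codons are dropped. Codons containing N (or any
#' non-ACGT base) translate to "X": they are treated as neither stop nor
#' cysteine by downstream criteria, and the result carries a
#' \code{contains_n} attribute.
#'
#' @param s DNA string
#' @param frame 0, 1 or 2: offset of the first codon
#' @return amino-acid string ("*" for stops), attribute \code{contains_n}
#' @export
translate_dna <- function(s, frame = 0L) {
  s <- toupper(s)
  n <- nchar(s) - frame
  ncod <- n %/% 3L
  if (ncod <= 0L) {
    out <- ""
    attr(out, "contains_n") <- FALSE
    return(out)
  }
  starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L
  codons <- substring(s, starts, starts + 2L)
  tab <- .codon_table()
  aa <- unname(tab[codons])
  bad <- is.na(aa)
  aa[bad] <- "X"
  out <- paste(aa, collapse = "")
  attr(out, "contains_n") <- any(bad)
  out
}

#' Read FASTA into a named character vector
#' @param path FASTA file
#' @return named character vector (uppercased sequences)
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- names(set)
  out
}

#' Write a named character vector as wrapped FASTA
#' @param seqs named character vector
#' @param path output file
#' @param width line width (default 60)
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Write gene-segment annotations as GFF3
#'
#' Coordinates are converted from the package's 0-based half-open internal
#' convention to GFF3 1-based inclusive.
#'
#' @param ann annotation data.frame (see \code{\link{call_alleles}})
#' @param path output file
#' @param source source column value
#' @export
write_annotation_gff3 <- function(ann, path, source = "vdjgermline") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(ann)) {
    type <- paste0(ann$segment_class, "_gene_segment")
    attrs <- sprintf("ID=%s;Name=%s;gene=%s;novel=%s;functionality=%s",
                     ann$ann_id, ann$allele_call, ann$gene,
                     tolower(as.character(ann$novel)),
                     ann$functionality %||% "")
    lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     ann$region_ref, source, type,
                     ann$start + 1L, ann$end, ann$strand, attrs)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write annotations as TSV
#' @param ann annotation data.frame
#' @param path output file
#' @export
write_annotation_tsv <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
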