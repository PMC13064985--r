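# Allele library parsing, merging and nearest-allele search.
#
# A library is a data.frame of class "allele_library" with one row per
# allele: name ("IGHV1-2*02"), gene, allele_suffix, segment_class (V/D/J),
# locus (IGH/IGK/IGL/TRA/TRB/TRG/TRD), sequence (uppercase ACGTN),
# functionality (functional/ORF/pseudogene/unknown), source (library
# label), dup_group (shared id for identical sequences under different
# names). Attributes: label, n_skipped, rejected (per-record report).

LOCI <- c("IGH", "IGK", "IGL", "TRA", "TRB", "TRG", "TRD")
.name_rx <- "^(IGH|IGK|IGL|TRA|TRB|TRG|TRD)([VDJ])"

.parse_allele_name <- function(name) {
  m <- regmatches(name, regexec(.name_rx, name))[[1]]
  if (length(m) == 0L) return(NULL)
  star <- regexpr("*", name, fixed = TRUE)
  gene <- if (star > 0) substr(name, 1, star - 1L) else name
  suffix <- if (star > 0) substr(name, star + 1L, nchar(name)) else ""
  list(gene = gene, allele_suffix = suffix, locus = m[2], segment_class = m[3])
}

.parse_functionality <- function(x) {
  x <- toupper(gsub("[][()]", "", trimws(x %||% "")))
  if (x %in% c("F", "FUNCTIONAL")) "functional"
  else if (x == "ORF") "ORF"
  else if (x %in% c("P", "PSEUDO", "PSEUDOGENE")) "pseudogene"
  else "unknown"
}

.new_allele_library <- function(df, label, n_skipped = 0L,
                                rejected = NULL) {
  df$dup_group <- match(df$sequence, unique(df$sequence))
  rownames(df) <- NULL
  structure(df, class = c("allele_library", "data.frame"),
            label = label, n_skipped = n_skipped,
            rejected = rejected %||%
              data.frame(name = character(0), reason = character(0)))
}

#' Parse a V/D/J allele library from FASTA
#'
#' Accepts pipe-delimited headers (\code{name|species|functionality}, the
#' IMGT reference-set dialect, in any field order as long as one field is a
#' parseable allele name) as well as bare \code{>name} headers. Sequences
#' are uppercased; records with characters outside A/C/G/T/N are rejected
#' and reported; records whose header carries no parseable allele name are
#' skipped and counted. Identical sequences under different names share a
#' \code{dup_group} id.
#'
#' @param path FASTA file
#' @param label library label recorded as each record's source
#' @return an \code{allele_library} data.frame
#' @export
parse_library <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty library")
  seqs <- read_fasta(path)
  if (length(seqs) == 0L) stop("empty library")
  rows <- list(); rejected <- list(); n_skipped <- 0L
  for (i in seq_along(seqs)) {
    header <- names(seqs)[i]
    fields <- trimws(strsplit(header, "|", fixed = TRUE)[[1]])
    parsed <- NULL; name <- NA_character_; fun_field <- ""
    for (f in fields) {
      p <- .parse_allele_name(f)
      if (!is.null(p)) { parsed <- p; name <- f; break }
    }
    if (is.null(parsed)) {
      n_skipped <- n_skipped + 1L
      message("skipping record with unparseable header: ", header)
      next
    }
    if (length(fields) >= 3L) fun_field <- fields[3L]
    s <- toupper(seqs[[i]])
    if (nchar(s) == 0L || grepl("[^ACGTN]", s)) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(name = name, reason = "non-ACGTN sequence")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = name, gene = parsed$gene, allele_suffix = parsed$allele_suffix,
      segment_class = parsed$segment_class, locus = parsed$locus,
      sequence = s, functionality = .parse_functionality(fun_field),
      source = label, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("empty library")
  df <- do.call(rbind, rows)
  if (anyDuplicated(df$name)) {
    dup <- df$name[duplicated(df$name)]
    warning("duplicate allele names in library: ",
            paste(unique(dup), collapse = ", "))
  }
  .new_allele_library(df, label, n_skipped,
                      if (length(rejected)) do.call(rbind, rejected) else NULL)
}

#' Construct an allele library from vectors (programmatic use)
#' @param name allele names ("IGHV1-2*02" form)
#' @param sequence DNA sequences
#' @param functionality declared functionality (default "unknown")
#' @param source source label
#' @param label library label
#' @return an \code{allele_library}
#' @export
allele_library <- function(name, sequence, functionality = "unknown",
                           source = label, label = "library") {
  parsed <- lapply(name, .parse_allele_name)
  if (any(vapply(parsed, is.null, logical(1))))
    stop("unparseable allele name(s)")
  df <- data.frame(
    name = name,
    gene = vapply(parsed, `[[`, "", "gene"),
    allele_suffix = vapply(parsed, `[[`, "", "allele_suffix"),
    segment_class = vapply(parsed, `[[`, "", "segment_class"),
    locus = vapply(parsed, `[[`, "", "locus"),
    sequence = toupper(sequence),
    functionality = rep_len(functionality, length(name)),
    source = rep_len(source, length(name)), stringsAsFactors = FALSE)
  .new_allele_library(df, label)
}

#' @export
print.allele_library <- function(x, ...) {
  cat(sprintf("Allele library '%s': %d records (%s)\n",
              attr(x, "label"), nrow(x),
              paste(sprintf("%s=%d", names(table(x$segment_class)),
                            as.integer(table(x$segment_class))),
                    collapse = ", ")))
  cat(sprintf("  loci: %s; duplicate-sequence groups: %d; skipped: %d\n",
              paste(unique(x$locus), collapse = ","),
              sum(table(x$dup_group) > 1L), attr(x, "n_skipped")))
  invisible(x)
}

#' Merge two allele libraries by sequence identity
#'
#' Sequence-identity equivalence classes are computed over the union; one
#' representative is kept per class (from \code{a} when the class occurs in
#' \code{a}, else from \code{b}); the provenance of both source labels is
#' retained on shared representatives. Merging is exact string equality
#' after uppercasing (libraries are stored in coding orientation).
#'
#' @param a,b \code{allele_library} objects
#' @return merged \code{allele_library}; size |a| + |b| - shared classes
#' @export
merge_libraries <- function(a, b) {
  la <- attr(a, "label") %||% "a"; lb <- attr(b, "label") %||% "b"
  if (!nrow(a) && !nrow(b))
    return(.new_allele_library(as.data.frame(a), paste0(la, "+", lb)))
  all <- rbind(as.data.frame(a), as.data.frame(b))
  all$dup_group <- NULL
  keys <- unique(all$sequence)
  keep <- all[match(keys, all$sequence), , drop = FALSE]
  src <- vapply(keys, function(s)
    paste(unique(all$source[all$sequence == s]), collapse = ","), "")
  keep$source <- unname(src)
  .new_allele_library(keep, paste0(la, "+", lb))
}

#' Find the library allele closest to a query sequence
#'
#' Minimizes unit-cost global edit distance; ties are broken by higher
#' identity, then smaller length difference, then lexicographically
#' smallest name, so nearest-allele assignment (and hence novelty calling)
#' is fully deterministic.
#'
#' @param query DNA string
#' @param lib \code{allele_library}
#' @param class_filter restrict to one segment class ("V","D","J"); NULL
#'   searches all records
#' @return list with \code{record} (one-row data.frame) and
#'   \code{transcript} (see \code{\link{edit_transcript}})
#' @export
closest_allele <- function(query, lib, class_filter = NULL) {
  stopifnot(nchar(query) > 0L)
  df <- as.data.frame(lib)
  if (!is.null(class_filter)) df <- df[df$segment_class == class_filter, ]
  if (!nrow(df)) stop("empty class")
  query <- toupper(query)
  d <- drop(utils::adist(query, df$sequence))
  cand <- which(d == min(d))
  if (length(cand) > 1L) {
    tr <- lapply(cand, function(i) edit_transcript(query, df$sequence[i]))
    ident <- vapply(tr, `[[`, 0, "identity")
    lend <- abs(nchar(df$sequence[cand]) - nchar(query))
    ord <- order(-ident, lend, df$name[cand])
    best <- cand[ord[1L]]
    transcript <- tr[[ord[1L]]]
  } else {
    best <- cand
    transcript <- edit_transcript(query, df$sequence[best])
  }
  list(record = df[best, , drop = FALSE], transcript = transcript)
}

#' Write a merged-library report TSV
#' @param lib \code{allele_library}
#' @param path output file
#' @export
write_library_report <- function(lib, path) {
  df <- as.data.frame(lib)[, c("name", "source", "dup_group",
                               "segment_class", "locus")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an allele library as FASTA (name|source|functionality headers)
#' @param lib \code{allele_library}
#' @param path output file
#' @export
write_library_fasta <- function(lib, path) {
  fun_code <- c(functional = "F", ORF = "ORF", pseudogene = "P",
                unknown = "unknown")
  seqs <- lib$sequence
  names(seqs) <- sprintf("%s|%s|%s", lib$name, lib$source,
                         fun_code[lib$functionality])
  write_fasta(seqs, path)
}
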