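# Alignment wrappers around the compiled Gotoh aligner, plus BTOP-style
# edit transcripts. A transcript always reads query-vs-target: runs of
# matches are integers, substitutions are query/target base pairs, a gap
# in the target is "q-" (insertion in query), a gap in the query is "-t".

#' Global affine-gap alignment of two sequences
#'
#' @param a,b sequences (query, target); any single-letter alphabet
#' @param match,mismatch,gap_open,gap_ext scoring; a gap of length g costs
#'   \code{gap_open + (g-1)*gap_ext}
#' @return list with \code{score}, aligned strings \code{a_aln}/\code{b_aln},
#'   \code{matches}, \code{columns}
#' @export
align_global <- function(a, b, match = 1, mismatch = -1,
                         gap_open = -2, gap_ext = -1) {
  cpp_align(a, b, match, mismatch, gap_open, gap_ext, FALSE)
}

#' Glocal alignment: query end-to-end inside a target window
#'
#' The query is aligned completely; the target may have unaligned flanks.
#' \code{t_start}/\code{t_end} give the 0-based half-open aligned target
#' block.
#'
#' @inheritParams align_global
#' @return list with \code{score}, \code{t_start}, \code{t_end}, aligned
#'   strings, \code{matches}, \code{columns}
#' @export
align_glocal <- function(a, b, match = 1, mismatch = -1,
                         gap_open = -2, gap_ext = -1) {
  cpp_align(a, b, match, mismatch, gap_open, gap_ext, TRUE)
}

#' BTOP-style edit string from an alignment
#' @param a_aln,b_aln equal-length aligned strings (query, target)
#' @return single BTOP-like string
#' @export
btop_from_alignment <- function(a_aln, b_aln) {
  qa <- strsplit(a_aln, "")[[1]]
  ta <- strsplit(b_aln, "")[[1]]
  out <- character(0)
  run <- 0L
  for (i in seq_along(qa)) {
    if (qa[i] == ta[i] && qa[i] != "-") {
      run <- run + 1L
    } else {
      if (run > 0L) { out <- c(out, as.character(run)); run <- 0L }
      out <- c(out, paste0(qa[i], ta[i]))
    }
  }
  if (run > 0L) out <- c(out, as.character(run))
  paste(out, collapse = "")
}

#' Parse a BTOP string into an operation table
#' @param btop BTOP-like string
#' @return data.frame with columns op ("match","sub","ins","del"), len,
#'   q (query base) and t (target base)
#' @export
parse_btop <- function(btop) {
  toks <- regmatches(btop, gregexpr("[0-9]+|[A-Za-z*-][A-Za-z*-]", btop))[[1]]
  op <- character(length(toks)); len <- integer(length(toks))
  q <- t <- rep(NA_character_, length(toks))
  for (i in seq_along(toks)) {
    if (grepl("^[0-9]+$", toks[i])) {
      op[i] <- "match"; len[i] <- as.integer(toks[i])
    } else {
      qc <- substr(toks[i], 1, 1); tc <- substr(toks[i], 2, 2)
      q[i] <- qc; t[i] <- tc; len[i] <- 1L
      op[i] <- if (tc == "-") "ins" else if (qc == "-") "del" else "sub"
    }
  }
  data.frame(op = op, len = len, q = q, t = t, stringsAsFactors = FALSE)
}

#' Replay a BTOP transcript on the target to reconstruct the query
#' @param btop BTOP-like string (query-vs-target)
#' @param target target sequence the transcript was computed against
#' @return reconstructed query string
#' @export
replay_btop <- function(btop, target) {
  ops <- parse_btop(btop)
  tpos <- 0L
  out <- character(0)
  for (i in seq_len(nrow(ops))) {
    if (ops$op[i] == "match") {
      out <- c(out, slice0(target, tpos, tpos + ops$len[i]))
      tpos <- tpos + ops$len[i]
    } else if (ops$op[i] == "sub") {
      out <- c(out, ops$q[i]); tpos <- tpos + 1L
    } else if (ops$op[i] == "ins") {
      out <- c(out, ops$q[i])
    } else {  # del: target base absent from query
      tpos <- tpos + 1L
    }
  }
  paste(out, collapse = "")
}

#' Unit-cost edit transcript between query and target
#'
#' Levenshtein-optimal global alignment (unit costs); the returned
#' transcript replayed on the target reconstructs the query.
#'
#' @param query,target DNA strings
#' @return list: \code{btop}, \code{distance}, \code{identity}
#'   (matches/aligned columns), \code{matches}, \code{columns}
#' @export
edit_transcript <- function(query, target) {
  al <- cpp_align(query, target, 0, -1, -1, -1, FALSE)
  transcript_from_alignment(al$a_aln, al$b_aln)
}

transcript_from_alignment <- function(a_aln, b_aln) {
  n <- nchar(a_aln)
  qa <- strsplit(a_aln, "")[[1]]; ta <- strsplit(b_aln, "")[[1]]
  matches <- sum(qa == ta & qa != "-")
  list(btop = btop_from_alignment(a_aln, b_aln),
       distance = n - matches,
       identity = if (n > 0) matches / n else 0,
       matches = matches, columns = n)
}

#' Stable 8-hex-digit content hash of a sequence
#'
#' FNV-1a (32-bit) over the uppercased sequence; identical across runs and
#' platforms, used for provisional novel-allele names.
#' @param s character scalar
#' @return 8 lowercase hex digits
#' @export
content_hash8 <- function(s) cpp_hash8(toupper(s))
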