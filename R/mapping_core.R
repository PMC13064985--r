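# Seed-and-extend placement of a query sequence inside a subject sequence.
# Exact k-mer seeds locate candidate diagonals; a glocal affine alignment
# of the full query against a padded local window scores each candidate.
# Queries shorter than 16 bp (short D segments) are scanned exhaustively
# by exact matching, which at the default D identity threshold is the
# admissible hit set anyway.

#' Build an exact k-mer index of a subject sequence
#' @param s subject DNA string
#' @param k k-mer length
#' @return index list used by \code{\link{find_placements}}
#' @export
kmer_index <- function(s, k = 11L) {
  n <- nchar(s)
  if (n < k) {
    return(list(env = new.env(hash = TRUE, parent = emptyenv()),
                uk = character(0), pos = list(), k = k, n = n))
  }
  starts <- seq_len(n - k + 1L)
  kms <- substring(s, starts, starts + k - 1L)
  uk <- unique(kms)
  id <- match(kms, uk)
  pos <- split(starts, factor(id, levels = seq_along(uk)))
  names(pos) <- uk
  env <- list2env(pos, hash = TRUE, size = 2L * length(uk),
                  parent = emptyenv())
  list(env = env, uk = uk, pos = pos, k = k, n = n)
}

.cluster_starts <- function(cand, slack) {
  cand <- sort(unique(cand))
  if (!length(cand)) return(integer(0))
  grp <- cumsum(c(1L, diff(cand) > slack))
  vapply(split(cand, grp), function(g) as.integer(round(stats::median(g))),
         integer(1))
}

# q is always given in coding orientation; for strand "-" the search uses
# revcomp(q) against the forward subject and reports forward coordinates.
.placements_one_strand <- function(q, s, idx, strand, params, min_identity) {
  qs <- if (strand == "-") revcomp(q) else q
  L <- nchar(q); n <- idx$n; k <- idx$k
  hits <- list()
  if (L < 16L) {
    # exhaustive exact scan
    m <- gregexpr(qs, s, fixed = TRUE)[[1]]
    if (m[1] != -1L) {
      for (p in as.integer(m)) {
        hits[[length(hits) + 1L]] <- list(
          start = p - 1L, end = p - 1L + L, strand = strand,
          identity = 1.0, score = L * params$match,
          matches = L, columns = L, btop = as.character(L),
          observed = q)
      }
    }
    return(hits)
  }
  starts_q <- unique(c(seq(1L, L - k + 1L, by = k), L - k + 1L))
  kms <- substring(qs, starts_q, starts_q + k - 1L)
  found <- mget(kms, envir = idx$env, ifnotfound = list(NULL))
  cand <- integer(0)
  for (j in seq_along(found)) {
    if (!is.null(found[[j]]))
      cand <- c(cand, found[[j]] - starts_q[j] + 1L)
  }
  cand <- cand[cand > -L & cand <= n]
  slack <- max(4L, as.integer(ceiling(params$band_frac * L)))
  centers <- .cluster_starts(cand, slack)
  # window padding: the seed-diagonal spread bounds the net indel shift,
  # so the DP window can be much tighter than the band cap
  spread <- if (length(cand)) diff(range(cand)) else 0L
  slack <- min(slack, max(8L, spread + 8L))
  seen <- character(0)
  for (d in centers) {
    # fast path: exact occurrence at the seeded diagonal
    if (d >= 1L && d + L - 1L <= n && substr(s, d, d + L - 1L) == qs) {
      key <- paste(d - 1L, d - 1L + L, sep = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      hits[[length(hits) + 1L]] <- list(
        start = d - 1L, end = d - 1L + L, strand = strand,
        identity = 1.0, score = L * params$match, matches = L,
        columns = L, btop = as.character(L), observed = q)
      next
    }
    # substitution-only fast path: Hamming comparison on the diagonal
    if (d >= 1L && d + L - 1L <= n) {
      tgt <- substr(s, d, d + L - 1L)
      mism <- which(charToRaw(qs) != charToRaw(tgt))
      # a few substitutions cannot be beaten by a gapped alignment under
      # affine costs; take the diagonal alignment directly
      if (length(mism) > 0L && length(mism) <= 3L &&
          (L - length(mism)) / L >= min_identity) {
        key <- paste(d - 1L, d - 1L + L, sep = ":")
        if (key %in% seen) next
        seen <- c(seen, key)
        qa <- qs; ta <- tgt
        observed <- if (strand == "-") revcomp(tgt) else tgt
        if (strand == "-") { qa <- q; ta <- observed }
        hits[[length(hits) + 1L]] <- list(
          start = d - 1L, end = d - 1L + L, strand = strand,
          identity = (L - length(mism)) / L,
          score = (L - length(mism)) * params$match +
            length(mism) * params$mismatch,
          matches = L - length(mism), columns = L,
          btop = btop_from_alignment(qa, ta), observed = observed)
        next
      }
    }
    ws <- max(1L, d - slack)
    we <- min(n, d + L - 1L + slack)
    if (we - ws + 1L < ceiling(L * min_identity)) next
    window <- substr(s, ws, we)
    al <- cpp_align(qs, window, params$match, params$mismatch,
                    params$gap_open, params$gap_ext, TRUE)
    if (al$columns == 0L) next
    identity <- al$matches / al$columns
    if (identity < min_identity) next
    h_start <- ws - 1L + al$t_start   # 0-based on subject
    h_end <- ws - 1L + al$t_end
    key <- paste(h_start, h_end, sep = ":")
    if (key %in% seen) next
    seen <- c(seen, key)
    observed_fwd <- slice0(s, h_start, h_end)
    if (strand == "-") {
      observed <- revcomp(observed_fwd)
      # transcript in coding orientation: re-derive from q vs observed
      al2 <- cpp_align(q, observed, params$match, params$mismatch,
                       params$gap_open, params$gap_ext, FALSE)
      btop <- btop_from_alignment(al2$a_aln, al2$b_aln)
      matches <- al2$matches; columns <- al2$columns
      score <- al2$score
      identity <- matches / columns
      if (identity < min_identity) next
    } else {
      observed <- observed_fwd
      btop <- btop_from_alignment(al$a_aln, al$b_aln)
      matches <- al$matches; columns <- al$columns
      score <- al$score
    }
    hits[[length(hits) + 1L]] <- list(
      start = h_start, end = h_end, strand = strand,
      identity = identity, score = score,
      matches = matches, columns = columns, btop = btop,
      observed = observed)
  }
  hits
}

#' Locate all placements of a query on both strands of a subject
#'
#' @param query DNA string (coding orientation)
#' @param subject subject DNA string (forward strand)
#' @param idx optional precomputed \code{\link{kmer_index}} of the subject
#' @param min_identity minimum identity (matches / aligned columns)
#' @param params \code{\link{vdj_params}}
#' @return data.frame: start, end (0-based half-open on the forward
#'   subject), strand, identity, score, matches, columns, btop, observed
#'   (strand-corrected sequence); sorted by identity then score descending
#' @export
find_placements <- function(query, subject, idx = NULL,
                            min_identity = 0.9, params = vdj_params()) {
  query <- toupper(query)
  if (is.null(idx)) {
    subject <- toupper(subject)
    idx <- kmer_index(subject, params$k_seed)
  }
  # with a supplied index the subject is assumed uppercase already
  fw <- .placements_one_strand(query, subject, idx, "+", params, min_identity)
  rc <- .placements_one_strand(query, subject, idx, "-", params, min_identity)
  hits <- c(fw, rc)
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), identity = numeric(0),
                      score = numeric(0), matches = integer(0),
                      columns = integer(0), btop = character(0),
                      observed = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(hits, function(h)
    data.frame(start = h$start, end = h$end, strand = h$strand,
               identity = h$identity, score = h$score, matches = h$matches,
               columns = h$columns, btop = h$btop, observed = h$observed,
               stringsAsFactors = FALSE)))
  df <- df[order(-df$identity, -df$score, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}
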