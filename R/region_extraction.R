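# Locus extraction via conserved flanking-gene anchors, and reference-
# guided scaffolding of fragmented regions.
#
# An extracted region is a list of class "extracted_region": sample_id,
# haplotype, locus, contig, start, end (0-based half-open on the forward
# strand of the contig), strand, sequence (locus-forward orientation),
# complete, scaffolded, components (data.frame of source pieces).

#' Define a locus extraction specification
#'
#' @param locus locus name (IGH, IGK, IGL, TRA, TRB, TRG, TRD)
#' @param upstream_gene,downstream_gene named character vectors
#'   \code{c(name =, seq =)}: anchor gene name and DNA sequence. The
#'   upstream gene precedes the V segments in locus-forward orientation.
#' @param max_region_length maximum anchored span in bp
#' @return a \code{region_spec} list
#' @export
region_spec <- function(locus, upstream_gene, downstream_gene,
                        max_region_length = 5e6) {
  stopifnot(nchar(upstream_gene[["seq"]]) > 0,
            nchar(downstream_gene[["seq"]]) > 0,
            max_region_length > nchar(upstream_gene[["seq"]]),
            max_region_length > nchar(downstream_gene[["seq"]]))
  structure(list(locus = locus, upstream_gene = upstream_gene,
                 downstream_gene = downstream_gene,
                 max_region_length = max_region_length),
            class = "region_spec")
}

.new_region <- function(sequence, locus, contig = "scaffold", start = 0L,
                        end = nchar(sequence), strand = "+",
                        complete = FALSE, scaffolded = FALSE,
                        components = NULL, sample_id = "", haplotype = "") {
  structure(list(sample_id = sample_id, haplotype = haplotype,
                 locus = locus, contig = contig, start = start, end = end,
                 strand = strand, sequence = sequence, complete = complete,
                 scaffolded = scaffolded,
                 components = components %||%
                   data.frame(contig = contig, start = start, end = end,
                              strand = strand, stringsAsFactors = FALSE)),
            class = "extracted_region")
}

#' @export
print.extracted_region <- function(x, ...) {
  cat(sprintf(
    "Extracted region %s (%s|%s): %s:%d-%d (%s), %d bp, complete=%s, scaffolded=%s\n",
    x$locus, x$sample_id, x$haplotype, x$contig, x$start, x$end, x$strand,
    nchar(x$sequence), x$complete, x$scaffolded))
  invisible(x)
}

#' Locate a flanking-gene anchor in an assembly
#'
#' All placements with identity at or above \code{min_identity} on either
#' strand, sorted by identity descending. Coordinates are 0-based
#' half-open on the forward strand of each contig.
#'
#' @param assembly named character vector of contig sequences
#' @param anchor anchor DNA sequence (>= 30 bp)
#' @param min_identity minimum placement identity
#' @param params \code{\link{vdj_params}}
#' @return data.frame: contig, start, end, strand, identity
#' @export
locate_anchor <- function(assembly, anchor, min_identity = 0.85,
                          params = vdj_params()) {
  if (nchar(anchor) < 30L) stop("anchor shorter than 30 bp")
  out <- list()
  for (ct in names(assembly)) {
    hits <- find_placements(anchor, assembly[[ct]],
                            min_identity = min_identity, params = params)
    if (nrow(hits))
      out[[length(out) + 1L]] <- data.frame(
        contig = ct, start = hits$start, end = hits$end,
        strand = hits$strand, identity = hits$identity,
        stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(-df$identity, df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Extract an IG/TCR locus delimited by two flanking-gene anchors
#'
#' When both anchors lie on one contig within \code{max_region_length} and
#' in a consistent orientation, the region spans from the outer edge of
#' the upstream anchor to the outer edge of the downstream anchor (anchors
#' included) and is reported in locus-forward orientation (minus-strand
#' loci are reverse-complemented). Otherwise the best partial region is
#' returned with \code{complete = FALSE} and all anchor placements listed
#' in \code{components}.
#'
#' @param assembly named character vector of contigs
#' @param spec a \code{\link{region_spec}}
#' @param params \code{\link{vdj_params}}
#' @param sample_id,haplotype identifiers stored on the region
#' @return an \code{extracted_region}
#' @export
extract_region <- function(assembly, spec, params = vdj_params(),
                           sample_id = "", haplotype = "") {
  assembly <- vapply(assembly, toupper, "")
  up <- locate_anchor(assembly, spec$upstream_gene[["seq"]],
                      params$anchor_min_identity, params)
  dn <- locate_anchor(assembly, spec$downstream_gene[["seq"]],
                      params$anchor_min_identity, params)
  if (!nrow(up) && !nrow(dn)) {
    stop("locus not detected: upstream anchor '",
         spec$upstream_gene[["name"]], "' not found; downstream anchor '",
         spec$downstream_gene[["name"]], "' not found")
  }
  # enumerate compatible pairs
  best <- NULL
  if (nrow(up) && nrow(dn)) {
    for (i in seq_len(nrow(up))) for (j in seq_len(nrow(dn))) {
      if (up$contig[i] != dn$contig[j]) next
      if (up$strand[i] != dn$strand[j]) next
      if (up$strand[i] == "+") {
        if (up$start[i] >= dn$start[j]) next
        span <- dn$end[j] - up$start[i]
      } else {
        if (dn$start[j] >= up$start[i]) next
        span <- up$end[i] - dn$start[j]
      }
      if (span > spec$max_region_length) next
      qual <- up$identity[i] + dn$identity[j]
      if (is.null(best) || qual > best$qual)
        best <- list(i = i, j = j, qual = qual)
    }
  }
  if (!is.null(best)) {
    u <- up[best$i, ]; d <- dn[best$j, ]
    ct <- u$contig
    if (u$strand == "+") { rs <- u$start; re <- d$end }
    else { rs <- d$start; re <- u$end }
    seq_fwd <- slice0(assembly[[ct]], rs, re)
    seq_out <- if (u$strand == "-") revcomp(seq_fwd) else seq_fwd
    return(.new_region(seq_out, spec$locus, contig = ct, start = rs,
                       end = re, strand = u$strand, complete = TRUE,
                       sample_id = sample_id, haplotype = haplotype))
  }
  # partial: best single anchor; report whole carrying contig
  partials <- rbind(
    if (nrow(up)) cbind(up, anchor = spec$upstream_gene[["name"]]),
    if (nrow(dn)) cbind(dn, anchor = spec$downstream_gene[["name"]]))
  bp <- partials[which.max(partials$identity), ]
  ct <- bp$contig
  seq_fwd <- assembly[[ct]]
  seq_out <- if (bp$strand == "-") revcomp(seq_fwd) else seq_fwd
  .new_region(seq_out, spec$locus, contig = ct, start = 0L,
              end = nchar(seq_fwd), strand = bp$strand, complete = FALSE,
              components = data.frame(contig = partials$contig,
                                      start = partials$start,
                                      end = partials$end,
                                      strand = partials$strand,
                                      stringsAsFactors = FALSE),
              sample_id = sample_id, haplotype = haplotype)
}

#' Reference-guided scaffolding of fragmented locus contigs
#'
#' Each contig is anchored to the reference region by its exact unique
#' shared k-mers; contigs are ordered by the median reference position of
#' their anchors, oriented by majority anchor strand, and joined with
#' \code{gap_n} N characters. Contigs without unique anchors are excluded
#' with a warning.
#'
#' @param contigs named character vector (>= 2 candidate contigs)
#' @param reference_region reference locus sequence (DNA string)
#' @param gap_n number of N characters between joined contigs
#' @param k anchor k-mer length
#' @param min_anchors minimum unique shared k-mers to place a contig
#' @param locus locus label stored on the result
#' @return an \code{extracted_region} with \code{scaffolded = TRUE} and
#'   per-component offsets in \code{components}
#' @export
scaffold_fragments <- function(contigs, reference_region, gap_n = 100L,
                               k = 21L, min_anchors = 5L, locus = "") {
  if (length(contigs) < 2L) stop("cannot scaffold: need >= 2 contigs")
  reference_region <- toupper(reference_region)
  ridx <- kmer_index(reference_region, k)
  cnt <- lengths(ridx$pos)
  uniq_ref <- ridx$uk[cnt == 1L]
  placed <- list()
  for (nm in names(contigs)) {
    s <- toupper(contigs[[nm]])
    n <- nchar(s)
    if (n < k) { warning("contig ", nm, " shorter than k; excluded"); next }
    starts <- seq_len(n - k + 1L)
    kms <- substring(s, starts, starts + k - 1L)
    tab <- table(kms)
    uniq_c <- names(tab)[tab == 1L]
    use <- kms %in% uniq_c
    fw_hit <- use & (kms %in% uniq_ref)
    rc_kms <- revcomp(kms[use])
    rc_hit_idx <- which(use)[rc_kms %in% uniq_ref]
    n_fw <- sum(fw_hit); n_rc <- length(rc_hit_idx)
    if (max(n_fw, n_rc) < min_anchors) {
      warning("contig ", nm, " has no unique reference anchors; excluded")
      next
    }
    if (n_fw >= n_rc) {
      refpos <- unlist(mget(kms[fw_hit], envir = ridx$env),
                       use.names = FALSE)
      strand <- "+"
    } else {
      refpos <- unlist(mget(rc_kms[rc_kms %in% uniq_ref], envir = ridx$env),
                       use.names = FALSE)
      strand <- "-"
    }
    placed[[length(placed) + 1L]] <- list(
      name = nm, seq = if (strand == "-") revcomp(s) else s,
      strand = strand, mid = stats::median(refpos), len = n)
  }
  if (length(placed) < 2L) stop("cannot scaffold: <2 anchorable contigs")
  ord <- order(vapply(placed, `[[`, 0, "mid"))
  placed <- placed[ord]
  gap <- strrep("N", gap_n)
  seqs <- vapply(placed, `[[`, "", "seq")
  scaffold <- paste(seqs, collapse = gap)
  off <- cumsum(c(0L, utils::head(nchar(seqs), -1L) + gap_n))
  comp <- data.frame(
    contig = vapply(placed, `[[`, "", "name"),
    start = off, end = off + nchar(seqs),
    strand = vapply(placed, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  .new_region(scaffold, locus, contig = "scaffold", start = 0L,
              end = nchar(scaffold), strand = "+", complete = FALSE,
              scaffolded = TRUE, components = comp)
}
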