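# Placement of library alleles on an extracted region, greedy overlap
# resolution, and known/novel allele calling.

.class_threshold <- function(class, params) {
  if (class == "D") params$min_identity_d else params$min_identity_vj
}

#' Map library alleles onto an extracted region
#'
#' For each library record, all placements on both strands with identity
#' at or above the class threshold are emitted. V/J records are seeded by
#' exact k-mers and extended by affine glocal alignment of the full allele
#' against a padded local window; D records shorter than 16 bp are scanned
#' exhaustively. Hits flush against a region edge with incomplete query
#' coverage are flagged "edge-truncated".
#'
#' @param region an \code{extracted_region}
#' @param lib an \code{allele_library}
#' @param params \code{\link{vdj_params}}
#' @return data.frame of segment hits: segment_class, gene, best_allele,
#'   start, end, strand (region-relative, 0-based half-open), identity,
#'   score, distance, btop, observed_sequence, flags
#' @export
map_segments <- function(region, lib, params = vdj_params()) {
  s <- toupper(region$sequence)
  n <- nchar(s)
  idx <- kmer_index(s, params$k_seed)
  rows <- list()
  df <- as.data.frame(lib)
  for (i in seq_len(nrow(df))) {
    cls <- df$segment_class[i]
    thr <- .class_threshold(cls, params)
    hits <- find_placements(df$sequence[i], s, idx = idx,
                            min_identity = thr, params = params)
    if (!nrow(hits)) next
    if (cls == "D") {
      hits <- hits[hits$end - hits$start >= params$min_len_d, , drop = FALSE]
    }
    if (!nrow(hits)) next
    qlen <- nchar(df$sequence[i])
    for (h in seq_len(nrow(hits))) {
      flags <- character(0)
      # coverage = aligned query bases / query length (columns minus
      # target-only gap columns)
      ops <- parse_btop(hits$btop[h])
      q_aligned <- hits$columns[h] - sum(ops$len[ops$op == "del"])
      qcov <- q_aligned / qlen
      at_edge <- hits$start[h] == 0L || hits$end[h] == n
      if (cls != "D" && qcov < 0.95) {
        if (at_edge) flags <- c(flags, "edge-truncated") else next
      }
      rows[[length(rows) + 1L]] <- list(
        segment_class = cls, gene = df$gene[i], best_allele = df$name[i],
        start = hits$start[h], end = hits$end[h], strand = hits$strand[h],
        identity = hits$identity[h], score = hits$score[h],
        distance = hits$columns[h] - hits$matches[h],
        btop = hits$btop[h], observed_sequence = hits$observed[h],
        flags = paste(flags, collapse = ";"))
    }
  }
  if (!length(rows)) return(.empty_hits())
  col <- function(nm) unlist(lapply(rows, `[[`, nm), use.names = FALSE)
  data.frame(
    segment_class = col("segment_class"), gene = col("gene"),
    best_allele = col("best_allele"),
    start = as.integer(col("start")), end = as.integer(col("end")),
    strand = col("strand"), identity = col("identity"),
    score = col("score"), distance = as.integer(col("distance")),
    btop = col("btop"), observed_sequence = col("observed_sequence"),
    flags = col("flags"), stringsAsFactors = FALSE)
}

.empty_hits <- function() {
  data.frame(segment_class = character(0), gene = character(0),
             best_allele = character(0), start = integer(0),
             end = integer(0), strand = character(0), identity = numeric(0),
             score = numeric(0), distance = integer(0), btop = character(0),
             observed_sequence = character(0), flags = character(0),
             stringsAsFactors = FALSE)
}

#' Resolve overlapping segment hits
#'
#' Greedy selection by descending score: a hit is kept iff its interval
#' overlaps no already-kept hit by more than \code{overlap_tol} bp.
#' Score ties are broken by higher identity, then longer hit, then smaller
#' start, then lexicographic allele name, so the selection is
#' deterministic.
#'
#' @param hits data.frame from \code{\link{map_segments}} (one region)
#' @param overlap_tol maximum tolerated overlap in bp
#' @return the retained subset, sorted by start
#' @export
resolve_overlaps <- function(hits, overlap_tol = 10L) {
  if (!nrow(hits)) return(hits)
  ord <- order(-hits$score, -hits$identity, -(hits$end - hits$start),
               hits$start, hits$best_allele)
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  ks <- ke <- integer(0)
  for (i in seq_len(nrow(hits))) {
    ov <- pmax(0L, pmin(ke, hits$end[i]) - pmax(ks, hits$start[i]))
    if (!length(ov) || max(ov) <= overlap_tol) {
      keep[i] <- TRUE
      ks <- c(ks, hits$start[i]); ke <- c(ke, hits$end[i])
    }
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call known and novel alleles from resolved hits
#'
#' A hit whose observed sequence is identical to a library allele of the
#' same class is annotated as that allele. Other hits are flagged novel
#' with a provisional name \code{gene*x<hash8>} where hash8 is a stable
#' content hash of the observed sequence (identical across samples, runs
#' and platforms, so cohort confirmation counts line up). Edge-truncated
#' hits are excluded from novel-allele calling.
#'
#' @param hits resolved hits (one region)
#' @param lib \code{allele_library}
#' @param region optional \code{extracted_region} supplying ids
#' @return annotation data.frame: hit columns plus sample_id, haplotype,
#'   locus, region_ref, ann_id, allele_call, novel, provisional_name
#' @export
call_alleles <- function(hits, lib, region = NULL) {
  ann <- hits
  ann$sample_id <- if (!is.null(region)) region$sample_id else ""
  ann$haplotype <- if (!is.null(region)) region$haplotype else ""
  ann$locus <- if (!is.null(region)) region$locus else ""
  ann$region_ref <- if (!is.null(region))
    paste(region$sample_id, region$haplotype, region$locus, sep = "|")
    else "region"
  ann$complete <- if (!is.null(region)) region$complete else NA
  if (!nrow(ann)) {
    ann$ann_id <- ann$allele_call <- ann$provisional_name <- character(0)
    ann$novel <- logical(0)
    return(ann)
  }
  df <- as.data.frame(lib)
  novel <- logical(nrow(ann)); call <- character(nrow(ann))
  prov <- rep(NA_character_, nrow(ann))
  for (i in seq_len(nrow(ann))) {
    same <- df$segment_class == ann$segment_class[i] &
      df$sequence == ann$observed_sequence[i]
    truncated <- grepl("edge-truncated", ann$flags[i])
    if (any(same)) {
      exact <- df$name[same]
      call[i] <- if (ann$best_allele[i] %in% exact) ann$best_allele[i]
                 else sort(exact)[1L]
      novel[i] <- FALSE
    } else if (truncated) {
      call[i] <- ann$best_allele[i]
      novel[i] <- FALSE
    } else {
      novel[i] <- TRUE
      prov[i] <- paste0(ann$gene[i], "*x",
                        content_hash8(ann$observed_sequence[i]))
      call[i] <- prov[i]
    }
  }
  ann$allele_call <- call
  ann$novel <- novel
  ann$provisional_name <- prov
  ann$ann_id <- sprintf("%s|%s|%s:%d-%d(%s)", ann$region_ref,
                        ann$segment_class, ann$gene, ann$start, ann$end,
                        ann$strand)
  ann
}
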