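# Recombination signal sequence (RSS) extraction and adaptive motif
# modelling. Each RSS is a heptamer / spacer / nonamer with the heptamer
# abutting the coding end on the segment-proximal side. RSS are stored in
# a canonical orientation: reading away from the segment, heptamer first.
# On the genomic forward strand a 3' RSS therefore reads
# heptamer-spacer-nonamer, while a 5' RSS is the reverse complement of
# that reading placed upstream of the segment.

RSS_HEPTAMER_CONSENSUS <- "CACAGTG"
RSS_NONAMER_CONSENSUS <- "ACAAAAACC"
.BASES <- c("A", "C", "G", "T")

#' Default 12/23 spacer-class table
#'
#' Spacer classes per locus / segment class / side following the standard
#' organisation of the human IG and TCR loci; editable and replaceable by
#' the caller.
#'
#' @return data.frame: locus, segment_class, side, spacer_class
#' @export
default_spacer_table <- function() {
  tab <- rbind(
    c("IGH", "V", "3prime", 23), c("IGH", "D", "5prime", 12),
    c("IGH", "D", "3prime", 12), c("IGH", "J", "5prime", 23),
    c("IGK", "V", "3prime", 12), c("IGK", "J", "5prime", 23),
    c("IGL", "V", "3prime", 23), c("IGL", "J", "5prime", 12),
    c("TRA", "V", "3prime", 23), c("TRA", "J", "5prime", 12),
    c("TRB", "V", "3prime", 23), c("TRB", "D", "5prime", 12),
    c("TRB", "D", "3prime", 23), c("TRB", "J", "5prime", 12),
    c("TRG", "V", "3prime", 23), c("TRG", "J", "5prime", 12),
    c("TRD", "V", "3prime", 23), c("TRD", "D", "5prime", 12),
    c("TRD", "D", "3prime", 23), c("TRD", "J", "5prime", 12))
  data.frame(locus = tab[, 1], segment_class = tab[, 2], side = tab[, 3],
             spacer_class = as.integer(tab[, 4]), stringsAsFactors = FALSE)
}

.spacer_for <- function(spacer_table, locus, class, side) {
  i <- which(spacer_table$locus == locus &
             spacer_table$segment_class == class &
             spacer_table$side == side)
  if (!length(i)) return(NA_integer_)
  spacer_table$spacer_class[i[1]]
}

.rss_sides <- function(class) {
  switch(class, V = "3prime", J = "5prime", D = c("5prime", "3prime"))
}

#' Extract the RSS flanking an annotated segment
#'
#' V segments carry one 3' RSS, J segments one 5' RSS, D segments both.
#' The heptamer is taken immediately adjacent to the coding boundary
#' (offset 0); once motif models exist, offsets 0..\code{edge_slack} and
#' spacer lengths within \code{spacer_tol} of the tabulated class are
#' scanned and the best-scoring combination kept. Segments with
#' insufficient flank return records flagged "truncated-flank" with
#' \code{pass = FALSE}.
#'
#' @param region \code{extracted_region}
#' @param annotation one-row annotation
#' @param spacer_table see \code{\link{default_spacer_table}}
#' @param params \code{\link{vdj_params}}
#' @param models optional trained models (\code{\link{train_rss_models}})
#' @return data.frame of RSS records: ann_id, side, heptamer, spacer,
#'   spacer_len, nonamer, spacer_class, start, end, score_hep, p_hep,
#'   score_non, p_non, pass, flags
#' @export
extract_rss <- function(region, annotation, spacer_table =
                          default_spacer_table(),
                        params = vdj_params(), models = NULL,
                        .as_rows = FALSE, .region_upper = NULL,
                        .region_rc = NULL) {
  s <- .region_upper %||% toupper(region$sequence)
  L <- nchar(s)
  # coding-oriented region and segment coordinates
  if (annotation$strand == "+") {
    rc_region <- s; a0 <- annotation$start; a1 <- annotation$end
  } else {
    rc_region <- .region_rc %||% revcomp(s)
    a0 <- L - annotation$end
    a1 <- L - annotation$start
  }
  rows <- list()
  for (side in .rss_sides(annotation$segment_class)) {
    sp <- .spacer_for(spacer_table, annotation$locus,
                      annotation$segment_class, side)
    if (is.na(sp)) next
    tol <- params$spacer_tol
    need <- 7L + sp + tol + 9L + params$edge_slack
    # candidate (offset, spacer_len) grid; offset 0 / exact spacer until
    # models are available
    offsets <- if (is.null(models)) 0L else 0L:params$edge_slack
    spacers <- if (is.null(models)) sp else (sp - tol):(sp + tol)
    avail <- if (side == "3prime") nchar(rc_region) - a1 else a0
    if (avail < 7L + sp - tol + 9L) {
      rows[[length(rows) + 1L]] <- .rss_row(annotation, side, "", "", "",
                                            sp, NA_integer_, NA_integer_,
                                            flags = "truncated-flank")
      next
    }
    best <- NULL
    for (off in offsets) {
      for (spl in spacers) {
        tot <- off + 7L + spl + 9L
        if (tot > avail) next
        if (side == "3prime") {
          blk <- slice0(rc_region, a1 + off, a1 + tot)
        } else {
          blk <- revcomp(slice0(rc_region, a0 - tot, a0 - off))
        }
        hep <- substr(blk, 1L, 7L)
        spc <- substr(blk, 8L, 7L + spl)
        non <- substr(blk, 8L + spl, 16L + spl)
        sc <- 0
        if (!is.null(models)) {
          mh <- .model_for(models, annotation$locus,
                           annotation$segment_class, side, "heptamer",
                           params)
          mn <- .model_for(models, annotation$locus,
                           annotation$segment_class, side, "nonamer",
                           params)
          if (!is.null(mh)) sc <- sc + score_pwm(mh, hep)
          if (!is.null(mn)) sc <- sc + score_pwm(mn, non)
        }
        cand <- list(off = off, spl = spl, hep = hep, spc = spc, non = non,
                     sc = sc)
        if (is.null(best) || sc > best$sc) best <- cand
      }
    }
    if (is.null(best)) {
      rows[[length(rows) + 1L]] <- .rss_row(annotation, side, "", "", "",
                                            sp, NA_integer_, NA_integer_,
                                            flags = "truncated-flank")
      next
    }
    tot <- best$off + 7L + best$spl + 9L
    if (side == "3prime") { c0 <- a1 + best$off; c1 <- a1 + tot }
    else { c0 <- a0 - tot; c1 <- a0 - best$off }
    # back to forward-strand region coordinates
    if (annotation$strand == "+") { r0 <- c0; r1 <- c1 }
    else { r0 <- L - c1; r1 <- L - c0 }
    rows[[length(rows) + 1L]] <- .rss_row(annotation, side, best$hep,
                                          best$spc, best$non, sp, r0, r1)
  }
  if (.as_rows) return(rows)
  .rss_rows_to_df(rows)
}

.rss_row <- function(annotation, side, hep, spc, non, spacer_class,
                     start, end, flags = "") {
  list(ann_id = annotation$ann_id, locus = annotation$locus,
       segment_class = annotation$segment_class, side = side,
       heptamer = hep, spacer = spc, spacer_len = nchar(spc),
       nonamer = non, spacer_class = as.integer(spacer_class),
       start = start, end = end,
       score_hep = NA_real_, p_hep = NA_real_,
       score_non = NA_real_, p_non = NA_real_,
       pass = if (nzchar(flags)) FALSE else NA,
       flags = flags)
}

.rss_rows_to_df <- function(rows) {
  if (!length(rows)) return(.empty_rss())
  col <- function(nm) unlist(lapply(rows, `[[`, nm), use.names = FALSE)
  data.frame(ann_id = col("ann_id"), locus = col("locus"),
             segment_class = col("segment_class"), side = col("side"),
             heptamer = col("heptamer"), spacer = col("spacer"),
             spacer_len = as.integer(col("spacer_len")),
             nonamer = col("nonamer"),
             spacer_class = as.integer(col("spacer_class")),
             start = as.integer(col("start")), end = as.integer(col("end")),
             score_hep = col("score_hep"), p_hep = col("p_hep"),
             score_non = col("score_non"), p_non = col("p_non"),
             pass = col("pass"), flags = col("flags"),
             stringsAsFactors = FALSE)
}

.empty_rss <- function() {
  data.frame(ann_id = character(0), locus = character(0),
             segment_class = character(0), side = character(0),
             heptamer = character(0), spacer = character(0),
             spacer_len = integer(0), nonamer = character(0),
             spacer_class = integer(0), start = integer(0),
             end = integer(0), score_hep = numeric(0), p_hep = numeric(0),
             score_non = numeric(0), p_non = numeric(0), pass = logical(0),
             flags = character(0), stringsAsFactors = FALSE)
}

#' Build a position weight matrix from equal-length sequences
#'
#' Column probabilities are \code{(count + pseudocount) /
#' (n + 4 * pseudocount)}. Sequences containing N (or other non-ACGT
#' characters) are excluded and counted.
#'
#' @param seqs character vector of equal-length DNA strings
#' @param pseudocount nonnegative pseudocount
#' @param background length-4 base distribution (A,C,G,T)
#' @return object of class \code{pwm}: probs (L x 4), background,
#'   pseudocount, n_training, n_excluded
#' @export
build_pwm <- function(seqs, pseudocount = 0.5,
                      background = rep(0.25, 4)) {
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGT]", seqs)
  n_excluded <- sum(bad)
  seqs <- seqs[!bad]
  if (!length(seqs)) stop("no training RSS")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("training sequences must have equal length")
  mat <- do.call(rbind, strsplit(seqs, ""))
  probs <- t(apply(mat, 2, function(col) {
    cnt <- table(factor(col, levels = .BASES))
    (as.numeric(cnt) + pseudocount) / (length(col) + 4 * pseudocount)
  }))
  colnames(probs) <- .BASES
  lo <- log2(sweep(probs, 2, background, "/"))
  structure(list(probs = probs, background = background,
                 pseudocount = pseudocount, n_training = length(seqs),
                 n_excluded = n_excluded, log_odds = lo),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM: %d positions, %d training sequences, consensus %s\n",
              nrow(x$probs), x$n_training, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param pwm a \code{pwm}
#' @return character scalar
#' @export
pwm_consensus <- function(pwm) {
  paste(.BASES[apply(pwm$probs, 1, which.max)], collapse = "")
}

#' Log-odds score of a sequence under a PWM
#'
#' Sum over positions of log2(p/background). Positions with N contribute
#' the background-weighted mean column log-odds and set an attribute
#' \code{had_n}.
#'
#' @param pwm a \code{pwm}
#' @param seq DNA string of the PWM's length
#' @return score in bits
#' @export
score_pwm <- function(pwm, seq) {
  seq <- toupper(seq)
  L <- nrow(pwm$probs)
  stopifnot(nchar(seq) == L)
  lo <- pwm$log_odds %||% log2(sweep(pwm$probs, 2, pwm$background, "/"))
  b <- match(strsplit(seq, "")[[1]], .BASES)
  had_n <- anyNA(b)
  if (!had_n) {
    sc <- sum(lo[cbind(seq_len(L), b)])
  } else {
    sc <- 0
    for (i in seq_len(L)) {
      sc <- sc + if (is.na(b[i])) sum(pwm$background * lo[i, ])
                 else lo[i, b[i]]
    }
  }
  attr(sc, "had_n") <- had_n
  sc
}

#' Exact null distribution of PWM scores under the background
#'
#' For L with 4^L <= 65536 the distribution is computed by full
#' enumeration of all words (each weighted by its background
#' probability); otherwise by discretized dynamic programming over
#' positions with bin width \code{bin} bits.
#'
#' @param pwm a \code{pwm}
#' @param bin DP bin width in bits
#' @param method "auto" enumerates when 4^L <= 65536 and uses the DP
#'   otherwise; "enumerate" and "dp" force a route
#' @return list: scores (sorted), probs, exact (logical)
#' @export
pwm_score_distribution <- function(pwm, bin = 0.001,
                                   method = c("auto", "enumerate", "dp")) {
  method <- match.arg(method)
  lo <- log2(sweep(pwm$probs, 2, pwm$background, "/"))
  L <- nrow(lo)
  if (method == "enumerate" || (method == "auto" && 4^L <= 65536)) {
    scores <- 0; probs <- 1
    for (i in seq_len(L)) {
      scores <- as.vector(outer(scores, lo[i, ], "+"))
      probs <- as.vector(outer(probs, pwm$background, "*"))
    }
    ord <- order(scores)
    return(list(scores = scores[ord], probs = probs[ord], exact = TRUE))
  }
  # DP over binned scores
  q <- round(lo / bin)
  lo_min <- sum(apply(q, 1, min)); lo_max <- sum(apply(q, 1, max))
  width <- lo_max - lo_min + 1L
  dist <- numeric(width)  # index = binned score - lo_min + 1
  # initialise with position 1
  part_min <- cumsum(apply(q, 1, min))
  part_max <- cumsum(apply(q, 1, max))
  dist_off <- part_min[1]
  dist <- numeric(part_max[1] - part_min[1] + 1L)
  for (b in 1:4) {
    k <- q[1, b] - dist_off + 1L
    dist[k] <- dist[k] + pwm$background[b]
  }
  for (i in 2:L) {
    new_off <- part_min[i]
    new <- numeric(part_max[i] - part_min[i] + 1L)
    nz <- which(dist > 0)
    for (b in 1:4) {
      idx <- (nz + dist_off - 1L) + q[i, b] - new_off + 1L
      new[idx] <- new[idx] + dist[nz] * pwm$background[b]
    }
    dist <- new; dist_off <- new_off
  }
  nz <- which(dist > 0)
  list(scores = (nz + dist_off - 1L) * bin, probs = dist[nz],
       exact = FALSE)
}

#' Score a sequence and compute its exact p-value
#'
#' p = Pr(score(X) >= s) for X with independent positions drawn from the
#' background. Monotone nonincreasing in s; p(min score) = 1.
#'
#' @param pwm a \code{pwm}
#' @param seq DNA string of the PWM's length
#' @param bin DP bin width (see \code{\link{pwm_score_distribution}})
#' @return list: score_bits, p_value
#' @export
scan_score <- function(pwm, seq, bin = 0.001) {
  sc <- score_pwm(pwm, seq)
  dist <- attr(pwm, "null_dist")
  if (is.null(dist)) dist <- pwm_score_distribution(pwm, bin)
  # per-position rounding displaces a binned score by at most L*bin/2
  L <- nrow(pwm$probs)
  thr <- if (dist$exact) sc - 1e-9 else sc - L * bin / 2 - 1e-9
  p <- sum(dist$probs[dist$scores >= thr])
  p <- min(max(p, 0), 1)
  list(score_bits = as.numeric(sc), p_value = p)
}

.model_key <- function(locus, class, side, element)
  paste(locus, class, side, element, sep = "|")

.model_for <- function(models, locus, class, side, element, params) {
  m <- models[[.model_key(locus, class, side, element)]]
  if (!is.null(m) && m$n_training >= params$min_train) return(m)
  p <- models[[.model_key(locus, "*", "*", element)]]
  if (!is.null(p) && p$n_training >= params$min_train) return(p)
  NULL
}

#' Train RSS motif models from preliminarily functional segments
#'
#' Heptamer and nonamer are modelled separately per (locus, segment
#' class, side) stratum; duplicate (allele sequence, RSS sequence) pairs
#' are collapsed before counting so that each unique allele/RSS
#' combination contributes once. A pooled per-locus model per element is
#' also built as fallback for sparse strata. Null score distributions are
#' cached on each model.
#'
#' @param annotations annotation data.frame with functionality labels
#' @param rss_records RSS records from \code{\link{extract_rss}}
#' @param params \code{\link{vdj_params}}
#' @return named list of \code{pwm} models
#' @export
train_rss_models <- function(annotations, rss_records,
                             params = vdj_params()) {
  fun_ids <- annotations$ann_id[annotations$functionality == "functional"]
  tr <- rss_records[rss_records$ann_id %in% fun_ids &
                    !nzchar(rss_records$flags), , drop = FALSE]
  if (!nrow(tr)) return(list())
  obs <- annotations$observed_sequence[match(tr$ann_id, annotations$ann_id)]
  key <- paste(obs, tr$side, tr$heptamer, tr$spacer, tr$nonamer)
  tr <- tr[!duplicated(key), , drop = FALSE]
  models <- list()
  add_model <- function(key, seqs) {
    seqs <- seqs[nzchar(seqs)]
    if (!length(seqs)) return()
    m <- tryCatch(build_pwm(seqs, params$pwm_pseudocount),
                  error = function(e) NULL)
    if (is.null(m)) return()
    attr(m, "null_dist") <- pwm_score_distribution(m)
    models[[key]] <<- m
  }
  strata <- unique(tr[, c("locus", "segment_class", "side")])
  for (i in seq_len(nrow(strata))) {
    sel <- tr$locus == strata$locus[i] &
      tr$segment_class == strata$segment_class[i] &
      tr$side == strata$side[i]
    add_model(.model_key(strata$locus[i], strata$segment_class[i],
                         strata$side[i], "heptamer"), tr$heptamer[sel])
    add_model(.model_key(strata$locus[i], strata$segment_class[i],
                         strata$side[i], "nonamer"), tr$nonamer[sel])
  }
  for (loc in unique(tr$locus)) {
    add_model(.model_key(loc, "*", "*", "heptamer"),
              tr$heptamer[tr$locus == loc])
    add_model(.model_key(loc, "*", "*", "nonamer"),
              tr$nonamer[tr$locus == loc])
  }
  models
}

#' Score RSS records against trained models and set pass flags
#'
#' A record passes iff heptamer p <= alpha, nonamer p <= alpha and the
#' spacer length is within tolerance of its 12/23 class. Records in
#' strata without a usable model are flagged "no-model" and treated as
#' passing (the check is skipped, not failed). TRDD records are
#' additionally flagged "low-confidence".
#'
#' @param rss_records RSS records
#' @param models from \code{\link{train_rss_models}}
#' @param params \code{\link{vdj_params}}
#' @return updated RSS records
#' @export
score_rss <- function(rss_records, models, params = vdj_params()) {
  r <- rss_records
  for (i in seq_len(nrow(r))) {
    if (nzchar(r$flags[i]) && grepl("truncated-flank", r$flags[i])) next
    mh <- .model_for(models, r$locus[i], r$segment_class[i], r$side[i],
                     "heptamer", params)
    mn <- .model_for(models, r$locus[i], r$segment_class[i], r$side[i],
                     "nonamer", params)
    if (is.null(mh) || is.null(mn)) {
      r$flags[i] <- paste(c(r$flags[i][nzchar(r$flags[i])], "no-model"),
                          collapse = ";")
      r$pass[i] <- TRUE
      next
    }
    sh <- scan_score(mh, r$heptamer[i])
    sn <- scan_score(mn, r$nonamer[i])
    r$score_hep[i] <- sh$score_bits; r$p_hep[i] <- sh$p_value
    r$score_non[i] <- sn$score_bits; r$p_non[i] <- sn$p_value
    spacer_ok <- abs(r$spacer_len[i] - r$spacer_class[i]) <=
      params$spacer_tol
    r$pass[i] <- sh$p_value <= params$rss_alpha &&
      sn$p_value <= params$rss_alpha && spacer_ok
  }
  trdd <- r$locus == "TRD" & r$segment_class == "D"
  if (any(trdd)) {
    r$flags[trdd] <- vapply(r$flags[trdd], function(f)
      paste(unique(c(f[nzchar(f)], "low-confidence")), collapse = ";"), "")
  }
  r
}

#' Export PWM models as a MEME-compatible probability matrix file
#' @param models named list of \code{pwm}
#' @param path output file
#' @export
write_meme_pwm <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies", "A 0.25 C 0.25 G 0.25 T 0.25",
               ""), con)
  for (nm in names(models)) {
    m <- models[[nm]]
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      nrow(m$probs), m$n_training), con)
    writeLines(apply(m$probs, 1, function(p)
      paste(sprintf("%.6f", p), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}
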