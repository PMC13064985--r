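# Genomic functionality classification of V, D and J segments:
# functional / ORF / pseudogene. Criteria are organised in two tiers:
# any failed pseudogene-tier criterion makes the segment a pseudogene;
# otherwise any failed ORF-tier criterion demotes it to ORF; otherwise it
# is functional. Each classifier records every failed criterion id plus
# the observed evidence.
#
# Criterion ids
#   V  pseudogene tier: leader, v-frame, start-codon, inframe-stop, rss
#      ORF tier: end-stop (optional), donor-gt, acceptor-ag, two-cys
#   D  pseudogene tier: rss-5, rss-3
#   J  pseudogene tier: premature-stop, donor-gt, rss
#      ORF tier: j-motif

V_PSEUDO_CRITERIA <- c("leader", "v-frame", "start-codon", "inframe-stop",
                       "rss")
V_ORF_CRITERIA <- c("end-stop", "donor-gt", "acceptor-ag", "two-cys")
J_PSEUDO_CRITERIA <- c("premature-stop", "donor-gt", "rss")
J_ORF_CRITERIA <- c("j-motif")
D_PSEUDO_CRITERIA <- c("rss-5", "rss-3")

#' Combine criterion outcomes into a functionality label
#'
#' Pure tier-precedence rule: pseudogene > ORF > functional.
#'
#' @param failed character vector of failed criterion ids
#' @param pseudo_tier,orf_tier criterion ids belonging to each tier
#' @return "pseudogene", "ORF" or "functional"
#' @export
functionality_from_criteria <- function(failed, pseudo_tier, orf_tier) {
  if (any(failed %in% pseudo_tier)) "pseudogene"
  else if (any(failed %in% orf_tier)) "ORF"
  else "functional"
}

.call <- function(label, failed, evidence) {
  list(label = label, failed_criteria = failed, evidence = evidence)
}

#' Search for a V leader sequence upstream of a V segment
#'
#' Scans \code{window} bp upstream of the V start (in coding orientation)
#' for an ATG-initiated L-PART1 (26-70 bp) followed by an intron (>= 60
#' bp, canonically GT...AG) and an L-PART2 (8-13 bp) ending flush at the
#' V start, with L-PART1 + L-PART2 a multiple of 3. Among candidates the
#' one violating the fewest splice-site sub-criteria is chosen, then the
#' shortest intron, then the ATG closest to the V. Returns NULL when no
#' ATG-initiated candidate exists.
#'
#' @param region \code{extracted_region}
#' @param v_hit one-row hit/annotation (segment_class "V")
#' @param params \code{\link{vdj_params}}
#' @return list: lpart1, intron, lpart2 (region-coordinate c(start,end)),
#'   has_start_codon, donor_gt, acceptor_ag, truncated, lpart1_seq,
#'   lpart2_seq; or NULL
#' @export
find_leader <- function(region, v_hit, params = vdj_params()) {
  stopifnot(v_hit$segment_class == "V")
  s <- toupper(region$sequence)
  L <- nchar(s)
  window <- params$leader_window
  truncated <- FALSE
  if (v_hit$strand == "+") {
    w0 <- v_hit$start - window
    if (w0 < 0L) { w0 <- 0L; truncated <- TRUE }
    U <- slice0(s, w0, v_hit$start)
  } else {
    w1 <- v_hit$end + window
    if (w1 > L) { w1 <- L; truncated <- TRUE }
    U <- revcomp(slice0(s, v_hit$end, w1))
  }
  w <- nchar(U)
  atg <- gregexpr("ATG", U, fixed = TRUE)[[1]]
  if (atg[1] == -1L) return(NULL)
  atg <- as.integer(atg) - 1L          # 0-based L-PART1 starts
  l1r <- params$lpart1_range; l2r <- params$lpart2_range
  best <- NULL
  for (a in atg) {
    for (l2 in l2r[1]:l2r[2]) {
      for (l1 in l1r[1]:l1r[2]) {
        if ((l1 + l2) %% 3L != 0L) next
        intron_len <- w - l2 - (a + l1)
        if (intron_len < params$intron_min) next
        donor <- slice0(U, a + l1, a + l1 + 2L) == "GT"
        acceptor <- slice0(U, w - l2 - 2L, w - l2) == "AG"
        viol <- (!donor) + (!acceptor)
        cand <- list(a = a, l1 = l1, l2 = l2, intron_len = intron_len,
                     donor = donor, acceptor = acceptor, viol = viol)
        if (is.null(best) ||
            viol < best$viol ||
            (viol == best$viol && intron_len < best$intron_len) ||
            (viol == best$viol && intron_len == best$intron_len &&
             a > best$a) ||
            (viol == best$viol && intron_len == best$intron_len &&
             a == best$a && l2 < best$l2)) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  # map local (coding-orientation, 0-based in U) to region coordinates
  to_region <- function(p0, p1) {
    if (v_hit$strand == "+") {
      off <- v_hit$start - w
      c(off + p0, off + p1)
    } else {
      c(v_hit$end + (w - p1), v_hit$end + (w - p0))
    }
  }
  l1_iv <- c(best$a, best$a + best$l1)
  in_iv <- c(best$a + best$l1, w - best$l2)
  l2_iv <- c(w - best$l2, w)
  list(lpart1 = to_region(l1_iv[1], l1_iv[2]),
       intron = to_region(in_iv[1], in_iv[2]),
       lpart2 = to_region(l2_iv[1], l2_iv[2]),
       has_start_codon = TRUE,
       donor_gt = best$donor, acceptor_ag = best$acceptor,
       truncated = truncated,
       lpart1_seq = slice0(U, l1_iv[1], l1_iv[2]),
       lpart2_seq = slice0(U, l2_iv[1], l2_iv[2]))
}

#' Classify a V segment
#'
#' Pseudogene-tier criteria: leader identified; V length a multiple of 3;
#' start codon present; no in-frame stop codon in the spliced
#' L-PART1 + L-PART2 + V product (ATG frame); functional RSS. ORF-tier:
#' optional end-stop check (off by default), donor GT, acceptor AG, at
#' least two cysteines in the V translation. Codons containing N count as
#' neither stop nor cysteine and set a contains-N note in the evidence.
#'
#' @param v_seq observed V sequence (coding orientation)
#' @param leader result of \code{\link{find_leader}} or NULL
#' @param rss_ok logical: does the 3' RSS pass (TRUE when unassessed)
#' @param params \code{\link{vdj_params}}
#' @param downstream30 optional 30 bp 3' flank for the end-stop check
#' @return functionality call: label, failed_criteria, evidence
#' @export
classify_v <- function(v_seq, leader, rss_ok = TRUE, params = vdj_params(),
                       downstream30 = NULL) {
  failed <- character(0); ev <- list()
  v_seq <- toupper(v_seq)
  ev$leader <- !is.null(leader)
  if (is.null(leader)) failed <- c(failed, "leader")
  ev$v_length <- nchar(v_seq)
  if (nchar(v_seq) %% 3L != 0L) failed <- c(failed, "v-frame")
  if (!is.null(leader)) {
    ev$start_codon <- leader$has_start_codon
    if (!leader$has_start_codon) failed <- c(failed, "start-codon")
    spliced <- paste0(leader$lpart1_seq, leader$lpart2_seq, v_seq)
  } else {
    ev$start_codon <- NA
    spliced <- v_seq
  }
  aa <- translate_dna(spliced, 0L)
  ev$contains_n <- attr(aa, "contains_n")
  if (grepl("*", aa, fixed = TRUE)) failed <- c(failed, "inframe-stop")
  ev$rss <- rss_ok
  if (!isTRUE(rss_ok)) failed <- c(failed, "rss")
  # ORF tier
  if (params$check_end_stop) {
    has_end_stop <- !is.null(downstream30) &&
      grepl("*", translate_dna(downstream30, 0L), fixed = TRUE)
    ev$end_stop <- has_end_stop
    if (!has_end_stop) failed <- c(failed, "end-stop")
  }
  if (!is.null(leader)) {
    if (!leader$donor_gt) failed <- c(failed, "donor-gt")
    if (!leader$acceptor_ag) failed <- c(failed, "acceptor-ag")
    ev$donor_gt <- leader$donor_gt; ev$acceptor_ag <- leader$acceptor_ag
  }
  v_aa <- translate_dna(v_seq, 0L)
  ncys <- lengths(regmatches(v_aa, gregexpr("C", v_aa, fixed = TRUE)))
  ev$n_cysteines <- ncys
  if (ncys < 2L) failed <- c(failed, "two-cys")
  .call(functionality_from_criteria(failed, V_PSEUDO_CRITERIA,
                                    V_ORF_CRITERIA),
        failed, ev)
}

#' Classify a D segment: functional iff both flanking RSS pass
#' @param rss5_ok,rss3_ok do the 5' and 3' RSS pass
#' @return functionality call
#' @export
classify_d <- function(rss5_ok = TRUE, rss3_ok = TRUE) {
  failed <- character(0)
  if (!isTRUE(rss5_ok)) failed <- c(failed, "rss-5")
  if (!isTRUE(rss3_ok)) failed <- c(failed, "rss-3")
  .call(functionality_from_criteria(failed, D_PSEUDO_CRITERIA, character(0)),
        failed, list(rss5 = rss5_ok, rss3 = rss3_ok))
}

#' Classify a J segment
#'
#' Pseudogene tier: no premature stop codon in the motif frame (the
#' forward frame containing the [FW]G.G motif when present, else the frame
#' with fewest stops); donor splice site GT immediately 3' of the segment;
#' functional RSS. ORF tier: amino-acid motif [FW]G.G present.
#'
#' @param j_seq observed J sequence (coding orientation)
#' @param downstream2 the 2 bp immediately 3' of the segment
#' @param rss_ok does the 5' RSS pass
#' @return functionality call
#' @export
classify_j <- function(j_seq, downstream2, rss_ok = TRUE) {
  failed <- character(0); ev <- list()
  j_seq <- toupper(j_seq)
  aa <- vapply(0:2, function(f) as.character(translate_dna(j_seq, f)), "")
  motif_in <- which(grepl("[FW]G.G", aa))
  motif_present <- length(motif_in) > 0L
  frame <- if (motif_present) motif_in[1L] else
    which.min(vapply(aa, function(x)
      lengths(regmatches(x, gregexpr("*", x, fixed = TRUE))), 0L))
  ev$motif_frame <- frame - 1L
  ev$motif_present <- motif_present
  if (!motif_present) failed <- c(failed, "j-motif")
  if (grepl("*", aa[frame], fixed = TRUE))
    failed <- c(failed, "premature-stop")
  ev$donor <- identical(toupper(downstream2), "GT")
  if (!ev$donor) failed <- c(failed, "donor-gt")
  ev$rss <- rss_ok
  if (!isTRUE(rss_ok)) failed <- c(failed, "rss")
  .call(functionality_from_criteria(failed, J_PSEUDO_CRITERIA,
                                    J_ORF_CRITERIA),
        failed, ev)
}
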