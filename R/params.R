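#' Annotation parameter set
#'
#' Central tunable parameters for mapping, functionality classification and
#' RSS refinement. Defaults follow the package's calibration for
#' high-identity germline alleles (megablast-like scoring) and IMGT-style
#' genomic criteria.
#'
#' @param min_identity_vj minimum alignment identity for V and J hits
#' @param min_identity_d minimum identity for D hits (short segments need
#'   stricter matching)
#' @param min_len_d minimum aligned length for a D hit (bp)
#' @param k_seed exact k-mer seed length for V/J mapping; D records shorter
#'   than 16 bp are scanned exhaustively
#' @param band_frac window slack around a seeded placement, as a fraction of
#'   allele length
#' @param match,mismatch,gap_open,gap_ext alignment scoring
#' @param overlap_tol maximum tolerated overlap (bp) between retained hits
#' @param leader_window bp upstream of a V start searched for a leader
#' @param lpart1_range,lpart2_range,intron_min leader geometry bounds (bp)
#' @param check_end_stop enable the V ORF-tier "stop codon at the end of the
#'   sequence" criterion (off by default; see the methods vignette)
#' @param rss_alpha per-element p-value threshold for an RSS to pass
#' @param spacer_tol tolerated deviation (bp) from the tabulated 12/23
#'   spacer length
#' @param edge_slack heptamer offset scan range (bp) once motif models exist
#' @param pwm_pseudocount pseudocount for PWM estimation
#' @param min_train minimum training sequences per (locus, class, side,
#'   element) stratum before falling back to the pooled locus model
#' @param n_passes RSS refinement passes (preliminary classify, train,
#'   rescan, reclassify); 2 reaches the fixpoint on consistent data
#' @param anchor_min_identity minimum identity for flanking-gene placement
#' @param max_region_length maximum anchored region span (bp)
#' @return a named list of class \code{vdj_params}
#' @export
vdj_params <- function(min_identity_vj = 0.90, min_identity_d = 0.94,
                       min_len_d = 8L, k_seed = 11L, band_frac = 0.2,
                       match = 1, mismatch = -1, gap_open = -2, gap_ext = -1,
                       overlap_tol = 10L,
                       leader_window = 400L, lpart1_range = c(26L, 70L),
                       lpart2_range = c(8L, 13L), intron_min = 60L,
                       check_end_stop = FALSE,
                       rss_alpha = 1e-3, spacer_tol = 1L, edge_slack = 3L,
                       pwm_pseudocount = 0.5, min_train = 3L, n_passes = 2L,
                       anchor_min_identity = 0.85, max_region_length = 5e6) {
  p <- as.list(environment())
  class(p) <- "vdj_params"
  p
}
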