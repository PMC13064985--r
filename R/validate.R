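# Comparison of pipeline output against planted synthetic truth.

#' Evaluate annotations against a planted truth table
#'
#' A truth segment is recovered when an annotation with the same sample,
#' haplotype, locus, class, strand and exact start/end coordinates
#' exists. Label accuracy is the fraction of recovered segments whose
#' functionality label equals the expected label; criterion accuracy
#' additionally requires the planted failed criterion (when any) to
#' appear among the classifier's failed criteria.
#'
#' @param annotations combined annotation data.frame (pipeline output)
#' @param truth truth segment data.frame (generator output); columns
#'   sample_id, haplotype, locus, segment_class, start, end, strand,
#'   expected_label, expected_failed, novel
#' @return list: n_truth, n_recovered, recovery_pct, label_accuracy_pct,
#'   criterion_accuracy_pct, novel_accuracy_pct, missing, mismatched
#' @export
evaluate_against_truth <- function(annotations, truth) {
  key <- function(d) paste(d$sample_id, d$haplotype, d$locus,
                           d$segment_class, d$start, d$end, sep = "|")
  tk <- key(truth); ak <- key(annotations)
  hit <- match(tk, ak)
  recovered <- !is.na(hit)
  lab_ok <- crit_ok <- nov_ok <- rep(NA, nrow(truth))
  for (i in which(recovered)) {
    a <- annotations[hit[i], ]
    lab_ok[i] <- identical(a$functionality, truth$expected_label[i])
    crit_ok[i] <- lab_ok[i] &&
      (truth$expected_failed[i] == "" ||
       truth$expected_failed[i] %in%
         strsplit(a$failed_criteria, ";", fixed = TRUE)[[1]])
    nov_ok[i] <- identical(a$novel, truth$novel[i])
  }
  n_rec <- sum(recovered)
  pct <- function(x) if (n_rec) 100 * sum(x, na.rm = TRUE) / n_rec else 0
  list(n_truth = nrow(truth), n_recovered = n_rec,
       recovery_pct = 100 * n_rec / max(1L, nrow(truth)),
       label_accuracy_pct = pct(lab_ok),
       criterion_accuracy_pct = pct(crit_ok),
       novel_accuracy_pct = pct(nov_ok),
       missing = truth[!recovered, , drop = FALSE],
       mismatched = truth[recovered & !lab_ok %in% TRUE, , drop = FALSE])
}
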