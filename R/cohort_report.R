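# Cohort-level aggregation: per-class totals, unique and novel allele
# counts, novel-allele confirmation across individuals, zygosity,
# haplotype identity and concordance against curated annotation sets.

#' Aggregate annotations across samples and haplotypes
#'
#' Unique alleles are counted by distinct observed sequence per segment
#' class; novel alleles are distinct observed sequences absent from the
#' library. Zygosity per (individual, locus): homozygous iff both
#' haplotypes carry identical ordered allele content.
#'
#' @param annotations combined annotation data.frame (columns sample_id,
#'   haplotype, locus, segment_class, observed_sequence, novel,
#'   allele_call, start)
#' @return object of class \code{cohort_summary}: per_class_counts,
#'   unique_alleles, novel_alleles, zygosity
#' @export
aggregate_cohort <- function(annotations) {
  a <- annotations
  if (is.null(a) || !nrow(a)) {
    return(structure(list(
      per_class_counts = data.frame(locus_group = character(0),
                                    segment_class = character(0),
                                    n = integer(0)),
      unique_alleles = c(V = 0L, D = 0L, J = 0L),
      novel_alleles = c(V = 0L, D = 0L, J = 0L),
      zygosity = data.frame(individual = character(0), locus = character(0),
                            zygosity = character(0))),
      class = "cohort_summary"))
  }
  a$locus_group <- substr(a$locus, 1, 2)
  counts <- as.data.frame(table(locus_group = a$locus_group,
                                segment_class = a$segment_class),
                          stringsAsFactors = FALSE)
  names(counts)[3] <- "n"
  uniq <- vapply(c("V", "D", "J"), function(cl)
    length(unique(a$observed_sequence[a$segment_class == cl])), 0L)
  nov <- vapply(c("V", "D", "J"), function(cl)
    length(unique(a$observed_sequence[a$segment_class == cl & a$novel])),
    0L)
  zyg <- list()
  for (ind in unique(a$sample_id)) for (loc in unique(a$locus)) {
    sub <- a[a$sample_id == ind & a$locus == loc, ]
    if (!nrow(sub)) next
    haps <- unique(sub$haplotype)
    z <- if (length(haps) < 2L) "single-haplotype" else {
      keys <- vapply(haps, function(h) {
        sh <- sub[sub$haplotype == h, ]
        sh <- sh[order(sh$start), ]
        paste(sh$gene, sh$observed_sequence, sep = "=", collapse = ";")
      }, "")
      if (length(unique(keys)) == 1L) "homozygous" else "heterozygous"
    }
    zyg[[length(zyg) + 1L]] <- data.frame(individual = ind, locus = loc,
                                          zygosity = z,
                                          stringsAsFactors = FALSE)
  }
  structure(list(per_class_counts = counts,
                 unique_alleles = uniq, novel_alleles = nov,
                 zygosity = do.call(rbind, zyg)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n  segments annotated:\n")
  pc <- x$per_class_counts[x$per_class_counts$n > 0, ]
  if (nrow(pc)) print(pc, row.names = FALSE)
  cat("  unique alleles: ", paste(sprintf("%s=%d", names(x$unique_alleles),
                                          x$unique_alleles),
                                  collapse = ", "), "\n")
  cat("  novel alleles:  ", paste(sprintf("%s=%d", names(x$novel_alleles),
                                          x$novel_alleles),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Confirmation of novel alleles across individuals
#'
#' Support for a novel sequence is the number of distinct individuals
#' (not haplotypes) carrying it; \code{confirmed_at[[k]]} lists novel
#' sequences with support >= k.
#'
#' @param annotations combined annotation data.frame
#' @param thresholds integer vector of k values (default c(2, 4))
#' @return list: support (data.frame sequence, provisional_name,
#'   segment_class, support), confirmed_at (named list of data.frames)
#' @export
confirm_novel <- function(annotations, thresholds = c(2L, 4L)) {
  a <- annotations[annotations$novel, , drop = FALSE]
  if (!nrow(a)) {
    sup <- data.frame(sequence = character(0),
                      provisional_name = character(0),
                      segment_class = character(0), support = integer(0))
  } else {
    key <- unique(a[, c("observed_sequence", "provisional_name",
                        "segment_class")])
    sup <- data.frame(
      sequence = key$observed_sequence,
      provisional_name = key$provisional_name,
      segment_class = key$segment_class,
      support = vapply(key$observed_sequence, function(s)
        length(unique(a$sample_id[a$observed_sequence == s])), 0L),
      stringsAsFactors = FALSE)
    rownames(sup) <- NULL
  }
  confirmed <- lapply(thresholds, function(k)
    sup[sup$support >= k, , drop = FALSE])
  names(confirmed) <- as.character(thresholds)
  list(support = sup, confirmed_at = confirmed)
}

#' Compare two annotation sets for concordance
#'
#' A tool annotation matches a curated one iff they have the same segment
#' class and their intervals overlap by at least 1 bp; each annotation is
#' matched at most once, greedily by descending overlap length.
#'
#' @param tool,curated data.frames with segment_class, start, end
#' @return list of class \code{concordance_result}: matched, tool_only,
#'   reference_only, pairs (per-segment match records)
#' @export
compare_annotations <- function(tool, curated) {
  nt <- nrow(tool); nc <- nrow(curated)
  pairs <- list()
  if (nt && nc) {
    for (i in seq_len(nt)) for (j in seq_len(nc)) {
      if (tool$segment_class[i] != curated$segment_class[j]) next
      ov <- min(tool$end[i], curated$end[j]) -
        max(tool$start[i], curated$start[j])
      if (ov >= 1L)
        pairs[[length(pairs) + 1L]] <- c(i = i, j = j, ov = ov)
    }
  }
  used_i <- logical(nt); used_j <- logical(nc)
  matched <- list()
  if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(-pm[, "ov"], pm[, "i"], pm[, "j"]), , drop = FALSE]
    for (r in seq_len(nrow(pm))) {
      i <- pm[r, "i"]; j <- pm[r, "j"]
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      matched[[length(matched) + 1L]] <-
        data.frame(tool_idx = i, curated_idx = j,
                   overlap = pm[r, "ov"])
    }
  }
  n_matched <- length(matched)
  if (nt && nc && n_matched == 0L)
    warning("no overlapping annotations; coordinate systems may differ")
  structure(list(matched = n_matched,
                 tool_only = nt - n_matched,
                 reference_only = nc - n_matched,
                 pairs = if (n_matched) do.call(rbind, matched) else
                   data.frame(tool_idx = integer(0),
                              curated_idx = integer(0),
                              overlap = integer(0))),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "Concordance: %d matched, %d tool-only, %d reference-only (%.1f%%)\n",
    x$matched, x$tool_only, x$reference_only,
    100 * x$matched / max(1, x$matched + x$reference_only)))
  invisible(x)
}

#' Group identical haplotypes at a locus
#'
#' Haplotypes (complete regions only) are grouped by identical ordered
#' (gene, allele sequence) vectors; groups of size >= 2 are reported.
#'
#' @param annotations combined annotation data.frame (needs a
#'   \code{complete} column)
#' @param locus locus to examine
#' @return list of character vectors ("individual#haplotype") per group
#' @export
haplotype_identity <- function(annotations, locus) {
  a <- annotations[annotations$locus == locus & annotations$complete, ,
                   drop = FALSE]
  if (!nrow(a)) return(list())
  a$hap_id <- paste(a$sample_id, a$haplotype, sep = "#")
  keys <- vapply(unique(a$hap_id), function(h) {
    sh <- a[a$hap_id == h, ]
    sh <- sh[order(sh$start), ]
    paste(sh$gene, sh$observed_sequence, sep = "=", collapse = ";")
  }, "")
  groups <- split(names(keys), keys)
  unname(groups[lengths(groups) >= 2L])
}

#' Write a Table-2 style cohort summary TSV
#' @param summary a \code{cohort_summary}
#' @param confirmation result of \code{\link{confirm_novel}}
#' @param path output file
#' @export
write_cohort_tsv <- function(summary, confirmation, path) {
  rows <- list()
  classes <- c("V", "D", "J")
  rows$unique <- c("Unique alleles", summary$unique_alleles[classes],
                   sum(summary$unique_alleles))
  rows$novel <- c("Unique novel alleles", summary$novel_alleles[classes],
                  sum(summary$novel_alleles))
  for (k in names(confirmation$confirmed_at)) {
    cf <- confirmation$confirmed_at[[k]]
    per <- vapply(classes, function(cl) sum(cf$segment_class == cl), 0L)
    rows[[paste0("k", k)]] <- c(
      sprintf("Novel alleles present in at least %s individuals", k),
      per, sum(per))
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("row", classes, "Total")
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
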