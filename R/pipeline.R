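# End-to-end annotation of an extracted region and of whole assemblies /
# cohorts. The flow mirrors the adaptive RSS refinement: map and call
# alleles, classify preliminarily with the RSS criterion held open, train
# motif models from the preliminarily functional segments, rescan all RSS
# and reclassify. The train/rescan/reclassify cycle runs n_passes times;
# on consistent data the second pass is already a fixpoint.

.classify_all <- function(ann, region, leaders, rss, params) {
  if (!nrow(ann)) { ann$functionality <- character(0)
                    ann$failed_criteria <- character(0); return(ann) }
  lab <- character(nrow(ann)); fail <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    cls <- ann$segment_class[i]
    id <- ann$ann_id[i]
    rss_i <- rss[rss$ann_id == id, , drop = FALSE]
    pass_of <- function(side) {
      j <- which(rss_i$side == side)
      if (!length(j)) return(FALSE)        # required RSS absent
      isTRUE(rss_i$pass[j[1]]) || is.na(rss_i$pass[j[1]])
    }
    if (cls == "V") {
      fc <- classify_v(ann$observed_sequence[i], leaders[[id]],
                       rss_ok = pass_of("3prime"), params = params)
    } else if (cls == "D") {
      fc <- classify_d(pass_of("5prime"), pass_of("3prime"))
    } else {
      s <- toupper(region$sequence); L <- nchar(s)
      d2 <- if (ann$strand[i] == "+") slice0(s, ann$end[i],
                                             min(L, ann$end[i] + 2L))
            else revcomp(slice0(s, max(0L, ann$start[i] - 2L),
                                ann$start[i]))
      fc <- classify_j(ann$observed_sequence[i], d2,
                       rss_ok = pass_of("5prime"))
    }
    lab[i] <- fc$label
    fail[i] <- paste(fc$failed_criteria, collapse = ";")
  }
  ann$functionality <- lab
  ann$failed_criteria <- fail
  ann
}

#' Refine functionality labels using scored RSS records
#'
#' Applies the pass flags in \code{rss_records} (scored against
#' \code{models}) and reclassifies every annotation; labels are never
#' upgraded because only the RSS criterion can change and it was held
#' open during preliminary classification.
#'
#' @param annotations annotation data.frame
#' @param rss_records RSS records
#' @param models trained models
#' @param region the \code{extracted_region}
#' @param leaders named list of leader annotations (by ann_id)
#' @param params \code{\link{vdj_params}}
#' @return list: annotations (relabelled), rss (scored)
#' @export
refine_functionality <- function(annotations, rss_records, models, region,
                                 leaders, params = vdj_params()) {
  scored <- score_rss(rss_records, models, params)
  ann <- .classify_all(annotations, region, leaders, scored, params)
  list(annotations = ann, rss = scored)
}

#' Annotate one extracted region end-to-end
#'
#' @param region \code{extracted_region}
#' @param lib \code{allele_library}
#' @param params \code{\link{vdj_params}}
#' @param spacer_table 12/23 spacer classes
#' @param cdr_refs optional CDR reference table
#'   (\code{\link{read_cdr_references}})
#' @param n_passes override \code{params$n_passes}
#' @return list of class \code{region_annotation}: annotations, rss,
#'   leaders, models, cdr
#' @export
annotate_region <- function(region, lib, params = vdj_params(),
                            spacer_table = default_spacer_table(),
                            cdr_refs = NULL, n_passes = NULL) {
  n_passes <- n_passes %||% params$n_passes
  hits <- map_segments(region, lib, params)
  kept <- resolve_overlaps(hits, params$overlap_tol)
  ann <- call_alleles(kept, lib, region)
  leaders <- list()
  for (i in which(ann$segment_class == "V")) {
    leaders[[ann$ann_id[i]]] <- find_leader(region, ann[i, ], params)
  }
  # preliminary classification: RSS criterion held open
  rss0 <- .extract_all_rss(region, ann, spacer_table, params, models = NULL)
  rss_open <- rss0
  rss_open$pass <- NA
  rss_open$pass[nzchar(rss_open$flags) &
                grepl("truncated-flank", rss_open$flags)] <- NA
  ann <- .classify_all(ann, region, leaders, rss_open, params)
  models <- list()
  rss <- rss0
  for (p in seq_len(n_passes)) {
    models <- train_rss_models(ann, rss, params)
    rss <- .extract_all_rss(region, ann, spacer_table, params,
                            models = if (length(models)) models else NULL)
    ref <- refine_functionality(ann, rss, models, region, leaders, params)
    ann <- ref$annotations
    rss <- ref$rss
  }
  # D confidence: require flanking-RSS support
  if (nrow(ann)) {
    conf <- rep(TRUE, nrow(ann))
    for (i in which(ann$segment_class == "D")) {
      ri <- rss[rss$ann_id == ann$ann_id[i], , drop = FALSE]
      conf[i] <- nrow(ri) > 0 && all(ri$pass | is.na(ri$pass))
    }
    ann$confident <- conf
  } else ann$confident <- logical(0)
  cdr <- NULL
  if (!is.null(cdr_refs)) {
    cdr <- transfer_cdr_all(ann, cdr_refs, region, params)
  }
  structure(list(annotations = ann, rss = rss, leaders = leaders,
                 models = models, cdr = cdr, region = region),
            class = "region_annotation")
}

.extract_all_rss <- function(region, ann, spacer_table, params, models) {
  su <- toupper(region$sequence)
  src <- if (any(ann$strand == "-")) revcomp(su) else NULL
  rows <- list()
  for (i in seq_len(nrow(ann))) {
    rows <- c(rows, extract_rss(region, ann[i, ], spacer_table, params,
                                models, .as_rows = TRUE,
                                .region_upper = su, .region_rc = src))
  }
  .rss_rows_to_df(rows)
}

#' @export
print.region_annotation <- function(x, ...) {
  a <- x$annotations
  cat(sprintf("Region annotation %s: %d segments (%s); %d novel\n",
              x$region$locus, nrow(a),
              paste(sprintf("%s=%d", names(table(a$segment_class)),
                            as.integer(table(a$segment_class))),
                    collapse = ", "),
              sum(a$novel)))
  if (nrow(a))
    print(table(functionality = a$functionality, class = a$segment_class))
  invisible(x)
}

#' Annotate all loci of one assembly (one haplotype)
#'
#' @param assembly named character vector of contigs
#' @param specs list of \code{\link{region_spec}} (one per locus)
#' @param lib \code{allele_library}
#' @param params \code{\link{vdj_params}}
#' @param spacer_table,cdr_refs,n_passes passed through
#' @param sample_id,haplotype identifiers
#' @return list of \code{region_annotation}, named by locus; loci whose
#'   anchors are not found are skipped with a warning
#' @export
annotate_assembly <- function(assembly, specs, lib, params = vdj_params(),
                              spacer_table = default_spacer_table(),
                              cdr_refs = NULL, n_passes = NULL,
                              sample_id = "", haplotype = "") {
  out <- list()
  for (spec in specs) {
    reg <- tryCatch(
      extract_region(assembly, spec, params, sample_id, haplotype),
      error = function(e) { warning(conditionMessage(e)); NULL })
    if (is.null(reg)) next
    out[[spec$locus]] <- annotate_region(reg, lib, params, spacer_table,
                                         cdr_refs, n_passes)
  }
  out
}

#' Annotate a multi-sample cohort
#'
#' @param assemblies named list of assemblies (one per haplotype); names
#'   "individual#haplotype" or supplied via \code{sample_map}
#' @param specs list of \code{\link{region_spec}}
#' @param lib \code{allele_library}
#' @param sample_map optional data.frame(assembly, individual, haplotype)
#' @param ... passed to \code{\link{annotate_assembly}}
#' @return list: annotations (combined data.frame), rss (combined),
#'   per_region (list of \code{region_annotation})
#' @export
annotate_cohort <- function(assemblies, specs, lib, sample_map = NULL,
                            ...) {
  per_region <- list()
  ann_all <- list(); rss_all <- list(); cdr_all <- list()
  for (nm in names(assemblies)) {
    if (!is.null(sample_map)) {
      row <- sample_map[sample_map$assembly == nm, ]
      ind <- row$individual[1]; hap <- row$haplotype[1]
    } else {
      parts <- strsplit(nm, "#", fixed = TRUE)[[1]]
      ind <- parts[1]; hap <- if (length(parts) > 1) parts[2] else "1"
    }
    ras <- annotate_assembly(assemblies[[nm]], specs, lib,
                             sample_id = ind, haplotype = hap, ...)
    for (loc in names(ras)) {
      key <- paste(nm, loc, sep = "|")
      per_region[[key]] <- ras[[loc]]
      ann_all[[key]] <- ras[[loc]]$annotations
      rss_all[[key]] <- ras[[loc]]$rss
      if (!is.null(ras[[loc]]$cdr)) cdr_all[[key]] <- ras[[loc]]$cdr
    }
  }
  list(annotations = if (length(ann_all)) do.call(rbind, c(ann_all,
         make.row.names = FALSE)) else NULL,
       rss = if (length(rss_all)) do.call(rbind, c(rss_all,
         make.row.names = FALSE)) else NULL,
       cdr = if (length(cdr_all)) do.call(rbind, c(cdr_all,
         make.row.names = FALSE)) else NULL,
       per_region = per_region)
}
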