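# Scan stage: intersect deletion-type structural variants with the HML-2
# catalogue.  A deletion is a preintegration-allele candidate when it fully
# contains the locus (filter ii), its subtype is loss/deletion (filter i) and
# its effective length is under 1500 bp (filter iii, strict).  Candidate
# status is then decided by a breakpoint-consistency rule against the TSD
# call: a true preintegration deletion removes the element plus exactly one
# TSD copy.

#' Scan-stage configuration
#'
#' @param allowed_subtypes variant subtypes kept by [filter_variants()]
#'   (case-insensitive).
#' @param max_len strict upper bound (bp) on the effective deletion length;
#'   a deletion of exactly `max_len` is rejected ("shorter than 1500").
#' @param breakpoint_tol tolerance (bp) when comparing deletion breakpoints
#'   with the expected preintegration breakpoints.
#' @return a classed list of settings.
#' @export
scan_config <- function(allowed_subtypes = c("loss", "deletion"),
                        max_len = 1500L, breakpoint_tol = 10L) {
  stopifnot(max_len > 0, breakpoint_tol >= 0)
  structure(list(allowed_subtypes = tolower(allowed_subtypes),
                 max_len = as.integer(max_len),
                 breakpoint_tol = as.integer(breakpoint_tol)),
            class = "scan_config")
}

#' Filter variants by subtype (filter i)
#'
#' Keeps variants whose `var_subtype` is (case-insensitively) one of the
#' allowed subtypes, by default `loss` and `deletion`.
#'
#' @param variants variant records from [read_dgv()].
#' @param config a [scan_config()].
#' @return the retained subset, in input order.
#' @export
filter_variants <- function(variants, config = scan_config()) {
  variants[tolower(variants$var_subtype) %in% config$allowed_subtypes, ,
           drop = FALSE]
}

.empty_candidates <- function() {
  data.frame(locus_id = character(), accession = character(),
             chrom = character(), del_start = integer(), del_end = integer(),
             deletion_len = integer(), effective_len = integer(),
             status = character(), tsd_len_used = integer(),
             stringsAsFactors = FALSE)
}

#' Match deletions against the catalogue (filters ii and iii)
#'
#' A (locus, deletion) pair is emitted when the deletion interval fully
#' contains the locus's LTR (solo LTR) or the whole locus span
#' (provirus/truncated provirus) and the effective length is strictly below
#' `max_len`.  For a solo LTR the effective length is the deletion length;
#' for proviral structures the internal portion is discounted
#' (`deletion_len - (span_len - leftmost LTR length)`) so the residue is
#' comparable to a solo-LTR deletion.  Identical (locus, deletion-interval)
#' pairs reported by different studies collapse to one candidate with the
#' accessions concatenated.  Status is set later by [classify_candidates()].
#'
#' @param catalog an `"hml2_catalog"` from [assemble_loci()].
#' @param variants deletion-type variant records (after [filter_variants()]).
#' @param config a [scan_config()].
#' @return a `data.frame` of candidate sites, ordered by (chrom, locus,
#'   deletion interval).
#' @export
match_deletions <- function(catalog, variants, config = scan_config()) {
  if (nrow(catalog) == 0L || nrow(variants) == 0L) return(.empty_candidates())
  req_start <- ifelse(catalog$structure == "solo_ltr", catalog$ltr1_start,
                      catalog$start)
  req_end <- ifelse(catalog$structure == "solo_ltr", catalog$ltr1_end,
                    catalog$end)
  req <- GenomicRanges::GRanges(catalog$chrom,
                                IRanges::IRanges(req_start + 1L, req_end))
  del <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$start + 1L,
                                                 variants$end))
  hits <- GenomicRanges::findOverlaps(req, del, type = "within")
  if (!length(hits)) return(.empty_candidates())
  li <- S4Vectors::queryHits(hits)
  vi <- S4Vectors::subjectHits(hits)
  del_len <- variants$end[vi] - variants$start[vi]
  span_len <- catalog$end[li] - catalog$start[li]
  ltr_len <- catalog$ltr1_end[li] - catalog$ltr1_start[li]
  eff <- ifelse(catalog$structure[li] == "solo_ltr", del_len,
                del_len - (span_len - ltr_len))
  keep <- eff < config$max_len
  if (!any(keep)) return(.empty_candidates())
  li <- li[keep]; vi <- vi[keep]
  out <- data.frame(locus_id = catalog$locus_id[li],
                    accession = variants$accession[vi],
                    chrom = catalog$chrom[li],
                    del_start = variants$start[vi],
                    del_end = variants$end[vi],
                    deletion_len = del_len[keep],
                    effective_len = as.integer(eff[keep]),
                    status = NA_character_,
                    tsd_len_used = NA_integer_,
                    stringsAsFactors = FALSE)
  # collapse duplicate (locus, deletion-interval) pairs across studies
  key <- paste(out$locus_id, out$del_start, out$del_end)
  if (anyDuplicated(key)) {
    acc <- tapply(out$accession, key, paste, collapse = ",")
    out <- out[!duplicated(key), , drop = FALSE]
    out$accession <- as.character(acc[paste(out$locus_id, out$del_start,
                                            out$del_end)])
  }
  out <- out[order(out$chrom, out$locus_id, out$del_start, out$del_end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify one candidate against its TSD call
#'
#' Automates the paper-era manual browser curation with a breakpoint
#' consistency rule: the candidate is `preintegration_consistent` when the
#' deletion breakpoints lie within `breakpoint_tol` of the element span plus
#' exactly one TSD copy (either side); `regional_indel` when the deletion
#' contains the element plus both TSD copies plus more than `breakpoint_tol`
#' of extra sequence on each side; otherwise (including when no TSD call
#' exists) `ambiguous`.
#'
#' @param candidate one-row candidate data.frame from [match_deletions()].
#' @param locus the matching one-row catalogue entry.
#' @param tsd_len TSD length in bp, or `NA`/`NULL` when no TSD was called.
#' @param config a [scan_config()].
#' @return the candidate row with `status` and `tsd_len_used` filled in.
#' @export
classify_candidate <- function(candidate, locus, tsd_len, config = scan_config()) {
  tol <- config$breakpoint_tol
  if (is.null(tsd_len) || is.na(tsd_len)) {
    candidate$status <- "ambiguous"
    return(candidate)
  }
  s <- locus$start; e <- locus$end
  ds <- candidate$del_start; de <- candidate$del_end
  left_copy  <- abs(ds - (s - tsd_len)) <= tol && abs(de - e) <= tol
  right_copy <- abs(ds - s) <= tol && abs(de - (e + tsd_len)) <= tol
  regional <- ((s - tsd_len) - ds) > tol && (de - (e + tsd_len)) > tol
  candidate$status <- if (left_copy || right_copy) "preintegration_consistent"
                      else if (regional) "regional_indel"
                      else "ambiguous"
  candidate$tsd_len_used <- as.integer(tsd_len)
  candidate
}

#' Classify all candidates using a table of TSD calls
#'
#' @param candidates data.frame from [match_deletions()].
#' @param catalog the catalogue the candidates were matched against.
#' @param tsd_calls data.frame from [call_all()] (may be empty).
#' @param config a [scan_config()].
#' @return the candidates with `status`/`tsd_len_used` set.
#' @export
classify_candidates <- function(candidates, catalog, tsd_calls,
                                config = scan_config()) {
  if (nrow(candidates) == 0L) return(candidates)
  tsd_len <- tsd_calls$length[match(candidates$locus_id, tsd_calls$locus_id)]
  for (i in seq_len(nrow(candidates))) {
    locus <- catalog[match(candidates$locus_id[i], catalog$locus_id), ]
    candidates[i, ] <- classify_candidate(candidates[i, ], locus,
                                          tsd_len[i], config)
  }
  candidates
}
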