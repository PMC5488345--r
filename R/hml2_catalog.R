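# Catalogue assembly: from raw repeat records to HML-2 loci.
#
# An HML-2 locus is one of
#   solo_ltr            - a single LTR, no internal segment
#   provirus            - LTR ... HERVK-int(s) ... LTR, same strand
#   truncated_provirus  - one LTR plus internal segment(s)
# Linking uses the signed gap next.start - prev.end between neighbouring
# records on the same chromosome and strand, which must lie in
# [min_gap, max_gap] = [-1, 100] by default (-1 means one base overlapping).

#' Catalogue-assembly configuration
#'
#' @param ltr_names repeat-model names counted as HML-2 LTRs.  The default
#'   `c("LTR5", "LTR5_Hs")` deliberately excludes the older relatives LTR5A
#'   and LTR5B; matching is exact, never by prefix.
#' @param internal_names repeat-model names of the proviral internal region.
#' @param min_gap,max_gap allowed signed gap (bp) between an LTR and the
#'   nearest internal segment; `-1` allows a one-base overlap.
#' @param short_ltr_threshold LTR records shorter than this (bp) get the
#'   `short_ltr` flag (flag only, never an exclusion).
#' @param adjacency_threshold loci whose LTR lies within this many bp of
#'   another catalogued LTR get the `adjacent_ltr` flag.
#' @return a classed list of settings.
#' @export
catalog_config <- function(ltr_names = c("LTR5", "LTR5_Hs"),
                           internal_names = "HERVK-int",
                           min_gap = -1L, max_gap = 100L,
                           short_ltr_threshold = 50L,
                           adjacency_threshold = 10L) {
  stopifnot(min_gap <= max_gap, short_ltr_threshold >= 0, adjacency_threshold >= 0)
  structure(list(ltr_names = ltr_names, internal_names = internal_names,
                 min_gap = as.integer(min_gap), max_gap = as.integer(max_gap),
                 short_ltr_threshold = as.integer(short_ltr_threshold),
                 adjacency_threshold = as.integer(adjacency_threshold)),
            class = "catalog_config")
}

#' Select HML-2 LTR records by exact model name
#'
#' Keeps exactly the records whose `rep_name` is in `config$ltr_names`
#' (default LTR5 and LTR5_Hs).  Exact matching ensures LTR5A/LTR5B — older
#' HML-2 relatives — are excluded.
#'
#' @param records repeat records from [read_repeatmasker()].
#' @param config a [catalog_config()].
#' @return the selected subset, in input order.
#' @export
select_hml2_ltrs <- function(records, config = catalog_config()) {
  records[records$rep_name %in% config$ltr_names, , drop = FALSE]
}

#' Select proviral internal-segment records by exact model name
#'
#' @inheritParams select_hml2_ltrs
#' @return the selected subset, in input order.
#' @export
select_internals <- function(records, config = catalog_config()) {
  records[records$rep_name %in% config$internal_names, , drop = FALSE]
}

.empty_catalog <- function() {
  df <- data.frame(locus_id = character(), chrom = character(),
                   start = integer(), end = integer(), strand = character(),
                   structure = character(), ltr1_start = integer(),
                   ltr1_end = integer(), ltr2_start = integer(),
                   ltr2_end = integer(), n_internal = integer(),
                   short_ltr = logical(), adjacent_ltr = logical(),
                   stringsAsFactors = FALSE)
  df$internal_starts <- I(list())
  df$internal_ends <- I(list())
  df
}

# Parse one same-chromosome same-strand chain of linked records into loci.
# `chain` is a data.frame with columns start, end, type ("L"/"I"), row index.
.chain_to_loci <- function(chain) {
  n_ltr <- sum(chain$type == "L")
  loci <- list()
  orphans <- integer(0)
  used <- rep(FALSE, nrow(chain))
  if (n_ltr >= 2L) {
    # greedy left-to-right split into (LTR, int+, LTR) proviruses
    i <- 1L
    while (i <= nrow(chain)) {
      if (chain$type[i] == "L") {
        j <- i + 1L
        while (j <= nrow(chain) && chain$type[j] == "I") j <- j + 1L
        if (j <= nrow(chain) && chain$type[j] == "L" && j > i + 1L) {
          loci[[length(loci) + 1L]] <-
            list(structure = "provirus", ltr_rows = c(i, j),
                 int_rows = seq(i + 1L, j - 1L))
          used[i:j] <- TRUE
          i <- j + 1L
          next
        }
      }
      i <- i + 1L
    }
    # leftover LTRs in a multi-LTR chain become solo; leftover internals orphan
    for (k in which(!used)) {
      if (chain$type[k] == "L")
        loci[[length(loci) + 1L]] <- list(structure = "solo_ltr",
                                          ltr_rows = k, int_rows = integer(0))
      else orphans <- c(orphans, k)
    }
  } else if (n_ltr == 1L) {
    k <- which(chain$type == "L")
    ints <- which(chain$type == "I")
    if (length(ints))
      loci[[length(loci) + 1L]] <- list(structure = "truncated_provirus",
                                        ltr_rows = k, int_rows = ints)
    else
      loci[[length(loci) + 1L]] <- list(structure = "solo_ltr",
                                        ltr_rows = k, int_rows = integer(0))
  } else {
    orphans <- seq_len(nrow(chain))
  }
  list(loci = loci, orphans = orphans)
}

#' Assemble HML-2 loci from LTR and internal-segment records
#'
#' Links an LTR and an internal segment when they share chromosome and
#' strand and the signed gap (`next.start - prev.end` on position-sorted
#' records) lies in `[min_gap, max_gap]`.  Chains LTR–int(–int…)–LTR become
#' proviruses; a lone LTR with linked internal segment(s) becomes a truncated
#' provirus; unlinked LTRs are solo LTRs.  Chains with more than two LTRs are
#' split greedily left-to-right into (LTR, int+, LTR) triples and leftover
#' LTRs become solo.  Internal segments with no qualifying LTR are dropped
#' from the catalogue but reported in the `"orphan_internals"` attribute.
#' The result is invariant under input ordering and sorted by
#' (chrom, start).
#'
#' @param ltrs LTR records (already through [select_hml2_ltrs()]).
#' @param internals internal-segment records ([select_internals()]).
#' @param config a [catalog_config()].
#' @return a `data.frame` catalogue (class `"hml2_catalog"`): one row per
#'   locus with the covering span, structure label, component LTR intervals,
#'   internal intervals (list columns) and the `short_ltr`/`adjacent_ltr`
#'   flags.  `locus_id` is `chrom:start-end` of the span.
#' @export
assemble_loci <- function(ltrs, internals, config = catalog_config()) {
  if (nrow(ltrs) == 0L) {
    out <- .empty_catalog()
    class(out) <- c("hml2_catalog", class(out))
    attr(out, "orphan_internals") <- internals[0, , drop = FALSE]
    return(out)
  }
  recs <- rbind(
    data.frame(chrom = ltrs$chrom, start = ltrs$start, end = ltrs$end,
               strand = ltrs$strand, type = "L", stringsAsFactors = FALSE),
    if (nrow(internals))
      data.frame(chrom = internals$chrom, start = internals$start,
                 end = internals$end, strand = internals$strand, type = "I",
                 stringsAsFactors = FALSE))
  recs <- recs[order(recs$chrom, recs$start, recs$end, recs$type), , drop = FALSE]
  rownames(recs) <- NULL
  loci_rows <- list()
  orphan_rows <- list()
  for (key in unique(paste(recs$chrom, recs$strand))) {
    grp <- recs[paste(recs$chrom, recs$strand) == key, , drop = FALSE]
    # break into chains at unlinkable junctions; LTR-LTR neighbours never link
    if (nrow(grp) > 1L) {
      gap <- grp$start[-1L] - grp$end[-nrow(grp)]
      both_ltr <- grp$type[-1L] == "L" & grp$type[-nrow(grp)] == "L"
      brk <- gap < config$min_gap | gap > config$max_gap | both_ltr
      chain_id <- cumsum(c(TRUE, brk))
    } else chain_id <- 1L
    for (cid in unique(chain_id)) {
      chain <- grp[chain_id == cid, , drop = FALSE]
      parsed <- .chain_to_loci(chain)
      for (lc in parsed$loci) {
        lt <- chain[lc$ltr_rows, , drop = FALSE]
        it <- chain[lc$int_rows, , drop = FALSE]
        span_start <- min(lt$start, if (nrow(it)) it$start)
        span_end <- max(lt$end, if (nrow(it)) it$end)
        loci_rows[[length(loci_rows) + 1L]] <- list(
          chrom = chain$chrom[1L], start = span_start, end = span_end,
          strand = chain$strand[1L], structure = lc$structure,
          ltr1_start = lt$start[1L], ltr1_end = lt$end[1L],
          ltr2_start = if (nrow(lt) > 1L) lt$start[2L] else NA_integer_,
          ltr2_end = if (nrow(lt) > 1L) lt$end[2L] else NA_integer_,
          internal_starts = it$start, internal_ends = it$end)
      }
      if (length(parsed$orphans))
        orphan_rows[[length(orphan_rows) + 1L]] <-
          chain[parsed$orphans, , drop = FALSE]
    }
  }
  cat_df <- data.frame(
    chrom = vapply(loci_rows, `[[`, "", "chrom"),
    start = vapply(loci_rows, `[[`, 0L, "start"),
    end = vapply(loci_rows, `[[`, 0L, "end"),
    strand = vapply(loci_rows, `[[`, "", "strand"),
    structure = vapply(loci_rows, `[[`, "", "structure"),
    ltr1_start = vapply(loci_rows, `[[`, 0L, "ltr1_start"),
    ltr1_end = vapply(loci_rows, `[[`, 0L, "ltr1_end"),
    ltr2_start = vapply(loci_rows, `[[`, NA_integer_, "ltr2_start"),
    ltr2_end = vapply(loci_rows, `[[`, NA_integer_, "ltr2_end"),
    stringsAsFactors = FALSE)
  cat_df$n_internal <- vapply(loci_rows, function(x) length(x$internal_starts), 0L)
  cat_df$internal_starts <- I(lapply(loci_rows, `[[`, "internal_starts"))
  cat_df$internal_ends <- I(lapply(loci_rows, `[[`, "internal_ends"))
  ord <- order(cat_df$chrom, cat_df$start, cat_df$end)
  cat_df <- cat_df[ord, , drop = FALSE]
  rownames(cat_df) <- NULL
  cat_df$locus_id <- sprintf("%s:%d-%d", cat_df$chrom, cat_df$start, cat_df$end)

  # flags ---------------------------------------------------------------
  ltr_tab <- data.frame(
    chrom = c(cat_df$chrom, cat_df$chrom[!is.na(cat_df$ltr2_start)]),
    start = c(cat_df$ltr1_start, cat_df$ltr2_start[!is.na(cat_df$ltr2_start)]),
    end = c(cat_df$ltr1_end, cat_df$ltr2_end[!is.na(cat_df$ltr2_end)]),
    locus = c(seq_len(nrow(cat_df)), which(!is.na(cat_df$ltr2_start))),
    stringsAsFactors = FALSE)
  short <- (ltr_tab$end - ltr_tab$start) < config$short_ltr_threshold
  cat_df$short_ltr <- vapply(seq_len(nrow(cat_df)), function(i)
    any(short[ltr_tab$locus == i]), NA)
  adj <- rep(FALSE, nrow(ltr_tab))
  for (i in seq_len(nrow(ltr_tab))) {
    same <- ltr_tab$chrom == ltr_tab$chrom[i] & ltr_tab$locus != ltr_tab$locus[i]
    if (!any(same)) next
    d <- pmax(ltr_tab$start[same] - ltr_tab$end[i],
              ltr_tab$start[i] - ltr_tab$end[same], 0L)
    adj[i] <- any(d <= config$adjacency_threshold)
  }
  cat_df$adjacent_ltr <- vapply(seq_len(nrow(cat_df)), function(i)
    any(adj[ltr_tab$locus == i]), NA)

  cols <- c("locus_id", "chrom", "start", "end", "strand", "structure",
            "ltr1_start", "ltr1_end", "ltr2_start", "ltr2_end", "n_internal",
            "internal_starts", "internal_ends", "short_ltr", "adjacent_ltr")
  cat_df <- cat_df[, cols]
  class(cat_df) <- c("hml2_catalog", class(cat_df))
  orphans <- if (length(orphan_rows)) do.call(rbind, orphan_rows)
             else recs[0, , drop = FALSE]
  rownames(orphans) <- NULL
  attr(cat_df, "orphan_internals") <- orphans
  cat_df
}

#' Count autosomal HML-2 LTR records
#'
#' Counts raw LTR *records* (not assembled loci) on chr1–chr22.  On the
#' pinned hg19 RepeatMasker table this is the published 622; on synthetic
#' genomes it equals the number of planted autosomal LTR copies.
#'
#' @param ltrs LTR records from [select_hml2_ltrs()] (any data.frame with a
#'   normalized `chrom` column works).
#' @return integer count.
#' @export
count_autosomal_ltrs <- function(ltrs) {
  sum(ltrs$chrom %in% paste0("chr", 1:22))
}
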