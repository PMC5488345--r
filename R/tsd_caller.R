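# TSD inference.  At integration a retrovirus duplicates its target site,
# leaving a direct repeat of host sequence immediately left and right of the
# element.  The caller scans candidate lengths L from long to short and
# boundary offsets 0..max_offset on each side, globally aligns the two
# nominal-L flank windows, and accepts the first (longest) candidate whose
# alignment satisfies
#   identity > min_identity                    (strictly; matches / columns)
#   mismatches + gap columns <= mismatch_cap(L)
#   first and last alignment columns are matches
# The terminal-match condition encodes what a duplication block is: its
# boundary evidence is identical sequence, so an alignment ending in a gap or
# mismatch column has overrun the duplicated block that a shorter nominal
# length already captures; without it the longest-first search would pad
# shorter duplications with non-matching columns and inflate the length.
# The reported TSD length is the accepted alignment's column count.

#' TSD-caller configuration
#'
#' @param min_len,max_len candidate TSD length range in bp (default 4–500).
#' @param min_identity strict lower bound on alignment identity
#'   (matches / alignment columns); the default keeps calls with identity
#'   `> 0.75`.
#' @param max_offset maximum number of intervening bases allowed between a
#'   TSD copy and the element boundary on each side (default 2).
#' @param match,mismatch,gap alignment scores per column.
#' @return a classed list of settings.
#' @export
tsd_config <- function(min_len = 4L, max_len = 500L, min_identity = 0.75,
                       max_offset = 2L, match = 1L, mismatch = -1L,
                       gap = -2L) {
  stopifnot(min_len >= 1, min_len <= max_len,
            min_identity >= 0, min_identity < 1, max_offset >= 0)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_identity = min_identity,
                 max_offset = as.integer(max_offset),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap = as.integer(gap)),
            class = "tsd_config")
}

#' Allowed mismatch+gap count for a candidate TSD length
#'
#' One for lengths below 10 bp, two below 20 bp, three from 20 bp on.
#'
#' @param length candidate length(s) in bp, `>= 1`.
#' @return integer vector of caps.
#' @export
#' @examples
#' mismatch_cap(c(9, 10, 19, 20, 250))
mismatch_cap <- function(length) {
  if (any(length < 1)) stop("length must be >= 1")
  ifelse(length < 10, 1L, ifelse(length < 20, 2L, 3L))
}

#' Optimal global alignment of two sequences
#'
#' Needleman–Wunsch with linear per-column gap penalty and a deterministic
#' traceback (prefer match/mismatch, then gap in `a`, then gap in `b`).  The
#' ambiguity code `N` matches nothing and is scored/counted as a mismatch.
#'
#' @param a,b non-empty uppercase sequences over `A,C,G,T,N`.
#' @param scoring list with `match`, `mismatch`, `gap` (defaults +1/-1/-2).
#' @return list of class `"alignment_result"`: `aligned_a`, `aligned_b`
#'   (gapped, equal length), `matches`, `mismatches`, `gap_columns`, `score`
#'   and `identity` (= matches / alignment columns).
#' @export
#' @examples
#' global_align("ACGT", "AGGT")
global_align <- function(a, b, scoring = list(match = 1, mismatch = -1, gap = -2)) {
  if (!nzchar(a) || !nzchar(b)) stop("global alignment requires non-empty sequences")
  res <- .nw_align_cpp(a, b, as.integer(scoring$match),
                       as.integer(scoring$mismatch), as.integer(scoring$gap))
  res$identity <- res$matches / nchar(res$aligned_a)
  class(res) <- "alignment_result"
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat(sprintf("score %d | %d match, %d mismatch, %d gap | identity %.3f\n",
              x$score, x$matches, x$mismatches, x$gap_columns, x$identity))
  invisible(x)
}

# Acceptance rule shared by the anchored search.  `aln` is the raw list from
# .nw_align_cpp, `L` the nominal candidate length.
.tsd_accept <- function(aln, L, config) {
  cols <- nchar(aln$aligned_a)
  mmg <- aln$mismatches + aln$gap_columns
  if (mmg > mismatch_cap(L)) return(FALSE)
  if (aln$matches / cols <= config$min_identity) return(FALSE)
  a1 <- substr(aln$aligned_a, 1L, 1L); b1 <- substr(aln$aligned_b, 1L, 1L)
  a2 <- substr(aln$aligned_a, cols, cols); b2 <- substr(aln$aligned_b, cols, cols)
  a1 == b1 && a1 != "-" && a1 != "N" && a2 == b2 && a2 != "-" && a2 != "N"
}

# Core anchored search over (L, oL, oR) given the raw flank strings.
# `left` ends at the element span start, `right` begins at the span end.
# Returns NULL or a list(length, nominal_len, mismatch_gap_count, identity,
# left_offset, right_offset, aligned_a, aligned_b).
.tsd_search <- function(left, right, config) {
  nL <- nchar(left); nR <- nchar(right)
  top <- min(config$max_len, nL, nR)
  if (top < config$min_len) return(NULL)
  offs <- 0:config$max_offset
  for (L in seq(top, config$min_len)) {
    cap <- mismatch_cap(L)
    best <- NULL
    for (oL in offs) {
      if (oL + L > nL) next
      wa <- substr(left, nL - oL - L + 1L, nL - oL)
      for (oR in offs) {
        if (oR + L > nR) next
        wb <- substr(right, oR + 1L, oR + L)
        # any alignment's mismatch+gap count is >= the edit distance, so a
        # bounded edit-distance check safely skips hopeless windows
        if (.bounded_edit_cpp(wa, wb, cap) > cap) next
        aln <- .nw_align_cpp(wa, wb, config$match, config$mismatch, config$gap)
        if (!.tsd_accept(aln, L, config)) next
        mmg <- aln$mismatches + aln$gap_columns
        cand <- list(length = nchar(aln$aligned_a), nominal_len = L,
                     mismatch_gap_count = mmg,
                     identity = aln$matches / nchar(aln$aligned_a),
                     left_offset = oL, right_offset = oR,
                     aligned_a = aln$aligned_a, aligned_b = aln$aligned_b)
        if (is.null(best) ||
            mmg < best$mismatch_gap_count ||
            (mmg == best$mismatch_gap_count &&
             (oL + oR < best$left_offset + best$right_offset ||
              (oL + oR == best$left_offset + best$right_offset &&
               oL < best$left_offset))))
          best <- cand
      }
    }
    if (!is.null(best)) return(best)
  }
  NULL
}

#' Infer the TSD of one catalogued locus
#'
#' Extracts up to `max_len + max_offset` bp of flanking sequence on each side
#' of the locus span (clipped at contig edges) and runs the anchored search:
#' candidate lengths from `max_len` down to `min_len`, boundary offsets
#' `0..max_offset` per side; the first (longest) candidate passing the
#' identity, mismatch-cap and terminal-column rules is accepted.  Among
#' candidates of equal nominal length the one with the smallest
#' mismatch+gap count wins, then the smallest offset sum, then the smallest
#' left offset.
#'
#' @param genome a `"genome_accessor"` from [genome_open()].
#' @param locus a one-row catalogue entry (or list with `locus_id`, `chrom`,
#'   `start`, `end`, `structure`).
#' @param config a [tsd_config()].
#' @return a one-row `data.frame` TSD call (`locus_id`, `chrom`, `length`,
#'   per-copy genomic intervals, `mismatch_gap_count`, `identity`, offsets,
#'   `structure`), or `NULL` when no candidate passes or the flanks are too
#'   short.
#' @export
infer_tsd <- function(genome, locus, config = tsd_config()) {
  w <- config$max_len + config$max_offset
  fl <- fetch_flanks(genome, locus$chrom, locus$start, locus$end, w)
  if (nchar(fl$left) < config$min_len || nchar(fl$right) < config$min_len)
    return(NULL)
  hit <- .tsd_search(fl$left, fl$right, config)
  if (is.null(hit)) return(NULL)
  L <- hit$nominal_len
  data.frame(locus_id = locus$locus_id, chrom = locus$chrom,
             length = hit$length,
             left_start = locus$start - hit$left_offset - L,
             left_end = locus$start - hit$left_offset,
             right_start = locus$end + hit$right_offset,
             right_end = locus$end + hit$right_offset + L,
             mismatch_gap_count = hit$mismatch_gap_count,
             identity = hit$identity,
             left_offset = hit$left_offset, right_offset = hit$right_offset,
             structure = locus$structure, stringsAsFactors = FALSE)
}

#' Run the anchored TSD search directly on a flank pair
#'
#' The same search that [infer_tsd()] applies after flank extraction, exposed
#' for validation against [brute_force_tsd()] and for ad-hoc use on
#' sequences that are not backed by a genome.
#'
#' @param left,right uppercase flank sequences; `left` ends at the element
#'   boundary, `right` begins at it.
#' @param config a [tsd_config()].
#' @return `NULL` or a list with `length`, `nominal_len`,
#'   `mismatch_gap_count`, `identity`, `left_offset`, `right_offset` and the
#'   aligned sequences.
#' @export
tsd_from_flanks <- function(left, right, config = tsd_config()) {
  .tsd_search(toupper(left), toupper(right), config)
}

# Pure-R Needleman-Wunsch used only by the exhaustive oracle; written
# independently of the C++ kernel on purpose.  Same scoring contract and the
# same traceback preference (diagonal, gap in a, gap in b).
.r_nw_align <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  M <- matrix(0L, n + 1L, m + 1L)
  M[1L, ] <- gap * 0:m
  M[, 1L] <- gap * 0:n
  sc <- function(x, y) if (x == y && x != "N") match else mismatch
  for (i in seq_len(n)) for (j in seq_len(m))
    M[i + 1L, j + 1L] <- max(M[i, j] + sc(av[i], bv[j]),
                             M[i + 1L, j] + gap, M[i, j + 1L] + gap)
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L && M[i + 1L, j + 1L] == M[i, j] + sc(av[i], bv[j])) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1L; j <- j - 1L
    } else if (j > 0L && M[i + 1L, j + 1L] == M[i + 1L, j] + gap) {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
    } else {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
    }
  }
  gaps <- sum(ra == "-" | rb == "-")
  matches <- sum(ra == rb & ra != "-" & ra != "N")
  list(aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""),
       matches = matches, mismatches = length(ra) - gaps - matches,
       gap_columns = gaps, score = M[n + 1L, m + 1L])
}

#' Exhaustive TSD oracle for short flank pairs
#'
#' Enumerates every candidate `(L, left offset, right offset)` without any
#' search-order shortcut or pre-screen, aligns each window pair with an
#' independent pure-R aligner, applies the same acceptance rules, collects
#' all passing candidates and only then selects the winner (largest nominal
#' length, then fewest mismatches+gaps, then smallest offset sum, then
#' smallest left offset).  Must agree with [tsd_from_flanks()] on every
#' input; the tractability bound keeps it honest and fast.
#'
#' @param left,right flank sequences, each at most 64 bp.
#' @param config a [tsd_config()].
#' @return same shape as [tsd_from_flanks()] (without aligned sequences), or
#'   `NULL`.
#' @export
brute_force_tsd <- function(left, right, config = tsd_config()) {
  left <- toupper(left); right <- toupper(right)
  if (nchar(left) > 64L || nchar(right) > 64L)
    stop("brute_force_tsd is bounded to flanks of at most 64 bp")
  nL <- nchar(left); nR <- nchar(right)
  rows <- list()
  for (L in seq(config$min_len, min(config$max_len, nL, nR))) {
    for (oL in 0:config$max_offset) {
      if (oL + L > nL) next
      wa <- substr(left, nL - oL - L + 1L, nL - oL)
      for (oR in 0:config$max_offset) {
        if (oR + L > nR) next
        wb <- substr(right, oR + 1L, oR + L)
        aln <- .r_nw_align(wa, wb, config$match, config$mismatch, config$gap)
        cols <- nchar(aln$aligned_a)
        mmg <- aln$mismatches + aln$gap_columns
        ca <- c(substr(aln$aligned_a, 1L, 1L),
                substr(aln$aligned_a, cols, cols))
        cb <- c(substr(aln$aligned_b, 1L, 1L),
                substr(aln$aligned_b, cols, cols))
        ok <- mmg <= mismatch_cap(L) &&
              aln$matches / cols > config$min_identity &&
              all(ca == cb & ca != "-" & ca != "N")
        if (!ok) next
        rows[[length(rows) + 1L]] <-
          data.frame(L = L, oL = oL, oR = oR, length = cols,
                     mismatch_gap_count = mmg, identity = aln$matches / cols)
      }
    }
  }
  if (!length(rows)) return(NULL)
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$L, tab$mismatch_gap_count, tab$oL + tab$oR, tab$oL), ,
             drop = FALSE]
  w <- tab[1L, ]
  list(length = w$length, nominal_len = w$L,
       mismatch_gap_count = w$mismatch_gap_count, identity = w$identity,
       left_offset = w$oL, right_offset = w$oR)
}

#' Call TSDs for every locus in a catalogue
#'
#' Applies [infer_tsd()] to each locus in deterministic (chrom, start) order;
#' loci without an acceptable candidate simply yield no row.
#'
#' @param genome a `"genome_accessor"`.
#' @param catalog an `"hml2_catalog"`.
#' @param config a [tsd_config()].
#' @param skip_flagged drop loci flagged `short_ltr` or `adjacent_ltr`
#'   before calling.
#' @return a `data.frame` of TSD calls (possibly 0-row, with full columns).
#' @export
call_all <- function(genome, catalog, config = tsd_config(),
                     skip_flagged = FALSE) {
  empty <- data.frame(locus_id = character(), chrom = character(),
                      length = integer(), left_start = integer(),
                      left_end = integer(), right_start = integer(),
                      right_end = integer(), mismatch_gap_count = integer(),
                      identity = numeric(), left_offset = integer(),
                      right_offset = integer(), structure = character(),
                      stringsAsFactors = FALSE)
  if (nrow(catalog) == 0L) return(empty)
  cat_df <- catalog[order(catalog$chrom, catalog$start), , drop = FALSE]
  if (skip_flagged)
    cat_df <- cat_df[!(cat_df$short_ltr | cat_df$adjacent_ltr), , drop = FALSE]
  calls <- vector("list", nrow(cat_df))
  for (i in seq_len(nrow(cat_df)))
    calls[[i]] <- infer_tsd(genome, cat_df[i, ], config)
  calls <- calls[!vapply(calls, is.null, NA)]
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
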