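# Synthetic genomes with planted ERV insertions.  The generator models the
# integration mechanism directly: the tsd_len bases at the insertion point
# are duplicated to both sides of the inserted element (a direct repeat),
# then a configurable number of substitutions (and optionally indels) is
# injected into one copy.  Matching rmsk-dialect and DGV-dialect files are
# emitted (TSDs deliberately unannotated, as in real RepeatMasker output)
# together with a ground-truth ledger, so every pipeline stage can be tested
# without external downloads.

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(n, gc = 0.41) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Specify one planted element
#'
#' @param structure `"solo_ltr"`, `"provirus"` or `"truncated_provirus"`.
#' @param ltr_len LTR length in bp (proviral LTR pairs are identical copies,
#'   as at integration).
#' @param internal_len internal (HERVK-int) segment length in bp; ignored
#'   for solo LTRs.
#' @param internal_gap signed gap between LTR and internal segment, in
#'   `[-1, 100]`; `-1` means a one-base annotation overlap.
#' @param strand `"+"` or `"-"` (annotation strand; TSDs are strand-blind).
#' @param tsd_len target site duplication length in bp, 0–500; 0 plants no
#'   duplication.
#' @param tsd_mutations number of substitutions injected into the right
#'   copy, at interior positions (a boundary change would shorten the
#'   observable duplication and make the planted length ill-posed).
#' @param tsd_indels number of 1-bp indels injected into the right copy
#'   (off by default so the planted mutation count equals the expected
#'   alignment mismatch+gap count).
#' @param offset_left,offset_right intervening bases (0–2) between each TSD
#'   copy and the element boundary.
#' @param scenario which variant record to emit: `"none"`,
#'   `"preintegration_deletion"` (element plus the left TSD copy deleted),
#'   `"regional_indel"` (element plus both copies plus 200-bp margins), or
#'   `"pseudo_tsd"` (long homologous flanks from segmental duplication, no
#'   variant record; generation-only, the caller is expected to call it).
#' @param ltr_name repeat-model name to annotate the LTR(s) with; planting
#'   e.g. `"LTR5B"` creates a decoy the catalogue must exclude.
#' @param chrom index (1-based) of the chromosome to plant on.
#' @return a classed list describing the element.
#' @export
sim_element <- function(structure = c("solo_ltr", "provirus",
                                      "truncated_provirus"),
                        ltr_len = 968L, internal_len = 4000L,
                        internal_gap = 10L, strand = "+", tsd_len = 12L,
                        tsd_mutations = 0L, tsd_indels = 0L,
                        offset_left = 0L, offset_right = 0L,
                        scenario = c("none", "preintegration_deletion",
                                     "regional_indel", "pseudo_tsd"),
                        ltr_name = "LTR5_Hs", chrom = 1L) {
  structure_ <- match.arg(structure)
  scenario <- match.arg(scenario)
  stopifnot(ltr_len >= 1,
            internal_len >= if (structure_ == "solo_ltr") 0L else 1L,
            internal_gap >= -1, internal_gap <= 100,
            strand %in% c("+", "-"),
            tsd_len >= 0, tsd_len <= 500,
            tsd_mutations >= 0, tsd_indels >= 0,
            offset_left >= 0, offset_left <= 2,
            offset_right >= 0, offset_right <= 2,
            tsd_mutations + tsd_indels <= max(0L, tsd_len - 2L))
  structure(list(structure = structure_, ltr_len = as.integer(ltr_len),
                 internal_len = as.integer(internal_len),
                 internal_gap = as.integer(internal_gap), strand = strand,
                 tsd_len = as.integer(tsd_len),
                 tsd_mutations = as.integer(tsd_mutations),
                 tsd_indels = as.integer(tsd_indels),
                 offset_left = as.integer(offset_left),
                 offset_right = as.integer(offset_right),
                 scenario = scenario, ltr_name = ltr_name,
                 chrom = as.integer(chrom)),
            class = "sim_element")
}

#' Simulation configuration
#'
#' @param seed integer seed; a fixed seed makes [simulate_hml2()] output
#'   byte-identical across runs.
#' @param n_chroms number of chromosomes, named `chr1`, `chr2`, … (`chr23`
#'   and `chr24` become `chrX`/`chrY` so sex-chromosome behaviour is
#'   testable).
#' @param chrom_len background length of each chromosome in bp (planted
#'   material extends it).
#' @param gc background GC fraction (i.i.d. bases).
#' @param elements list of [sim_element()] specs.
#' @param confounders also emit, per chromosome carrying elements, a
#'   duplication-subtype record over the first element and a background
#'   deletion covering no locus — food for filters i and ii.
#' @return a classed list.
#' @export
sim_config <- function(seed = 1L, n_chroms = 1L, chrom_len = 50000L,
                       gc = 0.41, elements = list(), confounders = FALSE) {
  stopifnot(n_chroms >= 1, n_chroms <= 24, chrom_len >= 5000,
            gc > 0, gc < 1,
            all(vapply(elements, inherits, NA, "sim_element")))
  if (length(elements))
    stopifnot(all(vapply(elements, `[[`, 0L, "chrom") <= n_chroms))
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_len = as.integer(chrom_len), gc = gc,
                 elements = elements, confounders = isTRUE(confounders)),
            class = "sim_config")
}

.sim_chrom_names <- function(n) c(paste0("chr", 1:22), "chrX", "chrY")[seq_len(n)]

# Inject substitutions (and optional 1-bp indels) into one TSD copy.
# Mutations go to interior positions (2..len-1): a change at the first or
# last base shortens the observable duplication by definition, which would
# make the planted length ill-posed as ground truth.
.mutate_copy <- function(seq, n_sub, n_indel) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  interior <- function(vv) seq_len(length(vv))[-c(1L, length(vv))]
  pos <- integer(0)
  if (n_sub > 0L) {
    pos <- sort(sample(interior(v), n_sub))
    for (p in pos) v[p] <- sample(setdiff(.BASES, v[p]), 1L)
  }
  if (n_indel > 0L) {
    for (k in seq_len(n_indel)) {
      p <- sample(interior(v), 1L)
      if (stats::runif(1) < 0.5 && length(v) > 2L) v <- v[-p]
      else v <- append(v, sample(.BASES, 1L), after = p)
      pos <- c(pos, p)
    }
  }
  list(seq = paste(v, collapse = ""), positions = pos)
}

# Build one element's sequence and component annotation offsets (0-based,
# relative to the element span start).  A gap of -1 makes the neighbouring
# annotations share one base.
.build_element <- function(el) {
  ltr <- .random_dna(el$ltr_len)
  if (el$structure == "solo_ltr") {
    return(list(seq = ltr,
                comps = data.frame(start = 0L, end = el$ltr_len,
                                   name = el$ltr_name, class = "LTR",
                                   stringsAsFactors = FALSE)))
  }
  g <- el$internal_gap
  int_start <- el$ltr_len + g
  int_end <- int_start + el$internal_len
  if (el$structure == "truncated_provirus") {
    total <- int_end
    comps <- data.frame(start = c(0L, int_start), end = c(el$ltr_len, int_end),
                        name = c(el$ltr_name, "HERVK-int"),
                        class = c("LTR", "LTR"), stringsAsFactors = FALSE)
  } else {
    ltr2_start <- int_end + g
    total <- ltr2_start + el$ltr_len
    comps <- data.frame(start = c(0L, int_start, ltr2_start),
                        end = c(el$ltr_len, int_end, ltr2_start + el$ltr_len),
                        name = c(el$ltr_name, "HERVK-int", el$ltr_name),
                        class = c("LTR", "LTR", "LTR"),
                        stringsAsFactors = FALSE)
  }
  v <- strsplit(.random_dna(total), "", fixed = TRUE)[[1L]]
  internal <- strsplit(.random_dna(el$internal_len), "", fixed = TRUE)[[1L]]
  v[seq_len(el$ltr_len)] <- strsplit(ltr, "", fixed = TRUE)[[1L]]
  if (el$internal_len > 0L)
    v[(int_start + 1L):int_end] <- internal
  if (el$structure == "provirus")
    v[(ltr2_start + 1L):(ltr2_start + el$ltr_len)] <-
      strsplit(ltr, "", fixed = TRUE)[[1L]]
  list(seq = paste(v, collapse = ""), comps = comps)
}

#' Simulate a genome with planted ERV insertions
#'
#' Generates i.i.d. background sequence at the configured GC, plants each
#' element by duplicating the `tsd_len` target bases to both sides of the
#' inserted element (mutating the right copy), and emits a matching
#' rmsk-dialect annotation table, a DGV-dialect variant table (one record per
#' scenario-bearing element, 1-based on disk) and a ground-truth ledger.
#' Placements are spaced at least 1 kb apart and 600 bp from chromosome
#' ends; elements that do not fit raise an error before any output.
#' Identical seed and configuration give byte-identical files.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, writes `genome.fa`,
#'   `rmsk.tsv`, `dgv.tsv` and `truth.tsv` there.
#' @return a list of class `"hml2_sim"`: `genome`
#'   ([Biostrings::DNAStringSet]), `rmsk`, `dgv`, `truth` data.frames,
#'   `config`, and `paths` when `dir` was given.
#' @export
simulate_hml2 <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- .sim_chrom_names(config$n_chroms)
  margin <- 600L
  el_chrom <- vapply(config$elements, `[[`, 0L, "chrom")

  genome <- character(config$n_chroms)
  rmsk_rows <- list()
  dgv_rows <- list()
  truth_rows <- list()
  acc_n <- 0L

  for (ci in seq_len(config$n_chroms)) {
    idx <- which(el_chrom == ci)
    bg <- .random_dna(config$chrom_len, config$gc)
    if (!length(idx)) { genome[ci] <- bg; next }
    k <- length(idx)
    slot <- (config$chrom_len - 2L * margin) %/% k
    max_tsd <- max(vapply(config$elements[idx], `[[`, 0L, "tsd_len"))
    if (slot < 1000L + max_tsd)
      stop(sprintf("elements do not fit chromosome %s: %d slots of %d bp",
                   chroms[ci], k, slot))
    p <- margin + (seq_len(k) - 1L) * slot   # insertion points in bg coords
    pieces <- character(0)
    prev <- 0L       # bg consumed so far
    added <- 0L      # inserted material so far
    for (j in seq_len(k)) {
      el <- config$elements[[idx[j]]]
      tsd <- if (el$tsd_len > 0L)
               substr(bg, p[j] + 1L, p[j] + el$tsd_len) else ""
      mut <- if (el$tsd_len > 0L)
               .mutate_copy(tsd, el$tsd_mutations, el$tsd_indels)
             else list(seq = "", positions = integer(0))
      built <- .build_element(el)
      off_l <- .random_dna(el$offset_left)
      off_r <- .random_dna(el$offset_right)
      pieces <- c(pieces, substr(bg, prev + 1L, p[j] + el$tsd_len),
                  off_l, built$seq, off_r, mut$seq)
      left_start <- p[j] + added
      left_end <- left_start + el$tsd_len
      span_start <- left_end + el$offset_left
      span_end <- span_start + nchar(built$seq)
      right_start <- span_end + el$offset_right
      right_end <- right_start + nchar(mut$seq)
      prev <- p[j] + el$tsd_len
      added <- added + el$offset_left + nchar(built$seq) + el$offset_right +
               nchar(mut$seq)
      rmsk_rows[[length(rmsk_rows) + 1L]] <- data.frame(
        genoName = chroms[ci], genoStart = span_start + built$comps$start,
        genoEnd = span_start + built$comps$end, strand = el$strand,
        repName = built$comps$name, repClass = built$comps$class,
        repFamily = "ERVK", stringsAsFactors = FALSE)
      accession <- NA_character_
      intended <- NA_character_
      if (el$scenario == "preintegration_deletion") {
        acc_n <- acc_n + 1L
        accession <- sprintf("essv%04d", acc_n)
        intended <- "preintegration_consistent"
        dgv_rows[[length(dgv_rows) + 1L]] <- data.frame(
          accession = accession, chrom = chroms[ci], start = left_start,
          end = span_end, var_type = "CNV", var_subtype = "deletion",
          stringsAsFactors = FALSE)
      } else if (el$scenario == "regional_indel") {
        acc_n <- acc_n + 1L
        accession <- sprintf("essv%04d", acc_n)
        intended <- "regional_indel"
        dgv_rows[[length(dgv_rows) + 1L]] <- data.frame(
          accession = accession, chrom = chroms[ci],
          start = max(0L, left_start - 200L), end = right_end + 200L,
          var_type = "CNV", var_subtype = "loss", stringsAsFactors = FALSE)
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        element_id = sprintf("el%03d", idx[j]),
        locus_id = sprintf("%s:%d-%d", chroms[ci], span_start, span_end),
        chrom = chroms[ci], span_start = span_start, span_end = span_end,
        structure = el$structure, strand = el$strand, ltr_name = el$ltr_name,
        tsd_len = el$tsd_len, left_start = left_start, left_end = left_end,
        right_start = right_start, right_end = right_end,
        offset_left = el$offset_left, offset_right = el$offset_right,
        n_sub = el$tsd_mutations, n_indel = el$tsd_indels,
        mut_positions = paste(mut$positions, collapse = ","),
        left_seq = tsd, right_seq = mut$seq, scenario = el$scenario,
        intended_status = intended, accession = accession,
        stringsAsFactors = FALSE)
    }
    pieces <- c(pieces, substr(bg, prev + 1L, config$chrom_len))
    genome[ci] <- paste(pieces, collapse = "")
    if (config$confounders) {
      first <- truth_rows[[length(truth_rows) - k + 1L]]
      acc_n <- acc_n + 1L
      dgv_rows[[length(dgv_rows) + 1L]] <- data.frame(
        accession = sprintf("essv%04d", acc_n), chrom = chroms[ci],
        start = max(0L, first$span_start - 50L), end = first$span_end + 50L,
        var_type = "CNV", var_subtype = "duplication",
        stringsAsFactors = FALSE)
      acc_n <- acc_n + 1L
      dgv_rows[[length(dgv_rows) + 1L]] <- data.frame(
        accession = sprintf("essv%04d", acc_n), chrom = chroms[ci],
        start = 50L, end = 350L, var_type = "CNV", var_subtype = "deletion",
        stringsAsFactors = FALSE)
    }
  }

  dna <- Biostrings::DNAStringSet(setNames(genome, chroms))
  rmsk <- if (length(rmsk_rows)) do.call(rbind, rmsk_rows) else
    data.frame(genoName = character(), genoStart = integer(),
               genoEnd = integer(), strand = character(),
               repName = character(), repClass = character(),
               repFamily = character(), stringsAsFactors = FALSE)
  dgv <- if (length(dgv_rows)) do.call(rbind, dgv_rows) else
    data.frame(accession = character(), chrom = character(),
               start = integer(), end = integer(), var_type = character(),
               var_subtype = character(), stringsAsFactors = FALSE)
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else NULL
  rownames(rmsk) <- NULL
  if (!is.null(truth)) rownames(truth) <- NULL

  out <- list(genome = dna, rmsk = rmsk, dgv = dgv, truth = truth,
              config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  rmsk = file.path(dir, "rmsk.tsv"),
                  dgv = file.path(dir, "dgv.tsv"),
                  truth = file.path(dir, "truth.tsv"))
    Biostrings::writeXStringSet(dna, paths$genome)
    write.table(rmsk, paths$rmsk, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_dgv(dgv, paths$dgv)
    write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- paths
  }
  class(out) <- "hml2_sim"
  out
}

#' @export
print.hml2_sim <- function(x, ...) {
  cat(sprintf("<hml2_sim: %d chromosome(s), %d planted element(s), %d variant record(s)>\n",
              length(x$genome),
              if (is.null(x$truth)) 0L else nrow(x$truth), nrow(x$dgv)))
  invisible(x)
}

#' Compare pipeline output against the simulation ground truth
#'
#' Joins TSD calls and classified candidates back onto the truth ledger by
#' locus identifier and reports per-element recovery: whether a call was
#' expected (the planted duplication satisfies the caller's own acceptance
#' rules), whether the called length and mismatch count equal the planted
#' ones, the classification outcome, and preintegration/regional crossovers.
#'
#' @param truth the `truth` data.frame from [simulate_hml2()].
#' @param candidates classified candidates ([classify_candidates()]); may be
#'   empty.
#' @param tsd_calls TSD calls ([call_all()]); may be empty.
#' @param config the [tsd_config()] the calls were made with (defines which
#'   planted loads are within band).
#' @return list with `per_element` (data.frame) and `summary` (named list of
#'   counts and rates).
#' @export
truth_compare <- function(truth, candidates, tsd_calls,
                          config = tsd_config()) {
  stopifnot(is.data.frame(truth), nrow(truth) > 0L)
  if (nrow(tsd_calls) > 0L &&
      !any(tsd_calls$locus_id %in% truth$locus_id))
    stop("TSD calls do not match this simulation (no shared locus)")
  if (nrow(candidates) > 0L &&
      !any(candidates$locus_id %in% truth$locus_id))
    stop("candidates do not match this simulation (no shared locus)")
  m <- match(truth$locus_id, tsd_calls$locus_id)
  load <- truth$n_sub + truth$n_indel
  cap <- ifelse(truth$tsd_len >= 1, mismatch_cap(pmax(truth$tsd_len, 1L)), 0L)
  within_band <- truth$tsd_len >= config$min_len &
    truth$tsd_len <= config$max_len & truth$n_indel == 0L &
    truth$n_sub <= cap &
    (truth$tsd_len - truth$n_sub) / pmax(truth$tsd_len, 1L) > config$min_identity
  per <- data.frame(
    element_id = truth$element_id, locus_id = truth$locus_id,
    tsd_len = truth$tsd_len, planted_load = load,
    within_band = within_band,
    called = !is.na(m),
    called_length = tsd_calls$length[m],
    called_mm = tsd_calls$mismatch_gap_count[m],
    stringsAsFactors = FALSE)
  per$length_exact <- !is.na(m) & per$called_length == truth$tsd_len
  per$mm_exact <- !is.na(m) & per$called_mm == load
  cm <- match(truth$locus_id, candidates$locus_id)
  per$called_status <- candidates$status[cm]
  per$intended_status <- truth$intended_status
  per$crossover <- !is.na(per$intended_status) & !is.na(per$called_status) &
    per$intended_status != per$called_status &
    per$called_status != "ambiguous"
  over <- within_band == FALSE & truth$tsd_len > 0L
  per$overband_ok <- over &
    (!per$called | (!is.na(per$called_length) &
                      per$called_length < truth$tsd_len))
  summary <- list(
    n_elements = nrow(truth),
    n_within_band = sum(within_band),
    n_called = sum(per$called),
    n_length_exact = sum(per$length_exact[within_band]),
    n_mm_exact = sum(per$mm_exact[within_band]),
    recovery_rate = if (any(within_band))
      mean(per$length_exact[within_band] & per$mm_exact[within_band]) else NA_real_,
    n_overband = sum(over),
    n_overband_ok = sum(per$overband_ok[over]),
    n_classified = sum(!is.na(per$called_status)),
    n_status_correct = sum(!is.na(per$intended_status) &
                             !is.na(per$called_status) &
                             per$intended_status == per$called_status),
    n_crossovers = sum(per$crossover))
  list(per_element = per, summary = summary)
}
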