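# TSD inference: mismatch bands, global alignment, the anchored search and
# its exhaustive oracle, planted recovery, strand symmetry.

test_that("mismatch bands switch exactly at 10 and 20 bp", {
  expect_equal(mismatch_cap(c(1, 4, 9)), c(1L, 1L, 1L))
  expect_equal(mismatch_cap(c(10, 19)), c(2L, 2L))
  expect_equal(mismatch_cap(c(20, 250, 500)), c(3L, 3L, 3L))
  expect_error(mismatch_cap(0), ">= 1")
})

test_that("global alignment counts match/mismatch/gap columns correctly", {
  a <- global_align("ACGT", "ACGT")
  expect_equal(c(a$matches, a$mismatches, a$gap_columns), c(4L, 0L, 0L))
  expect_equal(a$identity, 1.0)
  b <- global_align("ACGT", "AGGT")
  expect_equal(c(b$matches, b$mismatches), c(3L, 1L))
  expect_equal(b$identity, 0.75)
  # N matches nothing, including itself
  n <- global_align("ANA", "ANA")
  expect_equal(c(n$matches, n$mismatches), c(2L, 1L))
  # deleting one base from a 12-mer costs exactly one gap column
  g <- global_align("ACGTTGCAGGTA", "ACGTGCAGGTA")
  expect_equal(g$gap_columns, 1L)
  expect_equal(g$matches, 11L)
  # de-gapping the aligned strings reproduces the inputs
  expect_equal(gsub("-", "", g$aligned_a), "ACGTTGCAGGTA")
  expect_equal(gsub("-", "", g$aligned_b), "ACGTGCAGGTA")
  expect_error(global_align("", "ACGT"), "non-empty")
})

# independent check of score optimality: enumerate every alignment of two
# short strings recursively and take the best score
enumerate_best_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (substr(a, i, i) == substr(b, j, j) && substr(a, i, i) != "N")
        match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

test_that("alignment scores are optimal (exhaustive enumeration, Biostrings)", {
  set.seed(51)
  for (k in 1:12) {
    a <- rand_dna(sample(3:7, 1))
    b <- rand_dna(sample(3:7, 1))
    expect_equal(global_align(a, b)$score, enumerate_best_score(a, b),
                 info = paste(a, b))
  }
  # independent implementation cross-check on longer sequences
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (k in 1:10) {
    a <- rand_dna(sample(10:40, 1))
    b <- rand_dna(sample(10:40, 1))
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2)
    expect_equal(global_align(a, b)$score, Biostrings::score(ref),
                 info = paste(a, b))
  }
})

test_that("planted TSDs come back at the planted length and load", {
  set.seed(52)
  # exact 12-bp duplicate at zero offsets
  fp <- make_flank_pair(12L)
  hit <- tsd_from_flanks(fp$left, fp$right)
  expect_equal(hit$length, 12L)
  expect_equal(hit$mismatch_gap_count, 0L)
  expect_equal(hit$identity, 1.0)
  expect_equal(c(hit$left_offset, hit$right_offset), c(0L, 0L))
  # 30-bp TSD with 2 substitutions in one copy
  fp <- make_flank_pair(30L, n_sub = 2L)
  hit <- tsd_from_flanks(fp$left, fp$right)
  expect_equal(hit$length, 30L)
  expect_equal(hit$mismatch_gap_count, 2L)
  # two intervening bases before the left LTR boundary (footnote-d geometry),
  # built by hand so no longer imperfect duplication can outrank the TSD
  tsd <- "ACGTTGACCTGATCAA"
  left <- paste0("GGGGGGGGGG", tsd, "CA")
  right <- paste0(tsd, "GGGGGGGGGG")
  hit <- tsd_from_flanks(left, right)
  expect_equal(hit$length, 16L)
  expect_equal(hit$left_offset, 2L)
  expect_equal(hit$right_offset, 0L)
})

test_that("identity and cap bounds are strict at the band edges", {
  # 8-bp pair with 1 interior mismatch: identity 7/8, within cap(8)=1
  left <- paste0("TTTTTTTTTT", "ACGTACGT")
  right <- paste0("ACGAACGT", "GGGGGGGGGG")
  hit <- tsd_from_flanks(left, right, tsd_config(min_len = 8))
  expect_equal(hit$length, 8L)
  expect_equal(hit$mismatch_gap_count, 1L)
  # 8-bp pair with 2 interior mismatches: identity 0.75 is not > 0.75
  right2 <- paste0("ACTAACGT", "GGGGGGGGGG")
  expect_null(tsd_from_flanks(left, right2, tsd_config(min_len = 8)))
})

test_that("anchored search equals the exhaustive oracle on random and adversarial flanks", {
  set.seed(53)
  cfg <- tsd_config()
  n_checked <- 0L
  check_pair <- function(left, right) {
    fast <- tsd_from_flanks(left, right, cfg)
    slow <- brute_force_tsd(left, right, cfg)
    if (is.null(slow)) expect_null(fast)
    else expect_equal(fast[c("length", "nominal_len", "mismatch_gap_count",
                             "identity", "left_offset", "right_offset")],
                      slow[c("length", "nominal_len", "mismatch_gap_count",
                             "identity", "left_offset", "right_offset")],
                      info = paste(left, right))
    invisible(NULL)
  }
  # random pairs, mostly without any planted duplication
  for (k in 1:60) {
    check_pair(rand_dna(sample(8:24, 1)), rand_dna(sample(8:24, 1)))
    n_checked <- n_checked + 1L
  }
  # planted structure at the band edges: offsets 0-2, loads at cap and cap+1
  for (L in c(6L, 9L, 10L, 19L, 20L, 30L)) {
    for (m in 0:min(mismatch_cap(L) + 1L, L - 2L)) {
      for (off in 0:2) {
        fp <- make_flank_pair(L, n_sub = m, off_left = off,
                              flank_len = min(64L, L + off + 10L))
        check_pair(fp$left, fp$right)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 120L)
})

test_that("random flanks rarely produce calls at min_len 10 but may at 4", {
  set.seed(54)
  calls4 <- 0L; calls10 <- 0L
  for (k in 1:100) {
    l <- rand_dna(40); r <- rand_dna(40)
    if (!is.null(tsd_from_flanks(l, r, tsd_config(min_len = 4)))) calls4 <- calls4 + 1L
    if (!is.null(tsd_from_flanks(l, r, tsd_config(min_len = 10)))) calls10 <- calls10 + 1L
  }
  expect_equal(calls10, 0L)
  expect_gte(calls4, calls10)
})

test_that("calls are strand-symmetric and satisfy their own invariants", {
  set.seed(55)
  els <- list(sim_element("solo_ltr", ltr_len = 700L, tsd_len = 25L,
                          tsd_mutations = 2L),
              sim_element("provirus", ltr_len = 500L, internal_len = 1200L,
                          tsd_len = 40L, strand = "-", chrom = 2L))
  sim <- simulate_hml2(sim_config(seed = 9, n_chroms = 2, chrom_len = 12000,
                                  elements = els))
  g <- genome_open(sim$genome)
  cat <- sim_catalog(sim)
  calls <- call_all(g, cat)
  expect_equal(nrow(calls), 2L)
  # invariants re-assertable from the genome: copy windows really align
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    expect_true(cl$length >= 4L && cl$length <= 500L)
    expect_gt(cl$identity, 0.75)
    expect_lte(cl$mismatch_gap_count, mismatch_cap(cl$length))
    wa <- genome_fetch(g, cl$chrom, cl$left_start, cl$left_end)
    wb <- genome_fetch(g, cl$chrom, cl$right_start, cl$right_end)
    aln <- global_align(wa, wb)
    expect_equal(aln$mismatches + aln$gap_columns, cl$mismatch_gap_count)
  }
  # reverse-complement the genome, mirror the loci: identical length and load
  rc <- Biostrings::reverseComplement(sim$genome)
  grc <- genome_open(rc)
  lens <- chrom_lengths(g)
  for (i in seq_len(nrow(cat))) {
    loc <- cat[i, ]
    L <- lens[[loc$chrom]]
    mirrored <- list(locus_id = loc$locus_id, chrom = loc$chrom,
                     start = L - loc$end, end = L - loc$start,
                     structure = loc$structure)
    fwd <- calls[calls$locus_id == loc$locus_id, ]
    rev <- infer_tsd(grc, mirrored, tsd_config())
    expect_equal(rev$length, fwd$length)
    expect_equal(rev$mismatch_gap_count, fwd$mismatch_gap_count)
  }
})

test_that("contig-edge loci and the brute-force bound are handled", {
  set.seed(56)
  g <- genome_open(Biostrings::DNAStringSet(c(chrE = rand_dna(50))))
  # locus flush against the contig start: left flank shorter than min_len
  expect_null(infer_tsd(g, list(locus_id = "x", chrom = "chrE", start = 2L,
                                end = 40L, structure = "solo_ltr"),
                        tsd_config(min_len = 4)))
  expect_error(brute_force_tsd(rand_dna(65), rand_dna(10)), "64")
})
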