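# Catalogue assembly: LTR selection, LTR/internal linking, structure labels,
# flags, autosomal counting.

test_that("LTR selection is exact-name and excludes LTR5A/LTR5B", {
  recs <- repeat_records("chr1", c(0, 100, 200, 300, 400) * 10L,
                         c(0, 100, 200, 300, 400) * 10L + 968L,
                         rep_name = c("LTR5_Hs", "LTR5A", "LTR5B", "LTR5",
                                      "LTR5_Hs?"))
  sel <- select_hml2_ltrs(recs)
  expect_equal(sel$rep_name, c("LTR5_Hs", "LTR5"))
  expect_equal(nrow(select_hml2_ltrs(no_records())), 0L)
})

test_that("gap band [-1, 100] governs LTR/internal linking", {
  mk <- function(int_start, int_strand = "+", int_end = 6000L) {
    ltrs <- repeat_records("chr1", 1000L, 1968L)
    ints <- repeat_records("chr1", int_start, int_end,
                           strand = int_strand, rep_name = "HERVK-int")
    assemble_loci(ltrs, ints, catalog_config())
  }
  # gaps -1, 0, 100 link; 101 and strand mismatch do not
  expect_equal(mk(1967L)$structure, "truncated_provirus")   # gap -1 (overlap)
  expect_equal(mk(1968L)$structure, "truncated_provirus")   # gap 0
  expect_equal(mk(2068L)$structure, "truncated_provirus")   # gap 100
  expect_equal(mk(2069L)$structure, "solo_ltr")             # gap 101
  expect_equal(mk(1960L)$structure, "solo_ltr")             # overlap beyond -1
  expect_equal(mk(1968L, int_strand = "-")$structure, "solo_ltr")
  # unlinked internal is an orphan, logged not catalogued
  orphans <- attr(mk(2069L), "orphan_internals")
  expect_equal(nrow(orphans), 1L)
  expect_equal(orphans$start, 2069L)
})

test_that("LTR-int-LTR chains become proviruses with the right span", {
  ltrs <- repeat_records("chr1", c(1000L, 6000L), c(1968L, 6968L))
  ints <- repeat_records("chr1", 1969L, 6000L, rep_name = "HERVK-int")
  cat <- assemble_loci(ltrs, ints, catalog_config())
  expect_equal(nrow(cat), 1L)
  expect_equal(cat$structure, "provirus")
  expect_equal(c(cat$start, cat$end), c(1000L, 6968L))
  expect_equal(c(cat$ltr2_start, cat$ltr2_end), c(6000L, 6968L))
  expect_equal(cat$locus_id, "chr1:1000-6968")
  # far-away internal: solo LTRs plus orphan
  ints2 <- repeat_records("chr1", 2100L, 5800L, rep_name = "HERVK-int")
  cat2 <- assemble_loci(ltrs, ints2, catalog_config())
  expect_equal(sort(cat2$structure), c("solo_ltr", "solo_ltr"))
})

test_that("tandem >2-LTR chains split greedily; leftover LTRs become solo", {
  # L I L I L: first triple is a provirus, trailing I orphaned, last L solo
  ltrs <- repeat_records("chr1", c(1000L, 6000L, 11000L),
                         c(1968L, 6968L, 11968L))
  ints <- repeat_records("chr1", c(1970L, 6970L), c(5990L, 10990L),
                         rep_name = "HERVK-int")
  cat <- assemble_loci(ltrs, ints, catalog_config())
  expect_equal(cat$structure, c("provirus", "solo_ltr"))
  expect_equal(cat$start, c(1000L, 11000L))
  expect_equal(nrow(attr(cat, "orphan_internals")), 1L)
})

test_that("assembly is invariant under input ordering", {
  set.seed(31)
  ltrs <- repeat_records(rep(c("chr1", "chr2"), each = 3),
                         c(1000L, 6000L, 20000L, 500L, 3000L, 9000L),
                         c(1968L, 6968L, 20968L, 1468L, 3968L, 9968L))
  ints <- repeat_records(c("chr1", "chr2"), c(1969L, 4000L), c(5999L, 8990L),
                         rep_name = "HERVK-int")
  ref <- assemble_loci(ltrs, ints, catalog_config())
  for (k in 1:3) {
    perm <- assemble_loci(ltrs[sample(nrow(ltrs)), ], ints[sample(nrow(ints)), ],
                          catalog_config())
    expect_identical(perm$locus_id, ref$locus_id)
    expect_identical(perm$structure, ref$structure)
  }
  # partition: every selected LTR appears in exactly one locus
  n_ltr_slots <- sum(ref$structure == "provirus") * 2L +
    sum(ref$structure != "provirus")
  expect_equal(n_ltr_slots, nrow(ltrs))
})

test_that("short and adjacent LTRs are flagged, never dropped", {
  ltrs <- repeat_records("chr1", c(1000L, 5000L, 5030L, 9000L),
                         c(1040L, 5025L, 5998L, 9968L))
  cat <- assemble_loci(ltrs, no_records(), catalog_config())
  expect_equal(nrow(cat), 4L)                    # flags are not exclusions
  expect_true(cat$short_ltr[cat$start == 1000L])   # 40 bp < 50
  expect_true(all(cat$adjacent_ltr[cat$start %in% c(5000L, 5030L)]))  # gap 5
  expect_false(cat$adjacent_ltr[cat$start == 9000L])
  expect_false(cat$short_ltr[cat$start == 9000L])
})

test_that("autosomal LTR counting uses records on chr1-22 only", {
  recs <- repeat_records(c("chrX", "chrY"), c(0L, 0L), c(968L, 968L))
  expect_equal(count_autosomal_ltrs(recs), 0L)
  recs2 <- repeat_records(c("chr1", "chr22", "chrX", "chr7"),
                          c(0, 2000, 4000, 6000), c(968, 2968, 4968, 6968))
  expect_equal(count_autosomal_ltrs(recs2), 3L)
  # synthetic genome: the count equals the number of planted autosomal copies
  set.seed(32)
  els <- list(sim_element("solo_ltr", tsd_len = 8L, chrom = 1L),
              sim_element("provirus", ltr_len = 500L, internal_len = 1500L,
                          tsd_len = 6L, chrom = 2L),
              sim_element("solo_ltr", tsd_len = 8L, chrom = 23L))  # chrX
  sim <- simulate_hml2(sim_config(seed = 5, n_chroms = 23, chrom_len = 15000,
                                  elements = els))
  ltrs <- select_hml2_ltrs(sim_repeats(sim))
  expect_equal(count_autosomal_ltrs(ltrs), 3L)  # 1 solo + 2 proviral copies
})
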