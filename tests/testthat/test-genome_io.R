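# Format boundary: parsers, coordinate conventions, flank extraction,
# report round trips.

test_that("rmsk parsing takes UCSC coordinates as 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("genoName", "genoStart", "genoEnd", "strand", "repName",
            "repClass", "repFamily"), collapse = "\t"),
    # Table-style locus chr7:16,237,347-16,238,314 (1-based) is rmsk start 16237346
    "chr7\t16237346\t16238314\t+\tLTR5_Hs\tLTR\tERVK",
    "chr7\t20000\t20968\tC\tLTR5\tLTR\tERVK"), path)
  rec <- read_repeatmasker(path)
  expect_equal(rec$start[1], 16237346L)
  expect_equal(rec$end[1], 16238314L)
  expect_equal(rec$strand[2], "-")   # RepeatMasker's 'C' is minus
  # headerless 16/17-column dialects
  row17 <- paste(c(585, 2000, 10, 0, 0, "chr1", 100, 200, -1000, "+",
                   "LTR5_Hs", "LTR", "ERVK", 1, 100, 0, 1), collapse = "\t")
  writeLines(row17, path)
  expect_equal(read_repeatmasker(path)$start, 100L)
  writeLines(paste(strsplit(row17, "\t")[[1]][-1], collapse = "\t"), path)
  expect_equal(read_repeatmasker(path)$rep_name, "LTR5_Hs")
})

test_that("rmsk parsing rejects malformed rows with the row number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("genoName", "genoStart", "genoEnd", "strand", "repName",
                 "repClass", "repFamily"), collapse = "\t")
  writeLines(c(hdr, "chr1\t100\t200\t+\tLTR5\tLTR\tERVK",
               "chr1\t300\tx\t+\tLTR5\tLTR\tERVK"), path)
  expect_error(read_repeatmasker(path), "row 2")
  writeLines(c(hdr, "chr1\t200\t100\t+\tLTR5\tLTR\tERVK"), path)
  expect_error(read_repeatmasker(path), "genoEnd")
  writeLines(c(hdr, "chr1\t100\t200\t?\tLTR5\tLTR\tERVK"), path)
  expect_error(read_repeatmasker(path), "strand")
  writeLines(hdr, path)
  expect_equal(nrow(read_repeatmasker(path)), 0L)
})

test_that("DGV coordinates convert to 0-based half-open and round-trip", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    paste(c("variantaccession", "chr", "start", "end", "varianttype",
            "variantsubtype"), collapse = "\t"),
    "esv2662783\t7\t16237347\t16238564\tCNV\tdeletion",
    "esv0000001\tchr7\t500\t900\tCNV\tduplication"), path)
  v <- read_dgv(path)
  expect_equal(v$start[1], 16237346L)
  expect_equal(v$end[1], 16238564L)
  # prefixed and unprefixed chromosome dialects normalize identically
  expect_equal(unique(v$chrom), "chr7")
  # duplication subtype retained (filtering is downstream)
  expect_equal(v$var_subtype[2], "duplication")
  out <- withr::local_tempfile(fileext = ".txt")
  write_dgv(v, out)
  v2 <- read_dgv(out)
  expect_identical(v2[, c("chrom", "start", "end")], v[, c("chrom", "start", "end")])
  # the on-disk numbers are the original 1-based inclusive ones
  raw <- read.delim(out, colClasses = "character")
  expect_equal(raw$start[1], "16237347")
  expect_equal(raw$chr[1], "7")
})

test_that("DGV parsing rejects missing columns and bad coordinates", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("variantaccession\tchr\tstart", "x\t1\t5"), path)
  expect_error(read_dgv(path), "missing column")
  writeLines(c(paste(c("variantaccession", "chr", "start", "end",
                       "varianttype", "variantsubtype"), collapse = "\t"),
               "x\t1\tfoo\t10\tCNV\tloss"), path)
  expect_error(read_dgv(path), "row 1")
})

test_that("flank extraction clips at contig edges and reconstructs the locus", {
  set.seed(11)
  g <- genome_open(Biostrings::DNAStringSet(c(chrA = rand_dna(30))))
  fl <- fetch_flanks(g, "chrA", 10, 20, 5)
  expect_equal(nchar(fl$left), 5L)
  expect_equal(fl$left, genome_fetch(g, "chrA", 5, 10))
  expect_equal(fl$right, genome_fetch(g, "chrA", 20, 25))
  # concatenation property: left + element + right == genome[start-w, end+w)
  expect_equal(paste0(fl$left, genome_fetch(g, "chrA", 10, 20), fl$right),
               genome_fetch(g, "chrA", 5, 25))
  expect_equal(nchar(fetch_flanks(g, "chrA", 3, 20, 5)$left), 3L)
  expect_equal(nchar(fetch_flanks(g, "chrA", 3, 28, 5)$right), 2L)
  expect_error(fetch_flanks(g, "chrB", 3, 20, 5), "chromosome")
  expect_error(genome_fetch(g, "chrA", 10, 40), "invalid interval")
})

test_that("file-backed and in-memory genome accessors agree; fetch uppercases", {
  set.seed(12)
  seqs <- Biostrings::DNAStringSet(c(chr1 = tolower(rand_dna(500)),
                                     chr2 = paste0(rand_dna(100), "NNN",
                                                   rand_dna(100))))
  fa <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(seqs, fa)
  gf <- genome_open(fa)
  gm <- genome_open(seqs)
  expect_equal(chrom_lengths(gf), chrom_lengths(gm))
  expect_equal(genome_fetch(gf, "chr1", 17, 211), genome_fetch(gm, "chr1", 17, 211))
  expect_equal(genome_fetch(gf, "chr1", 0, 8), toupper(as.character(
    Biostrings::subseq(seqs[["chr1"]], 1, 8))))
  expect_match(genome_fetch(gf, "chr2", 98, 105), "NNN")
})

test_that("TSV report round-trips records and BED emits two lines per TSD", {
  calls <- data.frame(locus_id = "chr7:100-200", chrom = "chr7", length = 250L,
                      left_start = 50L, left_end = 100L, right_start = 200L,
                      right_end = 250L, mismatch_gap_count = 2L,
                      identity = 0.992, left_offset = 0L, right_offset = 0L,
                      structure = "solo_ltr", stringsAsFactors = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(calls, tsv, "tsv", meta = "config_hash: abc")
  back <- read_report(tsv)
  expect_equal(back$locus_id, calls$locus_id)
  expect_equal(back$identity, calls$identity)
  expect_equal(attr(back, "meta"), "config_hash: abc")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_report(calls, bed, "bed")
  lines <- readLines(bed)
  expect_length(lines, 2L)
  expect_match(lines[1], "^chr7\t50\t100\tchr7:100-200\\|L")
  expect_match(lines[2], "\\|R")
  # empty input -> header-only file
  write_report(calls[0, ], tsv, "tsv")
  expect_equal(nrow(read_report(tsv)), 0L)
  expect_equal(readLines(tsv), paste0("#", paste(names(calls), collapse = "\t")))
})
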