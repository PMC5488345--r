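# Format boundary of the pipeline.  Everything downstream works on one
# coordinate convention: 0-based half-open intervals on "chr"-prefixed
# chromosome names.  Conversions from the external dialects (DGV is 1-based
# inclusive and drops the "chr" prefix; UCSC rmsk is already 0-based
# half-open) happen here and only here.

#' Normalize a chromosome name to the "chr"-prefixed dialect
#'
#' DGV omits the "chr" prefix while UCSC RepeatMasker tables include it;
#' comparisons inside the pipeline are dialect-insensitive because every name
#' is normalized on read.
#'
#' @param x character vector of chromosome names (e.g. `"7"`, `"chr7"`).
#' @return character vector with a `"chr"` prefix.
#' @export
#' @examples
#' normalize_chrom(c("7", "chr7", "X"))
normalize_chrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

#' Open a genome for random access
#'
#' Wraps either an indexed FASTA file on disk (a `.fai` index is created with
#' [Rsamtools::indexFa()] when absent) or an in-memory
#' [Biostrings::DNAStringSet] behind one accessor interface used by
#' [genome_fetch()] and [fetch_flanks()].
#'
#' @param x path to a FASTA file, or a named [Biostrings::DNAStringSet].
#' @return an object of class `"genome_accessor"`.
#' @export
genome_open <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L || !file.exists(x))
      stop("genome FASTA not found: ", paste(x, collapse = ", "))
    fai <- paste0(x, ".fai")
    if (!file.exists(fai)) Rsamtools::indexFa(x)
    fa <- Rsamtools::FaFile(x)
    idx <- Rsamtools::scanFaIndex(fa)
    lens <- setNames(GenomicRanges::width(idx),
                     as.character(GenomicRanges::seqnames(idx)))
    obj <- list(type = "fasta", fa = fa, lengths = lens, path = x)
  } else if (methods::is(x, "DNAStringSet")) {
    if (is.null(names(x))) stop("in-memory genome must have named sequences")
    obj <- list(type = "memory", seqs = x,
                lengths = setNames(Biostrings::width(x), names(x)))
  } else {
    stop("genome must be a FASTA path or a DNAStringSet")
  }
  structure(obj, class = "genome_accessor")
}

#' @export
print.genome_accessor <- function(x, ...) {
  cat(sprintf("<genome_accessor: %d sequence(s), %s bp total, %s>\n",
              length(x$lengths), format(sum(as.numeric(x$lengths)), big.mark = ","),
              if (x$type == "fasta") x$path else "in memory"))
  invisible(x)
}

#' Chromosome lengths of an open genome
#'
#' @param genome a `"genome_accessor"` from [genome_open()].
#' @return named integer vector of sequence lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_accessor"))
  genome$lengths
}

#' Fetch genome sequence over a 0-based half-open interval
#'
#' Soft-masked (lower-case) bases are uppercased; the ambiguity code `N` is
#' preserved.  The empty interval (`start == end`) returns `""`.
#'
#' @param genome a `"genome_accessor"`.
#' @param chrom chromosome name (any dialect; normalized internally).
#' @param start,end 0-based half-open interval with
#'   `0 <= start <= end <=` chromosome length.
#' @return a single uppercase character string of length `end - start`.
#' @export
genome_fetch <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "genome_accessor"))
  chrom <- normalize_chrom(chrom)
  len <- genome$lengths[chrom]
  if (is.na(len)) stop("chromosome not in genome: ", chrom)
  if (start < 0 || end < start || end > len)
    stop(sprintf("invalid interval %s:[%d,%d) (length %d)", chrom, start, end, len))
  if (start == end) return("")
  if (genome$type == "memory") {
    s <- Biostrings::subseq(genome$seqs[[chrom]], start + 1L, end)
  } else {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
    s <- Rsamtools::getSeq(genome$fa, gr)[[1L]]
  }
  toupper(as.character(s))
}

#' Extract the flanking sequences of a genomic element
#'
#' Returns up to `width` bp immediately left and right of the element,
#' clipped at the chromosome ends, always on the forward genome strand: TSDs
#' are direct repeats in genome orientation, so the element's strand is
#' irrelevant to flank extraction.
#'
#' @inheritParams genome_fetch
#' @param width flank width in bp (`>= 1`).
#' @return `list(left=, right=)` of uppercase character strings; `left` ends
#'   at `start`, `right` begins at `end`.
#' @export
fetch_flanks <- function(genome, chrom, start, end, width) {
  stopifnot(width >= 1)
  chrom <- normalize_chrom(chrom)
  len <- genome$lengths[chrom]
  if (is.na(len)) stop("chromosome not in genome: ", chrom)
  list(left  = genome_fetch(genome, chrom, max(0L, start - as.integer(width)), start),
       right = genome_fetch(genome, chrom, end, min(len, end + as.integer(width))))
}

.rmsk_cols <- c("bin", "swScore", "milliDiv", "milliIns", "milliDel",
                "genoName", "genoStart", "genoEnd", "genoLeft", "strand",
                "repName", "repClass", "repFamily", "repStart", "repEnd",
                "repLeft", "id")

.check_int <- function(x, what, rows) {
  bad <- !grepl("^-?[0-9]+$", x)
  if (any(bad))
    stop(sprintf("non-integer %s at row %d", what, rows[which(bad)[1L]]))
  as.integer(x)
}

#' Read a RepeatMasker annotation table (UCSC rmsk dialect)
#'
#' Accepts the joined UCSC table with or without the leading `bin` column,
#' headerless or with a (possibly `#`-commented) header line naming at least
#' `genoName`, `genoStart`, `genoEnd`, `strand`, `repName`, `repClass`,
#' `repFamily`.  UCSC coordinates are already 0-based half-open and are taken
#' as-is; rows are preserved in file order.  The RepeatMasker minus-strand
#' symbol `C` is normalized to `-`.
#'
#' @param path tab-separated rmsk file.
#' @return a `data.frame` of repeat records with columns `chrom`, `start`,
#'   `end`, `strand`, `rep_name`, `rep_class`, `rep_family`.
#' @export
read_repeatmasker <- function(path) {
  if (!file.exists(path)) stop("rmsk file not found: ", path)
  first <- readLines(path, n = 1L)
  empty_df <- data.frame(chrom = character(), start = integer(), end = integer(),
                         strand = character(), rep_name = character(),
                         rep_class = character(), rep_family = character(),
                         stringsAsFactors = FALSE)
  if (length(first) == 0L) return(empty_df)
  has_header <- grepl("genoName", first, fixed = TRUE)
  dt <- data.table::fread(path, sep = "\t", header = has_header,
                          colClasses = "character", data.table = FALSE,
                          strip.white = FALSE)
  if (nrow(dt) == 0L) return(empty_df)
  if (has_header) {
    names(dt) <- sub("^#", "", names(dt))
    need <- c("genoName", "genoStart", "genoEnd", "strand",
              "repName", "repClass", "repFamily")
    miss <- setdiff(need, names(dt))
    if (length(miss))
      stop("rmsk header missing column(s): ", paste(miss, collapse = ", "))
  } else {
    if (ncol(dt) == 17L) names(dt) <- .rmsk_cols
    else if (ncol(dt) == 16L) names(dt) <- .rmsk_cols[-1L]
    else stop(sprintf("rmsk row 1: expected 16 or 17 columns, got %d", ncol(dt)))
  }
  rows <- seq_len(nrow(dt))
  start <- .check_int(dt$genoStart, "genoStart", rows)
  end <- .check_int(dt$genoEnd, "genoEnd", rows)
  if (any(start >= end))
    stop(sprintf("rmsk row %d: genoEnd <= genoStart", which(start >= end)[1L]))
  strand <- dt$strand
  strand[strand == "C"] <- "-"
  bad <- !strand %in% c("+", "-")
  if (any(bad))
    stop(sprintf("rmsk row %d: unknown strand symbol '%s'",
                 which(bad)[1L], dt$strand[which(bad)[1L]]))
  data.frame(chrom = normalize_chrom(dt$genoName), start = start, end = end,
             strand = strand, rep_name = dt$repName, rep_class = dt$repClass,
             rep_family = dt$repFamily, stringsAsFactors = FALSE)
}

#' Read a DGV structural-variant table
#'
#' The DGV dialect is tab-separated with a header naming at least
#' `variantaccession`, `chr`, `start`, `end`, `varianttype`,
#' `variantsubtype`, and uses 1-based inclusive coordinates: these are
#' converted to the internal 0-based half-open convention (`start-1`, `end`)
#' and chromosome names gain the `chr` prefix.  No filtering happens here.
#'
#' @param path tab-separated DGV variant file.
#' @return a `data.frame` of variant records with columns `accession`,
#'   `chrom`, `start`, `end`, `var_type`, `var_subtype`.
#' @export
read_dgv <- function(path) {
  if (!file.exists(path)) stop("DGV file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  names(dt) <- tolower(names(dt))
  need <- c("variantaccession", "chr", "start", "end",
            "varianttype", "variantsubtype")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("DGV header missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(dt) == 0L)
    return(data.frame(accession = character(), chrom = character(),
                      start = integer(), end = integer(),
                      var_type = character(), var_subtype = character(),
                      stringsAsFactors = FALSE))
  rows <- seq_len(nrow(dt))
  start1 <- .check_int(dt$start, "start", rows)
  end1 <- .check_int(dt$end, "end", rows)
  start <- start1 - 1L
  if (any(start >= end1))
    stop(sprintf("DGV row %d: empty or inverted interval", which(start >= end1)[1L]))
  data.frame(accession = dt$variantaccession, chrom = normalize_chrom(dt$chr),
             start = start, end = end1, var_type = dt$varianttype,
             var_subtype = dt$variantsubtype, stringsAsFactors = FALSE)
}

#' Write variant records back in the DGV dialect
#'
#' Inverse of [read_dgv()]: coordinates go out 1-based inclusive and the
#' `chr` prefix is stripped, so a read–write round trip reproduces the
#' original numbers.
#'
#' @param variants data.frame from [read_dgv()] (or simulator output).
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_dgv <- function(variants, path) {
  out <- data.frame(variantaccession = variants$accession,
                    chr = sub("^chr", "", variants$chrom),
                    start = variants$start + 1L, end = variants$end,
                    varianttype = variants$var_type,
                    variantsubtype = variants$var_subtype,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pipeline report as TSV or BED
#'
#' The TSV carries `#`-prefixed metadata lines followed by a commented header
#' naming every column, then one row per record; [read_report()] reverses it.
#' BED output is 0-based half-open; TSD calls produce one line per TSD copy
#' (two per call) and candidate sites one line per (locus, deletion) pair,
#' with locus/accession identifiers in the name field.  Output is
#' deterministic given input order.
#'
#' @param records homogeneous data.frame of TSD calls, candidate sites, or
#'   any report table (TSV accepts any data.frame).
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @param meta optional character vector of metadata lines for the TSV header.
#' @return `invisible(path)`.
#' @export
write_report <- function(records, path, format = c("tsv", "bed"), meta = NULL) {
  format <- match.arg(format)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (format == "tsv") {
    if (!is.null(meta)) writeLines(paste0("# ", meta), con)
    writeLines(paste0("#", paste(names(records), collapse = "\t")), con)
    if (nrow(records)) {
      body <- do.call(paste, c(lapply(records, function(col) {
        if (is.numeric(col) && !is.integer(col))
          format(col, trim = TRUE, scientific = FALSE, digits = 15)
        else as.character(col)
      }), sep = "\t"))
      writeLines(body, con)
    }
  } else {
    lines <- character(0)
    if (all(c("left_start", "right_start") %in% names(records))) {
      for (i in seq_len(nrow(records))) {
        r <- records[i, ]
        sc <- round(r$identity * 1000)
        lines <- c(lines,
          sprintf("%s\t%d\t%d\t%s|L\t%d\t+", r$chrom, r$left_start, r$left_end,
                  r$locus_id, sc),
          sprintf("%s\t%d\t%d\t%s|R\t%d\t+", r$chrom, r$right_start, r$right_end,
                  r$locus_id, sc))
      }
    } else if (all(c("del_start", "del_end") %in% names(records))) {
      lines <- sprintf("%s\t%d\t%d\t%s|%s\t0\t+", records$chrom,
                       records$del_start, records$del_end,
                       records$locus_id, records$accession)
    } else if (nrow(records)) {
      stop("BED output supported for TSD calls and candidate sites only")
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read back a TSV report written by [write_report()]
#'
#' @param path report path.
#' @return the record data.frame (metadata lines in attribute `"meta"`).
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (!length(hdr)) stop("report has no commented header: ", path)
  header_line <- lines[max(hdr)]
  meta <- sub("^# ", "", lines[setdiff(hdr, max(hdr))])
  cols <- strsplit(sub("^#", "", header_line), "\t", fixed = TRUE)[[1L]]
  body <- lines[-hdr]
  if (!length(body)) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(text = body, sep = "\t", col.names = cols,
                            stringsAsFactors = FALSE, colClasses = "character")
    for (j in seq_along(df)) {
      x <- df[[j]]
      nz <- x[!is.na(x)]
      if (!length(nz)) next
      if (all(grepl("^-?[0-9]+$", nz))) df[[j]] <- as.integer(x)
      else if (!anyNA(suppressWarnings(as.numeric(nz)))) df[[j]] <- as.numeric(x)
    }
  }
  attr(df, "meta") <- meta
  df
}
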