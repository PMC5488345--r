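# Shared fixture builders.  Everything is generated in code at test time;
# seeds are fixed inside each test for reproducibility.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute n interior bases of a sequence (returns the mutated copy).
mutate_interior <- function(seq, n) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (n > 0L) {
    pos <- sample(seq(2L, length(v) - 1L), n)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  }
  paste(v, collapse = "")
}

# Build a flank pair with a planted TSD: `left` ends at the element boundary,
# `right` begins at it.  Mutations go into the right copy.
make_flank_pair <- function(tsd_len, n_sub = 0L, off_left = 0L, off_right = 0L,
                            flank_len = 40L) {
  tsd <- rand_dna(tsd_len)
  list(left = paste0(rand_dna(flank_len - tsd_len - off_left), tsd,
                     rand_dna(off_left)),
       right = paste0(rand_dna(off_right), mutate_interior(tsd, n_sub),
                      rand_dna(flank_len - tsd_len - off_right)),
       tsd = tsd)
}

# Repeat records in the package's internal shape.
repeat_records <- function(chrom, start, end, strand = "+",
                           rep_name = "LTR5_Hs", rep_class = "LTR",
                           rep_family = "ERVK") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, rep_name = rep_name, rep_class = rep_class,
             rep_family = rep_family, stringsAsFactors = FALSE)
}

no_records <- function() repeat_records(character(0), integer(0), integer(0),
                                        character(0), character(0),
                                        character(0), character(0))

# rmsk records from a simulation, reshaped to the parser's output so catalog
# functions can run on in-memory simulations without touching disk.
sim_repeats <- function(sim) {
  repeat_records(sim$rmsk$genoName, sim$rmsk$genoStart, sim$rmsk$genoEnd,
                 sim$rmsk$strand, sim$rmsk$repName, sim$rmsk$repClass,
                 sim$rmsk$repFamily)
}

sim_catalog <- function(sim, config = catalog_config()) {
  recs <- sim_repeats(sim)
  assemble_loci(select_hml2_ltrs(recs, config), select_internals(recs, config),
                config)
}

# The frozen planted-TSD study: every (length, load) cell for the canonical
# length set, loads 0..cap(L) plus one over-cap load per length (interior
# capacity permitting), twice over.
recovery_elements <- function() {
  lens <- c(4L, 9L, 10L, 19L, 20L, 50L, 111L, 250L, 450L, 500L)
  els <- list()
  for (rep in 1:2) for (L in lens) {
    loads <- 0:min(mismatch_cap(L) + 1L, L - 2L)
    for (m in loads)
      els[[length(els) + 1L]] <-
        sim_element("solo_ltr", ltr_len = 900L, tsd_len = L, tsd_mutations = m)
  }
  for (i in seq_along(els))
    els[[i]]$chrom <- as.integer((i - 1L) %/% 8L + 1L)
  els
}

recovery_sim <- function(seed = 1L) {
  els <- recovery_elements()
  simulate_hml2(sim_config(seed = seed, n_chroms = ceiling(length(els) / 8),
                           chrom_len = 25000L, elements = els))
}

# The frozen scan-discrimination study: >= 100 loci alternating planted
# preintegration deletions and regional indels.
scan_elements <- function(n = 100L) {
  els <- vector("list", n)
  for (i in seq_len(n)) {
    scen <- if (i %% 2L == 1L) "preintegration_deletion" else "regional_indel"
    els[[i]] <- sim_element("solo_ltr", ltr_len = 800L,
                            tsd_len = c(10L, 15L, 20L, 30L)[(i %% 4L) + 1L],
                            tsd_mutations = i %% 2L, scenario = scen,
                            chrom = as.integer((i - 1L) %/% 10L + 1L))
  }
  els
}

scan_sim <- function(seed = 1L, n = 100L) {
  simulate_hml2(sim_config(seed = seed, n_chroms = ceiling(n / 10),
                           chrom_len = 30000L, elements = scan_elements(n)))
}
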