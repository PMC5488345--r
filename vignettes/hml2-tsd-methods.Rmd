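---
title: "Detecting HML-2 insertional polymorphisms and inferring target site duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting HML-2 insertional polymorphisms and inferring target site duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

HML-2 (HERV-K) is the youngest subgroup of human endogenous retroviruses.
An intact provirus carries a long terminal repeat (LTR, ~970 bp) at each
end; homologous recombination between the two LTRs leaves a solo LTR, the
state of most HML-2 loci. At integration the retrovirus duplicates its
target site, leaving a *target site duplication* (TSD) — a direct repeat of
host sequence immediately left and right of the element, conventionally 5–6
bp for HERV-K but occasionally far longer. A locus is *insertionally
polymorphic* when some haplotypes carry the preintegration allele: the
element absent and a single copy of the target site present.

`hml2scan` implements the two computational stages of this analysis:

1. **Scan stage.** Build a catalogue of HML-2 loci from RepeatMasker
   annotations and intersect it with deletion-type records from a
   structural-variant table (DGV dialect). A deletion consistent with the
   preintegration state removes the element plus exactly one TSD copy;
   deletions that remove the element, both copies and extra sequence are
   *regional indels*, not preintegration alleles.
2. **TSD stage.** Infer each locus's TSD from the genomic sequence flanking
   it, by a global-alignment search over candidate lengths 4–500 bp.

A synthetic-genome simulator plants elements with known TSDs so both stages
are validated end to end without external data.

## Coordinates and input formats

All internal coordinates are 0-based half-open on `chr`-prefixed names.
The two external dialects differ — UCSC rmsk tables are already 0-based
half-open, DGV tables are 1-based inclusive without the `chr` prefix — and
the off-by-one conversion happens exactly once, in `read_dgv()` /
`write_dgv()`. Genomes are indexed FASTA (via `Rsamtools`) or in-memory
`DNAStringSet`s behind one accessor; fetches are uppercased, `N` preserved.

## Catalogue assembly

HML-2 LTRs are the repeat models `LTR5` and `LTR5_Hs`, matched by exact
name so that the older relatives `LTR5A`/`LTR5B` are excluded. An LTR and a
`HERVK-int` internal segment are linked when they share chromosome and
strand and the signed gap between them lies in `[-1, 100]` bp (−1 allows a
one-base annotation overlap). Chains LTR–int(–int…)–LTR become proviruses;
a lone LTR with linked internal segments is a truncated provirus; unlinked
LTRs are solo LTRs. Three further choices were genuinely open:

* **Tandem chains** with more than two LTRs are split greedily
  left-to-right into (LTR, int+, LTR) proviruses; leftover LTRs become solo
  and leftover internals are orphaned (reported in an attribute, not
  catalogued). Greedy splitting is deterministic and order-invariant.
* **Flags, not exclusions.** LTR records shorter than 50 bp and loci within
  10 bp of another catalogued LTR are flagged (`short_ltr`,
  `adjacent_ltr`); downstream stages accept `skip_flagged` but nothing is
  silently dropped, since the autosomal census that motivates these
  thresholds is itself uncertain.
* **Counting.** `count_autosomal_ltrs()` counts raw LTR *records* on
  chr1–22, not merged fragments or loci — the simplest reproducible
  reading of an annotation-table census.

## Scan stage

Variants pass three filters: (i) subtype `loss` or `deletion`
(case-insensitive); (ii) the deletion interval fully contains the locus —
the LTR for a solo LTR, the whole span for proviral structures
("covering" is containment, not overlap); (iii) effective length strictly
below 1500 bp. For proviral loci the effective length discounts the
internal portion, `deletion_len − (span_len − leftmost LTR length)`, so
the residue is comparable to a solo-LTR deletion; subtracting everything
but one LTR is one of two defensible readings of the published filter and
is the package's fixed choice. Identical (locus, interval) pairs from
different studies collapse into one candidate with concatenated accessions.

Manual genome-browser curation is replaced by a breakpoint-consistency
rule with tolerance `breakpoint_tol` (default 10 bp, reflecting the
imprecision of database breakpoints): a candidate is
`preintegration_consistent` when the deletion matches the element span
plus exactly one TSD copy on either side; `regional_indel` when it
contains the span plus both copies plus more than the tolerance of extra
sequence on each side; otherwise `ambiguous` (always so when the locus has
no TSD call). Shrinking the tolerance can only move calls toward
`ambiguous`, never create preintegration calls.

## TSD inference

For a locus spanning `[s, e)` the caller extracts up to
`max_len + max_offset` bp of forward-strand flank on each side (TSDs are
direct repeats in genome orientation, so element strand is irrelevant) and
scans candidate lengths `L` from `max_len` down to `min_len` and boundary
offsets `oL, oR ∈ [0, max_offset]` — offsets absorb the occasional few
intervening bases between a TSD copy and the element boundary, and are
searched symmetrically on both sides. Each candidate aligns the
nominal-`L` windows ending `oL` bp before `s` and starting `oR` bp after
`e` with Needleman–Wunsch (match +1, mismatch −1, gap −2 per column;
deterministic traceback preferring match/mismatch, then gap in the left
window, then gap in the right; `N` matches nothing, including itself).
A candidate is accepted when

* identity (matches / alignment columns) is **strictly** greater than
  `min_identity` (default 0.75),
* mismatch + gap columns do not exceed the length band: at most 1 for
  `L < 10`, 2 for `L < 20`, 3 for `L ≥ 20`, and
* the first and last alignment columns are **matches**.

The terminal-match condition encodes what a duplication block is: its
boundary evidence is identical sequence. Without it the longest-first
search degenerates — for any clean planted duplication of length `L`, the
window of nominal length `L+1` aligns as a terminal gap (or lucky terminal
mismatch) around the same block, stays within the mismatch band, and would
be reported at an inflated length. An alignment ending in a non-match
column has simply overrun the block that a shorter nominal length already
captures.

The first (largest-`L`) passing candidate wins; among candidates of equal
nominal length the smallest mismatch+gap count wins, then the smallest
`oL + oR`, then the smallest `oL`. The reported TSD length is the accepted
alignment's column count, so a copy may occupy `L ± gaps` bp of genome.
Loci flush against a contig edge where even `min_len` of flank cannot be
extracted yield no call.

Two implementation notes. A banded edit-distance pre-screen (cutoff = the
band cap) skips window pairs that cannot pass — any alignment's
mismatch+gap count is bounded below by the unit-cost edit distance — and
never changes results; the C++ kernel computes the alignment itself. An
independent pure-R oracle, `brute_force_tsd()`, enumerates every
`(L, oL, oR)` with no ordering shortcut or pre-screen and applies the same
acceptance rules; equality with the anchored search is property-tested on
hundreds of random and adversarial flank pairs up to the oracle's 64-bp
bound.

The published analysis aligned flanks with T-Coffee and selected the
longest high-identity pair; its exact parameters are not recoverable, so
this package defines the fully specified search above instead, and
real-data results may differ slightly from published tables at individual
loci. One reported number is irreconcilable on its face — a 250-bp TSD
listed with 2 mismatches alongside a 99.6% identity, while 248/250 is
99.2% — most plausibly because that identity compares each copy against a
sequenced preintegration allele, a wet-lab quantity outside this package's
scope; the discrepancy is documented, not resolved.

## The simulator and what passing tests mean

`simulate_hml2()` models the integration mechanism directly: i.i.d.
background at a configurable GC (default 0.41, the human genome-wide
value), elements planted by copying the `tsd_len` bases at the insertion
point to both sides, then injecting a configurable number of substitutions
(optionally 1-bp indels) into the right copy. Proviral LTR pairs are
planted as identical copies, as at integration. Matching rmsk- and
DGV-dialect files are emitted — TSDs deliberately unannotated, as in real
RepeatMasker output — plus a ground-truth ledger. Scenarios per element:
a preintegration deletion (element + left TSD copy), a regional indel
(element + both copies + 200-bp margins), a pseudo-TSD (a long duplication
flanking the element that arose without integration — the caller is
*expected* to call it, since sequence alone cannot distinguish the two;
truth labels it for reporting), or nothing. Mutations go to interior TSD
positions (2..len−1): a change at the first or last base shortens the
observable duplication by definition, which would make the planted length
ill-posed as ground truth.

What the simulator does **not** emulate: genomic repeat structure (Alu/L1
density around real loci, which defeated PCR at one published locus),
sequencing error, population sampling, or assembly artefacts. Passing
tests therefore demonstrate algorithmic correctness under the stated
model, not real-data accuracy; on real genomes the catalogue census and
call counts depend on the pinned annotation and variant releases.

Validation studies frozen into the test suite and `scripts/acceptance.R`
(sizes chosen to exercise every band edge): a 506-pair oracle-equivalence
study (random pairs of 8–28 bp flanks plus planted duplications at offsets
0–2 and loads at the band caps); an 86-locus recovery grid covering every
(length, load) cell for lengths {4, 9, 10, 19, 20, 50, 111, 250, 450, 500}
with loads 0..cap(L) plus one over-cap load; a 100-locus scan study
alternating preintegration deletions and regional indels; and a
byte-identity rerun of the whole pipeline.

## Known limitations

* **Short-length false calls.** At `min_len = 4` the acceptance bands
  admit, e.g., 5-bp blocks at 4/5 identity with one mismatch; in random
  sequence such admissible blocks arise near a locus with probability of
  roughly 5–10%, so 4-bp calls are unreliable and a planted 4-bp TSD is
  occasionally outranked by a genuine longer near-duplication in the
  realized sequence. This is inherent to the published thresholds;
  raising `min_len` to 10 removes essentially all false calls (a
  property test measures both settings).
* The caller cannot distinguish pseudo-TSDs (segmental-duplication
  recombination products) from integration TSDs — by construction.
* Classification requires a TSD call; loci without one are `ambiguous`
  even when breakpoints look consistent.
* Cross-species orthology, allele frequencies and age estimation are out
  of scope.
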