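---
title: "Models and methods behind the spidr pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the spidr pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical model and the procedural choices
behind each stage of the package, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, and
the known limits of the method. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The experimental design in one paragraph

A pool of antibody-coated beads is incubated with UV-crosslinked lysate in
a single immunoprecipitation. Each bead carries many copies of one
antibody plus a handful of DNA oligo tags naming that antibody. Split-pool
barcoding then ligates one tag per round onto every molecule on a bead
(Odd/Even/Terminal tag chemistry, one tag set per round), so all molecules
from one bead share a barcode string. After `r` rounds of `k` tags, two
beads collide with probability `1/k^r` — about 1 in 430 million for 8
rounds of 12 tags — so a complete barcode string effectively names a bead.
Sequencing yields two libraries: antibody-oligo reads (tag + UMI) and
cDNA reads of the captured RNA, marked by a ligated RPM adaptor
(`ATCAGCACTTA`). Grouping by barcode string reconstructs each bead as a
"SPIDR cluster"; the cluster's oligo tags vote on its protein identity,
and its RNA reads become that protein's binding evidence.

## Barcode decoding

Tag order on the read is the reverse of ligation order (the last-ligated
Terminal tag is sequenced first); this is configurable (`read_order`)
because read architecture is library-construction dependent. Decoding is
positional: tag lengths are fixed per round, so each round's segment sits
at a deterministic offset and is matched against that round's tag set with
at most `mismatch_tolerance` mismatches (default 1). Scheme validation
requires tags within a round to be pairwise more than
`2 * mismatch_tolerance` apart in Hamming distance, which makes
error-tolerant matching unambiguous. A segment with no tag within
tolerance leaves a gap; gapped reads are kept (for ligation-efficiency
audit) but never clustered. Reads are routed by the RPM adaptor: present
(anchored at either end, within tolerance) means RNA, otherwise a match
against the antibody oligo-tag dictionary means OLIGO, else UNASSIGNED —
routing is a partition and nothing is silently dropped.

## Clusters, deduplication, assignment

Clusters form over complete barcode strings only. Barcode strings that are
out of round order or contain an identical repeated tag denote ligation
events that could not have happened sequentially and are filtered.
Deduplication is exact-match and scoped per cluster: oligo records
collapse on (antibody tag, UMI) — UMIs are deliberately scoped within an
antibody tag so distinct tag species with coincidentally equal UMIs
survive — and RNA records collapse on (reference, start, end, strand).
Strand is in the key because antisense duplicates are biologically
distinct molecules. Both operators are idempotent and commute.

Assignment applies three thresholds literally: at least `min_oligos = 3`
deduplicated tags, modal-tag fraction at least `frac_unique = 0.8`
(boundary inclusive), at most `max_rnas = 100` RNA records. A tie for the
mode is ambiguous: no principled tie-break exists, and a false assignment
costs more than a lost cluster. The `max_rnas` guard is applied in all
analyses, not only the two-condition comparison, for consistency; it
removes rare mega-clusters (bead doublets, barcode collisions).

## The permutation background

The central statistic asks: is this protein's coverage in a window higher
than any protein's coverage would be there, at matched depth? For a target
protein with `n` reads, all reads assigned to *other* proteins (negative
controls included) form the pool; the pool is downsampled to exactly `n`
reads without replacement, `n_perms >= 100` independent times. Windows
tile genomic coordinates from 0 at a fixed width (default 100 nt; 10 nt
and 1 nt for fine mapping), separately per strand; a read increments every
window it overlaps, identically for observed and permuted reads, so the
enrichment ratio is unbiased with respect to the counting rule.

Per window: `enrichment = observed / expected`, where `expected` is the
mean permuted count, and `p = (k + 1) / (n_perms + 1)` with `k` the number
of permutations whose count is at or above the observed one — the observed
sample is included in numerator and denominator, so the smallest
attainable p is `1/(n_perms + 1)` and the test is valid and conservative
under ties. Peaks require `observed >= 10` and `p < 0.05` (strict).
When `expected` is exactly zero the ratio is floored at
`observed / (1 / n_perms)` and flagged (`zero_expected`); this preserves
ordering among floored windows and leaves the p-value untouched, but
floored enrichments are not comparable with unfloored ones — treat them as
"above the measurable range", not as numbers.

The pool is other proteins' *assigned* reads. Reads of ambiguous clusters
are excluded by default: an ambiguous cluster of the target protein's own
beads carries that protein's binding-site reads, and letting them into the
background deflates true-site enrichment (and, combined with the
zero-expected floor, can let background positions outrank true crosslink
sites in sparse single-nucleotide profiles). `protein_enrichment()` has an
`unassigned` argument for users who want the wider pool deliberately.

### Calibration and its limit at small panel sizes

Because every permutation subsamples the *same* finite pool realization,
permutation counts are mutually correlated while the observed count is
independent of them. If `f = n / N_pool`, the observed fluctuation around
the pool-implied mean is wider than the permutation spread by
`sqrt((1 + f) / (1 - f))`. With many multiplexed proteins (`f` of a few
percent) this is negligible, and tie-inclusive discreteness keeps the
caller conservative. With only 10 proteins (`f ~ 1/9`, factor ~1.12) the
unconditional rate of `p < 0.05` runs near 0.06-0.07 instead of 0.05; the
package's null-calibration battery (`validation_null_fpr()`) measures the
fraction of windows falsely *called* (both thresholds) per protein, which
the count filter keeps near 0.05-0.07 at the canonical 200k-read, 100 kb
conditions. The same battery reports the conditional rate among
candidate (>= 10-read) windows, which is substantially higher at moderate
depth because conditioning on the count filter selects upward
fluctuations. Both numbers are computed, not asserted, and the acceptance
suite holds the called fraction to its stated bound so the miscalibration
is visible rather than hidden. Users multiplexing few proteins should
prefer larger panels, more permutations only for resolution (not bias),
or an explicit negative-control pool much deeper than any target.

## Truncation mapping

Reverse transcriptase stalls at the residual crosslink adduct, so the 3'
end of the cDNA — the alignment end nearest the RNA 5' terminus — marks
the protein contact at single-nucleotide resolution: the smallest
coordinate for plus-strand reads, `end - 1` for minus-strand reads. The
identical permutation machinery runs at window width 1 on these
coordinates. Positional deduplication caps per-(cluster, coordinate)
counts at one, so truncation pile-ups are supported by reads from many
beads, which is exactly the evidence structure one wants. Motif-centered
profiles aggregate truncation counts by signed, strand-aware offset from
motif starts restricted to significant peaks.

## Annotation

One label per peak, resolved by priority over the union of all
same-strand overlapping features: miRNA, CDS, 5'UTR, 3'UTR, proximal
intron, distal intron, non-coding exon, non-coding intron, else
intergenic. "Proximal" means within 500 nt of a splice site, measured
from the nearer boundary of the overlapped intron (the measurement point
is a package choice; the convention is stated here because upstream
definitions vary). Peaks whose non-coding annotation comes from a miRNA
host gene are relabeled miRNA-proximal — binding in a host transcript is
usually about the miRNA, and restricting the relabel to non-coding
features keeps CDS/UTR evidence of protein-coding hosts intact (a package
choice where the host rule is underdetermined). UTRs come from explicit
GTF features when present and are otherwise derived as exonic-minus-CDS
per coding transcript with GenomicRanges set operations. The rRNA
blacklist ships empty and configurable: published coordinates for such
regions are assembly-specific and the interval printed in the protocol
this package follows is not usable as printed (start exceeds end).

## Comparison statistics

Peak-set overlap uses the exact hypergeometric upper tail over a window
universe, with the odds ratio from the 2x2 table (Haldane-Anscombe 0.5
only when a cell is zero, flagged). The universe is every fixed window
with at least one read in the combined pool of both datasets — never-
observable windows would inflate significance; "all genomic windows" is
available as an option. The L2 shuffle test flattens two protein-by-
category composition matrices, takes the Euclidean norm of their
difference, and builds the null by permuting protein rows of one matrix
while holding the other fixed, alternating sides, 1000 draws by default;
small L2 means similar, so the empirical p is the fraction of null values
at or below the observed, add-one smoothed.

## Differential binding

Background-corrected bedGraphs are mapped to genes with absolute-maximum
semantics (the magnitude of the extreme value, matching the common
groupby-absmax convention), the best isoform represents the gene, and
values are divided by the protein's bead-cluster count in each condition
to remove detection bias from unequal bead numbers. Genes with zero
coverage in either condition are excluded from ratios (log undefined).
TOP-score bins default to four categories at breaks 1, 2, 3 (scores are
user-supplied; published score tables use roughly this range, and the
edges are configuration, not science). Group comparisons use a two-sided
Mann-Whitney U with midrank ties: exact enumeration of all rank
assignments up to combined n = 20, the tie-corrected normal approximation
beyond. Read-count ratios between conditions are bead-normalized and
report zero-denominator proteins as flagged infinities rather than
dropping them.

## The synthetic-data generator

`simulate_experiment()` emulates: beads evenly spread over the antibody
panel (two negative controls, IgG and empty beads, by default); oligo
tags per bead from a zero-truncated Poisson whose mean (default 4)
reproduces the observed median of 4 tags per cluster; tag crosstalk as a
per-tag probability (default 5%) of naming a different antibody, which
yields the observed >80% single-antibody clusters; background RNA reads
per bead from a negative binomial (size 4, mean 20 by default), placed
uniformly on a single 100 kb contig with a miniature annotation (coding
genes on both strands, one with two isoforms and one with a long intron,
a histone-like single-exon gene, a non-coding gene, and a miRNA inside a
non-coding host); planted footprints whose read counts realize a
requested fold over the matched-depth background expectation, with a
configurable fraction of reads truncating exactly at the crosslink; PCR
duplicates (default 10%) as coordinate-identical copies within the bead;
and per-bead, per-round ligation failures (default 2%) that corrupt that
round's segment on every read of the bead (failed segments are emitted as
N-runs: a truncated ligation product does not sequence as a valid tag,
and modeling it in place keeps the positional architecture decodable).

It does **not** emulate: sequencing errors beyond what mismatch tolerance
absorbs, quality-score structure, alignment artifacts (indels, clipping,
multimapping), fragment-length variation, transcript-level read
generation (background is genome-uniform, not expression-weighted), or
barcode hopping. Passing tests therefore demonstrate correctness of the
decision rules and statistics under the assumed generative structure, not
robustness to alignment or chemistry artifacts in real libraries.

Determinism: every stochastic step runs under one seed scope and restores
the caller's RNG state; identical config and seed give byte-identical
files, which the pipeline's checksum manifest makes checkable.

## Canonical validation conditions

The validation batteries fix their problem sizes as the package's
canonical desk-scale conditions: null calibration on 10 proteins with
200k raw background reads (10,000 beads at mean 20 reads; roughly 35% of
raw reads are lost to ligation failures, deduplication and ambiguous
clusters before the caller, as in a real experiment); planted-peak
recovery with 50 sites at 10-fold enrichment (about 24-40 raw reads per
site under these conditions, all at least 20); assignment accuracy on
10,000 beads at 5% crosstalk; truncation resolution with 20 proteins, one
80-read site each at truncation fraction 0.5. Footprints are planted 10 nt
into a window so 50-nt reads stay inside one 100-nt window, making
"the window containing the site" the unambiguous truth unit.

## Known limitations

* The permutation test's finite-pool inflation at small panel sizes,
  quantified above.
* Exact-match UMI collapse only; no directional-network UMI error
  correction.
* Positional barcode decoding assumes fixed tag lengths and no indels in
  the tag region.
* Annotation handles GENCODE-dialect GTF attributes (`gene_type` /
  `gene_biotype`); exotic dialects need attribute mapping upstream.
* `read_alignments()` supports match-only CIGARs, which is what the
  simulator emits; spliced or clipped alignments should be ingested
  through the BAM route of a full aligner-aware loader.
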