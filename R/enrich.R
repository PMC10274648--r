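#' Count reads in fixed genomic windows
#'
#' Tiles each reference with non-overlapping windows of fixed width starting
#' at coordinate 0 and increments every window a read's interval overlaps.
#' Counting is strand-aware: plus- and minus-strand reads accumulate in
#' separate maps. The window widths used in practice are 10 or 100 nt.
#'
#' @param reads data.table of RNA records (`reference`, `start`, `end`,
#'   `strand`; 0-based half-open).
#' @param window window width in nt.
#' @param genome_sizes optional named vector of reference lengths; reads
#'   running off the end of a reference raise an error naming the read.
#' @return Sparse count table: `reference`, `strand`, `wstart`, `count`
#'   (windows with zero reads are absent).
#' @export
count_windows <- function(reads, window = 100L, genome_sizes = NULL) {
  reads <- as.data.table(reads)
  if (!nrow(reads))
    return(data.table(reference = character(), strand = character(),
                      wstart = integer(), count = integer()))
  if (!is.null(genome_sizes)) {
    lim <- genome_sizes[reads$reference]
    bad <- which(is.na(lim) | reads$end > lim | reads$start < 0L)
    if (length(bad)) {
      id <- if ("read_id" %in% names(reads)) reads$read_id[bad[1L]]
            else sprintf("row %d", bad[1L])
      stop("read beyond reference bounds: ", id)
    }
  }
  ex <- expand_windows(reads, window)
  ex[, .(count = .N), by = .(reference, strand, wstart)]
}

# one row per (read, overlapped window)
expand_windows <- function(reads, window, extra = NULL) {
  w1 <- reads$start %/% window
  w2 <- (reads$end - 1L) %/% window
  k <- w2 - w1 + 1L
  idx <- rep.int(seq_len(nrow(reads)), k)
  out <- data.table(
    reference = reads$reference[idx], strand = reads$strand[idx],
    wstart = (w1[idx] + (sequence(k) - 1L)) * as.integer(window))
  if (!is.null(extra)) for (col in names(extra)) out[, (col) := extra[[col]][idx]]
  out
}

#' Matched-depth permutation background
#'
#' Builds the empirical null for one protein: all reads not assigned to that
#' protein are randomly downsampled, without replacement, to the protein's
#' own read count, and window counts are computed exactly as for the
#' observed reads. The downsampling is repeated `n_perms` (at least 100)
#' independent times.
#'
#' @param target_n number of reads assigned to the protein of interest.
#' @param other_reads data.table pool of all reads assigned to other
#'   proteins (negative controls included).
#' @param n_perms number of independent downsamples (default 100).
#' @param window window width in nt (1 for truncation profiles).
#' @param seed RNG seed; same seed reproduces identical permutations.
#' @return An object of class `spidr_background` holding the per-window
#'   permutation counts, the sampled read indices (for audit), `n_perms`,
#'   `target_n` and `window`.
#' @export
permutation_background <- function(target_n, other_reads, n_perms = 100L,
                                   window = 100L, seed = NULL) {
  other_reads <- as.data.table(other_reads)
  npool <- nrow(other_reads)
  if (npool < target_n)
    stop(sprintf(paste0("background pool (%d reads) is smaller than the target ",
                        "depth (%d); permutations sample without replacement - ",
                        "reduce the target or enlarge the pool"), npool, target_n))
  if (n_perms < 100L) stop("at least 100 permutations are required")
  local_seed(seed, {
    idx <- vapply(seq_len(n_perms), function(i) sample.int(npool, target_n),
                  integer(target_n))
    flat <- as.vector(idx)
    picked <- other_reads[flat]
    ex <- expand_windows(picked, window,
                         extra = list(perm = rep(seq_len(n_perms),
                                                 each = target_n)))
    perm_counts <- ex[, .(count = .N), by = .(perm, reference, strand, wstart)]
    structure(list(perm_counts = perm_counts, perm_indices = idx,
                   pool = other_reads, n_perms = as.integer(n_perms),
                   target_n = as.integer(target_n),
                   window = as.integer(window)),
              class = "spidr_background")
  })
}

#' Window enrichment and permutation p-values
#'
#' For every window with at least one observed read, computes the
#' normalized enrichment — observed count divided by the mean count over
#' the permutations (expected) — and the permutation p-value
#' `(k + 1) / (n_perms + 1)`, where `k` is the number of permutations whose
#' count is greater than or equal to the observed count (the observed score
#' is included in numerator and denominator). Windows whose expected mean
#' is exactly zero get enrichment `observed / (1 / n_perms)` and are
#' flagged (`zero_expected`); the p-value is unaffected.
#'
#' @param observed count table from [count_windows()].
#' @param background a `spidr_background` on the same window grid.
#' @return data.table of window statistics: `reference`, `strand`, `start`,
#'   `end`, `observed`, `expected_mean`, `enrichment`, `p_value`,
#'   `n_perms`, `zero_expected`.
#' @export
window_enrichment <- function(observed, background) {
  stopifnot(inherits(background, "spidr_background"))
  np <- background$n_perms
  w <- background$window
  obs <- as.data.table(observed)
  if (!nrow(obs))
    return(data.table(reference = character(), strand = character(),
                      start = integer(), end = integer(), observed = integer(),
                      expected_mean = numeric(), enrichment = numeric(),
                      p_value = numeric(), n_perms = integer(),
                      zero_expected = logical()))
  pc <- background$perm_counts[obs, on = c("reference", "strand", "wstart"),
                               allow.cartesian = TRUE]
  # absent (perm, window) combinations are zero-count permutations; with
  # observed >= 1 they contribute neither to k nor to the expected sum
  stats <- pc[, .(
    observed = i.count[1L],
    sum_perm = sum(count, na.rm = TRUE),
    k_ge = sum(!is.na(count) & count >= i.count[1L])
  ), by = .(reference, strand, wstart)]
  stats[, expected_mean := sum_perm / np]
  stats[, p_value := (k_ge + 1) / (np + 1)]
  stats[, zero_expected := expected_mean == 0]
  stats[, enrichment := fifelse(zero_expected, observed * as.numeric(np),
                                observed / expected_mean)]
  stats[, `:=`(start = wstart, end = wstart + w, n_perms = np,
               sum_perm = NULL, k_ge = NULL, wstart = NULL)]
  setcolorder(stats, c("reference", "strand", "start", "end", "observed",
                       "expected_mean", "enrichment", "p_value", "n_perms",
                       "zero_expected"))
  setorder(stats, reference, strand, start)
  stats[]
}

#' Call significantly enriched windows
#'
#' Keeps windows with at least `min_reads` observed reads and a permutation
#' p-value strictly below `alpha` (defaults 10 reads, 0.05).
#'
#' @param stats window statistics from [window_enrichment()].
#' @param min_reads minimum observed read count (inclusive).
#' @param alpha p-value threshold (strict `<`).
#' @return The significant subset of `stats`.
#' @export
call_peaks <- function(stats, min_reads = 10L, alpha = 0.05) {
  stats[observed >= min_reads & p_value < alpha][]
}

#' One protein's window statistics against the pooled background
#'
#' Convenience wrapper: target reads are those assigned to `protein`, the
#' permutation pool is every read not assigned to that protein — the other
#' proteins' reads (negative controls included) plus, when supplied, the
#' reads of ambiguous clusters, which are equally "not assigned" — and
#' both are counted on the same grid.
#'
#' @param assigned data.table of assigned RNA records (from
#'   [split_by_protein()]`$assigned`).
#' @param protein protein name.
#' @param window window width in nt.
#' @param n_perms number of permutations.
#' @param seed RNG seed.
#' @param genome_sizes optional reference bounds check.
#' @param unassigned optional data.table of RNA records from ambiguous
#'   clusters ([split_by_protein()]`$ambiguous`) added to the pool.
#' @return [window_enrichment()] output.
#' @export
protein_enrichment <- function(assigned, protein, window = 100L,
                               n_perms = 100L, seed = NULL,
                               genome_sizes = NULL, unassigned = NULL) {
  assigned <- as.data.table(assigned)
  sel <- assigned[["protein"]] == protein
  target <- assigned[sel]
  cols <- c("reference", "start", "end", "strand")
  pool <- assigned[!sel, ..cols]
  if (!is.null(unassigned) && nrow(unassigned))
    pool <- rbind(pool, as.data.table(unassigned)[, ..cols])
  obs <- count_windows(target, window, genome_sizes)
  bg <- permutation_background(nrow(target), pool, n_perms, window, seed)
  window_enrichment(obs, bg)
}

#' Crosslink truncation coordinate of a read
#'
#' Reverse transcription stalls at the protein-RNA crosslink, so the 3' end
#' of the cDNA — the alignment end nearest the RNA 5' terminus — marks the
#' binding site at single-nucleotide resolution: the smallest coordinate
#' for plus-strand reads, `end - 1` for minus-strand reads.
#'
#' @param reads data.table of RNA records.
#' @return Integer vector of genomic truncation positions.
#' @export
truncation_coordinate <- function(reads) {
  ifelse(reads$strand == "-", reads$end - 1L, reads$start)
}

# reads reduced to 1-nt records at their truncation coordinate
truncation_records <- function(reads) {
  pos <- truncation_coordinate(reads)
  data.table(reference = reads$reference, start = pos, end = pos + 1L,
             strand = reads$strand)
}

#' Per-nucleotide truncation counts
#'
#' @param reads data.table of RNA records.
#' @return data.table `reference`, `strand`, `pos`, `count`; counts sum to
#'   the number of contributing reads.
#' @export
truncation_profile <- function(reads) {
  tr <- truncation_records(reads)
  tr[, .(count = .N), by = .(reference, strand, pos = start)][]
}

#' Single-nucleotide truncation enrichment
#'
#' Applies the identical downsampling machinery as the window analysis at a
#' window width of 1 nt on truncation coordinates: the frequency of reads
#' ending at the 3' end of the cDNA for the protein of interest, against
#' matched-depth downsamples of all other proteins' truncations.
#'
#' @param target_reads RNA records assigned to the protein of interest.
#' @param other_reads pool of all reads not assigned to that protein.
#' @param n_perms number of permutations (default 100).
#' @param seed RNG seed.
#' @return [window_enrichment()]-style statistics with 1-nt windows
#'   (`start` is the truncation coordinate).
#' @export
truncation_enrichment <- function(target_reads, other_reads, n_perms = 100L,
                                  seed = NULL) {
  target_reads <- as.data.table(target_reads)
  if (!nrow(target_reads))
    return(window_enrichment(data.table(), structure(
      list(perm_counts = data.table(), n_perms = as.integer(n_perms),
           target_n = 0L, window = 1L), class = "spidr_background")))
  tt <- truncation_records(target_reads)
  ot <- truncation_records(as.data.table(other_reads))
  obs <- count_windows(tt, window = 1L)
  bg <- permutation_background(nrow(tt), ot, n_perms, window = 1L, seed = seed)
  window_enrichment(obs, bg)
}

#' Truncation frequency centered on motif positions
#'
#' Aggregates truncation counts by signed offset from each motif's first
#' base, restricted to motifs inside significant peaks; offsets are
#' strand-aware (upstream of the motif is negative) and counts are
#' normalized to frequencies.
#'
#' @param reads RNA records whose truncations are profiled.
#' @param peaks called peaks ([call_peaks()] output); motifs outside them
#'   are ignored.
#' @param motif_hits data.table of motif intervals (`reference`, `start`,
#'   `end`, `strand`), e.g. from an external motif scan.
#' @param half_width window half-width around the motif start in nt.
#' @return data.table with `offset` and `frequency` (empty when no motif
#'   survives the peak restriction).
#' @export
motif_centered_profile <- function(reads, peaks, motif_hits, half_width = 50L) {
  motif_hits <- as.data.table(motif_hits)
  empty <- data.table(offset = integer(), frequency = numeric())
  if (!nrow(motif_hits)) return(empty)
  pk <- as.data.table(peaks)[, .(reference, start, end)]
  if (!nrow(pk)) return(empty)
  setkey(pk, reference, start, end)
  mh <- copy(motif_hits)
  if (!"strand" %in% names(mh)) mh[, strand := "+"]
  ov <- foverlaps(mh, pk, by.x = c("reference", "start", "end"),
                  nomatch = NULL)
  mh <- unique(ov[, .(reference, start = i.start, strand)])
  if (!nrow(mh)) return(empty)
  tp <- truncation_profile(as.data.table(reads))
  rows <- vector("list", nrow(mh))
  for (i in seq_len(nrow(mh))) {
    m <- mh[i]
    sel <- tp[reference == m$reference & pos >= m$start - half_width &
                pos <= m$start + half_width]
    if (!nrow(sel)) next
    off <- sel$pos - m$start
    if (m$strand == "-") off <- -off
    rows[[i]] <- data.table(offset = off, count = sel$count)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  prof <- rbindlist(rows)[, .(count = sum(count)), by = offset]
  prof[, frequency := count / sum(count)]
  setorder(prof, offset)
  prof[, .(offset, frequency)][]
}

#' Export window enrichment as bedGraph
#'
#' Four-column bedGraph (reference, start, end, enrichment), 0-based
#' half-open; windows with zero observed reads are omitted (they are never
#' present in the statistics). A `track` header line is written.
#'
#' @param stats window statistics from [window_enrichment()].
#' @param path output path.
#' @param name track name.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(stats, path, name = "spidr_enrichment") {
  con <- file(path, "w")
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  if (nrow(stats)) {
    d <- stats[observed > 0]
    setorder(d, reference, start)
    writeLines(sprintf("%s\t%d\t%d\t%.6g", d$reference, d$start, d$end,
                       d$enrichment), con)
  }
  close(con)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path bedGraph path (optional `track` header tolerated).
#' @return data.table with `reference`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & nzchar(lines)]
  if (!length(lines))
    return(data.table(reference = character(), start = integer(),
                      end = integer(), value = numeric()))
  d <- fread(text = lines, header = FALSE,
             col.names = c("reference", "start", "end", "value"))
  d[]
}

#' Export reads under significant peaks as FASTA
#'
#' Subsets reads to those falling within called peaks and writes their
#' sequences for external de novo motif discovery.
#'
#' @param reads RNA records with a `read_id` column.
#' @param peaks called peaks.
#' @param genome named character vector of reference sequences.
#' @param path output FASTA path.
#' @return Number of sequences written, invisibly.
#' @export
export_peak_reads_fasta <- function(reads, peaks, genome, path) {
  reads <- as.data.table(reads)
  pk <- as.data.table(peaks)[, .(reference, start, end)]
  setkey(pk, reference, start, end)
  ov <- foverlaps(reads, pk, by.x = c("reference", "start", "end"),
                  nomatch = NULL)
  sel <- unique(ov[, .(read_id, reference, start = i.start, end = i.end,
                       strand)])
  seqs <- substring(genome[sel$reference], sel$start + 1L, sel$end)
  neg <- sel$strand == "-"
  if (any(neg)) seqs[neg] <- reverse_complement(seqs[neg])
  dna <- Biostrings::DNAStringSet(setNames(seqs, sel$read_id))
  Biostrings::writeXStringSet(dna, path)
  invisible(length(dna))
}
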