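#' Identify split-pool barcodes and route reads
#'
#' Decodes the barcode string on read 2 by positional matching: each round's
#' segment (tag lengths are fixed, so offsets are deterministic) is compared
#' against that round's tag set allowing up to `mismatch_tolerance`
#' mismatches; rounds with no tag within tolerance leave a gap (`*`).
#' Read 1 then routes the pair: reads carrying the RPM adaptor (anchored at
#' either end, within tolerance) are RNA; otherwise, if `antibody_tags` is
#' supplied and the read starts with a known antibody oligo tag, the read is
#' OLIGO and its UMI is extracted; everything else is UNASSIGNED. No read is
#' dropped.
#'
#' Barcode strings are reported in ligation order (round 1 first) joined
#' with periods, regardless of the on-read order.
#'
#' @param reads data.table with `read_id`, `seq1`, `seq2` (see
#'   [read_fastq_pair()]).
#' @param scheme a [spidr_scheme()].
#' @param antibody_tags optional named character vector (antibody ->
#'   oligo-tag sequence) used to decode OLIGO reads.
#' @return data.table with `read_id`, `barcode`, `n_tags`, `read_class`,
#'   `residual_sequence`, `umi`, `antibody_tag`, `sample_label`.
#' @export
identify_barcodes <- function(reads, scheme, antibody_tags = NULL) {
  reads <- as.data.table(reads)
  n <- nrow(reads)
  n_rounds <- length(scheme$rounds)
  tagmat <- matrix(NA_character_, nrow = n, ncol = n_rounds)
  if (n > 0L) {
    off <- 0L
    for (i in read_order_rounds(scheme)) {
      tags <- scheme$rounds[[i]]$tags
      len <- nchar(tags[[1]])
      seg <- substr(reads$seq2, off + 1L, off + len)
      seg[nchar(seg) < len] <- NA_character_
      tagmat[, i] <- match_tags(seg, tags, scheme$mismatch_tolerance)
      off <- off + len
    }
  }
  barcode <- if (n > 0L)
    apply(tagmat, 1L, function(r) paste(ifelse(is.na(r), "*", r), collapse = "."))
  else character(0)
  n_tags <- as.integer(rowSums(!is.na(tagmat)))

  rpm <- scheme$rpm_sequence
  tol <- scheme$mismatch_tolerance
  Lr <- nchar(rpm)
  s1 <- reads$seq1
  has5 <- nchar(s1) >= Lr & hamming_to(substr(s1, 1L, Lr), rpm) <= tol
  has3 <- nchar(s1) >= Lr &
    hamming_to(substr(s1, nchar(s1) - Lr + 1L, nchar(s1)), rpm) <= tol
  has5[is.na(has5)] <- FALSE; has3[is.na(has3)] <- FALSE
  is_rna <- has5 | has3

  read_class <- rep("UNASSIGNED", n)
  antibody <- rep(NA_character_, n)
  umi <- rep(NA_character_, n)
  read_class[is_rna] <- "RNA"
  if (!is.null(antibody_tags) && any(!is_rna)) {
    ablen <- nchar(antibody_tags[[1]])
    cand <- which(!is_rna & nchar(s1) >= ablen + scheme$umi_length)
    if (length(cand)) {
      hit <- match_tags(substr(s1[cand], 1L, ablen), antibody_tags, tol)
      ok <- !is.na(hit)
      idx <- cand[ok]
      read_class[idx] <- "OLIGO"
      antibody[idx] <- hit[ok]
      umi[idx] <- substr(s1[idx], ablen + 1L, ablen + scheme$umi_length)
    }
  }
  residual <- s1
  residual[is_rna] <- trim_rpm(s1[is_rna], scheme)

  out <- data.table(
    read_id = reads$read_id, barcode = barcode, n_tags = n_tags,
    read_class = read_class, residual_sequence = residual,
    umi = umi, antibody_tag = antibody,
    sample_label = barcode_sample_labels(barcode, scheme)
  )
  out[]
}

#' Trim the RPM adaptor from read ends
#'
#' Removes one occurrence of the RPM sequence anchored at the 5' end and one
#' at the 3' end (each allowing up to the scheme's mismatch tolerance);
#' interior sequence is untouched.
#'
#' @param sequences character vector of nucleotide sequences.
#' @param scheme a [spidr_scheme()] (or a list with `rpm_sequence` and
#'   `mismatch_tolerance`).
#' @return Trimmed sequences.
#' @export
trim_rpm <- function(sequences, scheme) {
  rpm <- scheme$rpm_sequence
  tol <- scheme$mismatch_tolerance
  L <- nchar(rpm)
  s <- sequences
  hit5 <- nchar(s) >= L & hamming_to(substr(s, 1L, L), rpm) <= tol
  hit5[is.na(hit5)] <- FALSE
  s[hit5] <- substr(s[hit5], L + 1L, nchar(s[hit5]))
  hit3 <- nchar(s) >= L & hamming_to(substr(s, nchar(s) - L + 1L, nchar(s)), rpm) <= tol
  hit3[is.na(hit3)] <- FALSE
  s[hit3] <- substr(s[hit3], 1L, nchar(s[hit3]) - L)
  s
}

#' Ligation efficiency report
#'
#' For k = 0..n_rounds, the count and within-class fraction of reads with
#' exactly k identified tags, split by read class.
#'
#' @param tagged data.table from [identify_barcodes()].
#' @param scheme a [spidr_scheme()].
#' @return data.table with `read_class`, `n_tags`, `count`, `fraction`.
#' @export
ligation_report <- function(tagged, scheme) {
  empty <- data.table(read_class = character(), n_tags = integer(),
                      count = integer(), fraction = numeric())
  if (!nrow(tagged)) return(empty)
  n_rounds <- length(scheme$rounds)
  tab <- as.data.table(tagged)[, .(count = .N), by = .(read_class, n_tags)]
  grid <- CJ(read_class = unique(tab$read_class), n_tags = 0:n_rounds)
  tab <- tab[grid, on = c("read_class", "n_tags")]
  tab[is.na(count), count := 0L]
  tab[, fraction := count / sum(count), by = read_class]
  setorder(tab, read_class, n_tags)
  tab[]
}

# condition label from the sample-round tag of each barcode string
barcode_sample_labels <- function(barcodes, scheme) {
  if (is.null(scheme$sample_round_index)) return(rep(NA_character_, length(barcodes)))
  i <- scheme$sample_round_index
  tag <- vapply(strsplit(barcodes, ".", fixed = TRUE),
                function(p) if (length(p) >= i) p[[i]] else "*", character(1))
  tag[tag == "*"] <- NA_character_
  if (is.null(scheme$sample_map)) return(tag)
  unname(scheme$sample_map[tag])
}

#' Attach decoded barcodes to aligned RNA records
#'
#' Joins alignments to tagged reads by `read_id` and carries over the
#' barcode string, tag count and sample label.
#'
#' @param alignments data.table of aligned records (see
#'   [read_alignments()]).
#' @param tagged data.table from [identify_barcodes()].
#' @return Alignments with `barcode`, `n_tags`, `sample_label` columns.
#' @export
attach_barcodes <- function(alignments, tagged) {
  out <- as.data.table(alignments)[
    as.data.table(tagged)[, .(read_id, barcode, n_tags, sample_label)],
    on = "read_id", nomatch = NULL]
  out[]
}
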