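#' Assign clusters to proteins by majority vote
#'
#' Each cluster represents one bead, so the frequency of (deduplicated)
#' antibody oligo tags determines the protein identity. A cluster is
#' assigned to its modal antibody tag when all three thresholds hold:
#' at least `min_oligos` observed tags, the modal tag representing at least
#' `frac_unique` of all tags (boundary inclusive), and at most `max_rnas`
#' RNA records. Anything else — including a tie for the mode, for which no
#' principled break exists — is `AMBIGUOUS`.
#'
#' @param clusters a deduplicated `spidr_clusters` object.
#' @param min_oligos minimum oligo tags per cluster (default 3).
#' @param frac_unique minimum modal-tag fraction (default 0.8).
#' @param max_rnas maximum RNA records per cluster (default 100).
#' @param scheme optional [spidr_scheme()] used to derive `sample_label`
#'   from the barcode's sample-round tag.
#' @return data.table with `barcode`, `protein` (or `"AMBIGUOUS"`),
#'   `n_oligos`, `top_fraction`, `n_rnas`, `sample_label`.
#' @export
assign_clusters <- function(clusters, min_oligos = 3L, frac_unique = 0.8,
                            max_rnas = 100L, scheme = NULL) {
  counts <- clusters$oligos[, .(n = .N), by = .(barcode, antibody_tag)]
  votes <- counts[, {
    top <- if (.N) max(n) else NA_integer_
    .(protein_mode = if (.N) antibody_tag[which.max(n)] else NA_character_,
      tie = sum(n == top) > 1L,
      n_oligos = sum(n),
      top_fraction = top / sum(n))
  }, by = barcode]
  rna_n <- clusters$rnas[, .(n_rnas = .N), by = barcode]
  all_bc <- data.table(barcode = union(votes$barcode, rna_n$barcode))
  out <- votes[all_bc, on = "barcode"]
  out <- rna_n[out, on = "barcode"]
  out[is.na(n_rnas), n_rnas := 0L]
  out[is.na(n_oligos), `:=`(n_oligos = 0L, top_fraction = 0, tie = TRUE)]
  out[, protein := fifelse(
    !tie & n_oligos >= min_oligos & top_fraction >= frac_unique &
      n_rnas <= max_rnas,
    protein_mode, "AMBIGUOUS")]
  out[, sample_label := if (is.null(scheme)) NA_character_
      else barcode_sample_labels(barcode, scheme)]
  setcolorder(out, c("barcode", "protein", "n_oligos", "top_fraction",
                     "n_rnas", "sample_label"))
  out[, c("protein_mode", "tie") := NULL]
  setorder(out, barcode)
  out[]
}

#' Split RNA records by assigned protein
#'
#' Every RNA record of an assigned cluster lands in exactly one output
#' stream keyed by (protein, sample label); records of `AMBIGUOUS` clusters
#' go to the ambiguous sink so counts are conserved.
#'
#' @param clusters a `spidr_clusters` object.
#' @param assignments output of [assign_clusters()].
#' @return list with `assigned` (RNA records plus `protein`,
#'   `sample_label`) and `ambiguous` (records of unassigned clusters).
#' @export
split_by_protein <- function(clusters, assignments) {
  rn <- assignments[clusters$rnas, on = "barcode", nomatch = NULL]
  assigned <- rn[protein != "AMBIGUOUS",
                 .(barcode, reference, start, end, strand, unique_mapping,
                   protein, sample_label)]
  ambiguous <- rn[protein == "AMBIGUOUS",
                  .(barcode, reference, start, end, strand, unique_mapping)]
  list(assigned = assigned[], ambiguous = ambiguous[])
}

#' Count assigned bead clusters per protein and sample
#'
#' These counts later normalize differential comparisons for antibody-bead
#' abundance differences between conditions. `AMBIGUOUS` clusters are never
#' counted.
#'
#' @param assignments output of [assign_clusters()].
#' @return data.table with `protein`, `sample_label`, `n_clusters`.
#' @export
bead_cluster_counts <- function(assignments) {
  assignments[protein != "AMBIGUOUS",
              .(n_clusters = .N), by = .(protein, sample_label)][]
}

#' Write per-protein RNA records as BED
#'
#' One BED6 file per (protein, sample label) pair.
#'
#' @param split output of [split_by_protein()].
#' @param dir output directory.
#' @return Named vector of paths, invisibly.
#' @export
write_split_beds <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keys <- unique(split$assigned[, .(protein, sample_label)])
  paths <- character(0)
  for (i in seq_len(nrow(keys))) {
    k <- keys[i]
    d <- split$assigned[protein == k$protein &
                          (is.na(k$sample_label) | sample_label == k$sample_label)]
    label <- if (is.na(k$sample_label)) k$protein
             else paste(k$protein, k$sample_label, sep = "_")
    path <- file.path(dir, paste0(label, ".bed"))
    bed <- d[, .(reference, start, end, name = barcode, score = 0L, strand)]
    setorder(bed, reference, start, end)
    fwrite(bed, path, sep = "\t", col.names = FALSE)
    paths[label] <- path
  }
  invisible(paths)
}
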