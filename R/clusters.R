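#' Build SPIDR clusters from tagged reads
#'
#' Groups deduplicatable records by complete barcode string: one cluster
#' (bead) per distinct barcode. Oligo records come from tagged OLIGO reads;
#' RNA records from aligned reads carrying a barcode (see
#' [attach_barcodes()]). Reads with incomplete barcodes (any round gap) and
#' RNA reads that did not map uniquely are not clustered; their counts are
#' kept in the object so record conservation is auditable.
#'
#' @param tagged_oligo data.table from [identify_barcodes()] (OLIGO reads).
#' @param rna data.table of aligned RNA records with a `barcode` column.
#' @return An object of class `spidr_clusters`: list with `oligos`
#'   (`barcode`, `antibody_tag`, `umi`), `rnas` (`barcode`, `reference`,
#'   `start`, `end`, `strand`, `unique_mapping`) and `unclustered` counts.
#' @export
build_clusters <- function(tagged_oligo, rna = NULL) {
  tg <- as.data.table(tagged_oligo)
  olg_all <- tg[read_class == "OLIGO" & !is.na(antibody_tag)]
  olg_ok <- olg_all[barcode_complete(barcode)]
  oligos <- olg_ok[, .(barcode, antibody_tag, umi)]

  unclustered <- list(oligo_incomplete = nrow(olg_all) - nrow(olg_ok),
                      rna_unbarcoded = 0L, rna_multimapping = 0L)
  rnas <- data.table(barcode = character(), reference = character(),
                     start = integer(), end = integer(), strand = character(),
                     unique_mapping = logical())
  if (!is.null(rna) && nrow(rna)) {
    rna <- as.data.table(rna)
    if (!"barcode" %in% names(rna)) stop("RNA records must carry a 'barcode' column")
    if (!"unique_mapping" %in% names(rna)) rna[, unique_mapping := TRUE]
    ok_bc <- !is.na(rna$barcode) & barcode_complete(rna$barcode)
    unclustered$rna_unbarcoded <- sum(!ok_bc)
    keep <- rna[ok_bc]
    unclustered$rna_multimapping <- sum(!keep$unique_mapping)
    keep <- keep[unique_mapping == TRUE]
    rnas <- keep[, .(barcode, reference, start = as.integer(start),
                     end = as.integer(end), strand, unique_mapping)]
  }
  structure(list(oligos = oligos, rnas = rnas, unclustered = unclustered),
            class = "spidr_clusters")
}

barcode_complete <- function(barcode) {
  !is.na(barcode) & !grepl("*", barcode, fixed = TRUE) & nzchar(barcode)
}

#' @export
print.spidr_clusters <- function(x, ...) {
  cat(sprintf("spidr clusters: %d clusters | %d oligo records | %d RNA records\n",
              n_clusters(x), nrow(x$oligos), nrow(x$rnas)))
  u <- x$unclustered
  cat(sprintf("  unclustered: %d incomplete-oligo, %d unbarcoded-RNA, %d multimapping-RNA\n",
              u$oligo_incomplete, u$rna_unbarcoded, u$rna_multimapping))
  invisible(x)
}

#' Number of distinct clusters
#' @param clusters a `spidr_clusters` object.
#' @return Count of distinct barcode strings across oligo and RNA records.
#' @export
n_clusters <- function(clusters) {
  length(union(unique(clusters$oligos$barcode), unique(clusters$rnas$barcode)))
}

#' Filter invalid barcode strings
#'
#' Removes clusters whose barcode string is incomplete, out of round order
#' (a tag appearing in a round it does not belong to), or contains an
#' identical repeated tag — ligation events that could not have occurred
#' sequentially. Removal counts are attached as the `"removed"` attribute.
#'
#' @param clusters a `spidr_clusters` object.
#' @param scheme the [spidr_scheme()] the barcodes were decoded against.
#' @return Filtered `spidr_clusters`.
#' @export
filter_barcode_strings <- function(clusters, scheme) {
  bcs <- union(unique(clusters$oligos$barcode), unique(clusters$rnas$barcode))
  valid <- bcs[barcode_string_valid(bcs, scheme)]
  out <- structure(list(
    oligos = clusters$oligos[barcode %in% valid],
    rnas = clusters$rnas[barcode %in% valid],
    unclustered = clusters$unclustered
  ), class = "spidr_clusters")
  attr(out, "removed") <- list(
    clusters = length(bcs) - length(valid),
    oligo_records = nrow(clusters$oligos) - nrow(out$oligos),
    rna_records = nrow(clusters$rnas) - nrow(out$rnas))
  out
}

# vectorized validity of period-joined barcode strings against a scheme
barcode_string_valid <- function(barcodes, scheme) {
  n_rounds <- length(scheme$rounds)
  round_tags <- lapply(scheme$rounds, function(r) names(r$tags))
  vapply(strsplit(barcodes, ".", fixed = TRUE), function(p) {
    if (length(p) != n_rounds || any(p == "*")) return(FALSE)
    if (anyDuplicated(p)) return(FALSE)             # identical repeats
    for (i in seq_len(n_rounds))
      if (!p[[i]] %in% round_tags[[i]]) return(FALSE)  # out of round order
    TRUE
  }, logical(1))
}

#' Deduplicate oligo records
#'
#' Collapses oligo records to unique (antibody tag, UMI) pairs within each
#' cluster; PCR duplicates share the UMI and disappear. UMIs are scoped per
#' antibody tag so distinct tag species with coincidentally equal UMIs
#' survive. Idempotent.
#'
#' @param clusters a `spidr_clusters` object.
#' @return Clusters with deduplicated oligo records.
#' @export
dedup_oligos <- function(clusters) {
  clusters$oligos <- unique(clusters$oligos,
                            by = c("barcode", "antibody_tag", "umi"))
  clusters
}

#' Deduplicate RNA records
#'
#' Collapses RNA records sharing identical genomic start and end positions
#' (and strand) within a cluster, removing PCR duplication events.
#' Idempotent.
#'
#' @param clusters a `spidr_clusters` object.
#' @return Clusters with deduplicated RNA records.
#' @export
dedup_rnas <- function(clusters) {
  clusters$rnas <- unique(clusters$rnas,
                          by = c("barcode", "reference", "start", "end", "strand"))
  clusters
}

#' Write a cluster file
#'
#' One cluster per line: the period-joined barcode string followed by
#' tab-separated records, `OLG:<antibody>:<umi>` for oligo tags and
#' `RNA:<reference>:<start>-<end>:<strand>` for RNA records (0-based
#' half-open). Records and clusters are written in a canonical sort order so
#' the write -> read round trip is bit-exact.
#'
#' @param clusters a `spidr_clusters` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  olg <- copy(clusters$oligos)[, token := paste("OLG", antibody_tag, umi, sep = ":")]
  rna <- copy(clusters$rnas)[, token := sprintf("RNA:%s:%d-%d:%s",
                                                reference, start, end, strand)]
  setorder(olg, barcode, antibody_tag, umi)
  setorder(rna, barcode, reference, start, end, strand)
  tokens <- rbind(olg[, .(barcode, ord = 1L, token)],
                  rna[, .(barcode, ord = 2L, token)])
  setorder(tokens, barcode, ord, token)
  lines <- tokens[, .(line = paste(c(barcode[1L], token), collapse = "\t")),
                  by = barcode]$line
  writeLines(lines, path)
  invisible(path)
}

#' Read a cluster file
#'
#' Parses the format written by [write_clusters()].
#'
#' @param path cluster file path.
#' @return A `spidr_clusters` object (`unique_mapping` is `TRUE` for all RNA
#'   records: multimappers are dropped before clustering and never written).
#' @export
read_clusters <- function(path) {
  lines <- readLines(path)
  olg_rows <- list(); rna_rows <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    bc <- parts[1L]
    for (tok in parts[-1L]) {
      f <- strsplit(tok, ":", fixed = TRUE)[[1]]
      if (f[1L] == "OLG") {
        olg_rows[[length(olg_rows) + 1L]] <- data.table(
          barcode = bc, antibody_tag = f[2L], umi = f[3L])
      } else if (f[1L] == "RNA") {
        se <- as.integer(strsplit(f[3L], "-", fixed = TRUE)[[1]])
        rna_rows[[length(rna_rows) + 1L]] <- data.table(
          barcode = bc, reference = f[2L], start = se[1L], end = se[2L],
          strand = f[4L], unique_mapping = TRUE)
      } else stop("unknown cluster record type: ", f[1L])
    }
  }
  empty_o <- data.table(barcode = character(), antibody_tag = character(),
                        umi = character())
  empty_r <- data.table(barcode = character(), reference = character(),
                        start = integer(), end = integer(), strand = character(),
                        unique_mapping = logical())
  structure(list(
    oligos = if (length(olg_rows)) rbindlist(olg_rows) else empty_o,
    rnas = if (length(rna_rows)) rbindlist(rna_rows) else empty_r,
    unclustered = list(oligo_incomplete = 0L, rna_unbarcoded = 0L,
                       rna_multimapping = 0L)
  ), class = "spidr_clusters")
}
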