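library(data.table)

# small fixed scheme shared across tests (3 rounds x 4 tags, 6-nt tags)
tiny_scheme <- function(...) {
  example_scheme(n_rounds = 3L, tags_per_round = 4L, tag_length = 6L,
                 seed = 99L, ...)
}

# degenerate schemes for barcode-space arithmetic (bypass the >=2-tags rule)
flat_scheme <- function(n_rounds, tags_per_round, tag_length = 4L) {
  rounds <- lapply(seq_len(n_rounds), function(i) {
    tags <- random_tags(tags_per_round, tag_length, seed = 1000L + i)
    names(tags) <- sprintf("R%dT%02d", i, seq_along(tags))
    list(name = sprintf("round%d", i),
         category = if (i == n_rounds) "TERMINAL" else if (i %% 2) "ODD" else "EVEN",
         tags = tags)
  })
  spidr_scheme(rounds, validate = FALSE)
}

random_tags <- function(n, len, seed) {
  set.seed(seed)
  replicate(n, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = ""))
}

# build a spidr_clusters object directly from record tables
make_clusters <- function(oligos = NULL, rnas = NULL) {
  o <- if (is.null(oligos)) data.table(barcode = character(),
                                       antibody_tag = character(),
                                       umi = character()) else as.data.table(oligos)
  r <- if (is.null(rnas)) data.table(barcode = character(),
                                     reference = character(), start = integer(),
                                     end = integer(), strand = character(),
                                     unique_mapping = logical()) else {
    r0 <- as.data.table(rnas)
    if (!"unique_mapping" %in% names(r0)) r0[, unique_mapping := TRUE]
    r0
  }
  structure(list(oligos = o, rnas = r,
                 unclustered = list(oligo_incomplete = 0L, rna_unbarcoded = 0L,
                                    rna_multimapping = 0L)),
            class = "spidr_clusters")
}

# minimal RNA record table
rna_records <- function(start, end, strand = "+", reference = "chrS") {
  data.table(reference = reference, start = as.integer(start),
             end = as.integer(end), strand = strand)
}

# a permutation background built from explicit per-permutation counts, for
# arithmetic tests of window_enrichment
manual_background <- function(counts_by_perm, reference = "chrS",
                              strand = "+", wstart = 0L, window = 10L) {
  n_perms <- length(counts_by_perm)
  pc <- data.table(perm = seq_len(n_perms), reference = reference,
                   strand = strand, wstart = as.integer(wstart),
                   count = as.integer(counts_by_perm))[count > 0]
  structure(list(perm_counts = pc, perm_indices = NULL, pool = NULL,
                 n_perms = as.integer(n_perms), target_n = NA_integer_,
                 window = as.integer(window)),
            class = "spidr_background")
}

# run the demultiplex -> cluster -> assign front half of the pipeline
process_sim <- function(sim) {
  tagged_oligo <- identify_barcodes(sim$oligo_reads, sim$scheme,
                                    sim$antibody_oligos)
  tagged_cdna <- identify_barcodes(sim$cdna_reads, sim$scheme)
  rna <- attach_barcodes(sim$alignments, tagged_cdna)
  clusters <- build_clusters(tagged_oligo, rna)
  clusters <- filter_barcode_strings(clusters, sim$scheme)
  clusters <- dedup_rnas(dedup_oligos(clusters))
  assignments <- assign_clusters(clusters, scheme = sim$scheme)
  list(tagged_oligo = tagged_oligo, tagged_cdna = tagged_cdna,
       clusters = clusters, assignments = assignments,
       split = split_by_protein(clusters, assignments))
}

temp_path <- function(name) file.path(tempdir(), name)
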