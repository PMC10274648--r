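#' Run the full SPIDR pipeline on a simulated experiment
#'
#' Orchestrates the stages end to end: simulate (or accept a prebuilt
#' `spidr_sim`), identify barcodes and route reads, build/filter/
#' deduplicate clusters, assign proteins, split RNA records, compute
#' permutation-background window enrichment and call peaks per protein,
#' annotate peaks, and write every output plus a checksum manifest.
#' Identical config and seed reproduce identical checksums.
#'
#' @param config list of stage parameters: `sim` (a [sim_config()]) or
#'   `sim_object` (a prebuilt `spidr_sim`), `out_dir`, and optional
#'   overrides `window` (100), `n_perms` (100), `min_reads` (10), `alpha`
#'   (0.05), `min_oligos` (3), `frac_unique` (0.8), `max_rnas` (100),
#'   `proximal_nt` (500), `proteins` (default: all with assigned reads),
#'   `seed`.
#' @return list with `manifest` (data.table file/md5), `assignments`,
#'   `peaks`, `stats_by_protein`, `counters` (per-stage log counts).
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  if (is.null(config$sim) && is.null(config$sim_object))
    stop("config needs a 'sim' config or a 'sim_object'")
  window <- config$window %||% 100L
  n_perms <- config$n_perms %||% 100L
  min_reads <- config$min_reads %||% 10L
  alpha <- config$alpha %||% 0.05
  seed <- config$seed %||% 1L
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  sim <- config$sim_object %||% simulate_experiment(config$sim)
  scheme <- sim$scheme

  tagged_oligo <- identify_barcodes(sim$oligo_reads, scheme, sim$antibody_oligos)
  tagged_cdna <- identify_barcodes(sim$cdna_reads, scheme)
  rna <- attach_barcodes(sim$alignments, tagged_cdna)

  clusters <- build_clusters(tagged_oligo, rna)
  clusters <- filter_barcode_strings(clusters, scheme)
  removed <- attr(clusters, "removed")
  clusters <- dedup_rnas(dedup_oligos(clusters))

  assignments <- assign_clusters(
    clusters, min_oligos = config$min_oligos %||% 3L,
    frac_unique = config$frac_unique %||% 0.8,
    max_rnas = config$max_rnas %||% 100L, scheme = scheme)
  split <- split_by_protein(clusters, assignments)

  proteins <- config$proteins %||% sort(unique(split$assigned$protein))
  stats_by_protein <- list(); peak_list <- list()
  for (i in seq_along(proteins)) {
    p <- proteins[i]
    if (!nrow(split$assigned[protein == p])) next
    st <- protein_enrichment(split$assigned, p, window = window,
                             n_perms = n_perms, seed = seed + i,
                             genome_sizes = sim$genome_sizes)
    stats_by_protein[[p]] <- st
    pk <- call_peaks(st, min_reads, alpha)
    if (nrow(pk)) { pk[, protein := p]; peak_list[[p]] <- pk }
    export_bedgraph(st, file.path(out, sprintf("%s.enrichment.bedgraph", p)),
                    name = p)
  }
  peaks <- if (length(peak_list)) rbindlist(peak_list) else
    data.table(reference = character(), strand = character(),
               start = integer(), end = integer(), observed = integer(),
               expected_mean = numeric(), enrichment = numeric(),
               p_value = numeric(), n_perms = integer(),
               zero_expected = logical(), protein = character())

  db <- build_annotation_db(sim$annotation$gr)
  peaks_ann <- annotate_peaks(peaks, db,
                              proximal_nt = config$proximal_nt %||% 500L)

  write_clusters(clusters, file.path(out, "clusters.txt"))
  fwrite(assignments, file.path(out, "assignments.tsv"), sep = "\t")
  fwrite(ligation_report(rbind(tagged_oligo, tagged_cdna), scheme),
         file.path(out, "ligation_report.tsv"), sep = "\t")
  fwrite(peaks_ann, file.path(out, "peaks.annotated.tsv"), sep = "\t")
  fwrite(bead_cluster_counts(assignments),
         file.path(out, "bead_cluster_counts.tsv"), sep = "\t")

  counters <- list(
    reads_oligo = nrow(sim$oligo_reads), reads_rna = nrow(sim$cdna_reads),
    rna_unbarcoded = clusters$unclustered$rna_unbarcoded,
    clusters_filtered = removed$clusters,
    clusters_total = n_clusters(clusters),
    clusters_ambiguous = assignments[protein == "AMBIGUOUS", .N],
    peaks_called = nrow(peaks))
  fwrite(data.table(counter = names(counters),
                    value = unlist(counters)),
         file.path(out, "counters.tsv"), sep = "\t")

  files <- sort(list.files(out, full.names = TRUE))
  manifest <- data.table(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  fwrite(manifest, file.path(out, "manifest.tsv"), sep = "\t")
  list(manifest = manifest, assignments = assignments, peaks = peaks_ann,
       stats_by_protein = stats_by_protein, counters = counters)
}
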