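#' Validation batteries on canonical synthetic conditions
#'
#' These functions run the pipeline end to end on fixed synthetic study
#' conditions and measure calibration and recovery against the simulator's
#' truth tables. They back the package's self-validation: null calibration
#' of the permutation peak caller, planted-peak recovery, protein-assignment
#' accuracy, and single-nucleotide truncation resolution.
#'
#' @name validation
NULL

# shared front half: demultiplex, cluster, filter, dedup, assign, split
process_experiment <- function(sim) {
  tagged_oligo <- identify_barcodes(sim$oligo_reads, sim$scheme,
                                    sim$antibody_oligos)
  tagged_cdna <- identify_barcodes(sim$cdna_reads, sim$scheme)
  rna <- attach_barcodes(sim$alignments, tagged_cdna)
  clusters <- build_clusters(tagged_oligo, rna)
  clusters <- filter_barcode_strings(clusters, sim$scheme)
  clusters <- dedup_rnas(dedup_oligos(clusters))
  assignments <- assign_clusters(clusters, scheme = sim$scheme)
  list(clusters = clusters, assignments = assignments,
       split = split_by_protein(clusters, assignments))
}

#' @describeIn validation Null calibration of the permutation peak caller:
#'   a no-binding experiment (10 proteins, 200k RNA reads on a 100 kb
#'   genome) is processed end to end and, for every protein, two error
#'   measures are reported over the window tiling: `called_fraction`, the
#'   fraction of all windows that would be falsely called peaks
#'   (>= `min_reads` observed and p < `alpha`), and `fpr_conditional`, the
#'   fraction of candidate (>= `min_reads`) windows with p < `alpha`.
#'   The permutation p is discrete and tie-inclusive, hence conservative;
#'   a small residual inflation remains because all permutations subsample
#'   one finite pool realization (see the methods vignette).
#' @param seed RNG seed for the whole battery.
#' @param n_beads,n_perms,window,min_reads,alpha condition parameters; the
#'   defaults are the canonical conditions (10k beads x 20 expected reads
#'   = 200k background RNA reads).
#' @return `validation_null_fpr`: data.table with `protein`,
#'   `n_candidate_windows`, `called_fraction`, `fpr_conditional`.
#' @export
validation_null_fpr <- function(seed = 1L, n_beads = 10000L, n_perms = 100L,
                                window = 100L, min_reads = 10L, alpha = 0.05) {
  cfg <- sim_config(n_beads = n_beads, rna_reads = list(size = 4, mu = 20),
                    seed = seed)
  sim <- make_null_experiment(cfg)
  pr <- process_experiment(sim)
  n_windows <- 2L * ceiling(cfg$genome_length / window)   # both strands
  proteins <- sort(unique(pr$split$assigned$protein))
  out <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    st <- protein_enrichment(pr$split$assigned, proteins[i], window = window,
                             n_perms = n_perms, seed = seed + i,
                             genome_sizes = sim$genome_sizes)
    cand <- st[observed >= min_reads]
    out[[i]] <- data.table(
      protein = proteins[i],
      n_candidate_windows = nrow(cand),
      called_fraction = cand[, sum(p_value < alpha)] / n_windows,
      fpr_conditional = cand[, mean(p_value < alpha)])
  }
  rbindlist(out)
}

# canonical planted-site layout: k sites per protein on distinct windows,
# crosslink 10 nt into a window so the 50-nt reads stay inside it
planted_layout <- function(proteins, sites_per_protein, fold,
                           truncation_fraction, window = 100L, reads = NA) {
  k <- length(proteins) * sites_per_protein
  widx <- 7L + 19L * seq_len(k)
  data.frame(protein = rep(proteins, each = sites_per_protein),
             reference = "chrS", position = widx * window + 10L,
             width = 30L, fold = fold,
             truncation_fraction = truncation_fraction,
             reads = as.integer(reads))
}

#' @describeIn validation Planted-peak recovery: 50 sites at 10-fold
#'   enrichment (10 per protein for 5 proteins, against 5 undisturbed
#'   proteins/controls) are planted, the pipeline and peak caller are run
#'   for every protein, and called windows are compared with the truth
#'   windows. Returns recall over planted windows and precision of all
#'   called peaks.
#' @param fold planted enrichment fold.
#' @return `validation_planted_recovery`: list with `recall`, `precision`,
#'   `n_sites`, `n_called`, `min_site_reads`.
#' @export
validation_planted_recovery <- function(seed = 2L, n_beads = 5000L,
                                        n_perms = 100L, window = 100L,
                                        fold = 10) {
  sites <- planted_layout(sprintf("RBP%02d", 1:5), 10L, fold,
                          truncation_fraction = 0, window = window)
  cfg <- sim_config(n_beads = n_beads, rna_reads = list(size = 4, mu = 8),
                    planted_sites = sites, seed = seed)
  sim <- simulate_experiment(cfg)
  pr <- process_experiment(sim)
  truth <- as.data.table(sim$truth$planted)
  truth[, wstart := (position %/% window) * window]
  called <- list()
  proteins <- sort(unique(pr$split$assigned$protein))
  for (i in seq_along(proteins)) {
    p <- proteins[i]
    st <- protein_enrichment(pr$split$assigned, p, window = window,
                             n_perms = n_perms, seed = seed + i,
                             genome_sizes = sim$genome_sizes)
    pk <- call_peaks(st)
    if (nrow(pk)) called[[p]] <- pk[, .(protein = p, strand, start)]
  }
  called <- if (length(called)) rbindlist(called) else
    data.table(protein = character(), strand = character(), start = integer())
  truth_key <- truth[, paste(protein, strand, wstart)]
  called_key <- called[, paste(protein, strand, start)]
  list(recall = mean(truth_key %in% called_key),
       precision = if (nrow(called)) mean(called_key %in% truth_key) else NA_real_,
       n_sites = nrow(truth), n_called = nrow(called),
       min_site_reads = min(truth$n_reads))
}

#' @describeIn validation Assignment accuracy under the observed cluster
#'   statistics (median 4 oligo tags, 5% tag crosstalk): fraction of
#'   non-ambiguous cluster assignments matching the bead's truth antibody,
#'   plus the cluster tag statistics the protocol reports (median tags per
#'   cluster, fraction of clusters whose tags name a single antibody).
#' @return `validation_assignment_accuracy`: list with `accuracy`,
#'   `n_assigned`, `median_tags_per_cluster`, `single_antibody_fraction`.
#' @export
validation_assignment_accuracy <- function(seed = 3L, n_beads = 10000L) {
  cfg <- sim_config(n_beads = n_beads, crosstalk_rate = 0.05,
                    rna_reads = list(size = 4, mu = 2), seed = seed)
  sim <- simulate_experiment(cfg)
  pr <- process_experiment(sim)
  called <- pr$assignments[protein != "AMBIGUOUS"]
  truth <- merge(called, sim$truth$beads[, .(barcode, antibody)],
                 by = "barcode")
  tags_per_cluster <- pr$clusters$oligos[, .N, by = barcode]
  single_ab <- pr$clusters$oligos[, .(single = uniqueN(antibody_tag) == 1L),
                                  by = barcode]
  list(accuracy = mean(truth$protein == truth$antibody),
       n_assigned = nrow(called),
       median_tags_per_cluster = stats::median(tags_per_cluster$N),
       single_antibody_fraction = mean(single_ab$single))
}

#' @describeIn validation Truncation resolution: one crosslink site per
#'   protein across 20 proteins, half of each site's reads truncating
#'   exactly at the crosslink; per protein, checks whether the planted
#'   nucleotide is the argmax of single-nucleotide truncation enrichment
#'   on the reference.
#' @return `validation_truncation_argmax`: list with `argmax_rate`,
#'   `n_sites`, `min_truncation_reads`.
#' @export
validation_truncation_argmax <- function(seed = 4L, n_beads = 4000L,
                                         n_perms = 100L) {
  proteins <- sprintf("RBP%02d", 1:20)
  sites <- planted_layout(proteins, 1L, fold = 10,
                          truncation_fraction = 0.5, reads = 80L)
  cfg <- sim_config(n_beads = n_beads, antibodies = proteins,
                    rna_reads = list(size = 4, mu = 5),
                    planted_sites = sites, seed = seed)
  sim <- simulate_experiment(cfg)
  pr <- process_experiment(sim)
  truth <- as.data.table(sim$truth$planted)
  hit <- logical(0); min_tr <- Inf
  for (i in seq_len(nrow(truth))) {
    p <- truth$protein[i]
    tgt <- pr$split$assigned[protein == p]
    if (!nrow(tgt)) next
    te <- truncation_enrichment(tgt, pr$split$assigned[protein != p],
                                n_perms = n_perms, seed = seed + i)
    te <- te[strand == truth$strand[i]]
    hit <- c(hit, nrow(te) > 0 &&
               te[which.max(enrichment), start] == truth$position[i])
    o <- te[start == truth$position[i], observed]
    if (length(o)) min_tr <- min(min_tr, o)
  }
  list(argmax_rate = mean(hit), n_sites = nrow(truth),
       min_truncation_reads = min_tr)
}
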