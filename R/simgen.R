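#' Configure a synthetic SPIDR experiment
#'
#' The simulator emulates the data-generating process of a split-pool
#' multiplexed CLIP experiment: antibody-coated beads acquire a barcode
#' string over several ligation rounds, a handful of antibody oligo tags
#' (zero-truncated Poisson, median 4 under the default mean), and RNA reads
#' drawn from a uniform transcriptome background plus optional planted RBP
#' footprints with crosslink truncation pile-ups. Inter-bead crosstalk, PCR
#' duplication and per-round ligation failures are modeled explicitly, and
#' every emitted read is traceable through truth tables.
#'
#' @param n_beads number of beads (clusters) to simulate.
#' @param antibodies character vector of antibody names, including any
#'   negative controls; beads are spread evenly across them.
#' @param tags_per_cluster_mean expected number of oligo tags per bead; the
#'   default 4 reproduces the observed median of 4 tags per cluster.
#' @param crosstalk_rate probability that an oligo tag on a bead reports a
#'   different antibody than the bead's own.
#' @param rna_reads list with `size` and `mu`: negative-binomial parameters
#'   for background RNA reads per bead.
#' @param read_length RNA read length in nt.
#' @param planted_sites `NULL` or a data.frame with columns `protein`,
#'   `reference`, `position` (crosslink coordinate, 0-based), `width`
#'   (footprint length), `fold` (target enrichment over the permutation
#'   background), `truncation_fraction`, and optionally `strand` (default
#'   `"+"`) and `reads` (overrides the fold-derived read count).
#' @param pcr_duplication_rate probability a read gains one PCR duplicate.
#' @param ligation_failure_rate per-bead, per-round probability that the
#'   round's tag is unreadable on that bead.
#' @param genome_length synthetic contig length in nt (single contig `chrS`).
#' @param window analysis window width used when converting `fold` into a
#'   planted read count.
#' @param scheme a [spidr_scheme()]; default [example_scheme()].
#' @param sample_label condition label attached to the run.
#' @param seed RNG seed; fixed seed gives byte-identical outputs.
#' @return A validated `spidr_sim_config` list.
#' @export
sim_config <- function(n_beads = 2000L,
                       antibodies = c(sprintf("RBP%02d", 1:8), "IGG", "BEAD"),
                       tags_per_cluster_mean = 4,
                       crosstalk_rate = 0.05,
                       rna_reads = list(size = 4, mu = 20),
                       read_length = 50L,
                       planted_sites = NULL,
                       pcr_duplication_rate = 0.1,
                       ligation_failure_rate = 0.02,
                       genome_length = 100000L,
                       window = 100L,
                       scheme = NULL,
                       sample_label = "pooled",
                       seed = 1L) {
  rates <- c(crosstalk = crosstalk_rate, pcr = pcr_duplication_rate,
             ligation = ligation_failure_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (tags_per_cluster_mean <= 1) stop("tags_per_cluster_mean must exceed 1")
  if (!is.null(planted_sites)) {
    planted_sites <- as.data.table(planted_sites)
    if (!"strand" %in% names(planted_sites)) planted_sites[, strand := "+"]
    if (!"reads" %in% names(planted_sites)) planted_sites[, reads := NA_integer_]
    need <- c("protein", "reference", "position", "width", "fold",
              "truncation_fraction")
    miss <- setdiff(need, names(planted_sites))
    if (length(miss)) stop("planted_sites missing columns: ", paste(miss, collapse = ", "))
    if (any(planted_sites$fold < 1)) stop("planted enrichment fold must be >= 1")
    if (any(planted_sites$truncation_fraction < 0 | planted_sites$truncation_fraction > 1))
      stop("truncation_fraction must lie in [0, 1]")
    if (!all(planted_sites$protein %in% antibodies))
      stop("planted_sites reference proteins absent from the antibody panel")
  }
  structure(list(
    n_beads = as.integer(n_beads), antibodies = antibodies,
    tags_per_cluster_mean = tags_per_cluster_mean,
    crosstalk_rate = crosstalk_rate, rna_reads = rna_reads,
    read_length = as.integer(read_length), planted_sites = planted_sites,
    pcr_duplication_rate = pcr_duplication_rate,
    ligation_failure_rate = ligation_failure_rate,
    genome_length = as.integer(genome_length), window = as.integer(window),
    scheme = scheme, sample_label = sample_label, seed = as.integer(seed)
  ), class = "spidr_sim_config")
}

# zero-truncated Poisson sampler and the lambda matching a target mean
rztpois <- function(n, lambda) {
  p0 <- ppois(0, lambda)
  qpois(p0 + runif(n) * (1 - p0), lambda)
}

ztpois_lambda <- function(mean_target) {
  uniroot(function(l) l / (1 - exp(-l)) - mean_target,
          interval = c(1e-8, mean_target * 10))$root
}

# antibody oligo-tag dictionary: one well-separated sequence per antibody
antibody_oligo_tags <- function(antibodies, tag_length = 12L, min_dist = 3L) {
  kept <- character(0)
  while (length(kept) < length(antibodies)) {
    cand <- random_dna(1L, tag_length)
    if (all(vapply(kept, function(t) hamming(t, cand) >= min_dist, logical(1))))
      kept <- c(kept, cand)
  }
  setNames(kept, antibodies)
}

#' Simulate a complete SPIDR experiment
#'
#' Generates, fully in memory, the paired oligo-tag and cDNA read libraries,
#' pre-aligned RNA records, the synthetic genome and its GTF annotation, and
#' truth tables tying every read back to its bead. Reads carry the bead's
#' barcode string on read 2 (in scheme read order, with ligation failures
#' applied at the bead level); oligo read 1 is the antibody tag followed by a
#' UMI; cDNA read 1 is the RPM adaptor followed by the genomic insert.
#'
#' Planted sites receive enough reads for the requested fold enrichment over
#' the permutation background expectation (or an explicit `reads` count), and
#' a `truncation_fraction` of those reads end their cDNA 3' end exactly at
#' the crosslink coordinate.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `spidr_sim`: a list with `config`, `scheme`,
#'   `antibody_oligos`, `genome` (named character), `genome_sizes`,
#'   `annotation` (GRanges + isoform table), `oligo_reads`, `cdna_reads`,
#'   `alignments` and `truth` (beads, planted, crosslinks, provenance).
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "spidr_sim_config"))
  local_seed(cfg$seed, {
    scheme <- cfg$scheme %||% example_scheme()
    G <- cfg$genome_length
    L <- cfg$read_length
    genome <- paste(sample(DNA_BASES, G, replace = TRUE), collapse = "")
    annot <- synth_annotation(G)

    if (!is.null(cfg$planted_sites)) {
      ps <- cfg$planted_sites
      bad <- ps[position < 0 | position >= G |
                (strand == "+" & position + width > G) |
                (strand == "-" & position - width + 1 < 0)]
      if (nrow(bad))
        stop("planted site outside the synthetic genome: ",
             paste(bad$protein, bad$position, collapse = "; "))
    }

    ## beads ----------------------------------------------------------------
    n <- cfg$n_beads
    beads <- data.table(
      bead_id = sprintf("BD%06d", seq_len(n)),
      antibody = sample(rep_len(cfg$antibodies, n))
    )
    n_rounds <- length(scheme$rounds)
    tag_mat <- vapply(scheme$rounds,
                      function(r) sample(names(r$tags), n, replace = TRUE),
                      character(n))
    if (n == 1L) tag_mat <- matrix(tag_mat, nrow = 1L)
    beads[, barcode := apply(tag_mat, 1L, paste, collapse = ".")]
    fail_mat <- matrix(runif(n * n_rounds) < cfg$ligation_failure_rate,
                       nrow = n)
    beads[, survived_ligation := rowSums(fail_mat) == 0L]

    # barcode read (read 2) per bead, failures replace the segment in place
    seg_list <- vector("list", n_rounds)
    ro <- read_order_rounds(scheme)
    for (j in seq_along(ro)) {
      i <- ro[j]
      tags <- scheme$rounds[[i]]$tags
      seg <- unname(tags[tag_mat[, i]])
      bad <- fail_mat[, i]
      if (any(bad)) seg[bad] <- strrep("N", nchar(tags[[1]]))
      seg_list[[j]] <- seg
    }
    bead_r2 <- do.call(paste0, seg_list)

    ## oligo-tag reads ------------------------------------------------------
    lambda <- ztpois_lambda(cfg$tags_per_cluster_mean)
    n_tags <- rztpois(n, lambda)
    beads[, n_tags := n_tags]
    ob <- rep.int(seq_len(n), n_tags)           # bead index per oligo tag
    olg_ab <- beads$antibody[ob]
    flip <- runif(length(ob)) < cfg$crosstalk_rate
    if (any(flip)) {
      k <- length(cfg$antibodies)
      cur <- match(olg_ab[flip], cfg$antibodies)
      shift <- sample.int(k - 1L, sum(flip), replace = TRUE)
      olg_ab[flip] <- cfg$antibodies[((cur - 1L + shift) %% k) + 1L]
    }
    oligo <- data.table(
      bead_idx = ob, antibody_tag = olg_ab,
      umi = random_dna(length(ob), scheme$umi_length),
      duplicate_of = NA_character_
    )
    dup <- which(runif(nrow(oligo)) < cfg$pcr_duplication_rate)
    if (length(dup)) {
      dups <- oligo[dup]
      oligo[, read_id := sprintf("OLG%07d", .I)]
      dups[, duplicate_of := oligo$read_id[dup]]
      dups[, read_id := sprintf("OLG%07d", nrow(oligo) + .I)]
      oligo <- rbind(oligo, dups)
    } else oligo[, read_id := sprintf("OLG%07d", .I)]
    ab_tags <- antibody_oligo_tags(cfg$antibodies)
    oligo[, `:=`(bead_id = beads$bead_id[bead_idx],
                 seq1 = paste0(ab_tags[antibody_tag], umi),
                 seq2 = bead_r2[bead_idx])]

    ## RNA reads ------------------------------------------------------------
    n_bg <- rnbinom(n, size = cfg$rna_reads$size, mu = cfg$rna_reads$mu)
    rb <- rep.int(seq_len(n), n_bg)
    rna <- data.table(
      bead_idx = rb,
      start = sample.int(G - L + 1L, length(rb), replace = TRUE) - 1L,
      strand = sample(c("+", "-"), length(rb), replace = TRUE),
      truncated = FALSE, site_id = NA_integer_
    )
    rna[, end := start + L]

    planted <- NULL
    if (!is.null(cfg$planted_sites) && nrow(cfg$planted_sites)) {
      planted <- copy(cfg$planted_sites)
      planted[, site_id := .I]
      bg_per_protein <- beads[rb, .N, by = antibody]
      c1 <- (cfg$window + L - 1) / G * 0.5   # expected bg fraction per window, per strand
      planted[, n_reads := {
        nb <- bg_per_protein[antibody == protein[1], N]
        if (!length(nb)) nb <- 0L
        if (all(!is.na(reads))) as.integer(reads) else {
          denom <- 1 - c1 * sum(fold)
          if (denom <= 0) stop("planted folds infeasible for protein ", protein[1])
          pmax(1L, as.integer(round(fold * c1 * nb / denom)))
        }
      }, by = protein]
      site_rows <- vector("list", nrow(planted))
      for (s in seq_len(nrow(planted))) {
        p <- planted[s]
        bidx <- which(beads$antibody == p$protein)
        if (!length(bidx)) stop("no beads carry antibody ", p$protein)
        m <- p$n_reads
        ntr <- as.integer(round(p$truncation_fraction * m))
        off <- c(rep.int(0L, ntr), sample.int(p$width, m - ntr, replace = TRUE) - 1L)
        if (p$strand == "+") {
          st <- p$position + off
          en <- st + L
        } else {
          en <- p$position + 1L - off
          st <- en - L
        }
        site_rows[[s]] <- data.table(
          bead_idx = sample(bidx, m, replace = TRUE), start = st, end = en,
          strand = p$strand, truncated = seq_len(m) <= ntr, site_id = p$site_id)
      }
      rna <- rbind(rna, rbindlist(site_rows))
      setkey(rna, NULL)
    }
    rna[end > G, `:=`(start = start - (end - G), end = G)]
    rna[start < 0L, `:=`(end = end - start, start = 0L)]
    rna[, duplicate_of := NA_character_]
    dup <- which(runif(nrow(rna)) < cfg$pcr_duplication_rate)
    if (length(dup)) {
      dups <- rna[dup]
      rna[, read_id := sprintf("RNA%07d", .I)]
      dups[, duplicate_of := rna$read_id[dup]]
      dups[, read_id := sprintf("RNA%07d", nrow(rna) + .I)]
      rna <- rbind(rna, dups)
    } else rna[, read_id := sprintf("RNA%07d", .I)]
    rna[, bead_id := beads$bead_id[bead_idx]]

    inserts <- substring(genome, rna$start + 1L, rna$end)
    neg <- rna$strand == "-"
    if (any(neg)) inserts[neg] <- reverse_complement(inserts[neg])
    cdna <- data.table(
      read_id = rna$read_id, bead_id = rna$bead_id,
      duplicate_of = rna$duplicate_of,
      seq1 = paste0(scheme$rpm_sequence, inserts),
      seq2 = bead_r2[rna$bead_idx]
    )
    alignments <- rna[, .(read_id, reference = "chrS", start, end, strand,
                          mapq = 255L, unique_mapping = TRUE)]

    truth <- list(
      beads = beads[, .(bead_id, antibody, barcode, n_tags, survived_ligation)],
      planted = if (is.null(planted)) data.table(
        site_id = integer(), protein = character(), reference = character(),
        position = integer(), width = integer(), fold = numeric(),
        truncation_fraction = numeric(), strand = character(),
        n_reads = integer()) else
        planted[, .(site_id, protein, reference, position, width, fold,
                    truncation_fraction, strand, n_reads)],
      crosslinks = if (is.null(planted)) data.table(
        site_id = integer(), protein = character(), reference = character(),
        pos = integer(), strand = character()) else
        planted[, .(site_id, protein, reference, pos = position, strand)],
      provenance = rbind(
        oligo[, .(read_id, bead_id, class = "OLIGO", duplicate_of)],
        rna[, .(read_id, bead_id, class = "RNA", duplicate_of)])
    )
    structure(list(
      config = cfg, scheme = scheme, antibody_oligos = ab_tags,
      genome = setNames(genome, "chrS"), genome_sizes = c(chrS = G),
      annotation = annot,
      oligo_reads = oligo[, .(read_id, bead_id, antibody_tag, umi,
                              duplicate_of, seq1, seq2)],
      cdna_reads = cdna,
      alignments = alignments,
      truth = truth
    ), class = "spidr_sim")
  })
}

#' Simulate a null experiment (no planted binding)
#'
#' All proteins draw RNA reads from the same uniform background over the
#' synthetic genome; used to calibrate the permutation peak caller.
#'
#' @param cfg a [sim_config()] with empty `planted_sites`.
#' @return A `spidr_sim`, as [simulate_experiment()].
#' @export
make_null_experiment <- function(cfg) {
  if (!is.null(cfg$planted_sites) && nrow(cfg$planted_sites))
    stop("a null experiment must not have planted sites")
  simulate_experiment(cfg)
}

#' @export
print.spidr_sim <- function(x, ...) {
  cat(sprintf("spidr synthetic experiment: %d beads, %d antibodies, genome %d nt\n",
              x$config$n_beads, length(x$config$antibodies), x$config$genome_length))
  cat(sprintf("  oligo reads: %d | RNA reads: %d | planted sites: %d\n",
              nrow(x$oligo_reads), nrow(x$cdna_reads), nrow(x$truth$planted)))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits gzip FASTQ pairs for the oligo and cDNA libraries, the aligned RNA
#' records as SAM, the genome as indexed FASTA, the annotation as GTF, the
#' barcode scheme as YAML, and the truth tables as TSV.
#'
#' @param sim a `spidr_sim` from [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fastq_pair(sim$oligo_reads, p("oligo_R1.fastq.gz"), p("oligo_R2.fastq.gz"))
  write_fastq_pair(sim$cdna_reads, p("cdna_R1.fastq.gz"), p("cdna_R2.fastq.gz"))
  write_sam(sim$alignments, sim$genome_sizes, p("alignments.sam"))
  dna <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(dna, p("genome.fa"))
  Rsamtools::indexFa(p("genome.fa"))
  rtracklayer::export(sim$annotation$gr, p("annotation.gtf"), format = "gtf")
  write_scheme(sim$scheme, p("scheme.yaml"))
  fwrite(sim$truth$beads, p("truth_beads.tsv"), sep = "\t")
  fwrite(sim$truth$planted, p("truth_planted.tsv"), sep = "\t")
  fwrite(sim$truth$crosslinks, p("truth_crosslinks.tsv"), sep = "\t")
  fwrite(sim$truth$provenance, p("truth_provenance.tsv"), sep = "\t")
  ab <- data.table(antibody = names(sim$antibody_oligos),
                   tag = unname(sim$antibody_oligos))
  fwrite(ab, p("antibody_tags.tsv"), sep = "\t")
  files <- c(oligo_r1 = p("oligo_R1.fastq.gz"), oligo_r2 = p("oligo_R2.fastq.gz"),
             cdna_r1 = p("cdna_R1.fastq.gz"), cdna_r2 = p("cdna_R2.fastq.gz"),
             sam = p("alignments.sam"), genome = p("genome.fa"),
             gtf = p("annotation.gtf"), scheme = p("scheme.yaml"),
             beads = p("truth_beads.tsv"), planted = p("truth_planted.tsv"),
             crosslinks = p("truth_crosslinks.tsv"),
             provenance = p("truth_provenance.tsv"),
             antibody_tags = p("antibody_tags.tsv"))
  invisible(files)
}

write_fastq_pair <- function(reads, path1, path2) {
  q1 <- strrep("I", nchar(reads$seq1))
  q2 <- strrep("I", nchar(reads$seq2))
  con <- gzfile(path1, "wb")
  writeLines(paste0("@", reads$read_id, "\n", reads$seq1, "\n+\n", q1), con)
  close(con)
  con <- gzfile(path2, "wb")
  writeLines(paste0("@", reads$read_id, "\n", reads$seq2, "\n+\n", q2), con)
  close(con)
}

#' Read a paired FASTQ library into a read table
#'
#' @param path1,path2 FASTQ (optionally gzip) paths for mates 1 and 2.
#' @return data.table with `read_id`, `seq1`, `seq2`.
#' @export
read_fastq_pair <- function(path1, path2) {
  rd <- function(p) {
    ln <- readLines(p)
    ids <- sub("^@", "", ln[seq(1L, length(ln), by = 4L)])
    ids <- sub("\\s.*$", "", ids)
    list(id = ids, seq = ln[seq(2L, length(ln), by = 4L)])
  }
  a <- rd(path1); b <- rd(path2)
  if (!identical(a$id, b$id)) stop("FASTQ mates are not in the same order")
  data.table(read_id = a$id, seq1 = a$seq, seq2 = b$seq)
}

write_sam <- function(alignments, genome_sizes, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome_sizes), genome_sizes))
  flag <- ifelse(alignments$strand == "-", 16L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                 alignments$read_id, flag, alignments$reference,
                 alignments$start + 1L, alignments$mapq %||% 255L,
                 alignments$end - alignments$start)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read aligned RNA records from SAM/BAM
#'
#' SAM input is converted with `Rsamtools::asBam()` first. Records are
#' returned in the package's internal 0-based half-open convention. Only
#' match-only CIGARs (`<n>M`) are supported, matching what the simulator
#' emits; unmapped reads are dropped. `unique_mapping` is derived from the
#' mapping quality (`mapq >= min_mapq`) and the secondary-alignment flag.
#'
#' @param path SAM or BAM file.
#' @param min_mapq mapping quality at or above which a read counts as
#'   uniquely mapped (default 30).
#' @return data.table with `read_id`, `reference`, `start`, `end`, `strand`,
#'   `mapq`, `unique_mapping`.
#' @export
read_alignments <- function(path, min_mapq = 30L) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar")))[[1]]
  keep <- !is.na(res$pos)
  width <- suppressWarnings(as.integer(sub("^([0-9]+)M$", "\\1", res$cigar[keep])))
  if (anyNA(width)) stop("read_alignments supports match-only CIGARs (<n>M)")
  data.table(
    read_id = res$qname[keep],
    reference = as.character(res$rname[keep]),
    start = res$pos[keep] - 1L,
    end = res$pos[keep] - 1L + width,
    strand = ifelse(bitwAnd(res$flag[keep], 16L) > 0L, "-", "+"),
    mapq = res$mapq[keep],
    unique_mapping = res$mapq[keep] >= min_mapq &
      bitwAnd(res$flag[keep], 256L) == 0L
  )
}
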