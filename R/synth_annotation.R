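#' Miniature annotation for the synthetic genome
#'
#' Builds a GENCODE-flavoured annotation on the single synthetic contig
#' `chrS`, scaled to the genome length, with enough variety to exercise
#' every peak-annotation category: multi-exon protein-coding genes on both
#' strands (one with two isoforms, one with a long intron for the
#' proximal/distal split), a histone-like single-exon coding gene, a
#' non-coding multi-exon gene, and a miRNA embedded in the intron of a
#' non-coding host gene. Coordinates are returned as a 1-based `GRanges`
#' (GTF convention) plus a 0-based half-open isoform-span table used by the
#' differential module.
#'
#' @param genome_length contig length in nt (>= 10000 recommended).
#' @return list with `gr` (GRanges with `type`, `gene_id`, `transcript_id`,
#'   `gene_name`, `gene_type` metadata) and `isoforms` (data.table).
#' @export
synth_annotation <- function(genome_length = 100000L) {
  G <- as.integer(genome_length)
  s <- function(f) as.integer(round(f * G))   # scale a fraction to 0-based coord
  rows <- list()
  add <- function(type, start0, end0, gene, tx, gtype, strand) {
    rows[[length(rows) + 1L]] <<- data.table(
      type = type, start = start0, end = end0, gene_id = gene,
      transcript_id = tx, gene_type = gtype, strand = strand)
  }
  gene_tx <- function(gene, gtype, strand, isoforms) {
    # isoforms: named list tx -> list(exons=list(c(a,b),...), cds=..., utr5=, utr3=)
    all_start <- min(vapply(isoforms, function(i) min(vapply(i$exons, `[`, numeric(1), 1L)), numeric(1)))
    all_end <- max(vapply(isoforms, function(i) max(vapply(i$exons, `[`, numeric(1), 2L)), numeric(1)))
    add("gene", s(all_start), s(all_end), gene, NA_character_, gtype, strand)
    for (tx in names(isoforms)) {
      iso <- isoforms[[tx]]
      st <- min(vapply(iso$exons, `[`, numeric(1), 1L))
      en <- max(vapply(iso$exons, `[`, numeric(1), 2L))
      add("transcript", s(st), s(en), gene, tx, gtype, strand)
      for (e in iso$exons) add("exon", s(e[1]), s(e[2]), gene, tx, gtype, strand)
      for (e in iso$cds %||% list()) add("CDS", s(e[1]), s(e[2]), gene, tx, gtype, strand)
      for (e in iso$utr5 %||% list()) add("five_prime_utr", s(e[1]), s(e[2]), gene, tx, gtype, strand)
      for (e in iso$utr3 %||% list()) add("three_prime_utr", s(e[1]), s(e[2]), gene, tx, gtype, strand)
    }
  }

  gene_tx("GENE1", "protein_coding", "+", list(
    "GENE1-T1" = list(exons = list(c(.05, .07), c(.09, .11), c(.13, .15)),
                      cds = list(c(.06, .07), c(.09, .11), c(.13, .14)),
                      utr5 = list(c(.05, .06)), utr3 = list(c(.14, .15))),
    "GENE1-T2" = list(exons = list(c(.05, .07), c(.13, .15)),
                      cds = list(c(.06, .07), c(.13, .14)),
                      utr5 = list(c(.05, .06)), utr3 = list(c(.14, .15)))))
  gene_tx("GENE2", "protein_coding", "-", list(
    "GENE2-T1" = list(exons = list(c(.20, .23), c(.27, .30)),
                      cds = list(c(.21, .23), c(.27, .29)),
                      utr5 = list(c(.29, .30)), utr3 = list(c(.20, .21)))))
  gene_tx("HIST1", "protein_coding", "+", list(
    "HIST1-T1" = list(exons = list(c(.35, .36)),
                      cds = list(c(.352, .358)),
                      utr5 = list(c(.35, .352)), utr3 = list(c(.358, .36)))))
  gene_tx("LNC1", "lincRNA", "+", list(
    "LNC1-T1" = list(exons = list(c(.42, .43), c(.45, .46)))))
  gene_tx("MIRHG1", "lincRNA", "+", list(
    "MIRHG1-T1" = list(exons = list(c(.55, .555), c(.595, .60)))))
  # miRNA inside the MIRHG1 intron; fixed 80 nt so it stays sub-window sized
  mir_start <- s(.57)
  rows[[length(rows) + 1L]] <- data.table(
    type = c("gene", "transcript", "exon"), start = mir_start,
    end = mir_start + 80L, gene_id = "MIR1",
    transcript_id = c(NA, "MIR1-T1", "MIR1-T1"),
    gene_type = "miRNA", strand = "+")
  gene_tx("GENE3", "protein_coding", "+", list(
    "GENE3-T1" = list(exons = list(c(.70, .72), c(.78, .80)),
                      cds = list(c(.705, .72), c(.78, .795)),
                      utr5 = list(c(.70, .705)), utr3 = list(c(.795, .80)))))

  feat <- rbindlist(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = "chrS",
    ranges = IRanges::IRanges(start = feat$start + 1L, end = feat$end),
    strand = feat$strand)
  S4Vectors::mcols(gr)$type <- feat$type
  S4Vectors::mcols(gr)$gene_id <- feat$gene_id
  S4Vectors::mcols(gr)$transcript_id <- feat$transcript_id
  S4Vectors::mcols(gr)$gene_name <- feat$gene_id
  S4Vectors::mcols(gr)$gene_type <- feat$gene_type
  S4Vectors::mcols(gr)$phase <- ifelse(feat$type == "CDS", 0L, NA_integer_)
  iso <- feat[type == "transcript",
              .(gene_id, transcript_id, reference = "chrS", start, end, strand)]
  list(gr = gr, isoforms = iso)
}
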