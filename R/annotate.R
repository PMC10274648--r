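#' Build an annotation index from a GTF
#'
#' Loads a GENCODE-dialect GTF (attributes `gene_id`, `transcript_id`,
#' `gene_type` or `gene_biotype`) and derives the interval sets the peak
#' annotator needs: miRNA exons, CDS, 5'/3' UTRs (explicit
#' `five_prime_utr`/`three_prime_utr` features when present, otherwise
#' derived as exonic-minus-CDS per coding transcript), introns of coding
#' and of non-coding transcripts, non-coding exons, and the set of miRNA
#' host genes (non-miRNA genes whose span contains a miRNA gene). GTF
#' coordinates (1-based closed) are handled natively as `GRanges`.
#'
#' @param gtf path to a GTF file, or a `GRanges` with a `type` column.
#' @return An object of class `spidr_annotation_db`.
#' @export
build_annotation_db <- function(gtf) {
  gr <- if (methods::is(gtf, "GRanges")) gtf
        else rtracklayer::import(gtf, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  gtype <- if ("gene_type" %in% names(mc)) mc$gene_type
           else if ("gene_biotype" %in% names(mc)) mc$gene_biotype
           else rep(NA_character_, length(gr))
  S4Vectors::mcols(gr)$gene_type <- gtype
  type <- mc$type

  genes <- gr[type == "gene"]
  exons <- gr[type == "exon"]
  cds <- gr[type == "CDS"]
  mirna_exons <- exons[S4Vectors::mcols(exons)$gene_type == "miRNA"]

  coding_tx <- unique(S4Vectors::mcols(cds)$transcript_id)
  utr5 <- gr[type %in% c("five_prime_utr", "five_prime_UTR")]
  utr3 <- gr[type %in% c("three_prime_utr", "three_prime_UTR")]
  if (!length(utr5) && !length(utr3) && length(cds)) {
    d <- derive_utrs(exons, cds, coding_tx)
    utr5 <- d$utr5; utr3 <- d$utr3
  }

  introns_c <- GenomicRanges::GRanges(); introns_nc <- GenomicRanges::GRanges()
  tx_ids <- unique(S4Vectors::mcols(exons)$transcript_id)
  tx_ids <- tx_ids[!is.na(tx_ids)]
  ex_by_tx <- S4Vectors::split(exons, S4Vectors::mcols(exons)$transcript_id)
  for (tx in tx_ids) {
    ex <- ex_by_tx[[tx]]
    if (length(ex) < 2L) next
    intr <- GenomicRanges::setdiff(range(ex), ex)
    if (!length(intr)) next
    if (tx %in% coding_tx) introns_c <- c(introns_c, intr)
    else introns_nc <- c(introns_nc, intr)
  }
  nc_exons <- exons[!(S4Vectors::mcols(exons)$transcript_id %in% coding_tx) &
                      S4Vectors::mcols(exons)$gene_type != "miRNA"]

  mir_genes <- genes[S4Vectors::mcols(genes)$gene_type == "miRNA"]
  hosts <- genes[S4Vectors::mcols(genes)$gene_type != "miRNA"]
  host_hit <- GenomicRanges::findOverlaps(hosts, mir_genes, type = "any",
                                          ignore.strand = TRUE)
  host_ids <- unique(S4Vectors::mcols(hosts)$gene_id[S4Vectors::queryHits(host_hit)])

  structure(list(
    genes = genes, mirna_exons = mirna_exons, cds = cds,
    utr5 = utr5, utr3 = utr3, introns_coding = introns_c,
    introns_noncoding = introns_nc, noncoding_exons = nc_exons,
    host_gene_ids = host_ids
  ), class = "spidr_annotation_db")
}

# UTR derivation: exonic parts outside the CDS span, sided by strand
derive_utrs <- function(exons, cds, coding_tx) {
  u5 <- list(); u3 <- list()
  ex_by <- S4Vectors::split(exons, S4Vectors::mcols(exons)$transcript_id)
  cds_by <- S4Vectors::split(cds, S4Vectors::mcols(cds)$transcript_id)
  for (tx in coding_tx) {
    ex <- ex_by[[tx]]; cc <- cds_by[[tx]]
    if (is.null(ex) || is.null(cc)) next
    parts <- GenomicRanges::setdiff(ex, cc)
    if (!length(parts)) next
    cs <- min(GenomicRanges::start(cc)); ce <- max(GenomicRanges::end(cc))
    plus <- as.character(GenomicRanges::strand(parts)[1L]) != "-"
    up <- GenomicRanges::end(parts) < cs
    down <- GenomicRanges::start(parts) > ce
    if (plus) { u5[[tx]] <- parts[up]; u3[[tx]] <- parts[down] }
    else { u5[[tx]] <- parts[down]; u3[[tx]] <- parts[up] }
  }
  cat_grl <- function(l) if (length(l)) do.call(c, unname(l)) else GenomicRanges::GRanges()
  list(utr5 = cat_grl(u5), utr3 = cat_grl(u3))
}

#' Filter peaks by mapping provenance and blacklist
#'
#' Removes peaks from non-uniquely-mapped regions (when the peaks carry a
#' `unique_mapping` column) and peaks overlapping blacklist intervals
#' (e.g. poorly aligning rRNA regions). Removal counts are attached as the
#' `"removed"` attribute.
#'
#' @param peaks data.table of peaks (`reference`, `start`, `end`, ...).
#' @param blacklist optional data.table of intervals (`reference`, `start`,
#'   `end`), 0-based half-open; malformed intervals (start >= end) raise a
#'   validation error.
#' @return Filtered peaks.
#' @export
filter_peaks <- function(peaks, blacklist = NULL) {
  pk <- as.data.table(peaks)
  n0 <- nrow(pk)
  n_nonuniq <- 0L
  if ("unique_mapping" %in% names(pk)) {
    n_nonuniq <- sum(!pk$unique_mapping)
    pk <- pk[unique_mapping == TRUE]
  }
  n_black <- 0L
  if (!is.null(blacklist) && nrow(blacklist)) {
    bl <- as.data.table(blacklist)
    if (any(bl$start >= bl$end))
      stop("malformed blacklist interval (start >= end)")
    setkey(bl, reference, start, end)
    ov <- foverlaps(pk, bl[, .(reference, start, end)],
                    by.x = c("reference", "start", "end"), which = TRUE,
                    nomatch = NULL)
    drop <- unique(ov$xid)
    n_black <- length(drop)
    if (n_black) pk <- pk[-drop]
  }
  attr(pk, "removed") <- list(non_unique = n_nonuniq, blacklist = n_black,
                              input = n0)
  pk[]
}

ANNOTATION_LEVELS <- c("miRNA", "miRNA_proximal", "CDS", "5UTR", "3UTR",
                       "proximal_intron", "distal_intron", "noncoding_exon",
                       "noncoding_intron", "intergenic")

#' Annotate peaks by feature priority
#'
#' Assigns each peak exactly one label. Overlapping annotations are
#' resolved by priority: miRNA, CDS, 5'UTR, 3'UTR, proximal intron (within
#' `proximal_nt` of a splice site), distal intron (further than
#' `proximal_nt`), non-coding exon, non-coding intron; peaks overlapping
#' nothing are `intergenic`. Peaks whose resulting annotation is a
#' non-coding feature of a miRNA host gene are marked `miRNA_proximal`.
#' Priority is evaluated over the union of all overlapping features of all
#' genes. Matching requires same-strand overlap by default.
#'
#' @param peaks data.table of peaks (`reference`, `start`, `end`, `strand`;
#'   0-based half-open).
#' @param db a `spidr_annotation_db` from [build_annotation_db()].
#' @param proximal_nt splice-site proximity threshold in nt (default 500),
#'   measured from the nearer intron boundary.
#' @param stranded require same-strand overlap (default `TRUE`).
#' @return The peaks with an `annotation` column (factor over the
#'   annotation categories).
#' @export
annotate_peaks <- function(peaks, db, proximal_nt = 500L, stranded = TRUE) {
  pk <- as.data.table(peaks)
  n <- nrow(pk)
  out <- copy(pk)
  if (!n) { out[, annotation := factor(character(), ANNOTATION_LEVELS)]; return(out[]) }
  pgr <- GenomicRanges::GRanges(
    pk$reference, IRanges::IRanges(pk$start + 1L, pk$end),
    strand = if ("strand" %in% names(pk)) pk$strand else "*")
  ig <- !stranded
  hit <- function(subject) {
    if (!length(subject)) return(rep(FALSE, n))
    IRanges::overlapsAny(pgr, subject, ignore.strand = ig)
  }
  in_mirna <- hit(db$mirna_exons)
  in_cds <- hit(db$cds)
  in_utr5 <- hit(db$utr5)
  in_utr3 <- hit(db$utr3)
  in_nc_exon <- hit(db$noncoding_exons)
  in_nc_intron <- hit(db$introns_noncoding)

  # coding introns: proximal vs distal by distance to the nearer splice site
  in_ci_prox <- rep(FALSE, n); in_ci_dist <- rep(FALSE, n)
  if (length(db$introns_coding)) {
    ov <- GenomicRanges::findOverlaps(pgr, db$introns_coding, ignore.strand = ig)
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
      d5 <- GenomicRanges::start(pgr)[qi] - GenomicRanges::start(db$introns_coding)[si]
      d3 <- GenomicRanges::end(db$introns_coding)[si] - GenomicRanges::end(pgr)[qi]
      dd <- pmax(0L, pmin(d5, d3))
      mind <- tapply(dd, qi, min)
      idx <- as.integer(names(mind))
      in_ci_prox[idx] <- mind <= proximal_nt
      in_ci_dist[idx] <- mind > proximal_nt
    }
  }
  label <- rep("intergenic", n)
  label[in_nc_intron] <- "noncoding_intron"
  label[in_nc_exon] <- "noncoding_exon"
  label[in_ci_dist] <- "distal_intron"
  label[in_ci_prox] <- "proximal_intron"
  label[in_utr3] <- "3UTR"
  label[in_utr5] <- "5UTR"
  label[in_cds] <- "CDS"
  label[in_mirna] <- "miRNA"

  # miRNA-host rule: non-coding features of a host gene become miRNA_proximal
  if (length(db$host_gene_ids)) {
    hosts <- db$genes[S4Vectors::mcols(db$genes)$gene_id %in% db$host_gene_ids]
    in_host <- hit(hosts)
    nc <- label %in% c("noncoding_exon", "noncoding_intron")
    label[nc & in_host] <- "miRNA_proximal"
  }
  out[, annotation := factor(label, levels = ANNOTATION_LEVELS)]
  out[]
}

#' Per-protein annotation composition
#'
#' Drops intergenic peaks, keeps proteins with strictly more than
#' `min_peaks` remaining peaks, and returns the fraction of each protein's
#' peaks per annotation category (rows sum to 1).
#'
#' @param annotated_peaks data.table with `protein` and `annotation`
#'   columns (see [annotate_peaks()]).
#' @param min_peaks protein inclusion threshold (strict `>`, default 100).
#' @return Numeric matrix, proteins x annotation categories.
#' @export
annotation_composition <- function(annotated_peaks, min_peaks = 100L) {
  pk <- as.data.table(annotated_peaks)[annotation != "intergenic"]
  keep <- pk[, .N, by = protein][N > min_peaks, protein]
  pk <- pk[protein %in% keep]
  cats <- setdiff(ANNOTATION_LEVELS, "intergenic")
  mat <- matrix(0, nrow = length(keep), ncol = length(cats),
                dimnames = list(sort(keep), cats))
  if (nrow(pk)) {
    tab <- pk[, .N, by = .(protein, annotation)]
    mat[cbind(tab$protein, as.character(tab$annotation))] <- tab$N
    mat <- mat / rowSums(mat)
  }
  mat
}
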