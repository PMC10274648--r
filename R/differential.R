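#' Gene-level signal from a background-corrected bedGraph
#'
#' Maps bedGraph values onto gene isoforms with absolute-maximum semantics:
#' per isoform, the value is the largest absolute bedGraph value
#' intersecting the isoform span (returned as the magnitude); per gene, the
#' isoform with the highest value is kept. Genes with no overlapping
#' bedGraph interval get 0. The bedGraph must be position-sorted within
#' each reference.
#'
#' @param bedgraph data.table from [read_bedgraph()] (`reference`, `start`,
#'   `end`, `value`).
#' @param isoforms data.table of isoform spans: `gene_id`,
#'   `transcript_id`, `reference`, `start`, `end` (0-based half-open).
#' @return data.table with `gene_id`, `isoform`, `raw_value`.
#' @export
gene_signal <- function(bedgraph, isoforms) {
  bg <- as.data.table(bedgraph)
  iso <- as.data.table(isoforms)
  if (nrow(bg) && bg[, any(start != cummax(start)), by = reference][, any(V1)])
    stop("bedGraph must be sorted by start within each reference")
  per_iso <- iso[, .(gene_id, isoform = transcript_id, reference, start, end)]
  if (nrow(bg)) {
    setkey(bg, reference, start, end)
    ov <- foverlaps(per_iso, bg, by.x = c("reference", "start", "end"),
                    nomatch = NA)
    vals <- ov[, .(raw_value = {
      v <- value[!is.na(value)]
      if (length(v)) max(abs(v)) else 0
    }), by = .(gene_id, isoform)]
  } else {
    vals <- per_iso[, .(raw_value = 0), by = .(gene_id, isoform)]
  }
  vals[order(-raw_value), .SD[1L], by = gene_id][
    , .(gene_id, isoform, raw_value)][order(gene_id)][]
}

#' Normalize gene signals by bead-cluster counts
#'
#' Detection depends on how many antibody beads a protein had in each
#' condition, so mapped values are divided by the number of assigned bead
#' clusters for that (protein, condition); downstream ratios then compare
#' bead-normalized values.
#'
#' @param signals data.table of gene signals carrying `protein` and
#'   `condition` columns in addition to `raw_value`.
#' @param bead_counts data.table from [bead_cluster_counts()] with columns
#'   `protein`, `sample_label`, `n_clusters` (sample_label = condition).
#' @return `signals` with a `corrected_value` column.
#' @export
normalize_by_beads <- function(signals, bead_counts) {
  s <- as.data.table(signals)
  bc <- as.data.table(bead_counts)[, .(protein, condition = sample_label,
                                       n_clusters)]
  out <- bc[s, on = c("protein", "condition")]
  if (any(is.na(out$n_clusters) | out$n_clusters == 0)) {
    bad <- unique(out[is.na(n_clusters) | n_clusters == 0,
                      paste(protein, condition)])
    stop("zero or missing bead-cluster count for: ",
         paste(bad, collapse = ", "))
  }
  out[, corrected_value := raw_value / n_clusters]
  out[]
}

#' Per-gene log-ratios grouped by TOP score
#'
#' Computes `log2(corrected_treated / corrected_control)` per gene and bins
#' genes into TOP-score categories from a user-supplied score table
#' (e.g. published TOP motif scores). Genes with zero signal in either
#' condition are excluded (the log-ratio is undefined); genes without a
#' score fall into an `"unscored"` bin.
#'
#' @param control,treated data.tables with `gene_id` and
#'   `corrected_value` (or `raw_value`) columns for the two conditions.
#' @param top_scores data.table with `gene_id`, `score`.
#' @param bin_edges numeric breaks for the score categories (default four
#'   categories: `c(-Inf, 1, 2, 3, Inf)`).
#' @param labels optional category labels (length `length(bin_edges) - 1`).
#' @return data.table with `gene_id`, `log2_ratio`, `score`, `category`.
#' @export
top_grouped_ratios <- function(control, treated, top_scores,
                               bin_edges = c(-Inf, 1, 2, 3, Inf),
                               labels = NULL) {
  val_col <- function(d) if ("corrected_value" %in% names(d)) "corrected_value"
                         else "raw_value"
  ctl <- as.data.table(control)[, .(gene_id, control = get(val_col(control)))]
  trt <- as.data.table(treated)[, .(gene_id, treated = get(val_col(treated)))]
  m <- trt[ctl, on = "gene_id", nomatch = NULL]
  if (!nrow(m)) stop("no genes shared between the two conditions")
  m <- m[control > 0 & treated > 0]
  m[, log2_ratio := log2(treated / control)]
  ts <- as.data.table(top_scores)[, .(gene_id, score)]
  m <- ts[m, on = "gene_id"]
  if (is.null(labels))
    labels <- paste0("TOP", seq_len(length(bin_edges) - 1L))
  m[, category := as.character(cut(score, breaks = bin_edges,
                                   labels = labels, right = TRUE))]
  m[is.na(category), category := "unscored"]
  m[, .(gene_id, log2_ratio, score, category)][]
}

#' Two-sided Mann-Whitney U test between two score groups
#'
#' Rank-based U with tie correction. When the combined sample size is at
#' most 20, the null distribution of U is enumerated exactly over all
#' rank assignments (ties included via midranks); larger samples use the
#' normal approximation with continuity and tie correction.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return list with `statistic` (U for `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (n <= 20L) {
    combs <- utils::combn(n, nx)
    u_null <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    p <- 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs))
    list(statistic = u_obs, p_value = min(1, p), method = "exact enumeration")
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(statistic = u_obs, p_value = wt$p.value,
         method = "normal approximation")
  }
}

#' Mann-Whitney comparison of two TOP-score categories
#'
#' @param grouped output of [top_grouped_ratios()].
#' @param groupA,groupB category labels to compare.
#' @return [mann_whitney()] result.
#' @export
group_test <- function(grouped, groupA, groupB) {
  a <- grouped[category == groupA, log2_ratio]
  b <- grouped[category == groupB, log2_ratio]
  if (!length(a) || !length(b))
    stop("empty group: ", if (!length(a)) groupA else groupB)
  mann_whitney(a, b)
}

#' Per-protein read-count ratios between conditions
#'
#' Number of assigned RNA reads per protein in the treated condition over
#' the control condition, after bead-count normalization. Proteins with
#' zero normalized reads in the denominator are flagged (`infinite`) and
#' kept, not dropped.
#'
#' @param assigned_control,assigned_treated assigned RNA record tables
#'   (from [split_by_protein()]`$assigned`) for the two conditions.
#' @param bead_counts_control,bead_counts_treated bead-cluster counts per
#'   condition ([bead_cluster_counts()]); `NULL` skips normalization.
#' @return data.table with `protein`, `reads_control`, `reads_treated`,
#'   `ratio`, `infinite`, sorted by ratio (infinite first).
#' @export
read_count_ratio <- function(assigned_control, assigned_treated,
                             bead_counts_control = NULL,
                             bead_counts_treated = NULL) {
  cc <- as.data.table(assigned_control)[, .(reads_control = .N), by = protein]
  tt <- as.data.table(assigned_treated)[, .(reads_treated = .N), by = protein]
  m <- merge(cc, tt, by = "protein", all = TRUE)
  m[is.na(reads_control), reads_control := 0L]
  m[is.na(reads_treated), reads_treated := 0L]
  norm_c <- rep(1, nrow(m)); norm_t <- rep(1, nrow(m))
  if (!is.null(bead_counts_control)) {
    bcc <- as.data.table(bead_counts_control)[, .(n = sum(n_clusters)), by = protein]
    norm_c <- bcc[m, on = "protein"]$n
  }
  if (!is.null(bead_counts_treated)) {
    bct <- as.data.table(bead_counts_treated)[, .(n = sum(n_clusters)), by = protein]
    norm_t <- bct[m, on = "protein"]$n
  }
  m[, ratio := (reads_treated / ifelse(is.na(norm_t) | norm_t == 0, NA, norm_t)) /
               (reads_control / ifelse(is.na(norm_c) | norm_c == 0, NA, norm_c))]
  m[, infinite := is.infinite(ratio) | is.na(ratio) |
      reads_control == 0]
  setorder(m, -ratio, na.last = TRUE)
  m[]
}
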