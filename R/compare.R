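#' Hypergeometric overlap of two window sets
#'
#' Tests whether two peak-window sets share more windows than expected by
#' chance over a common universe of windows. The 2x2 table over the
#' universe gives the odds ratio `(n11 * n00) / (n10 * n01)` (a
#' Haldane-Anscombe 0.5 correction is applied, and flagged, only when a
#' table cell is zero) and an exact hypergeometric upper-tail p-value
#' `P(X >= n11)`.
#'
#' @param setA,setB character vectors of window identifiers (any stable
#'   encoding, e.g. `"chr:start"`), subsets of `universe`.
#' @param universe character vector of all windows under consideration. A
#'   sensible default universe is every fixed window with at least one read
#'   in the combined pool of both datasets.
#' @return list with `n11`, `n10`, `n01`, `n00`, `odds_ratio`,
#'   `haldane_corrected`, `p_value`, `universe_size`.
#' @export
hypergeometric_overlap <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("setA and setB must be subsets of the universe")
  N <- length(universe)
  n11 <- length(intersect(setA, setB))
  n10 <- length(setA) - n11
  n01 <- length(setB) - n11
  n00 <- N - n11 - n10 - n01
  cells <- c(n11, n10, n01, n00)
  corrected <- any(cells == 0)
  or_cells <- if (corrected) cells + 0.5 else cells
  odds_ratio <- (or_cells[1] * or_cells[4]) / (or_cells[2] * or_cells[3])
  p <- phyper(n11 - 1, length(setA), N - length(setA), length(setB),
              lower.tail = FALSE)
  list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
       odds_ratio = odds_ratio, haldane_corrected = corrected,
       p_value = p, universe_size = N)
}

#' L2-norm shuffle test for annotation-composition similarity
#'
#' Compares two protein x annotation-category composition matrices. The
#' observed statistic is the Euclidean (L2) norm of the difference of the
#' flattened matrices. The null distribution is built by randomly
#' permuting the protein rows of one matrix while holding the other fixed
#' (each protein's within-row percentages stay intact), alternating which
#' matrix is shuffled, for `n_samples` draws in total. Small L2 means
#' similar, so the empirical p-value is the fraction of null values less
#' than or equal to the observed one, with the observed draw included in
#' numerator and denominator.
#'
#' @param matA,matB numeric matrices with identical row (protein) and
#'   column (category) label sets.
#' @param n_samples number of shuffles (default 1000).
#' @param seed RNG seed.
#' @return list with `observed_l2`, `null_distribution`, `empirical_p`.
#' @export
l2_shuffle_test <- function(matA, matB, n_samples = 1000L, seed = NULL) {
  missA <- setdiff(rownames(matB), rownames(matA))
  missB <- setdiff(rownames(matA), rownames(matB))
  missCA <- setdiff(colnames(matB), colnames(matA))
  missCB <- setdiff(colnames(matA), colnames(matB))
  if (length(c(missA, missB, missCA, missCB)))
    stop("matrix labels differ; missing: ",
         paste(unique(c(missA, missB, missCA, missCB)), collapse = ", "))
  matB <- matB[rownames(matA), colnames(matA), drop = FALSE]
  l2 <- function(a, b) sqrt(sum((as.vector(a) - as.vector(b))^2))
  observed <- l2(matA, matB)
  local_seed(seed, {
    null <- numeric(n_samples)
    for (i in seq_len(n_samples)) {
      perm <- sample.int(nrow(matA))
      null[i] <- if (i %% 2L == 1L) l2(matA, matB[perm, , drop = FALSE])
                 else l2(matA[perm, , drop = FALSE], matB)
    }
    p <- (sum(null <= observed) + 1) / (n_samples + 1)
    list(observed_l2 = observed, null_distribution = null, empirical_p = p)
  })
}

#' Window identifiers for a peak table
#'
#' Encodes each peak window as `"reference:strand:start"` for use with
#' [hypergeometric_overlap()].
#'
#' @param stats window statistics or peaks (`reference`, `strand`, `start`).
#' @return Character vector of window ids.
#' @export
window_ids <- function(stats) {
  sprintf("%s:%s:%d", stats$reference, stats$strand, stats$start)
}
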