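#' @import data.table
#' @importFrom stats rbinom rnbinom runif qpois ppois uniroot wilcox.test phyper setNames
#' @importFrom utils head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL leaves the stream untouched.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

# n random DNA strings of length len
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  cols <- lapply(seq_len(len), function(i) sample(DNA_BASES, n, replace = TRUE))
  do.call(paste0, cols)
}

# Hamming distance between two equal-length strings
hamming <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# Per-element Hamming distance of a character vector against one reference
# string; elements whose length differs get NA.
hamming_to <- function(x, ref) {
  L <- nchar(ref)
  out <- rep.int(NA_integer_, length(x))
  ok <- !is.na(x) & nchar(x) == L
  if (!any(ok)) return(out)
  refi <- utf8ToInt(ref)
  m <- vapply(x[ok], function(s) sum(utf8ToInt(s) != refi), integer(1L), USE.NAMES = FALSE)
  out[ok] <- m
  out
}

# Match each segment against a named set of equal-length tags allowing at most
# max_mismatch mismatches; returns tag names (NA where no tag is close enough).
match_tags <- function(segments, tags, max_mismatch = 1L) {
  hit <- names(tags)[match(segments, tags)]
  if (max_mismatch > 0L) {
    todo <- which(is.na(hit) & !is.na(segments))
    if (length(todo)) {
      mm <- matrix(NA_integer_, nrow = length(todo), ncol = length(tags))
      for (j in seq_along(tags)) mm[, j] <- hamming_to(segments[todo], tags[[j]])
      best <- max.col(-replace(mm, is.na(mm), .Machine$integer.max), ties.method = "first")
      bestd <- mm[cbind(seq_along(todo), best)]
      ok <- !is.na(bestd) & bestd <= max_mismatch
      hit[todo[ok]] <- names(tags)[best[ok]]
    }
  }
  hit
}

reverse_complement <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# suppress R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "antibody", "antibody_tag", "barcode", "bead_id", "count",
  "duplicate_of", "end", "enrichment", "expected_mean", "gene_id", "i.count",
  "i.value", "k_ge", "n_oligos", "n_perm_present", "n_rnas", "n_tags", "observed",
  "p_value", "perm", "protein", "read_class", "read_id", "reference", "sample_label",
  "start", "strand", "sum_perm", "top_fraction", "transcript_id", "umi",
  "unique_mapping", "value", "wstart", "isoform", "raw_value", "corrected_value",
  "log2_ratio", "score", "category", "condition", "pos", "offset", "annotation",
  "zero_expected", "n_reads", "width"
))
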