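#' Split-pool barcode schemes
#'
#' A barcode scheme describes the split-and-pool ligation architecture of a
#' SPIDR experiment: the ordered rounds of tag ligation (each round drawing
#' from its own set of Odd, Even or Terminal tags), the RPM adaptor sequence
#' that marks RNA-derived reads, the UMI length on oligo-tag reads, and the
#' per-tag mismatch tolerance used when decoding reads.
#'
#' Tag sequences within a round must be pairwise separated by a Hamming
#' distance greater than twice the mismatch tolerance so that error-tolerant
#' matching is unambiguous. Tag order on the sequenced read is by default the
#' reverse of ligation order (the last-ligated Terminal tag is read first).
#'
#' @param rounds list of round specifications, each a list with elements
#'   `name` (string), `category` (one of `"ODD"`, `"EVEN"`, `"TERMINAL"`) and
#'   `tags` (named character vector, tag name -> sequence).
#' @param rpm_sequence RNA-adaptor sequence whose presence routes a read into
#'   the RNA stream (default `"ATCAGCACTTA"`).
#' @param umi_length UMI length in bases on oligo-tag reads.
#' @param mismatch_tolerance maximum Hamming mismatches tolerated per tag.
#' @param read_order `"reverse_ligation"` (default) or `"ligation"`; the order
#'   in which round tags appear along the barcode read.
#' @param sample_round_index optional index of the round whose tag encodes the
#'   experimental condition.
#' @param sample_map optional named character vector mapping tag names of the
#'   sample round to condition labels.
#' @param validate check scheme invariants (default `TRUE`).
#' @return An object of class `spidr_scheme`.
#' @export
spidr_scheme <- function(rounds, rpm_sequence = "ATCAGCACTTA", umi_length = 8L,
                         mismatch_tolerance = 1L,
                         read_order = c("reverse_ligation", "ligation"),
                         sample_round_index = NULL, sample_map = NULL,
                         validate = TRUE) {
  read_order <- match.arg(read_order)
  rounds <- lapply(rounds, function(r) {
    list(name = as.character(r$name), category = toupper(as.character(r$category)),
         tags = unlist(r$tags))
  })
  scheme <- structure(list(
    rounds = rounds, rpm_sequence = toupper(rpm_sequence),
    umi_length = as.integer(umi_length),
    mismatch_tolerance = as.integer(mismatch_tolerance),
    read_order = read_order,
    sample_round_index = if (is.null(sample_round_index)) NULL else as.integer(sample_round_index),
    sample_map = sample_map
  ), class = "spidr_scheme")
  if (validate) validate_scheme(scheme)
  scheme
}

#' Validate a barcode scheme
#'
#' Checks every scheme invariant: non-empty ACGT RPM sequence, at least two
#' uniquely named tags per round, equal tag lengths within a round, pairwise
#' Hamming separation greater than `2 * mismatch_tolerance`, and a valid
#' Odd/Even/Terminal category layout (Terminal only in the last-ligated round).
#'
#' @param scheme a [spidr_scheme()].
#' @return The scheme, invisibly; errors describe the offending round.
#' @export
validate_scheme <- function(scheme) {
  if (!nzchar(scheme$rpm_sequence))
    stop("scheme is missing an rpm_sequence")
  if (grepl("[^ACGT]", scheme$rpm_sequence))
    stop("rpm_sequence must be over the alphabet {A,C,G,T}")
  if (!length(scheme$rounds)) stop("scheme has no rounds")
  n <- length(scheme$rounds)
  for (i in seq_len(n)) {
    r <- scheme$rounds[[i]]
    tags <- r$tags
    if (!r$category %in% c("ODD", "EVEN", "TERMINAL"))
      stop(sprintf("round '%s': unknown category '%s'", r$name, r$category))
    if (r$category == "TERMINAL" && i != n)
      stop(sprintf("round '%s': TERMINAL tags must be in the last-ligated round", r$name))
    if (length(tags) < 2L)
      stop(sprintf("round '%s': needs at least 2 tags", r$name))
    if (anyDuplicated(names(tags)))
      stop(sprintf("round '%s': duplicate tag names", r$name))
    if (anyDuplicated(tags))
      stop(sprintf("round '%s': duplicate tag sequences", r$name))
    if (length(unique(nchar(tags))) != 1L)
      stop(sprintf("round '%s': tag sequences must have equal length", r$name))
    if (any(grepl("[^ACGT]", tags)))
      stop(sprintf("round '%s': tag sequences must be over {A,C,G,T}", r$name))
    lim <- 2L * scheme$mismatch_tolerance
    for (a in seq_len(length(tags) - 1L)) for (b in seq(a + 1L, length(tags))) {
      if (hamming(tags[[a]], tags[[b]]) <= lim)
        stop(sprintf("round '%s': tags '%s' and '%s' are within 2 x mismatch_tolerance mismatches",
                     r$name, names(tags)[a], names(tags)[b]))
    }
  }
  if (!is.null(scheme$sample_round_index) &&
      (scheme$sample_round_index < 1L || scheme$sample_round_index > n))
    stop("sample_round_index out of range")
  invisible(scheme)
}

#' Number of distinct barcode strings a scheme can produce
#'
#' The product over rounds of the number of tags per round. The chance that
#' two beads receive the same barcode string is `1 / barcode_space(scheme)`;
#' e.g. 8 rounds of 12 tags give `12^8`, about 430 million.
#'
#' @param scheme a [spidr_scheme()].
#' @return Barcode-space size as a double (may exceed integer range).
#' @export
barcode_space <- function(scheme) {
  prod(vapply(scheme$rounds, function(r) length(r$tags), numeric(1)))
}

#' Load a barcode scheme from a YAML or JSON config file
#'
#' The file carries `rounds` (list of name/category/tags), `rpm_sequence`,
#' `umi_length`, `mismatch_tolerance`, `read_order` and optionally
#' `sample_round_index` / `sample_map`. Both YAML and JSON dialects are
#' accepted; the extension selects the parser (`.json` -> JSON, otherwise
#' YAML, which is a JSON superset anyway).
#'
#' @param path config file path.
#' @return A validated [spidr_scheme()].
#' @export
load_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme config not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  if (is.null(raw$rpm_sequence)) stop("scheme config is missing rpm_sequence")
  if (is.null(raw$rounds)) stop("scheme config is missing rounds")
  rounds <- raw$rounds
  if (is.data.frame(rounds))  # jsonlite may tabularize the round list
    rounds <- lapply(seq_len(nrow(rounds)), function(i)
      list(name = rounds$name[i], category = rounds$category[i],
           tags = unlist(rounds$tags[i])))
  spidr_scheme(
    rounds = rounds,
    rpm_sequence = raw$rpm_sequence,
    umi_length = raw$umi_length %||% 8L,
    mismatch_tolerance = raw$mismatch_tolerance %||% 1L,
    read_order = raw$read_order %||% "reverse_ligation",
    sample_round_index = raw$sample_round_index,
    sample_map = if (is.null(raw$sample_map)) NULL else unlist(raw$sample_map)
  )
}

#' Write a barcode scheme config
#'
#' @param scheme a [spidr_scheme()].
#' @param path output path; `.json` writes JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  obj <- list(
    rpm_sequence = scheme$rpm_sequence, umi_length = scheme$umi_length,
    mismatch_tolerance = scheme$mismatch_tolerance, read_order = scheme$read_order,
    rounds = lapply(scheme$rounds, function(r)
      list(name = r$name, category = r$category, tags = as.list(r$tags)))
  )
  if (!is.null(scheme$sample_round_index)) obj$sample_round_index <- scheme$sample_round_index
  if (!is.null(scheme$sample_map)) obj$sample_map <- as.list(scheme$sample_map)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else yaml::write_yaml(obj, path)
  invisible(path)
}

#' Generate an example split-pool scheme
#'
#' Builds a scheme with `n_rounds` rounds of `tags_per_round` random tag
#' sequences each, rejection-sampled so tags within a round are separated by
#' Hamming distance of at least `2 * mismatch_tolerance + 1`. Categories
#' follow the ligation grammar used in practice: rounds alternate ODD/EVEN
#' starting from ODD, and the last-ligated round is TERMINAL. Tag names are
#' globally unique (`R<round>T<tag>`).
#'
#' @param n_rounds number of split-pool rounds.
#' @param tags_per_round tags per round.
#' @param tag_length tag sequence length in bases.
#' @param mismatch_tolerance decoding tolerance carried into the scheme.
#' @param umi_length UMI length for oligo reads.
#' @param sample_round_index,sample_map optional condition encoding, see
#'   [spidr_scheme()].
#' @param seed RNG seed for tag generation.
#' @return A validated [spidr_scheme()].
#' @export
example_scheme <- function(n_rounds = 6L, tags_per_round = 12L, tag_length = 8L,
                           mismatch_tolerance = 1L, umi_length = 8L,
                           sample_round_index = NULL, sample_map = NULL,
                           seed = 42L) {
  local_seed(seed, {
    min_dist <- 2L * mismatch_tolerance + 1L
    rounds <- vector("list", n_rounds)
    for (i in seq_len(n_rounds)) {
      kept <- character(0)
      while (length(kept) < tags_per_round) {
        cand <- random_dna(1L, tag_length)
        if (all(vapply(kept, function(t) hamming(t, cand) >= min_dist, logical(1))))
          kept <- c(kept, cand)
      }
      names(kept) <- sprintf("R%dT%02d", i, seq_along(kept))
      cat_i <- if (i == n_rounds) "TERMINAL" else if (i %% 2L == 1L) "ODD" else "EVEN"
      rounds[[i]] <- list(name = sprintf("round%d", i), category = cat_i, tags = kept)
    }
    spidr_scheme(rounds,
                 umi_length = umi_length, mismatch_tolerance = mismatch_tolerance,
                 sample_round_index = sample_round_index, sample_map = sample_map)
  })
}

#' @export
print.spidr_scheme <- function(x, ...) {
  cat(sprintf("spidr barcode scheme: %d rounds, barcode space %.4g\n",
              length(x$rounds), barcode_space(x)))
  for (r in x$rounds)
    cat(sprintf("  %s [%s]: %d tags of %d nt\n", r$name, r$category,
                length(r$tags), nchar(r$tags[[1]])))
  cat(sprintf("  RPM %s | UMI %d nt | tolerance %d | read order %s\n",
              x$rpm_sequence, x$umi_length, x$mismatch_tolerance, x$read_order))
  invisible(x)
}

# rounds in the order they appear along the barcode read
read_order_rounds <- function(scheme) {
  idx <- seq_along(scheme$rounds)
  if (scheme$read_order == "reverse_ligation") idx <- rev(idx)
  idx
}
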