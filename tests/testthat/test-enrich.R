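test_that("reads increment every overlapped window, half-open", {
  cw <- count_windows(rna_records(105L, 125L), window = 10L)
  expect_equal(cw$wstart, c(100L, 110L, 120L))
  expect_equal(cw$count, c(1L, 1L, 1L))
  cw <- count_windows(rna_records(100L, 110L), window = 10L)
  expect_equal(cw$wstart, 100L)
  expect_equal(nrow(count_windows(rna_records(integer(0), integer(0)))), 0L)
  # strands are counted separately
  cw <- count_windows(rna_records(c(0L, 0L), c(10L, 10L), strand = c("+", "-")),
                      window = 10L)
  expect_equal(nrow(cw), 2L)
  expect_error(count_windows(rna_records(90L, 140L), window = 10L,
                             genome_sizes = c(chrS = 100L)), "beyond")
})

test_that("permutations downsample exactly to the target depth, reproducibly", {
  pool <- rna_records((0:999) * 10L, (0:999) * 10L + 50L)
  bg <- permutation_background(100L, pool, n_perms = 100L, window = 100L,
                               seed = 5L)
  per_perm <- bg$perm_counts[, .(total = sum(count)), by = perm]
  # each read of length 50 in 100-nt windows overlaps 1 or 2 windows
  expect_true(all(per_perm$total >= 100L & per_perm$total <= 200L))
  expect_true(all(apply(bg$perm_indices, 2, function(i) length(unique(i))) == 100L))
  bg2 <- permutation_background(100L, pool, n_perms = 100L, window = 100L,
                                seed = 5L)
  expect_identical(bg$perm_counts, bg2$perm_counts)
  expect_error(permutation_background(2000L, pool, 100L, 100L, 1L), "smaller")
  expect_error(permutation_background(10L, pool, n_perms = 50L), "100")
})

test_that("per-window permutation means match the uniform expectation", {
  # uniform pool over two abutting windows: reads of width 10 at window 0 or 1
  set.seed(7)
  starts <- sample(c(0L, 10L), 5000L, replace = TRUE)
  pool <- rna_records(starts, starts + 10L)
  bg <- permutation_background(500L, pool, n_perms = 100L, window = 10L,
                               seed = 9L)
  means <- bg$perm_counts[, .(m = sum(count) / 100), by = wstart]
  expect_equal(means$m, rep(250, 2), tolerance = 0.05)
})

test_that("enrichment and p-value arithmetic follow the permutation formula", {
  obs <- data.table(reference = "chrS", strand = "+", wstart = 0L, count = 20L)
  st <- window_enrichment(obs, manual_background(rep(5L, 100L)))
  expect_equal(st$enrichment, 4)
  expect_equal(st$expected_mean, 5)
  expect_equal(st$p_value, 1 / 101)                  # k = 0, observed included
  st <- window_enrichment(obs, manual_background(rep(20L, 100L)))
  expect_equal(st$p_value, 1)                        # k = n_perms
  st <- window_enrichment(obs, manual_background(c(rep(0L, 96L), rep(25L, 4L))))
  expect_equal(st$p_value, 5 / 101)
  # zero expected: floored enrichment, flagged
  st <- window_enrichment(obs, manual_background(rep(0L, 100L)))
  expect_true(st$zero_expected)
  expect_equal(st$enrichment, 20 * 100)
  expect_equal(st$p_value, 1 / 101)
})

test_that("p-values are monotone non-increasing in the observed count", {
  bg <- manual_background(rpois(100, 5))
  ps <- vapply(1:30, function(o) {
    window_enrichment(data.table(reference = "chrS", strand = "+",
                                 wstart = 0L, count = o), bg)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("peak calling applies both thresholds with the stated strictness", {
  st <- data.table(reference = "chrS", strand = "+", start = c(0L, 10L, 20L),
                   end = c(10L, 20L, 30L), observed = c(9L, 15L, 15L),
                   expected_mean = 1, enrichment = 10,
                   p_value = c(0.001, 0.0099, 0.05), n_perms = 100L,
                   zero_expected = FALSE)
  pk <- call_peaks(st)
  expect_equal(pk$start, 10L)     # 9 reads rejected; p = 0.05 exactly rejected
})

test_that("permutation p-values match a brute-force recomputation on a toy", {
  pool <- rna_records(c(rep(0L, 30L), rep(10L, 15L), rep(25L, 5L)),
                      c(rep(8L, 30L), rep(18L, 15L), rep(33L, 5L)))
  target <- rna_records(c(rep(0L, 6L), rep(10L, 3L), 25L),
                        c(rep(8L, 6L), rep(18L, 3L), 33L))
  obs <- count_windows(target, window = 10L)
  bg <- permutation_background(nrow(target), pool, n_perms = 100L,
                               window = 10L, seed = 21L)
  st <- window_enrichment(obs, bg)
  # independent recomputation from the stored permutation indices
  for (w in st$start) {
    k <- 0L; tot <- 0
    o <- obs[wstart == w, count]
    for (p in seq_len(bg$n_perms)) {
      reads <- bg$pool[bg$perm_indices[, p]]
      cnt <- sum(reads$start < w + 10L & reads$end > w)
      tot <- tot + cnt
      if (cnt >= o) k <- k + 1L
    }
    row <- st[start == w]
    expect_equal(row$p_value, (k + 1) / 101)
    expect_equal(row$expected_mean, tot / 100)
  }
})

test_that("truncation coordinates sit at the cDNA 3' end", {
  reads <- rna_records(c(1000L, 1000L, 500L), c(1150L, 1150L, 600L),
                       strand = c("+", "-", "+"))
  expect_equal(truncation_coordinate(reads), c(1000L, 1149L, 500L))
  # duplicates share the coordinate
  expect_equal(truncation_coordinate(reads)[1], truncation_coordinate(reads)[1])
  tp <- truncation_profile(reads)
  expect_equal(sum(tp$count), 3L)
})

test_that("truncation enrichment finds a planted crosslink", {
  cfg <- sim_config(
    n_beads = 1500L, rna_reads = list(size = 4, mu = 6), seed = 61L,
    planted_sites = data.frame(protein = "RBP01", reference = "chrS",
                               position = 4010L, width = 30L, fold = 10,
                               truncation_fraction = 0.5, reads = 60L))
  sim <- simulate_experiment(cfg)
  pr <- process_sim(sim)
  tgt <- pr$split$assigned[protein == "RBP01"]
  other <- pr$split$assigned[protein != "RBP01"]
  te <- truncation_enrichment(tgt, other, n_perms = 100L, seed = 63L)
  expect_equal(te[which.max(enrichment), start], 4010L)
  te2 <- truncation_enrichment(tgt, other, n_perms = 100L, seed = 63L)
  expect_identical(te, te2)
  empty <- truncation_enrichment(tgt[0], other, n_perms = 100L, seed = 1L)
  expect_equal(nrow(empty), 0L)
})

test_that("motif-centered profiles aggregate strand-aware offsets", {
  # truncations exactly 2 nt upstream of two motif starts
  reads <- rna_records(c(98L, 98L, 198L), c(150L, 150L, 250L))
  peaks <- data.table(reference = "chrS", start = c(90L, 190L),
                      end = c(160L, 260L), strand = "+")
  motifs <- data.table(reference = "chrS", start = c(100L, 200L),
                       end = c(108L, 208L), strand = "+")
  prof <- motif_centered_profile(reads, peaks, motifs, half_width = 20L)
  expect_equal(prof$offset, -2L)
  expect_equal(prof$frequency, 1)
  # minus-strand motif flips the offset sign
  prof <- motif_centered_profile(
    reads, peaks, data.table(reference = "chrS", start = 100L, end = 108L,
                             strand = "-"), half_width = 20L)
  expect_equal(prof$offset, 2L)
  # motifs outside peaks are ignored
  far <- data.table(reference = "chrS", start = 5000L, end = 5008L, strand = "+")
  expect_equal(nrow(motif_centered_profile(reads, peaks, far)), 0L)
  expect_equal(nrow(motif_centered_profile(reads, peaks, motifs[0])), 0L)
})

test_that("uniform truncations give a flat motif-centered profile", {
  set.seed(77)
  starts <- sample.int(1000L, 20000L, replace = TRUE) - 1L
  reads <- rna_records(starts, starts + 30L)
  peaks <- data.table(reference = "chrS", start = 0L, end = 1100L, strand = "+")
  motifs <- data.table(reference = "chrS", start = c(300L, 600L), end = c(308L, 608L),
                       strand = "+")
  prof <- motif_centered_profile(reads, peaks, motifs, half_width = 50L)
  expect_equal(nrow(prof), 101L)
  expect_lt(max(abs(prof$frequency - 1 / 101)), 3 / 101)
})

test_that("bedGraph export writes enrichment and round-trips", {
  st <- data.table(reference = "chrS", strand = "+", start = c(100L, 200L),
                   end = c(110L, 210L), observed = c(12L, 0L),
                   expected_mean = 3, enrichment = c(4, 0),
                   p_value = 0.01, n_perms = 100L, zero_expected = FALSE)
  path <- temp_path("enr.bedgraph")
  export_bedgraph(st, path)
  lines <- readLines(path)
  expect_match(lines[1], "^track")
  expect_equal(lines[2], "chrS\t100\t110\t4")   # zero-observed window omitted
  expect_equal(length(lines), 2L)
  rt <- read_bedgraph(path)
  expect_equal(rt$value, 4, tolerance = 1e-6)
  path2 <- temp_path("empty.bedgraph")
  export_bedgraph(st[0], path2)
  expect_equal(length(readLines(path2)), 1L)
})
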