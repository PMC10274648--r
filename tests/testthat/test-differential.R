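iso <- function(gene, tx, start, end) {
  data.table(gene_id = gene, transcript_id = tx, reference = "chrS",
             start = as.integer(start), end = as.integer(end))
}

test_that("gene signal takes the absolute maximum over the gene span", {
  bg <- data.table(reference = "chrS", start = c(100L, 200L, 300L),
                   end = c(150L, 250L, 350L), value = c(2, 5, 3))
  gs <- gene_signal(bg, iso("G1", "G1-T1", 50L, 400L))
  expect_equal(gs$raw_value, 5)
  # absmax semantics: magnitudes, not signed extremes
  bg2 <- copy(bg)[, value := c(2, -7, 3)]
  expect_equal(gene_signal(bg2, iso("G1", "G1-T1", 50L, 400L))$raw_value, 7)
})

test_that("the isoform with the highest mapped value represents the gene", {
  bg <- data.table(reference = "chrS", start = c(100L, 500L),
                   end = c(150L, 550L), value = c(5, 8))
  isos <- rbind(iso("G1", "T-short", 50L, 200L), iso("G1", "T-long", 50L, 600L))
  gs <- gene_signal(bg, isos)
  expect_equal(nrow(gs), 1L)
  expect_equal(gs$isoform, "T-long")
  expect_equal(gs$raw_value, 8)
})

test_that("genes without coverage get zero and unsorted bedGraphs error", {
  bg <- data.table(reference = "chrS", start = 100L, end = 150L, value = 5)
  gs <- gene_signal(bg, rbind(iso("G1", "T1", 50L, 200L),
                              iso("G2", "T2", 5000L, 6000L)))
  expect_equal(gs[gene_id == "G2", raw_value], 0)
  bad <- data.table(reference = "chrS", start = c(200L, 100L),
                    end = c(250L, 150L), value = 1)
  expect_error(gene_signal(bad, iso("G1", "T1", 50L, 400L)), "sorted")
})

test_that("bead-count normalization rescales values and errors on zero beads", {
  s <- data.table(gene_id = c("G1", "G1"), protein = "RBP01",
                  condition = c("control", "torin"), raw_value = c(10, 40))
  bc <- data.table(protein = "RBP01", sample_label = c("control", "torin"),
                   n_clusters = c(100L, 200L))
  out <- normalize_by_beads(s, bc)
  expect_equal(out[condition == "control", corrected_value], 0.1)
  expect_equal(out[condition == "torin", corrected_value], 0.2)
  # ratio after correction: log2(0.2 / 0.1) = 1
  expect_equal(log2(out[condition == "torin", corrected_value] /
                      out[condition == "control", corrected_value]), 1)
  bc0 <- copy(bc)[sample_label == "torin", n_clusters := 0L]
  expect_error(normalize_by_beads(s, bc0), "zero or missing")
  # equal bead counts leave ratios unchanged
  bce <- copy(bc)[, n_clusters := 150L]
  oute <- normalize_by_beads(s, bce)
  expect_equal(oute[condition == "torin", corrected_value] /
                 oute[condition == "control", corrected_value],
               s[condition == "torin", raw_value] /
                 s[condition == "control", raw_value])
})

test_that("TOP-grouped log ratios bin genes and handle unscored genes", {
  ctl <- data.table(gene_id = sprintf("G%d", 1:4), corrected_value = c(2, 4, 1, 3))
  trt <- data.table(gene_id = sprintf("G%d", 1:4), corrected_value = c(4, 4, 4, 6))
  ts <- data.table(gene_id = c("G1", "G2", "G3"), score = c(0.5, 1.5, 3.5))
  gr <- top_grouped_ratios(ctl, trt, ts)
  expect_equal(gr[gene_id == "G1", log2_ratio], 1)
  expect_equal(gr[gene_id == "G2", log2_ratio], 0)
  expect_equal(gr[gene_id == "G1", category], "TOP1")
  expect_equal(gr[gene_id == "G3", category], "TOP4")
  expect_equal(gr[gene_id == "G4", category], "unscored")
  # antisymmetry under swapping conditions
  rev <- top_grouped_ratios(trt, ctl, ts)
  m <- merge(gr, rev, by = "gene_id")
  expect_equal(m$log2_ratio.x, -m$log2_ratio.y)
  expect_error(top_grouped_ratios(ctl, data.table(gene_id = "ZZ",
                                                  corrected_value = 1), ts),
               "no genes shared")
})

test_that("Mann-Whitney exact path matches hand results and full enumeration", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  r <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)      # 2 * 1/C(6,3)-tail = 2/20
  # independent enumeration oracle over placements, all combined n <= 8
  set.seed(5)
  for (i in 1:20) {
    nx <- sample(1:4, 1); ny <- sample(1:4, 1)
    x <- sample(1:5, nx, replace = TRUE)  # ties included
    y <- sample(1:5, ny, replace = TRUE)
    r <- mann_whitney(x, y)
    rk <- rank(c(x, y)); n <- nx + ny
    u_all <- apply(utils::combn(n, nx), 2, function(ix)
      sum(rk[ix]) - nx * (nx + 1) / 2)
    u_obs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
    p_or <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
    expect_equal(r$p_value, p_or)
    expect_equal(r$statistic, u_obs)
  }
})

test_that("exact and approximate Mann-Whitney paths agree near the cutover", {
  set.seed(9)
  x <- rnorm(10); y <- rnorm(10, mean = 1)
  exact <- mann_whitney(x, y)            # n = 20: exact enumeration
  approx <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE))
  expect_equal(exact$p_value, approx$p.value, tolerance = 0.1)
  big <- mann_whitney(c(x, 0.1), y)      # n = 21: normal approximation
  expect_equal(big$method, "normal approximation")
})

test_that("group_test compares TOP categories and rejects empty groups", {
  gr <- data.table(gene_id = sprintf("G%d", 1:8),
                   log2_ratio = c(2, 2.2, 1.8, 2.1, 0, 0.1, -0.1, 0.05),
                   score = c(4, 4, 4, 4, 0, 0, 0, 0),
                   category = rep(c("TOP4", "TOP1"), each = 4))
  r <- group_test(gr, "TOP4", "TOP1")
  expect_lt(r$p_value, 0.05)
  expect_error(group_test(gr, "TOP4", "missing"), "empty group")
})

test_that("read-count ratios flag zero denominators and sort by ratio", {
  ctl <- data.table(protein = rep(c("A", "B"), c(100, 50)))
  trt <- data.table(protein = rep(c("A", "B", "C"), c(100, 200, 30)))
  rr <- read_count_ratio(ctl, trt)
  expect_equal(rr[protein == "A", ratio], 1)
  expect_equal(rr[protein == "B", ratio], 4)
  expect_true(rr[protein == "C", infinite])
  expect_equal(rr$protein[1], "C")   # infinite first after sorting by ratio
  # bead-count normalization cancels when counts are equal
  bc <- data.table(protein = c("A", "B", "C"), sample_label = "s",
                   n_clusters = 10L)
  rrn <- read_count_ratio(ctl, trt, bc, bc)
  expect_equal(rrn[protein == "B", ratio], 4)
})

test_that("a planted condition-specific gain is recovered through the full path", {
  G <- 100000L
  ann <- synth_annotation(G)
  # plant binding at the 5' ends of GENE1 and GENE3 (treated 4x control)
  sites <- function(mult) data.frame(
    protein = "RBP01", reference = "chrS", position = c(5010L, 70010L),
    width = 30L, fold = 5, truncation_fraction = 0,
    reads = as.integer(60 * mult))
  run_cond <- function(label, mult, seed) {
    cfg <- sim_config(n_beads = 1200L, planted_sites = sites(mult),
                      sample_label = label, seed = seed)
    sim <- simulate_experiment(cfg)
    pr <- process_sim(sim)
    st <- protein_enrichment(pr$split$assigned, "RBP01", n_perms = 100L,
                             seed = seed + 1L, genome_sizes = sim$genome_sizes)
    path <- temp_path(sprintf("diff_%s.bedgraph", label))
    export_bedgraph(st, path)
    list(signal = gene_signal(read_bedgraph(path), ann$isoforms),
         beads = pr$assignments[protein == "RBP01", .N])
  }
  ctl <- run_cond("control", 1, 71L)
  trt <- run_cond("torin", 4, 73L)
  ts <- data.table(gene_id = unique(ann$isoforms$gene_id),
                   score = ifelse(unique(ann$isoforms$gene_id) %in%
                                    c("GENE1", "GENE3"), 4, 0.5))
  gr <- top_grouped_ratios(ctl$signal, trt$signal, ts)
  high <- gr[category == "TOP4", log2_ratio]
  expect_equal(length(high), 2L)
  # planted 4-fold gain: log2 ratio near 2 for the high-TOP genes
  expect_equal(median(high), 2, tolerance = 0.35)
})
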