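valid_bc <- function(sc, i1, i2, i3) {
  paste(names(sc$rounds[[1]]$tags)[i1], names(sc$rounds[[2]]$tags)[i2],
        names(sc$rounds[[3]]$tags)[i3], sep = ".")
}

test_that("clusters group records by complete barcode string", {
  sc <- tiny_scheme()
  b1 <- valid_bc(sc, 1, 1, 1); b2 <- valid_bc(sc, 2, 2, 2)
  tagged <- data.table(
    read_id = sprintf("o%d", 1:3),
    barcode = c(b1, b1, b2), n_tags = 3L, read_class = "OLIGO",
    residual_sequence = "", umi = c("AA", "AB", "AC"),
    antibody_tag = "ABX", sample_label = NA_character_)
  rna <- data.table(read_id = sprintf("r%d", 1:4),
                    barcode = c(b1, b1, b1, NA),
                    reference = "chrS", start = c(0L, 10L, 20L, 30L),
                    end = c(50L, 60L, 70L, 80L), strand = "+",
                    unique_mapping = c(TRUE, TRUE, TRUE, TRUE))
  cl <- build_clusters(tagged, rna)
  expect_equal(n_clusters(cl), 2L)
  expect_equal(nrow(cl$oligos[barcode == b1]), 2L)
  expect_equal(nrow(cl$rnas[barcode == b1]), 3L)
  expect_equal(cl$unclustered$rna_unbarcoded, 1L)
  # conservation: all records accounted for
  expect_equal(nrow(cl$rnas) + cl$unclustered$rna_unbarcoded, nrow(rna))
})

test_that("multimapping RNA reads are dropped before clustering", {
  sc <- tiny_scheme()
  b <- valid_bc(sc, 1, 1, 1)
  rna <- data.table(barcode = b, reference = "chrS", start = 0L, end = 50L,
                    strand = "+", unique_mapping = c(TRUE, FALSE))
  cl <- build_clusters(
    data.table(read_id = "o", barcode = b, n_tags = 3L, read_class = "OLIGO",
               residual_sequence = "", umi = "AA", antibody_tag = "ABX",
               sample_label = NA_character_), rna)
  expect_equal(nrow(cl$rnas), 1L)
  expect_equal(cl$unclustered$rna_multimapping, 1L)
})

test_that("invalid barcode strings are filtered with counts logged", {
  sc <- tiny_scheme()
  good <- valid_bc(sc, 1, 2, 3)
  n1 <- names(sc$rounds[[1]]$tags); n2 <- names(sc$rounds[[2]]$tags)
  repeated <- paste(n1[1], n1[1], names(sc$rounds[[3]]$tags)[1], sep = ".")
  out_of_order <- paste(n2[1], n1[1], names(sc$rounds[[3]]$tags)[1], sep = ".")
  cl <- make_clusters(oligos = data.table(
    barcode = c(good, repeated, out_of_order),
    antibody_tag = "ABX", umi = c("A", "B", "C")))
  fl <- filter_barcode_strings(cl, sc)
  expect_equal(unique(fl$oligos$barcode), good)
  expect_equal(attr(fl, "removed")$clusters, 2L)
})

test_that("deduplication collapses UMI and positional duplicates and is idempotent", {
  sc <- tiny_scheme()
  b <- valid_bc(sc, 1, 1, 1)
  cl <- make_clusters(
    oligos = data.table(barcode = b, antibody_tag = c("A", "A", "A", "B"),
                        umi = c("u1", "u1", "u2", "u1")),
    rnas = data.table(barcode = b, reference = "chrS",
                      start = c(100L, 100L, 100L), end = c(250L, 250L, 250L),
                      strand = c("+", "+", "-")))
  d <- dedup_oligos(cl)
  expect_equal(nrow(d$oligos), 3L)                       # (A,u1),(A,u2),(B,u1)
  expect_equal(nrow(d$oligos[antibody_tag == "A"]), 2L)
  # UMI scoped per antibody: (B,u1) survives alongside (A,u1)
  expect_equal(nrow(d$oligos[antibody_tag == "B"]), 1L)
  d <- dedup_rnas(d)
  expect_equal(nrow(d$rnas), 2L)                          # strand kept in key
  # idempotence and commutativity
  expect_identical(dedup_oligos(d)$oligos, d$oligos)
  expect_identical(dedup_rnas(d)$rnas, d$rnas)
  ab <- dedup_rnas(dedup_oligos(cl)); ba <- dedup_oligos(dedup_rnas(cl))
  expect_identical(ab$oligos, ba$oligos)
  expect_identical(ab$rnas, ba$rnas)
})

test_that("dedup is idempotent on simulated clusters", {
  sim <- simulate_experiment(sim_config(n_beads = 200L,
                                        pcr_duplication_rate = 0.3, seed = 41L))
  pr <- process_sim(sim)
  cl <- pr$clusters
  expect_identical(dedup_oligos(cl)$oligos, cl$oligos)
  expect_identical(dedup_rnas(cl)$rnas, cl$rnas)
})

test_that("cluster counts match beads whose barcode survived ligation", {
  cfg <- sim_config(n_beads = 500L, ligation_failure_rate = 0.15,
                    crosstalk_rate = 0, pcr_duplication_rate = 0, seed = 43L)
  sim <- simulate_experiment(cfg)
  pr <- process_sim(sim)
  surv <- sim$truth$beads[survived_ligation == TRUE]
  # every cluster barcode is a surviving bead's truth barcode
  bcs <- union(unique(pr$clusters$oligos$barcode),
               unique(pr$clusters$rnas$barcode))
  expect_true(all(bcs %in% surv$barcode))
  # and essentially every surviving bead with reads yields a cluster
  expect_gt(length(bcs) / nrow(surv), 0.98)
})

test_that("record counts are conserved through clustering and splitting", {
  sim <- simulate_experiment(sim_config(n_beads = 400L, seed = 47L))
  tagged_oligo <- identify_barcodes(sim$oligo_reads, sim$scheme,
                                    sim$antibody_oligos)
  rna <- attach_barcodes(sim$alignments, identify_barcodes(sim$cdna_reads,
                                                           sim$scheme))
  cl <- build_clusters(tagged_oligo, rna)
  expect_equal(nrow(cl$rnas) + cl$unclustered$rna_unbarcoded +
                 cl$unclustered$rna_multimapping, nrow(sim$alignments))
  cl <- dedup_rnas(dedup_oligos(filter_barcode_strings(cl, sim$scheme)))
  asn <- assign_clusters(cl, scheme = sim$scheme)
  sp <- split_by_protein(cl, asn)
  expect_equal(nrow(sp$assigned) + nrow(sp$ambiguous), nrow(cl$rnas))
})

test_that("cluster files round-trip losslessly", {
  sc <- tiny_scheme()
  b1 <- valid_bc(sc, 1, 2, 3); b2 <- valid_bc(sc, 4, 3, 2)
  cl <- make_clusters(
    oligos = data.table(barcode = c(b1, b1, b2),
                        antibody_tag = c("ABX", "ABY", "ABX"),
                        umi = c("AACC", "GGTT", "CCAA")),
    rnas = data.table(barcode = c(b1, b2), reference = c("chrS", "chr2"),
                      start = c(100L, 900L), end = c(150L, 950L),
                      strand = c("+", "-")))
  path <- temp_path("clusters.txt")
  write_clusters(cl, path)
  rt <- read_clusters(path)
  setorder(cl$oligos, barcode, antibody_tag, umi)
  setorder(cl$rnas, barcode, reference, start, end, strand)
  expect_identical(rt$oligos, cl$oligos)
  expect_identical(rt$rnas, cl$rnas)
  # write -> read -> write is bit-exact
  path2 <- temp_path("clusters2.txt")
  write_clusters(rt, path2)
  expect_identical(readLines(path), readLines(path2))
})
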