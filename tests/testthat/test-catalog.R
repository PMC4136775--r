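two_plus_genes <- function() {
  left <- gene_model("GL", transcripts = list(
    make_tx("GL.T1", "GL", c(1000, 3000), c(2000, 5000))))
  right <- gene_model("GR", transcripts = list(
    make_tx("GR.T1", "GR", c(10000, 14000), c(11000, 15000))))
  other_chrom <- gene_model("GC", transcripts = list(
    make_tx("GC.T1", "GC", 500, 900, chrom = "chr2")))
  minus <- gene_model("GM", transcripts = list(
    make_tx("GM.T1", "GM", c(9000, 7000), c(9500, 7500), strand = "-")))
  as_ann(list(left, right, other_chrom, minus))
}

test_that("orientation classes follow chromosome, strand and gene order", {
  ann <- two_plus_genes()
  expect_equal(classify_orientation(list(gene5 = "GL", gene3 = "GR"), ann),
               "TANDEM_SAME_STRAND")
  expect_equal(classify_orientation(list(gene5 = "GR", gene3 = "GL"), ann),
               "SAME_STRAND_INVERTED")
  expect_equal(classify_orientation(list(gene5 = "GL", gene3 = "GC"), ann),
               "INTERCHROM")
  expect_equal(classify_orientation(list(gene5 = "GL", gene3 = "GM"), ann),
               "INTRACHROM_DIFF_STRAND")
  expect_error(classify_orientation(list(gene5 = "GL", gene3 = "NOPE"), ann),
               "NOPE")
})

test_that("minus-strand order: upstream means larger coordinates", {
  m1 <- gene_model("M1", transcripts = list(
    make_tx("M1.T1", "M1", 8000, 9000, strand = "-")))
  m2 <- gene_model("M2", transcripts = list(
    make_tx("M2.T1", "M2", 1000, 2000, strand = "-")))
  ann <- as_ann(list(m1, m2))
  expect_equal(classify_orientation(list(gene5 = "M1", gene3 = "M2"), ann),
               "TANDEM_SAME_STRAND")
  expect_equal(classify_orientation(list(gene5 = "M2", gene3 = "M1"), ann),
               "SAME_STRAND_INVERTED")
})

test_that("support filter keeps strictly more than the threshold", {
  calls <- make_calls(fusion_id = sprintf("F%d", 1:4),
                      split_reads = c(1L, 2L, 3L, 10L))
  expect_equal(apply_support_filter(calls)$split_reads, c(3L, 10L))
  expect_equal(nrow(apply_support_filter(calls, 0L)), 4L)
  expect_equal(nrow(apply_support_filter(calls[0], 2L)), 0L)
})

test_that("repeat filter is a half-open point test on both breakpoints", {
  reps <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  calls <- make_calls(
    fusion_id = c("in1", "out", "edge"),
    chrom5 = "chr1", chrom3 = "chr1",
    bp1 = c(150L, 50L, 250L), bp2 = c(300L, 300L, 200L))
  kept <- apply_repeat_filter(calls, reps)
  expect_setequal(kept$fusion_id, c("out", "edge"))  # end coord is exclusive
  # brute-force cross-check on random points
  set.seed(31)
  reps2 <- data.frame(chrom = "chr1",
                      start = sort(sample(0:900, 5)) * 10L)
  reps2$end <- reps2$start + 50L
  pts <- sample(0:9999, 300)
  got <- tandemchimera:::point_in_intervals(rep("chr1", 300), pts, reps2)
  want <- vapply(pts, function(p) {
    any(reps2$start <= p & p < reps2$end)
  }, logical(1))
  expect_equal(got, want)
})

test_that("boundary status distinguishes exact, near, internal, intronic", {
  tx <- make_tx("T", "G", c(0, 1000), c(200, 1200))
  expect_equal(as.character(boundary_status(199, tx, "5prime")),
               "AT_BOUNDARY")
  near <- boundary_status(197, tx, "5prime")
  expect_equal(as.character(near), "NEAR_BOUNDARY")
  expect_equal(attr(near, "distance"), 2L)
  expect_equal(as.character(boundary_status(100, tx, "5prime")),
               "INTRA_EXON")
  expect_equal(as.character(boundary_status(600, tx, "5prime")), "INTRONIC")
  expect_equal(as.character(boundary_status(1000, tx, "3prime")),
               "AT_BOUNDARY")
  # the retained-side edge differs per side: exon start is not a 5' edge
  expect_false(as.character(boundary_status(1000, tx, "5prime")) ==
                 "AT_BOUNDARY")
  expect_error(boundary_status(5000, tx, "5prime"), "outside")
  # minus strand: the 5' retained edge is the genomic start
  txm <- make_tx("TM", "G", c(1000, 0), c(1200, 200), strand = "-")
  expect_equal(as.character(boundary_status(1000, txm, "5prime")),
               "AT_BOUNDARY")
  expect_equal(as.character(boundary_status(199, txm, "3prime")),
               "AT_BOUNDARY")
})

test_that("breakpoint distance is |bp2 - bp1| and needs one chromosome", {
  expect_equal(breakpoint_distance(list(bp1 = 84900000, bp2 = 84925000,
                                        chrom5 = "c", chrom3 = "c")), 25000)
  expect_equal(breakpoint_distance(list(bp1 = 10, bp2 = 10,
                                        chrom5 = "c", chrom3 = "c")), 0)
  expect_equal(breakpoint_distance(list(bp1 = 500, bp2 = 100,
                                        chrom5 = "c", chrom3 = "c")),
               breakpoint_distance(list(bp1 = 100, bp2 = 500,
                                        chrom5 = "c", chrom3 = "c")))
  expect_error(breakpoint_distance(list(bp1 = 1, bp2 = 2, chrom5 = "c1",
                                        chrom3 = "c2")), "interchromosomal")
})

test_that("population frequencies partition fusions into venn regions", {
  cohort <- tiny_cohort()
  calls <- make_calls(
    fusion_id = c("F1", "F2", "F3"),
    carriers = list(list("CEU_01"), list(c("CEU_01", "FIN_02", "GBR_03")),
                    list(character(0))))
  pf <- population_frequencies(calls, cohort)
  f1 <- pf$frequencies[fusion_id == "F1"]
  expect_equal(f1$CEU, 1L)
  expect_equal(f1$FIN + f1$GBR, 0L)
  expect_equal(f1$combined_frequency, 1 / 12)
  expect_setequal(pf$venn$populations, c("CEU", "CEU+FIN+GBR"))
  # regions partition the carried fusions
  expect_equal(sum(pf$venn$n_fusions), 2L)
  bad <- make_calls(fusion_id = "FX", carriers = list(list("ZZZ_01")))
  expect_error(population_frequencies(bad, cohort), "ZZZ_01")
})

test_that("expression presence filter needs positivity in every population", {
  cohort <- tiny_cohort(n_per = 2)
  rpkm <- matrix(1, nrow = 2, ncol = 6,
                 dimnames = list(c("GA", "GB"), cohort$sample_id))
  calls <- make_calls(fusion_id = "F1", gene5 = "GA", gene3 = "GB")
  expect_equal(nrow(expression_presence_filter(calls, rpkm, cohort)), 1L)
  rpkm2 <- rpkm
  rpkm2["GA", cohort$population == "GBR"] <- 0
  expect_equal(nrow(expression_presence_filter(calls, rpkm2, cohort)), 0L)
  # borderline: exactly one positive sample per population is enough
  rpkm3 <- matrix(0, nrow = 2, ncol = 6,
                  dimnames = dimnames(rpkm))
  rpkm3[, c(1, 3, 5)] <- 1
  expect_equal(nrow(expression_presence_filter(calls, rpkm3, cohort)), 1L)
  expect_error(expression_presence_filter(
    make_calls(fusion_id = "F", gene5 = "GA", gene3 = "GZ"), rpkm, cohort),
    "GZ")
})

test_that("novelty is order-sensitive against the known list", {
  calls <- make_calls(fusion_id = c("F1", "F2"),
                      gene5 = c("A", "B"), gene3 = c("B", "A"))
  known <- data.frame(gene5 = "A", gene3 = "B")
  out <- annotate_novelty(calls, known)
  expect_equal(out$novel, c(FALSE, TRUE))
  all_novel <- annotate_novelty(calls, known[0, ])
  expect_true(all(all_novel$novel))
})

test_that("support and repeat filters commute", {
  set.seed(32)
  reps <- data.frame(chrom = "chr1", start = c(100L, 500L),
                     end = c(200L, 550L))
  calls <- make_calls(fusion_id = sprintf("F%02d", 1:40),
                      chrom5 = "chr1", chrom3 = "chr1",
                      bp1 = sample(0:600, 40), bp2 = sample(0:600, 40),
                      split_reads = sample(1:6, 40, replace = TRUE))
  a <- apply_repeat_filter(apply_support_filter(calls), reps)
  b <- apply_support_filter(apply_repeat_filter(calls, reps))
  expect_equal(a$fusion_id, b$fusion_id)
})
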