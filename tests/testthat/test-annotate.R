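single_pair <- function() {
  g5 <- gene_model("QA", transcripts = list(
    make_tx("QA.T1", "QA", c(0, 1000, 2000), c(100, 1100, 2100))))
  g3 <- gene_model("QB", transcripts = list(
    make_tx("QB.T1", "QB", c(10000, 11000, 12000), c(10100, 11100, 12100))))
  list(g5 = g5, g3 = g3)
}

test_that("fused transcripts join retained exon sets at exact boundaries", {
  p <- single_pair()
  txs <- build_chimeric_transcripts(
    list(fusion_id = "F1", bp1 = 1099, bp2 = 11000), p$g5, p$g3)
  expect_length(txs, 1L)
  fused <- txs[[1]]
  expect_equal(fused$gene_id, fused_gene_id("QA", "QB"))
  expect_equal(fused$exons,
               data.frame(start = c(0, 1000, 11000, 12000),
                          end = c(100, 1100, 11100, 12100)))
  expect_false(attr(fused, "truncated"))
})

test_that("an intra-exon breakpoint truncates the exon exactly", {
  p <- single_pair()
  txs <- build_chimeric_transcripts(
    list(fusion_id = "F1", bp1 = 1050, bp2 = 11030), p$g5, p$g3,
    snap_near_boundary = FALSE)
  fused <- txs[[1]]
  # half-open: the last retained base bp1 = 1050 means end = 1051
  expect_equal(fused$exons$end[2], 1051)
  expect_equal(fused$exons$start[3], 11030)
  expect_true(attr(fused, "truncated"))
})

test_that("near-boundary breakpoints snap to the annotated edge by default", {
  p <- single_pair()
  txs <- build_chimeric_transcripts(
    list(fusion_id = "F1", bp1 = 1097, bp2 = 11002), p$g5, p$g3)
  expect_equal(txs[[1]]$exons$end[2], 1100)
  expect_equal(txs[[1]]$exons$start[3], 11000)
  expect_false(attr(txs[[1]], "truncated"))
})

test_that("isoform combinations multiply and share one fused gene id", {
  g5 <- gene_model("QA", transcripts = list(
    make_tx("QA.T1", "QA", c(0, 1000), c(100, 1100)),
    make_tx("QA.T2", "QA", c(0, 500, 1000), c(100, 600, 1100))))
  g3 <- gene_model("QB", transcripts = list(
    make_tx("QB.T1", "QB", c(10000, 11000), c(10100, 11100)),
    make_tx("QB.T2", "QB", c(10000, 12000), c(10100, 12100)),
    make_tx("QB.T3", "QB", c(10500, 11000), c(10600, 11100))))
  txs <- build_chimeric_transcripts(
    list(fusion_id = "F1", bp1 = 1099, bp2 = 10000), g5, g3)
  expect_length(txs, 6L)
  expect_length(unique(vapply(txs, function(t) t$gene_id, "")), 1L)
})

test_that("minus-strand fusions mirror the retained-region logic", {
  g5 <- gene_model("MA", transcripts = list(
    make_tx("MA.T1", "MA", c(20000, 10000), c(20100, 10100), strand = "-")))
  g3 <- gene_model("MB", transcripts = list(
    make_tx("MB.T1", "MB", c(2000, 1000), c(2100, 1100), strand = "-")))
  # bp1 = genomic start of MA's second (transcription) exon; bp2 = last
  # genomic base retained of MB's first (transcription) exon
  txs <- build_chimeric_transcripts(
    list(fusion_id = "F1", bp1 = 10000, bp2 = 2000), g5, g3)
  fused <- txs[[1]]
  expect_equal(fused$exons$start, c(20000, 10000, 2000, 1000))
  # fused exon chain is strictly decreasing in genomic start (minus strand)
  expect_true(all(diff(fused$exons$start) < 0))
})

test_that("total fused exon length equals retained 5' plus retained 3'", {
  set.seed(51)
  p <- single_pair()
  for (i in 1:20) {
    bp1 <- sample(c(99, 1050, 1099, 2000), 1)
    bp2 <- sample(c(10000, 11030, 12000), 1)
    txs <- build_chimeric_transcripts(
      list(fusion_id = "F", bp1 = bp1, bp2 = bp2), p$g5, p$g3,
      snap_near_boundary = FALSE)
    fused <- txs[[1]]
    ex5 <- p$g5$transcripts[[1]]$exons
    ex3 <- p$g3$transcripts[[1]]$exons
    len5 <- sum(pmax(0, pmin(ex5$end, bp1 + 1) - ex5$start))
    len3 <- sum(pmax(0, ex3$end - pmax(ex3$start, bp2)))
    expect_equal(sum(fused$exons$end - fused$exons$start), len5 + len3)
    expect_true(all(diff(fused$exons$start) > 0))
  }
})

test_that("the custom annotation round-trips through GTF", {
  p <- single_pair()
  ann <- as_ann(list(p$g5, p$g3))
  catalog <- make_calls(fusion_id = "F1", gene5 = "QA", gene3 = "QB",
                        chrom5 = "chr1", chrom3 = "chr1",
                        bp1 = 1099L, bp2 = 11000L,
                        orientation = "TANDEM_SAME_STRAND")
  custom <- build_custom_annotation(catalog, ann)
  expect_setequal(names(custom), c("QA", "QB", fused_gene_id("QA", "QB")))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(custom, f)
  back <- parse_gtf(f)
  fid <- fused_gene_id("QA", "QB")
  expect_equal(back[[fid]]$transcripts[[1]]$exons,
               custom[[fid]]$transcripts[[1]]$exons)
})

test_that("gene-level aggregation sums transcripts and conserves totals", {
  expr <- structure(list(
    values = matrix(c(1, 2.5, 4, 0.5, 1.5, 2), nrow = 3,
                    dimnames = list(c("T1", "T2", "T3"), c("S1", "S2"))),
    transcript_id = c("T1", "T2", "T3"),
    gene_id = c("G1", "G1", "G2"), samples = c("S1", "S2")),
    class = "expression_table")
  gm <- aggregate_gene_rpkm(expr)
  expect_equal(gm["G1", "S1"], 3.5)
  expect_equal(gm["G2", "S1"], 4)
  expect_equal(colSums(gm), colSums(expr$values))
  # permutation invariance in transcript order
  perm <- c(3, 1, 2)
  expr2 <- expr
  expr2$values <- expr$values[perm, ]
  expr2$transcript_id <- expr$transcript_id[perm]
  expr2$gene_id <- expr$gene_id[perm]
  expect_equal(aggregate_gene_rpkm(expr2), gm)
  expr$gene_id[2] <- ""
  expect_error(aggregate_gene_rpkm(expr), "gene id")
})

test_that("expression comparison is restricted to carrier samples", {
  samples <- c("S1", "S2", "S3", "S4")
  gid <- fused_gene_id("QA", "QB")
  rpkm <- matrix(c(
    1, 1, 99, 99,     # chimera: carriers S1,S2 low; others high (masked)
    5, 5, 5, 5,
    6, 6, 6, 6), nrow = 3, byrow = TRUE,
    dimnames = list(c(gid, "QA", "QB"), samples))
  catalog <- make_calls(fusion_id = "F1", gene5 = "QA", gene3 = "QB",
                        carriers = list(list(c("S1", "S2"))))
  cmp <- compare_chimera_expression(rpkm, catalog)
  expect_equal(unname(sort(cmp$chimera_values)), c(1, 1))  # S3/S4 excluded
  expect_equal(length(cmp$partner_values), 4L)
  expect_equal(cmp$median_chimera, 1)
  expect_equal(cmp$median_partner, 5.5)
  # identical pools give D = 0
  rpkm2 <- rpkm
  rpkm2[] <- 5
  catalog2 <- make_calls(fusion_id = "F1", gene5 = "QA", gene3 = "QB",
                         carriers = list(list(samples)))
  cmp2 <- compare_chimera_expression(rpkm2, catalog2)
  expect_equal(cmp2$ks$D, 0)
  # zero carriers: fusion skipped, error only if nothing remains
  none <- make_calls(fusion_id = "F1", gene5 = "QA", gene3 = "QB",
                     carriers = list(list(character(0))))
  expect_error(compare_chimera_expression(rpkm, none), "no carrier")
})
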