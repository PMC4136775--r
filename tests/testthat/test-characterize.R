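# parametric single-isoform pair: fixed exon scaffolds, configurable CDS
scaffold_pair <- function(cds5s, cds5e, cds3s, cds3e) {
  g5 <- gene_model("P5", transcripts = list(
    make_tx("P5.T1", "P5", c(0, 1000, 2000, 3000), c(100, 1100, 2100, 3100),
            cds5s, cds5e)))
  g3 <- gene_model("P3", transcripts = list(
    make_tx("P3.T1", "P3", c(10000, 11000, 12000), c(10100, 11100, 12100),
            cds3s, cds3e)))
  list(g5 = g5, g3 = g3)
}

test_that("structural classes follow the retained-CDS rules", {
  # promoter swap: no 5' CDS retained, full 3' CDS under the 5' promoter
  p <- scaffold_pair(2000, 2090, 11020, 11080)
  r <- classify_structure(list(bp1 = 99, bp2 = 10000), p$g5, p$g3)
  expect_equal(r$class, "PROMOTER_SWAP")
  # 3' UTR swap: full 5' CDS kept, 3' CDS entirely excluded
  p <- scaffold_pair(20, 80, 10020, 10080)
  r <- classify_structure(list(bp1 = 99, bp2 = 11000), p$g5, p$g3)
  expect_equal(r$class, "UTR3_SWAP")
  # genuine read-through: both CDSs complete
  p <- scaffold_pair(20, 80, 11020, 11080)
  r <- classify_structure(list(bp1 = 99, bp2 = 11000), p$g5, p$g3)
  expect_equal(r$class, "GENUINE_READ_THROUGH")
  # frame classes: both CDSs truncated at the junction
  p <- scaffold_pair(c(1050, 2000), c(1100, 2040),
                     c(10050, 11000), c(10100, 11040))
  r <- classify_structure(list(bp1 = 1099, bp2 = 11000), p$g5, p$g3)
  expect_equal(r$class, "IN_FRAME")      # L5 = 50, S3 = 50
  expect_equal(r$L5, 50)
  expect_equal(r$S3, 50)
  p <- scaffold_pair(c(1050, 2000), c(1100, 2040),
                     c(10049, 11000), c(10100, 11040))
  r <- classify_structure(list(bp1 = 1099, bp2 = 11000), p$g5, p$g3)
  expect_equal(r$class, "OUT_OF_FRAME")  # L5 = 50 (2), S3 = 51 (0)
  # two non-coding partners cannot take any of the five classes
  g5 <- gene_model("N5", transcripts = list(
    make_tx("N5.T1", "N5", c(0, 1000), c(100, 1100))))
  g3 <- gene_model("N3", transcripts = list(
    make_tx("N3.T1", "N3", c(10000, 11000), c(10100, 11100))))
  r <- classify_structure(list(bp1 = 99, bp2 = 11000), g5, g3)
  expect_equal(r$class, "UNCLASSIFIABLE")
})

test_that("classification errors when no transcript pair is compatible", {
  p <- scaffold_pair(20, 80, 11020, 11080)
  expect_error(classify_structure(list(bp1 = 600, bp2 = 11000), p$g5, p$g3),
               "no transcript pair")
})

test_that("junction frame: identity junction and non-coding partner", {
  tx5 <- make_tx("A", "GA", c(0, 1000), c(100, 2100), 2000, 2050)
  tx3 <- make_tx("B", "GB", c(10000, 11000), c(10100, 11100), 11000, 11050)
  r <- junction_frame(tx5, tx3, bp1 = 1999, bp2 = 11000)
  expect_equal(r$L5, 0)
  expect_equal(r$S3, 0)
  expect_equal(r$frame, "IN_FRAME")
  nc <- make_tx("C", "GC", 0, 100)
  expect_error(junction_frame(nc, tx3, 50, 11000), "coding")
})

test_that("junction frame agrees with per-base codon-phase enumeration", {
  set.seed(41)
  for (i in 1:1000) {
    tx5 <- random_coding_tx("T5", "G5")
    tx3 <- random_coding_tx("T3", "G3")
    ex5 <- tx5$exons; ex3 <- tx3$exons
    bp1 <- sample(unlist(Map(seq, ex5$start, ex5$end - 1L)), 1)
    bp2 <- sample(unlist(Map(seq, ex3$start, ex3$end - 1L)), 1)
    got <- junction_frame(tx5, tx3, bp1, bp2)
    # oracle: list every CDS base in transcription order and count
    p5 <- cds_positions(tx5); p3 <- cds_positions(tx3)
    L5o <- if (tx5$strand == "+") sum(p5 <= bp1) else sum(p5 >= bp1)
    S3o <- if (tx3$strand == "+") sum(p3 < bp2) else sum(p3 > bp2)
    expect_equal(got$L5, L5o)
    expect_equal(got$S3, S3o)
    expect_equal(got$frame,
                 if (L5o %% 3 == S3o %% 3) "IN_FRAME" else "OUT_OF_FRAME")
  }
})

test_that("exclusion patterns count wholly excluded exons per pair", {
  p <- scaffold_pair(20, 80, 11020, 11080)
  # bp1 at the end of the penultimate exon, bp2 at the start of exon 2
  pats <- exon_exclusion_patterns(list(bp1 = 2099, bp2 = 11000), p$g5, p$g3)
  expect_equal(nrow(pats), 1L)
  expect_equal(pats$k5, 1)
  expect_equal(pats$k3, 1)
  expect_equal(pats$weight, 1)
  # nothing excluded when the junction joins the outermost boundaries
  pats0 <- exon_exclusion_patterns(list(bp1 = 3099, bp2 = 10000),
                                   p$g5, p$g3)
  expect_equal(unlist(pats0[, .(k5, k3)]), c(k5 = 0, k3 = 0),
               ignore_attr = TRUE)
})

test_that("multi-isoform pattern weights match hand enumeration", {
  g5 <- gene_model("M5", transcripts = list(
    make_tx("M5.T1", "M5", c(0, 1000, 2000), c(100, 1100, 2100)),
    make_tx("M5.T2", "M5", c(0, 2000), c(100, 2100))))
  g3 <- gene_model("M3", transcripts = list(
    make_tx("M3.T1", "M3", c(10000, 11000, 12000), c(10100, 11100, 12100)),
    make_tx("M3.T2", "M3", c(10000, 12000), c(10100, 12100)),
    make_tx("M3.T3", "M3", c(11000, 12000), c(11100, 12100))))
  call <- list(bp1 = 1099, bp2 = 12000)
  # hand enumeration over the 6 pairs: k5 is 1 (T1) or 0 (T2, exon at
  # 2000 starts after bp1? no: 2000 > 1099 so it is excluded -> k5 = 1);
  # k3: T1 -> 2, T2 -> 1, T3 -> 1
  pats <- exon_exclusion_patterns(call, g5, g3)
  expect_equal(sum(pats$weight), 1, tolerance = 1e-12)
  expect_equal(pats[k3 == 2]$weight, 2 / 6)
  expect_equal(pats[k3 == 1]$weight, 4 / 6)
  expect_true(all(pats$k5 == 1))
})

test_that("flanking lengths pick the intron next to the fusion exon", {
  g5 <- gene_model("F5", transcripts = list(
    make_tx("F5.T1", "F5", c(0, 200, 5000), c(100, 300, 5100))))
  g3 <- gene_model("F3", transcripts = list(
    make_tx("F3.T1", "F3", c(20000, 30000), c(20100, 30100))))
  fl <- flanking_feature_lengths(list(bp1 = 299, bp2 = 30000), g5, g3)
  expect_equal(fl$intron5, 4700)
  expect_equal(fl$intron3, 9900)
  expect_equal(fl$intron_background, 100)  # single-intron g3: none left
  expect_equal(fl$exon5, 100)
  # conservation: exons + introns tile the transcript span
  tx <- g5$transcripts[[1]]
  expect_equal(sum(tx$exons$end - tx$exons$start) +
                 sum(transcript_introns(tx)$end -
                       transcript_introns(tx)$start),
               max(tx$exons$end) - min(tx$exons$start))
})

test_that("terminal fusion exons without a flanking intron are skipped", {
  g5 <- gene_model("F5", transcripts = list(
    make_tx("F5.T1", "F5", c(0, 200), c(100, 300))))
  g3 <- gene_model("F3", transcripts = list(
    make_tx("F3.T1", "F3", c(20000, 30000), c(20100, 30100))))
  # bp1 inside the LAST exon of g5: no downstream intron
  fl <- flanking_feature_lengths(list(bp1 = 299, bp2 = 30000), g5, g3)
  expect_equal(length(fl$intron5), 0L)
  expect_equal(fl$n_skipped, 1L)
})

test_that("length comparison reports KS plus medians", {
  x <- c(1, 2, 3, 4)
  r <- compare_length_distributions(x, x)
  expect_equal(r$ks$D, 0)
  expect_equal(r$median_foreground, r$median_background)
  d <- compare_length_distributions(5, 5)
  expect_equal(d$ks$D, 0)
  d2 <- compare_length_distributions(5, 9)
  expect_equal(d2$ks$D, 1)
})
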