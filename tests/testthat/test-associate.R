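test_that("testable fusions need pooled frequency strictly above 5%", {
  freq <- data.table::data.table(
    fusion_id = c("F24", "F23", "F1"),
    combined_frequency = c(24 / 462, 23 / 462, 1 / 462))
  expect_equal(select_testable_fusions(freq), "F24")   # 5.19% in, 4.98% out
  expect_setequal(select_testable_fusions(freq, 0),
                  c("F24", "F23", "F1"))
})

test_that("variant extraction spans both genes plus the flank", {
  ann <- tiny_pair()   # GA span 0-3100, GB span 10000-12100
  gt <- make_gt(matrix(0L, nrow = 5, ncol = 2),
                pos = c(2951L, 2900L, 3302L, 5000L, 9801L))
  # 0-based positions: 2950 (inside GA), 2899, 3301 (201 past GA end),
  # 4999 (between genes), 9800 (exactly 200 before GB start)
  idx <- variants_in_fusion_interval(list(gene5 = "GA", gene3 = "GB"),
                                     ann, gt, flank = 200L)
  expect_setequal(idx, c(1L, 2L, 5L))
  # brute-force cross-check on random positions
  set.seed(61)
  pos <- sample(1:14000, 300)
  gt2 <- make_gt(matrix(0L, nrow = 300, ncol = 2), pos = pos)
  idx2 <- variants_in_fusion_interval(list(gene5 = "GA", gene3 = "GB"),
                                      ann, gt2, flank = 200L)
  want <- which(vapply(pos - 1L, function(p) {
    (p >= -200 && p < 3300) || (p >= 9800 && p < 12300)
  }, logical(1)))
  expect_setequal(idx2, want)
})

scan_fixture <- function(n = 60, n_var = 8, seed = 62, maf = 0.4,
                         frac_cases = 0.3) {
  set.seed(seed)
  dos <- matrix(stats::rbinom(n * n_var, 2, maf), nrow = n_var)
  gt <- make_gt(dos)
  cohort <- data.frame(sample_id = gt$samples,
                       population = "POP", stringsAsFactors = FALSE)
  carriers <- sample(cohort$sample_id, round(frac_cases * n))
  call <- list(fusion_id = "F1", carriers = list(carriers))
  list(gt = gt, cohort = cohort, call = call)
}

test_that("scan applies MAF filter, per-fusion Bonferroni and carrier OR", {
  fx <- scan_fixture()
  res <- fusion_case_control_scan(fx$call, fx$gt, cohort = fx$cohort)
  m <- nrow(res)
  expect_true(all(res$tested_m == m))
  expect_equal(res$adjusted_p, pmin(1, m * res$raw_p))
  expect_true(all(res$maf > 0.05))
  expect_true(all(res$n_cases + res$n_controls <= 60))
  # dosage identical in cases and controls -> p = 1, not significant
  dos <- matrix(rep(c(0L, 1L, 2L), each = 20), nrow = 1)
  gt1 <- make_gt(dos)
  call1 <- list(fusion_id = "F", carriers = list(gt1$samples[c(1, 21, 41)]))
  cohort1 <- data.frame(sample_id = gt1$samples, population = "P")
  r1 <- fusion_case_control_scan(call1, gt1, cohort = cohort1, maf_min = 0.0)
  expect_equal(r1$raw_p, 1)
  expect_false(r1$significant)
})

test_that("scan output is invariant to variant input order", {
  fx <- scan_fixture(seed = 63)
  res <- fusion_case_control_scan(fx$call, fx$gt, cohort = fx$cohort)
  perm <- sample(nrow(fx$gt$variants))
  gt_perm <- make_gt(fx$gt$dosages[perm, ],
                     pos = fx$gt$variants$pos[perm],
                     ids = fx$gt$variants$variant_id[perm])
  res2 <- fusion_case_control_scan(fx$call, gt_perm, cohort = fx$cohort)
  data.table::setorder(res, variant_id)
  data.table::setorder(res2, variant_id)
  expect_equal(res$raw_p, res2$raw_p)
  expect_equal(res$or_value, res2$or_value)
})

test_that("the allelic odds-ratio mode counts chromosomes", {
  # cases: dosages 2,1,0 (3 alt of 6); controls: 1,0,0,0 (1 alt of 8)
  dos <- matrix(c(2L, 1L, 0L, 1L, 0L, 0L, 0L), nrow = 1)
  gt <- make_gt(dos)
  cohort <- data.frame(sample_id = gt$samples, population = "P")
  call <- list(fusion_id = "F", carriers = list(gt$samples[1:3]))
  res <- fusion_case_control_scan(call, gt, cohort = cohort, maf_min = 0,
                                  or_mode = "allelic")
  expect_equal(res$or_value, (3 * 7) / (3 * 1))
  carrier <- fusion_case_control_scan(call, gt, cohort = cohort,
                                      maf_min = 0)
  expect_equal(carrier$or_value, (2 * 3) / (1 * 1))
})

test_that("the first-excluded breakpoint dialect converts per strand", {
  ann <- tiny_pair()   # plus strand
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(unname(fusion_column_map()), collapse = "\t")
  writeLines(c(hdr, "F1\tGA\tGB\tchr1\tchr1\t3100\t9999\t5\tS1"), f)
  calls <- parse_fusion_table(f, annotation = ann,
                              convention = "first-excluded")
  expect_equal(calls$bp1, 3099L)   # back onto the last retained base
  expect_equal(calls$bp2, 10000L)  # forward onto the first retained base
  expect_error(parse_fusion_table(f, convention = "first-excluded"),
               "annotation")
})

test_that("the repeat filter window widens the overlap test", {
  reps <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  calls <- make_calls(fusion_id = c("near", "far"), chrom5 = "chr1",
                      chrom3 = "chr1", bp1 = c(205L, 300L),
                      bp2 = c(500L, 500L))
  expect_equal(nrow(apply_repeat_filter(calls, reps)), 2L)
  expect_equal(apply_repeat_filter(calls, reps, window = 10L)$fusion_id,
               "far")
})

test_that("scan excludes indels by default and honors the flag", {
  dos <- matrix(stats::rbinom(40 * 2, 2, 0.4), nrow = 2)
  gt <- make_gt(dos, ref = c("A", "ACT"), alt = c("G", "A"))
  cohort <- data.frame(sample_id = gt$samples, population = "P")
  call <- list(fusion_id = "F", carriers = list(gt$samples[1:10]))
  res <- fusion_case_control_scan(call, gt, cohort = cohort)
  expect_equal(res$variant_id, "v001")
  res2 <- fusion_case_control_scan(call, gt, cohort = cohort,
                                   include_indels = TRUE)
  expect_equal(nrow(res2), 2L)
})

test_that("top variant takes the lowest p with positional tie-breaks", {
  res <- data.table::data.table(
    fusion_id = c("F1", "F1", "F1", "F2"),
    variant_id = c("b", "a", "c", "z"),
    pos = c(500L, 100L, 100L, 9L),
    raw_p = c(0.01, 0.01, 0.01, 0.5))
  top <- top_variant_per_fusion(res)
  expect_equal(top[fusion_id == "F1"]$variant_id, "a")  # pos, then id
  expect_equal(top[fusion_id == "F2"]$variant_id, "z")
  expect_true(all(top$raw_p <= 0.5))
})

test_that("feature overlap is half-open and collects nested labels", {
  feats <- data.frame(chrom = "chr1", start = c(100L, 120L, 300L),
                      end = c(200L, 160L, 400L),
                      name = c("outer", "inner", "far"))
  vars <- data.table::data.table(chrom = "chr1",
                                 pos = c(131L, 201L, 150L, 301L))
  # 0-based positions 130 (both), 200 (end-exclusive: none), 149, 300
  out <- overlap_variants_with_features(vars, feats)
  expect_equal(out$features,
               c("outer,inner", "", "outer,inner", "far"))
})

test_that("poly(A) screen keeps variants at least as frequent as the fusion", {
  feats <- data.frame(chrom = "chr1", start = c(1000L, 2000L),
                      end = c(1010L, 2010L),
                      name = c("polyA_signal", "polyA_site"),
                      gene_id = c("GA", "GA"))
  dos <- rbind(rep(c(0L, 1L), 10),          # MAF 0.25
               rep(c(0L, 0L, 0L, 1L), 5),   # MAF 0.125
               rep(c(0L, 1L), 10))
  gt <- make_gt(dos, pos = c(1005L, 1006L, 2005L),
                ref = c("A", "C", "GT"), alt = c("G", "T", "G"))
  catalog <- make_calls(fusion_id = "F1", gene5 = "GA", gene3 = "GB",
                        combined_frequency = 0.2)
  out <- polyA_variant_screen(catalog, gt, feats)
  expect_equal(out[variant_id == "v001"]$retained, TRUE)   # 0.25 >= 0.2
  expect_equal(out[variant_id == "v002"]$retained, FALSE)  # 0.125 < 0.2
  expect_true(out[variant_id == "v003"]$is_deletion)
  expect_true(out[variant_id == "v003"]$retained)
  none <- make_calls(fusion_id = "F2", gene5 = "GX", gene3 = "GB",
                     combined_frequency = 0.2)
  out2 <- polyA_variant_screen(none, gt, feats)
  expect_equal(out2$feature, "no feature")
})

test_that("poly(A) read selection trims tails and drops low complexity", {
  reads <- data.frame(
    id = c("tail", "plain", "allA", "head", "lowC"),
    seq = c(paste0("GCGTCGTCGTCGTCGTCGTCGTC", strrep("A", 20)),
            strrep("ACGT", 10),
            strrep("A", 50),
            paste0(strrep("T", 12), "GACGTACGTACGTACGTACGTAC"),
            paste0(strrep("C", 40), strrep("A", 15))),
    stringsAsFactors = FALSE)
  out <- polyA_read_selection(reads, min_tail = 10)
  expect_setequal(out$id, c("tail", "head"))
  expect_equal(out$trimmed_nt[out$id == "tail"], 20L)
  expect_equal(out$tail_type[out$id == "head"], "polyT")
  # never longer than the input; trimming is idempotent
  expect_true(all(nchar(out$seq) <= nchar(reads$seq[match(out$id, reads$id)])))
  again <- polyA_read_selection(out, min_tail = 10)
  expect_equal(nrow(again), 0L)   # no tails remain after trimming
})
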