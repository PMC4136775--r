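# Hand-built fixtures shared across test files.  All coordinates follow
# the internal 0-based half-open convention.

make_tx <- function(id, gene, starts, ends, cds_starts = integer(0),
                    cds_ends = integer(0), chrom = "chr1", strand = "+") {
  transcript_model(id, gene, chrom, strand,
                   data.frame(start = starts, end = ends),
                   data.frame(start = cds_starts, end = cds_ends))
}

make_calls <- function(...) {
  dt <- data.table::data.table(...)
  if (!"carriers" %in% names(dt)) dt[, carriers := list(list(character(0)))]
  data.table::setattr(dt, "class",
                      c("fusion_calls", class(data.table::data.table())))
  dt[]
}

make_gt <- function(dosages, chrom = "chr1", pos = NULL, ids = NULL,
                    ref = NULL, alt = NULL) {
  nv <- nrow(dosages)
  if (is.null(pos)) pos <- seq_len(nv) * 100L
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(nv))
  if (is.null(ref)) ref <- rep("A", nv)
  if (is.null(alt)) alt <- rep("G", nv)
  variants <- data.table::data.table(
    chrom = rep(chrom, nv), pos = pos, variant_id = ids, ref = ref,
    alt = alt, is_deletion = nchar(ref) > nchar(alt))
  rownames(dosages) <- ids
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("S%03d", seq_len(ncol(dosages)))
  }
  structure(list(variants = variants, dosages = dosages,
                 samples = colnames(dosages)), class = "genotype_table")
}

# A plus-strand tandem pair with multiple isoforms and CDS laid out so
# that structural classes are easy to set up by choosing breakpoints.
# GA: exons (0,100) (1000,1100) (2000,2100) (3000,3100); CDS in exons 2-3
#     (1020,1100) (2000,2050); second isoform skips exon 2.
# GB (placed downstream): exons (10000,10100) (11000,11100) (12000,12100);
#     CDS (11020,11100) (12000,12050); second isoform drops the last exon.
tiny_pair <- function() {
  ga <- gene_model("GA", "GENEA", list(
    make_tx("GA.T1", "GA", c(0, 1000, 2000, 3000),
            c(100, 1100, 2100, 3100), c(1020, 2000), c(1100, 2050)),
    make_tx("GA.T2", "GA", c(0, 2000, 3000), c(100, 2100, 3100),
            c(2000), c(2050))))
  gb <- gene_model("GB", "GENEB", list(
    make_tx("GB.T1", "GB", c(10000, 11000, 12000),
            c(10100, 11100, 12100), c(11020, 12000), c(11100, 12050)),
    make_tx("GB.T2", "GB", c(10000, 11000), c(10100, 11100),
            c(11020), c(11100))))
  as_ann(list(ga, gb))
}

as_ann <- function(genes) {
  names(genes) <- vapply(genes, function(g) g$gene_id, "")
  structure(genes, class = "gene_annotation")
}

tiny_cohort <- function(n_per = 4L, pops = c("CEU", "FIN", "GBR")) {
  data.frame(
    sample_id = sprintf("%s_%02d", rep(pops, each = n_per),
                        rep(seq_len(n_per), length(pops))),
    population = rep(pops, each = n_per), stringsAsFactors = FALSE)
}

# random transcript with a contiguous-in-transcript CDS; used by the
# per-base frame oracle
random_coding_tx <- function(id = "T", gene = "G", strand = NULL) {
  if (is.null(strand)) strand <- sample(c("+", "-"), 1)
  n_ex <- sample(2:6, 1)
  lens <- sample(30:120, n_ex, replace = TRUE)
  gaps <- sample(50:500, n_ex, replace = TRUE)
  starts <- cumsum(gaps + c(0, lens[-n_ex]))
  ex <- data.frame(start = starts, end = starts + lens)
  total <- sum(lens)
  a <- sample.int(total - 10L, 1)                 # CDS in transcript coords
  b <- a + sample.int(total - a, 1)
  # map transcript-coordinate interval [a, b) to genomic intervals
  tx_order <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
  cds <- list(); off <- 0L
  for (i in tx_order) {
    l <- ex$end[i] - ex$start[i]
    lo <- max(a, off); hi <- min(b, off + l)
    if (lo < hi) {
      if (strand == "+") {
        cds[[length(cds) + 1L]] <- c(ex$start[i] + (lo - off),
                                     ex$start[i] + (hi - off))
      } else {
        cds[[length(cds) + 1L]] <- c(ex$end[i] - (hi - off),
                                     ex$end[i] - (lo - off))
      }
    }
    off <- off + l
  }
  cds <- do.call(rbind, cds)
  exo <- ex[tx_order, ]
  make_tx(id, gene, exo$start, exo$end, cds[, 1], cds[, 2], strand = strand)
}

# every genomic CDS base of a transcript, in transcription order
cds_positions <- function(tx) {
  unlist(lapply(seq_len(nrow(tx$cds)), function(i) {
    p <- seq(tx$cds$start[i], tx$cds$end[i] - 1L)
    if (tx$strand == "-") rev(p) else p
  }))
}
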