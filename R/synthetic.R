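# Synthetic study generator.  Emits a self-consistent annotation, cohort,
# fusion truth, genotypes, expression and reads with the statistical
# structure the analysis assumes, so every pipeline stage can be tested
# closed-loop against known truth without external data.

#' Specification of a synthetic study cohort
#'
#' Defaults emulate the study design the pipeline targets: 462
#' lymphoblastoid samples from five populations, a rare-skewed chimera
#' frequency spectrum with a testable (>5%) minority, breakpoint-flanking
#' introns drawn longer than background introns, chimera expression below
#' partner-gene expression, and intronic causal variants acting on chimera
#' presence with a set carrier odds ratio.
#'
#' @param seed Integer seed fixing all randomness.
#' @param populations Named sample counts per population.
#' @param n_tandem Tandem same-strand fusions passing all filters.
#' @param n_low_support Decoy fusions with <= 2 split reads.
#' @param n_repeat_decoy Decoy fusions whose bp1 falls in a repeat.
#' @param n_inverted Same-strand calls running against gene order.
#' @param n_diff_strand,n_interchrom Other orientation classes.
#' @param n_background_genes Genes not involved in any fusion.
#' @param n_testable Tandem fusions given a pooled frequency above 5% and
#'   one causal variant each.
#' @param n_variants_per_locus Variants per testable locus (1 causal).
#' @param carrier_or Target carrier odds ratio of the causal variant.
#' @param causal_maf Minor allele frequency of the causal variant.
#' @param fusion_freq_range Pooled carrier frequency range of testable
#'   fusions.
#' @param class_mix Relative structural-class frequencies (default the
#'   10/28/11/15/17 mix over 81 fusions the method was built around).
#' @param pattern_mix data.frame `k5`, `k3`, `prob` of exclusion patterns;
#'   default modal (1,1) at 45%.
#' @param intron_fg_medians Median length (nt) of the intron following the
#'   fusion exon of the 5' partner and preceding it in the 3' partner.
#' @param intron_bg_medians Median length of the remaining introns of the
#'   two partners.
#' @param intron_sdlog Log-sd of the log-normal intron lengths.
#' @param rpkm_median_partner,rpkm_median_chimera,rpkm_sdlog Log-normal
#'   expression parameters (RPKM).
#' @param zero_one_population Zero one partner gene's expression in one
#'   population (exercises the expression-presence filter).
#' @param n_reads Reads emitted by [generate_polya_reads()].
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(seed = 1L,
                        populations = c(CEU = 91, FIN = 95, GBR = 94,
                                        TSI = 93, YRI = 89),
                        n_tandem = 220L, n_low_support = 10L,
                        n_repeat_decoy = 10L, n_inverted = 8L,
                        n_diff_strand = 10L, n_interchrom = 10L,
                        n_background_genes = 20L, n_testable = 12L,
                        n_variants_per_locus = 100L,
                        carrier_or = 5, causal_maf = 0.3,
                        fusion_freq_range = c(0.08, 0.25),
                        class_mix = c(GENUINE_READ_THROUGH = 10,
                                      PROMOTER_SWAP = 28, UTR3_SWAP = 11,
                                      IN_FRAME = 15, OUT_OF_FRAME = 17),
                        pattern_mix = data.frame(
                          k5 = c(1, 2, 1, 2, 3, 1),
                          k3 = c(1, 1, 2, 2, 1, 3),
                          prob = c(0.45, 0.16, 0.10, 0.12, 0.09, 0.08)),
                        intron_fg_medians = c(intron5 = 2516, intron3 = 3734),
                        intron_bg_medians = c(gene5 = 1400, gene3 = 1164),
                        intron_sdlog = 0.6,
                        rpkm_median_partner = 5.45,
                        rpkm_median_chimera = 1.33,
                        rpkm_sdlog = 0.8,
                        zero_one_population = FALSE,
                        n_reads = 400L) {
  stopifnot(all(populations > 0), carrier_or > 0,
            causal_maf > 0, causal_maf <= 0.5,
            all(intron_fg_medians > 0), all(intron_bg_medians > 0),
            abs(sum(pattern_mix$prob) - 1) < 1e-9)
  if (n_testable > n_tandem) stop("n_testable exceeds n_tandem")
  structure(as.list(environment()), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d samples / %d populations, %d tandem",
                     " fusions (%d testable), seed %d\n"),
              sum(x$populations), length(x$populations), x$n_tandem,
              x$n_testable, x$seed))
  invisible(x)
}

#' Cohort sample table
#'
#' @param spec A `cohort_spec`.
#' @return data.frame with `sample_id`, `population`.
#' @export
cohort_samples <- function(spec) {
  pops <- spec$populations
  data.frame(
    sample_id = unlist(lapply(names(pops), function(p) {
      sprintf("%s_%03d", p, seq_len(pops[[p]]))
    })),
    population = rep(names(pops), pops),
    stringsAsFactors = FALSE)
}

rlnorm_median <- function(n, median, sdlog) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

# ---- gene construction (local coordinates, plus strand) -------------------

# exon/intron layout and CDS for one partner pair realizing a target
# structural class and exclusion pattern; all coordinates local, 0-based,
# plus strand, transcription left-to-right
build_pair_local <- function(spec, class, k5, k3, bstat5, bstat3) {
  g5 <- build_partner_local(spec, role = "5prime", k = k5, class = class,
                            bstat = bstat5)
  # frame classes: the 3' partner's excluded CDS length must agree with
  # (IN_FRAME) or differ from (OUT_OF_FRAME) the retained 5' CDS modulo 3
  s3_mod <- if (class == "IN_FRAME") g5$L5 %% 3L
            else if (class == "OUT_OF_FRAME") (g5$L5 + 1L) %% 3L
            else NA_integer_
  g3 <- build_partner_local(spec, role = "3prime", k = k3, class = class,
                            bstat = bstat3, s3_mod = s3_mod)
  list(g5 = g5, g3 = g3)
}

build_partner_local <- function(spec, role, k, class, bstat,
                                s3_mod = NA_integer_) {
  n_ex <- sample(max(k + 2L, 4L):9L, 1L)
  lens <- sample(80:300, n_ex, replace = TRUE)
  f <- if (role == "5prime") n_ex - k else k + 1L     # fusion exon index
  lens[f] <- sample(150:300, 1L)
  host <- if (role == "5prime") f + 1L else f - 1L    # CDS host for swaps
  lens[host] <- max(lens[host], 120L)
  bg_med <- spec$intron_bg_medians[[if (role == "5prime") "gene5"
                                    else "gene3"]]
  fg_med <- spec$intron_fg_medians[[if (role == "5prime") "intron5"
                                    else "intron3"]]
  introns <- pmax(60, round(rlnorm_median(n_ex - 1L, bg_med,
                                          spec$intron_sdlog)))
  # the flanking intron: after the fusion exon (5') / before it (3')
  flank_idx <- if (role == "5prime") f else f - 1L
  introns[flank_idx] <- max(60, round(rlnorm_median(1L, fg_med,
                                                    spec$intron_sdlog)))
  starts <- cumsum(c(0L, lens[-n_ex] + introns))
  ex <- data.frame(start = starts, end = starts + lens)
  # breakpoint: at / near / inside the retained-side edge of the fusion exon
  d <- switch(bstat, AT_BOUNDARY = 0L, NEAR_BOUNDARY = sample(1:3, 1L),
              INTRA_EXON = sample(10:30, 1L))
  bp <- if (role == "5prime") ex$end[f] - 1L - d else ex$start[f] + d
  cds <- partner_cds(class, role, ex, f, s3_mod)
  list(exons = ex, cds = cds$cds, f = f, bp = bp, n_ex = n_ex,
       L5 = cds$L5, S3 = cds$S3, flank_idx = flank_idx,
       flank_intron = introns[flank_idx], bg_introns = introns[-flank_idx])
}

# CDS intervals (local coords) realizing the class on one side; margins
# keep the class stable under near-boundary / intra-exon breakpoint shifts
# (<= 33 nt into the fusion exon)
partner_cds <- function(class, role, ex, f, s3_mod = NA_integer_) {
  L5 <- NA_integer_; S3 <- NA_integer_
  frame_class <- class %in% c("IN_FRAME", "OUT_OF_FRAME")
  if (role == "5prime") {
    cds <- if (frame_class) {
      # frame classes: CDS straddles bp1 (exon f suffix + exon f+1 prefix)
      L5 <- 3L * sample(8:20, 1L)
      rbind(data.frame(start = ex$end[f] - L5, end = ex$end[f]),
            sub_iv(ex, f + 1L, 0L, 60L))
    } else switch(class,
      PROMOTER_SWAP = sub_iv(ex, f + 1L, 5L, 90L),   # in excluded exon
      UTR3_SWAP = sub_iv(ex, f, 5L, 90L),            # retained, clear of bp
      GENUINE_READ_THROUGH = sub_iv(ex, f, 5L, 90L))
  } else {
    cds <- if (frame_class) {
      # frame classes: CDS straddles bp2 (exon f-1 suffix + exon f prefix)
      base <- sample(24:42, 1L)
      S3 <- base + (s3_mod - base) %% 3L
      rbind(data.frame(start = ex$end[f - 1L] - S3, end = ex$end[f - 1L]),
            sub_iv(ex, f, 0L, 60L))
    } else switch(class,
      PROMOTER_SWAP = sub_iv(ex, f, 40L, 90L),       # retained, after bp2
      UTR3_SWAP = sub_iv(ex, f - 1L, 5L, 90L),       # in excluded exon
      GENUINE_READ_THROUGH = sub_iv(ex, f, 40L, 90L))
  }
  list(cds = cds, L5 = L5, S3 = S3)
}

sub_iv <- function(ex, i, offset, len) {
  data.frame(start = ex$start[i] + offset, end = ex$start[i] + offset + len)
}

# exon indices an extra isoform may skip without changing the fusion exon,
# the flanking intron, the excluded-exon counts or the breakpoint status
skippable_exons <- function(role, f, n_ex) {
  if (role == "5prime") {
    if (f >= 3L) 2L:(f - 1L) else integer(0)
  } else {
    if (f + 1L <= n_ex) (f + 1L):n_ex else integer(0)
  }
}

# assemble transcript models (canonical + skip isoforms) for one partner;
# local plus-strand coordinates
partner_transcripts <- function(p, role, gid) {
  txs <- list(local_tx(p$exons, p$cds, sprintf("%s.T01", gid)))
  cand <- skippable_exons(role, p$f, p$n_ex)
  n_iso <- min(length(cand), sample(0:2, 1L))
  if (n_iso > 0L) {
    skip <- cand[sample.int(length(cand), n_iso)]
    for (j in seq_len(n_iso)) {
      ex <- p$exons[-skip[j], , drop = FALSE]
      keep_cds <- !(p$cds$start >= p$exons$start[skip[j]] &
                      p$cds$end <= p$exons$end[skip[j]])
      txs[[j + 1L]] <- local_tx(ex, p$cds[keep_cds, , drop = FALSE],
                                sprintf("%s.T%02d", gid, j + 1L))
    }
  }
  txs
}

local_tx <- function(exons, cds, tid) {
  list(tid = tid, exons = exons, cds = cds)
}

# flip a local layout (span L) to the minus strand: genomic order reverses,
# transcription order of the stored rows is preserved
flip_iv <- function(iv, L) {
  data.frame(start = L - iv$end, end = L - iv$start)
}
flip_pos <- function(pos, L) L - 1L - pos

# place local transcripts at a genomic offset on a strand
materialize_gene <- function(gid, chrom, strand, offset, span, txs) {
  models <- lapply(txs, function(t) {
    ex <- t$exons; cd <- t$cds
    if (strand == "-") {
      ex <- flip_iv(ex, span)
      if (nrow(cd)) cd <- flip_iv(cd, span)
    }
    transcript_model(t$tid, gid, chrom, strand,
                     data.frame(start = ex$start + offset,
                                end = ex$end + offset),
                     if (nrow(cd)) data.frame(start = cd$start + offset,
                                              end = cd$end + offset)
                     else empty_intervals())
  })
  gene_model(gid, gid, models)
}

# a standalone (non-partner) gene
build_single_gene <- function(spec, gid, chrom, strand, offset) {
  n_ex <- sample(3:9, 1L)
  lens <- sample(80:300, n_ex, replace = TRUE)
  lens[2] <- max(lens[2], 120L)          # hosts the CDS
  introns <- pmax(60, round(rlnorm_median(n_ex - 1L,
                                          spec$intron_bg_medians[["gene5"]],
                                          spec$intron_sdlog)))
  starts <- cumsum(c(0L, lens[-n_ex] + introns))
  ex <- data.frame(start = starts, end = starts + lens)
  cds <- sub_iv(ex, 2L, 5L, 90L)
  span <- ex$end[n_ex]
  gene <- materialize_gene(gid, chrom, strand, offset, span,
                           list(local_tx(ex, cds, sprintf("%s.T01", gid))))
  list(gene = gene, span = span)
}

# ---- generate_annotation --------------------------------------------------

#' Generate the synthetic annotation and fusion layout
#'
#' Lays out tandem partner pairs (plus decoy, inverted, different-strand
#' and interchromosomal pairs and background genes) on two synthetic
#' chromosomes.  Each tandem pair realizes a known structural class,
#' exclusion pattern and breakpoint boundary status; the intron flanking
#' the fusion exon is drawn from the long (foreground) length
#' distribution, all others from the background distribution.
#'
#' @param spec A `cohort_spec`.
#' @return List of class `sim_annotation`: `annotation`
#'   (a `gene_annotation`), `pairs` (data.table of per-fusion truth:
#'   role, genes, breakpoints, class, pattern, boundary statuses,
#'   flanking-intron interval and lengths), `repeats`, `polya_features`,
#'   `rbp_features` (interval data.frames).
#' @export
generate_annotation <- function(spec) {
  set.seed(spec$seed)
  roles <- c(rep("tandem", spec$n_tandem),
             rep("low_support", spec$n_low_support),
             rep("repeat_decoy", spec$n_repeat_decoy),
             rep("inverted", spec$n_inverted),
             rep("diff_strand", spec$n_diff_strand),
             rep("interchrom", spec$n_interchrom))
  n_pairs <- length(roles)
  classes <- sample(names(spec$class_mix), n_pairs, replace = TRUE,
                    prob = spec$class_mix)
  pat_idx <- sample(nrow(spec$pattern_mix), n_pairs, replace = TRUE,
                    prob = spec$pattern_mix$prob)
  # boundary statuses: mostly exact, a few near-boundary / intra-exon on
  # the CDS-complete classes (frame arithmetic assumes exact boundaries)
  bstat5 <- rep("AT_BOUNDARY", n_pairs)
  bstat3 <- rep("AT_BOUNDARY", n_pairs)
  shiftable <- which(roles == "tandem" &
                       classes %in% c("PROMOTER_SWAP", "UTR3_SWAP",
                                      "GENUINE_READ_THROUGH"))
  if (length(shiftable) >= 10L) {
    pick <- sample(shiftable, 10L)
    bstat5[pick[1:3]] <- "NEAR_BOUNDARY"
    bstat3[pick[4:6]] <- "NEAR_BOUNDARY"
    bstat5[pick[7:8]] <- "INTRA_EXON"
    bstat3[pick[9:10]] <- "INTRA_EXON"
  }

  cursor <- c(chrS1 = 10000L, chrS2 = 10000L)
  genes <- list(); rows <- list(); gaps <- list()
  gene_no <- 0L
  next_gid <- function() {
    gene_no <<- gene_no + 1L
    sprintf("SGENE%04d", gene_no)
  }
  for (i in seq_len(n_pairs)) {
    role <- roles[i]
    chrom <- if (i %% 2L == 0L) "chrS1" else "chrS2"
    strand <- sample(c("+", "-"), 1L)
    fid <- sprintf("FUS%04d", i)
    if (role %in% c("tandem", "low_support", "repeat_decoy", "inverted")) {
      k5 <- spec$pattern_mix$k5[pat_idx[i]]
      k3 <- spec$pattern_mix$k3[pat_idx[i]]
      loc <- build_pair_local(spec, classes[i], k5, k3,
                              bstat5[i], bstat3[i])
      id5 <- next_gid(); id3 <- next_gid()
      txs5 <- partner_transcripts(loc$g5, "5prime", id5)
      txs3 <- partner_transcripts(loc$g3, "3prime", id3)
      span5 <- loc$g5$exons$end[loc$g5$n_ex]
      span3 <- loc$g3$exons$end[loc$g3$n_ex]
      # target breakpoint distance
      d_target <- if (stats::runif(1) < 0.02) {
        round(stats::runif(1, 3e5, 2e6))
      } else {
        min(170000, max(5000, round(rlnorm_median(1, 25000, 0.9))))
      }
      gap <- max(300, d_target - span5 - loc$g3$bp + loc$g5$bp)
      pair_span <- span5 + gap + span3
      off <- cursor[[chrom]]
      if (strand == "+") {
        off5 <- off; off3 <- off + span5 + gap
        bp1 <- off5 + loc$g5$bp; bp2 <- off3 + loc$g3$bp
        g5m <- materialize_gene(id5, chrom, "+", off5, span5, txs5)
        g3m <- materialize_gene(id3, chrom, "+", off3, span3, txs3)
      } else {
        # minus strand: 5' partner transcriptionally upstream = genomic right
        off3 <- off; off5 <- off + span3 + gap
        bp1 <- off5 + flip_pos(loc$g5$bp, span5)
        bp2 <- off3 + flip_pos(loc$g3$bp, span3)
        g5m <- materialize_gene(id5, chrom, "-", off5, span5, txs5)
        g3m <- materialize_gene(id3, chrom, "-", off3, span3, txs3)
      }
      cursor[[chrom]] <- off + pair_span + sample(5000:20000, 1L)
      gaps[[length(gaps) + 1L]] <- data.frame(
        chrom = chrom, start = off + pair_span + 500L,
        end = cursor[[chrom]] - 500L)
      genes[[id5]] <- g5m; genes[[id3]] <- g3m
      # genomic interval of the intron following the 5' fusion exon
      intr <- transcript_introns(g5m$transcripts[[1]])
      i5_iv <- intr[loc$g5$f, ]
      orientation <- if (role == "inverted") "SAME_STRAND_INVERTED"
                     else "TANDEM_SAME_STRAND"
      # an inverted call names the downstream gene as its 5' partner
      swap <- role == "inverted"
      rows[[i]] <- data.table::data.table(
        fusion_id = fid, role = role, orientation = orientation,
        gene5 = if (swap) id3 else id5, gene3 = if (swap) id5 else id3,
        chrom5 = chrom, chrom3 = chrom,
        bp1 = if (swap) bp2 else bp1, bp2 = if (swap) bp1 else bp2,
        class = if (swap) NA_character_ else classes[i],
        k5 = if (swap) NA_integer_ else k5,
        k3 = if (swap) NA_integer_ else k3,
        boundary5 = bstat5[i], boundary3 = bstat3[i],
        L5 = loc$g5$L5, S3 = loc$g3$S3,
        intron5_start = i5_iv$start, intron5_end = i5_iv$end,
        intron5_len = loc$g5$flank_intron,
        intron3_len = loc$g3$flank_intron)
    } else {
      # different-strand / interchromosomal call: two standalone genes
      id5 <- next_gid(); id3 <- next_gid()
      chromB <- if (role == "interchrom") {
        setdiff(c("chrS1", "chrS2"), chrom)
      } else chrom
      strandB <- if (role == "diff_strand") {
        setdiff(c("+", "-"), strand)
      } else sample(c("+", "-"), 1L)
      a <- build_single_gene(spec, id5, chrom, strand, cursor[[chrom]])
      cursor[[chrom]] <- cursor[[chrom]] + a$span + sample(5000:20000, 1L)
      b <- build_single_gene(spec, id3, chromB, strandB, cursor[[chromB]])
      cursor[[chromB]] <- cursor[[chromB]] + b$span + sample(5000:20000, 1L)
      genes[[id5]] <- a$gene; genes[[id3]] <- b$gene
      tx_a <- a$gene$transcripts[[1]]; tx_b <- b$gene$transcripts[[1]]
      rows[[i]] <- data.table::data.table(
        fusion_id = fid, role = role,
        orientation = if (role == "interchrom") "INTERCHROM"
                      else "INTRACHROM_DIFF_STRAND",
        gene5 = id5, gene3 = id3, chrom5 = chrom, chrom3 = chromB,
        bp1 = max(tx_a$exons$end) - 1L, bp2 = min(tx_b$exons$start),
        class = NA_character_, k5 = NA_integer_, k3 = NA_integer_,
        boundary5 = NA_character_, boundary3 = NA_character_,
        L5 = NA_integer_, S3 = NA_integer_,
        intron5_start = NA_integer_, intron5_end = NA_integer_,
        intron5_len = NA_real_, intron3_len = NA_real_)
    }
  }
  for (b in seq_len(spec$n_background_genes)) {
    chrom <- if (b %% 2L == 0L) "chrS1" else "chrS2"
    g <- build_single_gene(spec, next_gid(), chrom,
                           sample(c("+", "-"), 1L), cursor[[chrom]])
    cursor[[chrom]] <- cursor[[chrom]] + g$span + sample(5000:20000, 1L)
    genes[[g$gene$gene_id]] <- g$gene
  }
  pairs <- data.table::rbindlist(rows)

  # repeats: one interval over each repeat-decoy bp1 plus background
  # repeats in intergenic gaps (never over kept breakpoints)
  decoy <- pairs[pairs$role == "repeat_decoy"]
  rep_rows <- list()
  for (i in seq_len(nrow(decoy))) {
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      chrom = decoy$chrom5[i], start = decoy$bp1[i] - 10L,
      end = decoy$bp1[i] + 11L, name = "synthetic_repeat")
  }
  gap_df <- do.call(rbind, gaps)
  gap_df <- gap_df[gap_df$end - gap_df$start > 400, , drop = FALSE]
  take <- utils::head(seq_len(nrow(gap_df)), 30L)
  for (i in take) {
    s <- gap_df$start[i] + sample(0:200, 1L)
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      chrom = gap_df$chrom[i], start = s, end = s + sample(100:300, 1L),
      name = "synthetic_repeat")
  }
  repeats <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0))

  # poly(A) signal/site features near each 5' partner's transcription end
  pol_rows <- list()
  for (i in which(pairs$role == "tandem")) {
    g <- genes[[pairs$gene5[i]]]
    tail_pos <- if (g$strand == "+") g$end else g$start
    sig <- if (g$strand == "+") c(tail_pos - 30L, tail_pos - 24L)
           else c(tail_pos + 24L, tail_pos + 30L)
    site <- if (g$strand == "+") c(tail_pos - 5L, tail_pos)
            else c(tail_pos, tail_pos + 5L)
    pol_rows[[length(pol_rows) + 1L]] <- data.frame(
      chrom = g$chrom, start = c(min(sig), min(site)),
      end = c(max(sig), max(site)),
      name = c("polyA_signal", "polyA_site"), gene_id = g$gene_id)
  }
  polya_features <- if (length(pol_rows)) do.call(rbind, pol_rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), gene_id = character(0))

  # RBP-bound intervals inside a subset of partner-gene spans
  rbp_idx <- which(pairs$role == "tandem")[seq_len(
    min(30L, sum(pairs$role == "tandem")))]
  rbp_features <- if (length(rbp_idx)) {
    do.call(rbind, lapply(rbp_idx, function(i) {
      g <- genes[[pairs$gene5[i]]]
      s <- g$start + sample(0:(max(1, g$end - g$start - 200L)), 1L)
      data.frame(chrom = g$chrom, start = s, end = s + 150L, name = "PABPC1")
    }))
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0))
  }

  structure(list(annotation = as_annotation(genes), pairs = pairs,
                 repeats = repeats, polya_features = polya_features,
                 rbp_features = rbp_features),
            class = "sim_annotation")
}

# ---- generate_fusion_truth ------------------------------------------------

#' Generate fusion calls, carrier sets and the cohort
#'
#' Carrier counts follow a rare-skewed spectrum (most fusions in fewer
#' than 5 individuals); `n_testable` tandem fusions are given pooled
#' frequencies above 5%.  Split-read support is >= 3 except for the
#' low-support decoys (1-2 reads), which the support filter must remove.
#'
#' @param spec A `cohort_spec`.
#' @param sim A `sim_annotation` from [generate_annotation()].
#' @return List with `calls` (a `fusion_calls` table), `cohort`
#'   (sample/population table) and `truth` (the `pairs` table extended
#'   with carriers, frequency, split reads and flags).
#' @export
generate_fusion_truth <- function(spec, sim) {
  set.seed(spec$seed + 1000L)
  cohort <- cohort_samples(spec)
  n <- nrow(cohort)
  truth <- data.table::copy(sim$pairs)
  tandem_idx <- which(truth$role == "tandem")
  testable_idx <- tandem_idx[seq_len(spec$n_testable)]
  truth[, testable := FALSE]
  data.table::set(truth, i = testable_idx, j = "testable", value = TRUE)
  carr <- vector("list", nrow(truth))
  freq <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    if (truth$testable[i]) {
      p <- stats::runif(1, spec$fusion_freq_range[1], spec$fusion_freq_range[2])
      ncar <- max(ceiling(0.051 * n) + 1L, round(p * n))
    } else {
      ncar <- min(1L + stats::rpois(1, 1.2), 8L)
    }
    carr[[i]] <- sort(sample(cohort$sample_id, ncar))
    freq[i] <- ncar / n
  }
  truth[, carriers := carr]
  truth[, frequency := freq]
  truth[, split_reads := ifelse(role == "low_support",
                                sample(1:2, .N, replace = TRUE),
                                3L + stats::rpois(.N, 5))]
  truth[, expected_in_catalog := role != "low_support" &
          role != "repeat_decoy"]
  calls <- data.table::data.table(
    fusion_id = truth$fusion_id, gene5 = truth$gene5, gene3 = truth$gene3,
    chrom5 = truth$chrom5, chrom3 = truth$chrom3,
    bp1 = truth$bp1, bp2 = truth$bp2, split_reads = truth$split_reads,
    carriers = truth$carriers)
  data.table::setattr(calls, "class",
                      c("fusion_calls", class(data.table::data.table())))
  list(calls = calls[], cohort = cohort, truth = truth[])
}

# ---- generate_cohort_genotypes --------------------------------------------

# case/control carrier probabilities achieving carrier odds ratio `or`
# with marginal carrier probability q over R cases and S controls
solve_carrier_probs <- function(or, q, R, S) {
  N <- R + S
  f <- function(q0) {
    q1 <- or * q0 / (1 - q0 + or * q0)
    R * q1 + S * q0 - N * q
  }
  if (f(1 - 1e-12) < 0) {
    stop("requested odds ratio unattainable: feasible bound q <= ",
         signif((R + S * 1) / N, 3))
  }
  q0 <- stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  q1 <- or * q0 / (1 - q0 + or * q0)
  c(q1 = q1, q0 = q0)
}

#' Generate cohort genotypes with injected causal variants
#'
#' Each testable fusion receives one causal variant placed in the intron
#' following the 5' fusion exon, whose carrier status is sampled
#' conditional on fusion presence to achieve the specified carrier odds
#' ratio (marginal allele frequency held at `causal_maf`), plus null
#' variants at Hardy-Weinberg with MAF ~ Uniform(0.05, 0.5) spread over
#' the partner-gene loci, independent of the phenotype.
#'
#' @param spec A `cohort_spec`.
#' @param sim A `sim_annotation`.
#' @param truth Truth table from [generate_fusion_truth()].
#' @return List with `genotypes` (a `genotype_table`) and `causal`
#'   (data.table: fusion_id, variant_id, pos, target_or).
#' @export
generate_cohort_genotypes <- function(spec, sim, truth) {
  set.seed(spec$seed + 2000L)
  cohort <- cohort_samples(spec)
  samples <- cohort$sample_id
  n <- length(samples)
  test <- truth[truth$testable == TRUE]
  var_rows <- list(); dos_rows <- list(); causal_rows <- list()
  vno <- 0L
  for (i in seq_len(nrow(test))) {
    fus <- test[i]
    g5 <- sim$annotation[[fus$gene5]]
    g3 <- sim$annotation[[fus$gene3]]
    n_null <- spec$n_variants_per_locus - 1L
    # null variants fall on the partner genes (+/- 200 nt), the interval
    # the association scan extracts; the causal one keeps its own intron
    pos_pool <- setdiff(
      c(seq(g5$start - 200L, g5$end + 199L),
        seq(g3$start - 200L, g3$end + 199L)),
      fus$intron5_start:fus$intron5_end)
    pos_null <- sort(sample(pos_pool, n_null))
    pos_causal <- sample(fus$intron5_start:(fus$intron5_end - 1L), 1L)

    is_case <- samples %in% fus$carriers[[1]]
    m <- spec$causal_maf
    q <- 1 - (1 - m)^2                     # carrier probability under HWE
    pq <- solve_carrier_probs(spec$carrier_or, q, sum(is_case),
                              sum(!is_case))
    p_carrier <- ifelse(is_case, pq[["q1"]], pq[["q0"]])
    carrier <- stats::runif(n) < p_carrier
    p_hom <- m^2 / q                       # P(dosage 2 | carrier)
    d_causal <- integer(n)
    d_causal[carrier] <- 1L + (stats::runif(sum(carrier)) < p_hom)

    maf_null <- stats::runif(n_null, 0.05, 0.5)
    d_null <- vapply(maf_null, function(f) stats::rbinom(n, 2L, f),
                     integer(n))                       # n x n_null
    all_pos <- c(pos_causal, pos_null)
    ord <- order(all_pos)
    dmat <- cbind(d_causal, d_null)[, ord, drop = FALSE]
    all_pos <- all_pos[ord]
    ids <- sprintf("rsS%07d", vno + seq_along(all_pos))
    vno <- vno + length(all_pos)
    refalt <- ref_alt_pairs(length(all_pos))
    vr <- data.table::data.table(
      chrom = fus$chrom5, pos = all_pos + 1L, variant_id = ids,
      ref = refalt$ref, alt = refalt$alt,
      is_deletion = nchar(refalt$ref) > nchar(refalt$alt))
    var_rows[[i]] <- vr
    dos_rows[[i]] <- t(dmat)
    causal_rows[[i]] <- data.table::data.table(
      fusion_id = fus$fusion_id,
      variant_id = ids[which(all_pos == pos_causal)],
      pos = pos_causal + 1L, target_or = spec$carrier_or)
  }
  variants <- data.table::rbindlist(var_rows)
  dosages <- do.call(rbind, dos_rows)
  rownames(dosages) <- variants$variant_id
  colnames(dosages) <- samples
  gt <- structure(list(variants = variants, dosages = dosages,
                       samples = samples), class = "genotype_table")
  list(genotypes = gt, causal = data.table::rbindlist(causal_rows))
}

ref_alt_pairs <- function(k) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, k, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  list(ref = ref, alt = unname(alt))
}

# ---- generate_expression_table --------------------------------------------

#' Generate the transcript-level RPKM table
#'
#' Partner and background genes get log-normal gene-level RPKMs (median
#' `rpkm_median_partner`), positive in every sample, split across their
#' transcripts with fixed per-gene proportions.  Each tandem fusion's
#' fused gene (all isoform combinations, ids as produced by
#' [build_chimeric_transcripts()]) gets log-normal RPKM with median
#' `rpkm_median_chimera` in carrier samples and exactly 0 elsewhere.
#'
#' @param spec A `cohort_spec`.
#' @param sim A `sim_annotation`.
#' @param truth Truth table from [generate_fusion_truth()].
#' @return An `expression_table`.
#' @export
generate_expression_table <- function(spec, sim, truth) {
  set.seed(spec$seed + 3000L)
  cohort <- cohort_samples(spec)
  samples <- cohort$sample_id
  n <- length(samples)
  tid <- character(0); gid <- character(0); blocks <- list()
  for (g in sim$annotation) {
    txs <- g$transcripts
    gene_vals <- rlnorm_median(n, spec$rpkm_median_partner, spec$rpkm_sdlog)
    w <- stats::runif(length(txs), 0.2, 1)
    w <- w / sum(w)
    blocks[[length(blocks) + 1L]] <- outer(w, gene_vals)
    tid <- c(tid, names(txs))
    gid <- c(gid, rep(g$gene_id, length(txs)))
  }
  tandem <- truth[truth$role == "tandem"]
  for (i in seq_len(nrow(tandem))) {
    fus <- tandem[i]
    fgid <- fused_gene_id(fus$gene5, fus$gene3)
    tx5 <- names(sim$annotation[[fus$gene5]]$transcripts)
    tx3 <- names(sim$annotation[[fus$gene3]]$transcripts)
    combo <- expand.grid(t5 = tx5, t3 = tx3, stringsAsFactors = FALSE)
    ftids <- paste(fgid, combo$t5, combo$t3, sep = "|")
    vals <- numeric(n)
    is_car <- samples %in% fus$carriers[[1]]
    vals[is_car] <- rlnorm_median(sum(is_car), spec$rpkm_median_chimera,
                                  spec$rpkm_sdlog)
    w <- stats::runif(length(ftids), 0.2, 1)
    w <- w / sum(w)
    blocks[[length(blocks) + 1L]] <- outer(w, vals)
    tid <- c(tid, ftids)
    gid <- c(gid, rep(fgid, length(ftids)))
  }
  values <- do.call(rbind, blocks)
  rownames(values) <- tid
  colnames(values) <- samples
  if (spec$zero_one_population) {
    # silence fusion 1's 5' partner in the last population: its fusion
    # must then fail the expression-presence filter
    pop <- names(spec$populations)[length(spec$populations)]
    silenced <- cohort$sample_id[cohort$population == pop]
    values[gid == tandem$gene5[1], silenced] <- 0
  }
  structure(list(values = values, transcript_id = tid, gene_id = gid,
                 samples = samples), class = "expression_table")
}

# ---- generate_polya_reads -------------------------------------------------

#' Generate labelled reads for the poly(A)-read selection step
#'
#' Mixture of poly(A)-tailed, poly(T)-headed, untailed, low-complexity and
#' all-A reads with known labels, so the selection step can be verified
#' closed-loop.
#'
#' @param spec A `cohort_spec`.
#' @return List with `reads` (data.frame `id`, `seq`) and `labels`
#'   (character vector: `tailed`, `headed`, `none`, `low_complexity`,
#'   `all_A`).
#' @export
generate_polya_reads <- function(spec) {
  set.seed(spec$seed + 4000L)
  n <- spec$n_reads
  labels <- sample(c("tailed", "headed", "none", "low_complexity", "all_A"),
                   n, replace = TRUE, prob = c(0.35, 0.25, 0.25, 0.1, 0.05))
  stub <- function() {
    # sentinel first/last bases keep tail/head detection unambiguous
    len <- sample(30:60, 1L)
    paste0("G", paste(sample(c("A", "C", "G", "T"), len - 2L,
                             replace = TRUE), collapse = ""), "C")
  }
  seqs <- vapply(seq_len(n), function(i) {
    switch(labels[i],
           tailed = paste0(stub(), strrep("A", sample(10:25, 1L))),
           headed = paste0(strrep("T", sample(10:25, 1L)), stub()),
           none = stub(),
           low_complexity = paste0(strrep("C", 40L),
                                   strrep("A", sample(10:20, 1L))),
           all_A = strrep("A", 50L))
  }, "")
  list(reads = data.frame(id = sprintf("read_%05d", seq_len(n)), seq = seqs,
                          stringsAsFactors = FALSE),
       labels = labels)
}

# ---- simulate_study -------------------------------------------------------

#' Generate and write a complete synthetic study
#'
#' Runs every generator with the spec's seed and writes
#' `annotation.gtf`, `fusions.tsv`, `genotypes.vcf`, `rpkm.tsv`,
#' `repeats.bed`, `polya_sites.bed`, `rbp_sites.bed`, `reads.fastq`,
#' `cohort.tsv` and `truth.json` into `out_dir`.  Re-running with the same
#' spec reproduces every file byte for byte.
#'
#' @param spec A `cohort_spec`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the in-memory study: list with `sim`, `calls`,
#'   `cohort`, `truth`, `genotypes`, `causal`, `expression`, `reads`,
#'   `read_labels`.
#' @export
simulate_study <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_annotation(spec)
  ft <- generate_fusion_truth(spec, sim)
  gt <- generate_cohort_genotypes(spec, sim, ft$truth)
  expr <- generate_expression_table(spec, sim, ft$truth)
  reads <- generate_polya_reads(spec)

  write_gtf(sim$annotation, file.path(out_dir, "annotation.gtf"))
  write_fusion_table(ft$calls, file.path(out_dir, "fusions.tsv"))
  write_vcf(gt$genotypes, file.path(out_dir, "genotypes.vcf"))
  write_rpkm(expr, file.path(out_dir, "rpkm.tsv"))
  write_bed(sim$repeats, file.path(out_dir, "repeats.bed"))
  polya_bed <- sim$polya_features
  polya_bed$name <- paste(polya_bed$gene_id, polya_bed$name, sep = "|")
  write_bed(polya_bed, file.path(out_dir, "polya_sites.bed"))
  write_bed(sim$rbp_features, file.path(out_dir, "rbp_sites.bed"))
  write_fastq(reads$reads, file.path(out_dir, "reads.fastq"))
  utils::write.table(ft$cohort, file.path(out_dir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  truth_json <- data.table::copy(ft$truth)
  truth_json[, carriers := lapply(carriers, identity)]
  jsonlite::write_json(
    list(spec = spec[setdiff(names(spec), "pattern_mix")],
         pattern_mix = spec$pattern_mix,
         fusions = truth_json,
         causal_variants = gt$causal,
         read_labels = data.frame(id = reads$reads$id,
                                  label = reads$labels)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(sim = sim, calls = ft$calls, cohort = ft$cohort,
                 truth = ft$truth, genotypes = gt$genotypes,
                 causal = gt$causal, expression = expr,
                 reads = reads$reads, read_labels = reads$labels))
}
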