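# Structural characterization of tandem chimeras: which parts of the two
# partner gene structures survive the junction, whether the junction
# preserves reading frame, which exons are excluded, and how long the
# introns flanking the fusion exons are.

STRUCTURAL_CLASSES <- c("GENUINE_READ_THROUGH", "PROMOTER_SWAP", "UTR3_SWAP",
                        "IN_FRAME", "OUT_OF_FRAME")

boundary_rank <- function(status) {
  c(AT_BOUNDARY = 0, NEAR_BOUNDARY = 1, INTRA_EXON = 2, INTRONIC = 3)[[status]]
}

#' Select the transcript pair used for the single per-fusion class
#'
#' One structural class is reported per fusion, so one (transcript5,
#' transcript3) pair must represent it.  Pairs where both breakpoints sit
#' exactly at exon boundaries are preferred, then near-boundary, then
#' intra-exon pairs; ties are broken by the largest combined CDS length,
#' then by transcript ids for determinism.
#'
#' @param call Fusion call with `bp1`, `bp2`.
#' @param gene5,gene3 `gene_model`s of the partners.
#' @return List with `tx5`, `tx3`, `status5`, `status3`.
#' @export
select_transcript_pair <- function(call, gene5, gene3) {
  cand <- list(); score <- numeric(0)
  ids <- character(0)
  for (tx5 in gene5$transcripts) {
    if (!bp_in_span(tx5, call$bp1)) next
    s5 <- boundary_status(call$bp1, tx5, "5prime")
    for (tx3 in gene3$transcripts) {
      if (!bp_in_span(tx3, call$bp2)) next
      s3 <- boundary_status(call$bp2, tx3, "3prime")
      r5 <- boundary_rank(s5); r3 <- boundary_rank(s3)
      if (r5 == 3 || r3 == 3) next      # intronic breakpoints never pair
      cds <- total_cds_length(tx5) + total_cds_length(tx3)
      cand[[length(cand) + 1L]] <- list(tx5 = tx5, tx3 = tx3,
                                        status5 = as.character(s5),
                                        status3 = as.character(s3))
      # lexicographic score: worst rank, then rank sum, then -CDS length
      score <- c(score, max(r5, r3) * 1e12 + (r5 + r3) * 1e10 + (1e9 - cds))
      ids <- c(ids, paste(tx5$transcript_id, tx3$transcript_id))
    }
  }
  if (!length(cand)) {
    stop("no transcript pair compatible with breakpoints bp1=", call$bp1,
         " bp2=", call$bp2, " (nearest exon boundaries: ",
         nearest_boundaries(gene5, call$bp1), " | ",
         nearest_boundaries(gene3, call$bp2), ")")
  }
  cand[[order(score, ids)[1]]]
}

nearest_boundaries <- function(gene, bp) {
  edges <- unlist(lapply(gene$transcripts, function(tx) {
    c(tx$exons$start, tx$exons$end - 1L)
  }))
  paste(utils::head(sort(edges[order(abs(edges - bp))]), 3), collapse = ",")
}

#' Determine whether a chimeric junction preserves reading frame
#'
#' With `L5` the retained coding nucleotides of the 5' partner (from its
#' start codon up to `bp1`) and `S3` the excluded coding nucleotides of
#' the 3' partner (from its start codon up to, but not including, `bp2`),
#' the fused transcript keeps the 3' partner's native codon boundaries iff
#' `L5 mod 3 == S3 mod 3`.
#'
#' @param tx5,tx3 `transcript_model`s of the two partners (both coding).
#' @param bp1,bp2 Breakpoints (last retained / first retained base).
#' @return List with `frame` (`"IN_FRAME"`/`"OUT_OF_FRAME"`), `L5`, `S3`.
#' @export
junction_frame <- function(tx5, tx3, bp1, bp2) {
  if (!nrow(tx5$cds) || !nrow(tx3$cds)) {
    stop("junction_frame requires both partners to be coding")
  }
  L5 <- cds_retained_upto(tx5, bp1)
  S3 <- cds_excluded_before(tx3, bp2)
  frame <- if (L5 %% 3 == S3 %% 3) "IN_FRAME" else "OUT_OF_FRAME"
  list(frame = frame, L5 = L5, S3 = S3)
}

#' Structural class of a tandem chimera
#'
#' Using the selected transcript pair, the retained 5' region (exonic
#' sequence up to `bp1`) and retained 3' region (from `bp2`) decide the
#' class: no 5' CDS retained + complete 3' CDS = promoter swap (the 3'
#' partner's coding sequence runs under the 5' partner's promoter);
#' complete 5' CDS + no 3' CDS retained = 3' UTR swap; both CDSs complete
#' = genuine read-through; otherwise the junction frame decides in-frame
#' vs out-of-frame.  Fusions of two non-coding genes are reported as
#' `UNCLASSIFIABLE`.
#'
#' @param call Fusion call with `bp1`, `bp2`.
#' @param gene5,gene3 `gene_model`s of the partners.
#' @return List with `class`, `tx5_id`, `tx3_id`, `L5`, `S3` (frame
#'   quantities, `NA` unless frame was evaluated), `status5`, `status3`.
#' @export
classify_structure <- function(call, gene5, gene3) {
  pair <- select_transcript_pair(call, gene5, gene3)
  tx5 <- pair$tx5; tx3 <- pair$tx3
  tot5 <- total_cds_length(tx5); tot3 <- total_cds_length(tx3)
  L5r <- if (tot5) cds_retained_upto(tx5, call$bp1) else 0L
  excl3 <- if (tot3) cds_excluded_before(tx3, call$bp2) else 0L
  ret3 <- tot3 - excl3
  out <- list(class = NA_character_, tx5_id = tx5$transcript_id,
              tx3_id = tx3$transcript_id, L5 = NA_integer_, S3 = NA_integer_,
              status5 = pair$status5, status3 = pair$status3)
  if (L5r == 0L && tot3 > 0L && excl3 == 0L) {
    out$class <- "PROMOTER_SWAP"
  } else if (tot5 > 0L && L5r == tot5 && ret3 == 0L) {
    out$class <- "UTR3_SWAP"
  } else if (tot5 > 0L && L5r == tot5 && tot3 > 0L && excl3 == 0L) {
    out$class <- "GENUINE_READ_THROUGH"
  } else if (tot5 > 0L && tot3 > 0L) {
    fr <- junction_frame(tx5, tx3, call$bp1, call$bp2)
    out$class <- fr$frame
    out$L5 <- fr$L5
    out$S3 <- fr$S3
  } else {
    out$class <- "UNCLASSIFIABLE"
  }
  out
}

#' Exon-exclusion patterns over all transcript combinations
#'
#' For every (transcript5, transcript3) pair, `k5` counts the transcript5
#' exons lying entirely transcriptionally downstream of `bp1` (excluded
#' terminal exons, counted from the last exon) and `k3` the transcript3
#' exons entirely upstream of `bp2` (excluded leading exons).  Pattern
#' weights are pair counts normalized by the number of pairs, so they sum
#' to 1 per fusion.
#'
#' @param call Fusion call with `bp1`, `bp2`.
#' @param gene5,gene3 `gene_model`s of the partners.
#' @return data.table with `k5`, `k3`, `weight`.
#' @export
exon_exclusion_patterns <- function(call, gene5, gene3) {
  pats <- list(); n <- 0L
  for (tx5 in gene5$transcripts) {
    k5 <- retain_upto(tx5, call$bp1)$n_excluded
    for (tx3 in gene3$transcripts) {
      k3 <- retain_from(tx3, call$bp2)$n_excluded
      n <- n + 1L
      pats[[n]] <- c(k5 = k5, k3 = k3)
    }
  }
  tab <- data.table::as.data.table(do.call(rbind, pats))
  out <- tab[, .(weight = .N / n), by = .(k5, k3)]
  data.table::setorder(out, k5, k3)
  out[]
}

#' Lengths of the introns and exons flanking the fusion breakpoints
#'
#' The fusion exon of the 5' partner is the exon containing `bp1`; the
#' flanking intron (`intron5`) is the intron immediately following it in
#' transcription order.  Symmetrically `intron3` precedes the exon
#' containing `bp2`.  All remaining introns of both transcripts form the
#' background.  All transcript combinations contribute, but each distinct
#' intron is counted once per transcript, so multi-isoform genes do not
#' dominate.  Transcripts where the breakpoint is not exonic, or where the
#' fusion exon is terminal (no flanking intron), are skipped.
#'
#' @param call Fusion call with `bp1`, `bp2`.
#' @param gene5,gene3 `gene_model`s of the partners.
#' @return List with numeric vectors `intron5`, `intron3`,
#'   `intron_background`, `exon5`, `exon3`, `exon_background`, and
#'   `n_skipped` (transcripts without a usable flanking intron).
#' @export
flanking_feature_lengths <- function(call, gene5, gene3) {
  res <- list(intron5 = numeric(0), intron3 = numeric(0),
              intron_background = numeric(0), exon5 = numeric(0),
              exon3 = numeric(0), exon_background = numeric(0),
              n_skipped = 0L)
  for (tx in gene5$transcripts) {
    f <- flank_one(tx, call$bp1, after = TRUE)
    if (is.null(f)) { res$n_skipped <- res$n_skipped + 1L; next }
    res$intron5 <- c(res$intron5, f$flank_intron)
    res$exon5 <- c(res$exon5, f$fusion_exon_len)
    res$intron_background <- c(res$intron_background, f$other_introns)
    res$exon_background <- c(res$exon_background, f$other_exons)
  }
  for (tx in gene3$transcripts) {
    f <- flank_one(tx, call$bp2, after = FALSE)
    if (is.null(f)) { res$n_skipped <- res$n_skipped + 1L; next }
    res$intron3 <- c(res$intron3, f$flank_intron)
    res$exon3 <- c(res$exon3, f$fusion_exon_len)
    res$intron_background <- c(res$intron_background, f$other_introns)
    res$exon_background <- c(res$exon_background, f$other_exons)
  }
  res
}

# flanking intron of the exon containing bp; after=TRUE takes the intron
# following the exon in transcription order, FALSE the one preceding it
flank_one <- function(tx, bp, after) {
  ex <- tx$exons
  idx <- which(ex$start <= bp & bp < ex$end)
  if (!length(idx)) return(NULL)
  introns <- transcript_introns(tx)     # transcription order, n_exons - 1
  flank_idx <- if (after) idx else idx - 1L
  if (flank_idx < 1L || flank_idx > nrow(introns)) return(NULL)
  ilen <- introns$end - introns$start
  elen <- ex$end - ex$start
  list(flank_intron = ilen[flank_idx], other_introns = ilen[-flank_idx],
       fusion_exon_len = elen[idx], other_exons = elen[-idx])
}

#' Compare foreground and background length distributions
#'
#' Delegates to [ks_two_sample()] and reports medians alongside.
#'
#' @param foreground,background Numeric length samples (non-empty).
#' @return List with `ks` (a `ks_result`), `median_foreground`,
#'   `median_background`.
#' @export
compare_length_distributions <- function(foreground, background) {
  ks <- ks_two_sample(foreground, background)
  list(ks = ks, median_foreground = stats::median(foreground),
       median_background = stats::median(background))
}

#' Characterize all tandem fusions of a catalog
#'
#' Applies [classify_structure()], [exon_exclusion_patterns()] and
#' [flanking_feature_lengths()] to every `TANDEM_SAME_STRAND` call and
#' aggregates the exclusion-pattern table (per-fusion weights averaged, so
#' the aggregate is again a probability distribution) and the pooled
#' intron-length comparison.
#'
#' @param catalog A `fusion_calls` table with an `orientation` column.
#' @param annotation A `gene_annotation`.
#' @return List with `characterization` (data.table), `pattern_table`
#'   (aggregate k5/k3 weights), `lengths` (pooled flanking-length vectors)
#'   and `length_comparison` (5' and 3' intron KS results).
#' @export
characterize_fusions <- function(catalog, annotation) {
  tandem <- catalog[catalog$orientation == "TANDEM_SAME_STRAND"]
  rows <- list(); pat_list <- list()
  pool <- list(intron5 = numeric(0), intron3 = numeric(0),
               intron_background = numeric(0))
  for (i in seq_len(nrow(tandem))) {
    call <- tandem[i]
    g5 <- annotation[[call$gene5]]
    g3 <- annotation[[call$gene3]]
    cls <- classify_structure(call, g5, g3)
    pats <- exon_exclusion_patterns(call, g5, g3)
    modal <- pats[order(-weight, k5, k3)][1]
    fl <- flanking_feature_lengths(call, g5, g3)
    pool$intron5 <- c(pool$intron5, fl$intron5)
    pool$intron3 <- c(pool$intron3, fl$intron3)
    pool$intron_background <- c(pool$intron_background, fl$intron_background)
    rows[[i]] <- data.table::data.table(
      fusion_id = call$fusion_id, structural_class = cls$class,
      tx5_id = cls$tx5_id, tx3_id = cls$tx3_id,
      frame_L5_mod3 = if (is.na(cls$L5)) NA_integer_ else cls$L5 %% 3L,
      frame_S3_mod3 = if (is.na(cls$S3)) NA_integer_ else cls$S3 %% 3L,
      modal_k5 = modal$k5, modal_k3 = modal$k3,
      intron5_median = if (length(fl$intron5)) stats::median(fl$intron5)
                       else NA_real_,
      intron3_median = if (length(fl$intron3)) stats::median(fl$intron3)
                       else NA_real_,
      background_median = if (length(fl$intron_background))
        stats::median(fl$intron_background) else NA_real_)
    pat_list[[i]] <- pats
  }
  characterization <- data.table::rbindlist(rows)
  pattern_table <- aggregate_patterns(pat_list)
  length_comparison <- list(
    intron5 = if (length(pool$intron5) && length(pool$intron_background))
      compare_length_distributions(pool$intron5, pool$intron_background)
      else NULL,
    intron3 = if (length(pool$intron3) && length(pool$intron_background))
      compare_length_distributions(pool$intron3, pool$intron_background)
      else NULL)
  list(characterization = characterization, pattern_table = pattern_table,
       lengths = pool, length_comparison = length_comparison)
}

# average per-fusion pattern weights (each fusion contributes weight 1)
aggregate_patterns <- function(pat_list) {
  pat_list <- pat_list[lengths(pat_list) > 0]
  if (!length(pat_list)) {
    return(data.table::data.table(k5 = integer(0), k3 = integer(0),
                                  weight = numeric(0)))
  }
  all_pats <- data.table::rbindlist(pat_list)
  out <- all_pats[, .(weight = sum(weight) / length(pat_list)),
                  by = .(k5, k3)]
  data.table::setorder(out, -weight, k5, k3)
  out[]
}
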