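# Catalog stage: orientation classes, support/repeat/expression filters,
# breakpoint boundary status, distances, population frequencies, novelty.

ORIENTATION_CLASSES <- c("TANDEM_SAME_STRAND", "SAME_STRAND_INVERTED",
                         "INTRACHROM_DIFF_STRAND", "INTERCHROM")

#' Classify the genomic orientation of a fusion call
#'
#' Partners on different chromosomes are `INTERCHROM`; same chromosome,
#' opposite strands is `INTRACHROM_DIFF_STRAND`.  Same-strand pairs are
#' `TANDEM_SAME_STRAND` when the 5' partner is transcriptionally upstream
#' of the 3' partner and `SAME_STRAND_INVERTED` otherwise (the fusion runs
#' against the annotated gene order).
#'
#' @param call A single-row `fusion_calls` entry (or list with `gene5`,
#'   `gene3`).
#' @param annotation A `gene_annotation` containing both partners.
#' @return One of the orientation class labels.
#' @export
classify_orientation <- function(call, annotation) {
  g5 <- annotation[[call$gene5]]
  g3 <- annotation[[call$gene3]]
  if (is.null(g5) || is.null(g3)) {
    stop("unknown gene in fusion call: ",
         paste(setdiff(c(call$gene5, call$gene3), names(annotation)),
               collapse = ", "))
  }
  if (g5$chrom != g3$chrom) return("INTERCHROM")
  if (g5$strand != g3$strand) return("INTRACHROM_DIFF_STRAND")
  # transcriptional upstream: smaller start on '+', larger end on '-'
  upstream5 <- if (g5$strand == "+") g5$start < g3$start else g5$end > g3$end
  if (upstream5) "TANDEM_SAME_STRAND" else "SAME_STRAND_INVERTED"
}

#' Filter fusion calls by split-read support
#'
#' Keeps calls with strictly more than `min_split_reads` junction-spanning
#' reads (default 2, i.e. at least 3 reads).
#'
#' @param calls A `fusion_calls` table.
#' @param min_split_reads Strict lower bound on `split_reads`.
#' @return Filtered `fusion_calls`.
#' @export
apply_support_filter <- function(calls, min_split_reads = 2L) {
  stopifnot(min_split_reads >= 0)
  calls[calls$split_reads > min_split_reads]
}

#' Filter fusion calls whose breakpoints overlap repeat elements
#'
#' A call is dropped when either breakpoint position falls inside any
#' repeat interval (point-in-interval under the half-open convention; no
#' window is added around the breakpoint).
#'
#' @param calls A `fusion_calls` table (needs `chrom5`, `chrom3`).
#' @param repeats Intervals as from [parse_bed()].
#' @param window Half-width (nt) added around each breakpoint before the
#'   overlap test; default 0 (the breakpoint point only).
#' @return Filtered `fusion_calls`.
#' @export
apply_repeat_filter <- function(calls, repeats, window = 0L) {
  stopifnot(window >= 0)
  if (!nrow(calls)) return(calls)
  hits <- function(chrom, bp) {
    if (window == 0L) return(point_in_intervals(chrom, bp, repeats))
    vapply(seq_along(bp), function(i) {
      any(repeats$chrom == chrom[i] &
            repeats$start < bp[i] + window + 1L &
            bp[i] - window < repeats$end)
    }, logical(1))
  }
  calls[!(hits(calls$chrom5, calls$bp1) | hits(calls$chrom3, calls$bp2))]
}

#' Breakpoint position relative to exon-intron boundaries
#'
#' @param bp 0-based genomic breakpoint.
#' @param tx A `transcript_model`.
#' @param side `"5prime"` if `bp` is the last retained base of the 5'
#'   partner, `"3prime"` if it is the first retained base of the 3' partner
#'   (determines which exon edge counts as "at the boundary").
#' @return One of `"AT_BOUNDARY"`, `"NEAR_BOUNDARY"` (with attribute
#'   `distance` in 1..3), `"INTRA_EXON"`, `"INTRONIC"`.
#' @export
boundary_status <- function(bp, tx, side = c("5prime", "3prime")) {
  side <- match.arg(side)
  if (!bp_in_span(tx, bp)) {
    stop("breakpoint ", bp, " outside span of transcript ", tx$transcript_id)
  }
  ex <- tx$exons
  # genomic position of the retained-side edge base of each exon
  retained_edge <- if ((side == "5prime") == (tx$strand == "+")) {
    ex$end - 1L          # transcription-sense 3' edge of the exon
  } else {
    ex$start             # transcription-sense 5' edge
  }
  if (any(bp == retained_edge)) return("AT_BOUNDARY")
  d <- min(abs(bp - ex$start), abs(bp - (ex$end - 1L)))
  if (d >= 1L && d <= 3L) {
    return(structure("NEAR_BOUNDARY", distance = d))
  }
  inside <- any(ex$start <= bp & bp < ex$end)
  if (inside) "INTRA_EXON" else "INTRONIC"
}

#' Genomic distance between fusion breakpoints
#'
#' @param call Fusion call with `bp1`, `bp2`, `chrom5`, `chrom3`.
#' @return `|bp2 - bp1|` in nucleotides.
#' @export
breakpoint_distance <- function(call) {
  if (!is.null(call$chrom5) && !is.null(call$chrom3) &&
      call$chrom5 != call$chrom3) {
    stop("breakpoint distance undefined for interchromosomal call")
  }
  abs(call$bp2 - call$bp1)
}

#' Per-population carrier frequencies and the population venn partition
#'
#' @param calls A `fusion_calls` table.
#' @param cohort data.frame with `sample_id`, `population`.
#' @return List with `frequencies` (data.table: fusion_id, one carrier
#'   count column per population, `n_carriers`, `combined_frequency` over
#'   the pooled cohort) and `venn` (data.table: `populations` label =
#'   sorted populations with >= 1 carrier, `n_fusions`).
#' @export
population_frequencies <- function(calls, cohort) {
  pops <- sort(unique(cohort$population))
  pop_of <- stats::setNames(cohort$population, cohort$sample_id)
  n_total <- nrow(cohort)
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    carriers <- as_carriers(calls$carriers[[i]])
    unknown <- setdiff(carriers, names(pop_of))
    if (length(unknown)) {
      stop("carrier sample(s) without population label: ",
           paste(unknown, collapse = ", "))
    }
    cnt <- table(factor(pop_of[carriers], levels = pops))
    c(list(fusion_id = calls$fusion_id[i]), as.list(as.integer(cnt)),
      list(n_carriers = length(carriers),
           combined_frequency = length(carriers) / n_total))
  })
  freq <- data.table::rbindlist(rows)
  data.table::setnames(freq, c("fusion_id", pops, "n_carriers",
                               "combined_frequency"))
  present <- lapply(seq_len(nrow(freq)), function(i) {
    pops[as.integer(freq[i, pops, with = FALSE]) > 0]
  })
  carried <- lengths(present) > 0
  region <- vapply(present[carried], paste, "", collapse = "+")
  venn <- data.table::data.table(populations = names(table(region)),
                                 n_fusions = as.integer(table(region)))
  list(frequencies = freq, venn = venn)
}

#' Drop fusions whose partner genes are not expressed in every population
#'
#' A fusion is kept only if each partner gene has gene-level RPKM > 0 in at
#' least one sample of every population (so apparent population-specific
#' fusions cannot be explained by absent partner expression).
#'
#' @param calls A `fusion_calls` table.
#' @param gene_rpkm Matrix of gene-level RPKM (genes x samples), e.g. from
#'   [aggregate_gene_rpkm()].
#' @param cohort data.frame with `sample_id`, `population`.
#' @return Filtered `fusion_calls`.
#' @export
expression_presence_filter <- function(calls, gene_rpkm, cohort) {
  if (!nrow(calls)) return(calls)
  missing_genes <- setdiff(unique(c(calls$gene5, calls$gene3)),
                           rownames(gene_rpkm))
  if (length(missing_genes)) {
    stop("gene(s) missing from expression table: ",
         paste(missing_genes, collapse = ", "))
  }
  pops <- unique(cohort$population)
  # gene x population: any sample with positive RPKM?
  pos_by_pop <- vapply(pops, function(p) {
    samp <- intersect(cohort$sample_id[cohort$population == p],
                      colnames(gene_rpkm))
    apply(gene_rpkm[, samp, drop = FALSE] > 0, 1L, any)
  }, logical(nrow(gene_rpkm)))
  everywhere <- rownames(gene_rpkm)[apply(pos_by_pop, 1L, all)]
  calls[calls$gene5 %in% everywhere & calls$gene3 %in% everywhere]
}

#' Flag novel fusions against a known read-through list
#'
#' The comparison is order-sensitive: only the exact `(gene5, gene3)` pair
#' counts as known.
#'
#' @param calls A `fusion_calls` table.
#' @param known_pairs data.frame with `gene5`, `gene3` columns (may be
#'   empty).
#' @return `calls` with a logical `novel` column added.
#' @export
annotate_novelty <- function(calls, known_pairs) {
  known <- if (nrow(known_pairs)) {
    paste(known_pairs$gene5, known_pairs$gene3, sep = "\r")
  } else character(0)
  calls[, novel := !(paste(gene5, gene3, sep = "\r") %in% known)]
  calls[]
}

#' Build the filtered chimera catalog
#'
#' Runs the full catalog stage: split-read support filter, repeat filter,
#' orientation classification, breakpoint boundary status and distance for
#' tandem calls, per-population frequencies, optional expression-presence
#' filter and novelty annotation.
#'
#' @param calls A `fusion_calls` table.
#' @param annotation A `gene_annotation`.
#' @param cohort data.frame with `sample_id`, `population`.
#' @param repeats Optional repeat intervals ([parse_bed()]).
#' @param gene_rpkm Optional gene-level RPKM matrix for the
#'   expression-presence filter.
#' @param known_pairs Optional data.frame of known `(gene5, gene3)` pairs.
#' @param min_split_reads Strict split-read threshold (default 2).
#' @return List with `catalog` (annotated `fusion_calls`), `frequencies`
#'   and `venn` as in [population_frequencies()].
#' @export
build_catalog <- function(calls, annotation, cohort, repeats = NULL,
                          gene_rpkm = NULL, known_pairs = NULL,
                          min_split_reads = 2L) {
  kept <- apply_support_filter(calls, min_split_reads)
  if (!is.null(repeats)) kept <- apply_repeat_filter(kept, repeats)
  if (!is.null(gene_rpkm)) {
    kept <- expression_presence_filter(kept, gene_rpkm, cohort)
  }
  kept <- data.table::copy(kept)
  kept[, orientation := vapply(seq_len(.N), function(i) {
    classify_orientation(kept[i], annotation)
  }, "")]
  # boundary status and distance are defined for same-chromosome calls
  stat5 <- character(nrow(kept)); stat3 <- character(nrow(kept))
  dist <- rep(NA_integer_, nrow(kept))
  for (i in seq_len(nrow(kept))) {
    g5 <- annotation[[kept$gene5[i]]]
    g3 <- annotation[[kept$gene3[i]]]
    p5 <- best_boundary(kept$bp1[i], g5, "5prime")
    p3 <- best_boundary(kept$bp2[i], g3, "3prime")
    stat5[i] <- p5; stat3[i] <- p3
    if (kept$chrom5[i] == kept$chrom3[i]) {
      dist[i] <- abs(kept$bp2[i] - kept$bp1[i])
    }
  }
  kept[, `:=`(boundary5 = stat5, boundary3 = stat3, distance = dist)]
  if (is.null(known_pairs)) {
    known_pairs <- data.frame(gene5 = character(0), gene3 = character(0))
  }
  kept <- annotate_novelty(kept, known_pairs)
  pf <- population_frequencies(kept, cohort)
  kept[, combined_frequency := pf$frequencies$combined_frequency[
    match(fusion_id, pf$frequencies$fusion_id)]]
  list(catalog = kept, frequencies = pf$frequencies, venn = pf$venn)
}

# best (closest-to-boundary) status over all transcripts of a gene
best_boundary <- function(bp, gene, side) {
  rank <- c(AT_BOUNDARY = 1, NEAR_BOUNDARY = 2, INTRA_EXON = 3, INTRONIC = 4)
  best <- "INTRONIC"
  for (tx in gene$transcripts) {
    if (!bp_in_span(tx, bp)) next
    st <- boundary_status(bp, tx, side)
    if (rank[[st]] < rank[[best]]) best <- st
  }
  best
}

#' Write the catalog as TSV
#'
#' @param result Output of [build_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(result, path) {
  cat_dt <- data.table::copy(result$catalog)
  cat_dt[, carriers := vapply(carriers, paste, "", collapse = ",")]
  cat_dt[, combined_frequency := NULL]
  out <- merge(cat_dt, result$frequencies, by = "fusion_id", sort = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
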