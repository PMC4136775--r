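# Custom chimeric annotation: fused transcript models over all isoform
# combinations, emitted as GTF for an external quantifier, plus gene-level
# RPKM aggregation and the carrier-restricted expression comparison.

#' Fused gene id for a partner pair
#'
#' @param gene5,gene3 Partner gene ids.
#' @return `FUSION|<gene5>|<gene3>` (collision-free, grep-able).
#' @export
fused_gene_id <- function(gene5, gene3) paste("FUSION", gene5, gene3,
                                              sep = "|")

#' Build chimeric transcript models for one tandem fusion
#'
#' One fused transcript per (transcript5, transcript3) combination: the 5'
#' partner exons up to `bp1` followed by the 3' partner exons from `bp2`.
#' An exon spanning a breakpoint is truncated exactly at it (flagged via
#' the `truncated` attribute); exons entirely beyond the breakpoint are
#' dropped.  Near-boundary breakpoints (1-3 nt from an exon edge) are by
#' default snapped to the annotated boundary.  All fused transcripts of
#' one fusion share one new gene id ([fused_gene_id()]).
#'
#' @param call Tandem same-strand fusion call.
#' @param gene5,gene3 `gene_model`s of the partners.
#' @param snap_near_boundary Snap breakpoints 1-3 nt from an exon edge to
#'   that edge before building (default TRUE).
#' @return List of `transcript_model`s (possibly empty if no combination
#'   is compatible); each carries attributes `provenance` (source
#'   transcript ids) and `truncated` (any exon boundary modified).
#' @export
build_chimeric_transcripts <- function(call, gene5, gene3,
                                       snap_near_boundary = TRUE) {
  if (gene5$chrom != gene3$chrom || gene5$strand != gene3$strand) {
    stop("chimeric transcripts are built for tandem same-strand calls only")
  }
  strand <- gene5$strand
  gid <- fused_gene_id(gene5$gene_id, gene3$gene_id)
  out <- list()
  for (tx5 in gene5$transcripts) {
    bp1 <- call$bp1
    if (snap_near_boundary) bp1 <- snap_bp(bp1, tx5, "5prime")
    r5 <- retain_upto(tx5, bp1)
    if (!nrow(r5$kept)) {
      warning("bp1 upstream of transcript ", tx5$transcript_id,
              "; combination skipped")
      next
    }
    for (tx3 in gene3$transcripts) {
      bp2 <- call$bp2
      if (snap_near_boundary) bp2 <- snap_bp(bp2, tx3, "3prime")
      r3 <- retain_from(tx3, bp2)
      if (!nrow(r3$kept)) {
        warning("bp2 downstream of transcript ", tx3$transcript_id,
                "; combination skipped")
        next
      }
      exons <- rbind(r5$kept, r3$kept)
      tid <- paste(gid, tx5$transcript_id, tx3$transcript_id, sep = "|")
      fused <- transcript_model(tid, gid, gene5$chrom, strand, exons)
      attr(fused, "provenance") <- c(tx5 = tx5$transcript_id,
                                     tx3 = tx3$transcript_id,
                                     fusion_id = call$fusion_id)
      attr(fused, "truncated") <- any(r5$truncated) || any(r3$truncated)
      out[[length(out) + 1L]] <- fused
    }
  }
  out
}

# snap a breakpoint 1-3 nt from the retained-side exon edge onto the edge
snap_bp <- function(bp, tx, side) {
  if (!bp_in_span(tx, bp)) return(bp)
  st <- boundary_status(bp, tx, side)
  if (as.character(st) != "NEAR_BOUNDARY") return(bp)
  ex <- tx$exons
  edges <- if ((side == "5prime") == (tx$strand == "+")) ex$end - 1L
           else ex$start
  edges[which.min(abs(edges - bp))]
}

#' Build the custom annotation: original models plus fused transcripts
#'
#' @param catalog A `fusion_calls` table (only `TANDEM_SAME_STRAND` calls
#'   are fused; others pass through unrepresented).
#' @param annotation A `gene_annotation`.
#' @param snap_near_boundary See [build_chimeric_transcripts()].
#' @return A `gene_annotation` containing every original gene plus one
#'   fused gene per tandem fusion.
#' @export
build_custom_annotation <- function(catalog, annotation,
                                    snap_near_boundary = TRUE) {
  tandem <- catalog[catalog$orientation == "TANDEM_SAME_STRAND"]
  fused_genes <- list()
  for (i in seq_len(nrow(tandem))) {
    call <- tandem[i]
    txs <- build_chimeric_transcripts(call, annotation[[call$gene5]],
                                      annotation[[call$gene3]],
                                      snap_near_boundary)
    if (!length(txs)) next
    gid <- txs[[1]]$gene_id
    fused_genes[[gid]] <- gene_model(gid, gid, txs)
  }
  as_annotation(c(unclass(annotation), fused_genes))
}

#' Aggregate transcript RPKMs to gene level
#'
#' Gene-level RPKM is the per-sample sum of the RPKMs of all transcripts
#' sharing the gene id.
#'
#' @param expr An `expression_table`.
#' @return Numeric matrix, genes x samples.
#' @export
aggregate_gene_rpkm <- function(expr) {
  if (any(is.na(expr$gene_id)) || any(!nzchar(expr$gene_id))) {
    stop("transcript without gene id in expression table")
  }
  rowsum(expr$values, group = expr$gene_id)
}

#' Compare chimera and partner-gene expression in carrier samples
#'
#' For each fusion, the fused-gene RPKM and both partner-gene RPKMs are
#' collected over that fusion's carrier samples only (chimeras are absent
#' from non-carriers, whose zeros would otherwise swamp the comparison),
#' then pooled across fusions and compared with a two-sample KS test.
#'
#' @param gene_rpkm Gene-level RPKM matrix including fused genes
#'   ([aggregate_gene_rpkm()] on a table quantified against the custom
#'   annotation).
#' @param catalog A `fusion_calls` table with `carriers`.
#' @return List with `ks` (a `ks_result`), `median_chimera`,
#'   `median_partner`, `chimera_values`, `partner_values`, `n_skipped`
#'   (fusions with no carriers or absent from the matrix).
#' @export
compare_chimera_expression <- function(gene_rpkm, catalog) {
  chim <- numeric(0); part <- numeric(0); skipped <- 0L
  for (i in seq_len(nrow(catalog))) {
    call <- catalog[i]
    gid <- fused_gene_id(call$gene5, call$gene3)
    carriers <- intersect(as_carriers(call$carriers[[1]]),
                          colnames(gene_rpkm))
    if (!length(carriers) || !gid %in% rownames(gene_rpkm) ||
        !all(c(call$gene5, call$gene3) %in% rownames(gene_rpkm))) {
      skipped <- skipped + 1L
      next
    }
    chim <- c(chim, gene_rpkm[gid, carriers])
    part <- c(part, gene_rpkm[call$gene5, carriers],
              gene_rpkm[call$gene3, carriers])
  }
  if (!length(chim) || !length(part)) {
    stop("no carrier expression values to compare")
  }
  ks <- ks_two_sample(chim, part)
  list(ks = ks, median_chimera = stats::median(chim),
       median_partner = stats::median(part),
       chimera_values = chim, partner_values = part, n_skipped = skipped)
}
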