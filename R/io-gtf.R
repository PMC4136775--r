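#' Parse a Gencode-dialect GTF into gene models
#'
#' Reads `gene`/`transcript`/`exon`/`CDS` features, groups exon and CDS
#' records into transcripts and genes, and converts coordinates from the
#' GTF convention (1-based, inclusive) to the internal convention
#' (0-based, half-open).  Exons are ordered in transcription direction,
#' so they appear in reverse genomic order for minus-strand transcripts.
#'
#' @param path Path to a GTF file (plain text or gzip).
#' @return A `gene_annotation`: named list of [gene_model()] objects.
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 8L)) {
    bad <- which(body)[which(nf < 8L)[1]]
    stop("malformed GTF line ", bad, ": fewer than 8 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- S4Vectors::mcols(gr)$type %in% c("exon", "CDS")
  feat <- gr[keep]
  mc <- S4Vectors::mcols(feat)
  if (is.null(mc$transcript_id) || any(is.na(mc$transcript_id))) {
    stop("exon/CDS feature without transcript_id attribute")
  }
  if (is.null(mc$gene_id) || any(is.na(mc$gene_id))) {
    stop("exon/CDS feature without gene_id attribute")
  }
  ft <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(feat)),
    start = GenomicRanges::start(feat) - 1L,   # 1-based incl -> 0-based
    end = GenomicRanges::end(feat),            # inclusive end -> exclusive
    strand = as.character(GenomicRanges::strand(feat)),
    type = as.character(mc$type),
    gene_id = mc$gene_id,
    transcript_id = mc$transcript_id)
  gene_names <- gtf_gene_names(gr)

  tx_tabs <- split(ft, by = "transcript_id", sorted = TRUE)
  txs <- lapply(tx_tabs, function(tt) {
    strand <- tt$strand[1]
    dec <- (strand == "-")
    ex <- tt[tt$type == "exon"][order(start, decreasing = dec)]
    cd <- tt[tt$type == "CDS"][order(start, decreasing = dec)]
    transcript_model(tt$transcript_id[1], tt$gene_id[1], tt$chrom[1], strand,
                     as.data.frame(ex[, c("start", "end")]),
                     as.data.frame(cd[, c("start", "end")]))
  })
  by_gene <- split(txs, vapply(txs, `[[`, "", "gene_id"))
  genes <- lapply(names(by_gene), function(g) {
    nm <- if (g %in% names(gene_names)) gene_names[[g]] else g
    gene_model(g, nm, unname(by_gene[[g]]))
  })
  as_annotation(genes)
}

gtf_gene_names <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$gene_name)) return(character(0))
  ok <- !is.na(mc$gene_name) & !is.na(mc$gene_id)
  nm <- mc$gene_name[ok]
  names(nm) <- mc$gene_id[ok]
  nm[!duplicated(names(nm))]
}

#' Write gene models as a Gencode-dialect GTF
#'
#' Inverse of [parse_gtf()]: coordinates are converted back to 1-based
#' inclusive, and `gene`, `transcript`, `exon` and `CDS` feature lines are
#' emitted with `gene_id`, `gene_name` and `transcript_id` attributes.
#'
#' @param annotation A `gene_annotation` (named list of gene models).
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path, source = "tandemchimera") {
  out <- character(0)
  fmt <- function(chrom, type, start, end, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, source, type, start + 1L, end, strand, attrs)
  }
  for (g in annotation) {
    ga <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$gene_name)
    out <- c(out, fmt(g$chrom, "gene", g$start, g$end, g$strand, ga))
    for (tx in g$transcripts) {
      sp <- tx_span(tx)
      ta <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s";',
                    g$gene_id, g$gene_name, tx$transcript_id)
      out <- c(out, fmt(g$chrom, "transcript", sp[1], sp[2], g$strand, ta))
      ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
      out <- c(out, fmt(g$chrom, "exon", ex$start, ex$end, g$strand, ta))
      if (nrow(tx$cds)) {
        cd <- tx$cds[order(tx$cds$start), , drop = FALSE]
        out <- c(out, fmt(g$chrom, "CDS", cd$start, cd$end, g$strand, ta))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}
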