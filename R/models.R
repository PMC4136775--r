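# Internal coordinate convention: 0-based half-open [start, end) on the
# genome, everywhere.  GTF/VCF (1-based) are converted at the I/O boundary.
# Exons and CDS of a transcript are stored in TRANSCRIPTION order, i.e.
# reversed genomic order on the minus strand.

#' Construct a transcript model
#'
#' A transcript is an ordered set of exons (and optionally CDS intervals)
#' on one strand of one chromosome.  Intervals are 0-based half-open and
#' listed in transcription (5' to 3') order.
#'
#' @param transcript_id Character scalar.
#' @param gene_id Character scalar.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with integer columns `start`, `end`.
#' @param cds data.frame with integer columns `start`, `end` (may be empty);
#'   every CDS interval must be contained in an exon.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = empty_intervals()) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  cds <- as.data.frame(cds)[, c("start", "end")]
  tx <- structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons, cds = cds),
    class = "transcript_model")
  validate_transcript(tx)
  tx
}

empty_intervals <- function() data.frame(start = integer(0), end = integer(0))

validate_transcript <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 1L) stop("transcript ", tx$transcript_id, ": no exons")
  if (any(ex$start >= ex$end)) {
    stop("transcript ", tx$transcript_id, ": empty or inverted exon interval")
  }
  if (!tx$strand %in% c("+", "-")) {
    stop("transcript ", tx$transcript_id, ": strand must be '+' or '-'")
  }
  # transcription order: genomic starts increasing (+) or decreasing (-)
  if (nrow(ex) > 1L) {
    d <- diff(ex$start)
    ok <- if (tx$strand == "+") all(d > 0) else all(d < 0)
    if (!ok) stop("transcript ", tx$transcript_id,
                  ": exons not in transcription order")
    gs <- ex[order(ex$start), ]
    if (any(gs$start[-1] < gs$end[-nrow(gs)])) {
      stop("transcript ", tx$transcript_id, ": overlapping exons")
    }
  }
  if (nrow(tx$cds)) {
    inside <- vapply(seq_len(nrow(tx$cds)), function(i) {
      any(ex$start <= tx$cds$start[i] & tx$cds$end[i] <= ex$end)
    }, logical(1))
    if (!all(inside)) {
      stop("transcript ", tx$transcript_id, ": CDS interval outside exons")
    }
  }
  invisible(tx)
}

#' Construct a gene model
#'
#' @param gene_id,gene_name Identifiers.
#' @param transcripts List of [transcript_model()] objects sharing gene_id,
#'   chromosome and strand.
#' @return An object of class `gene_model` with a `span` covering all exons.
#' @export
gene_model <- function(gene_id, gene_name = gene_id, transcripts) {
  stopifnot(length(transcripts) >= 1L)
  chrom <- transcripts[[1]]$chrom
  strand <- transcripts[[1]]$strand
  for (tx in transcripts) {
    if (tx$gene_id != gene_id || tx$chrom != chrom || tx$strand != strand) {
      stop("gene ", gene_id, ": transcripts disagree on gene_id/chrom/strand")
    }
  }
  starts <- vapply(transcripts, function(t) min(t$exons$start), numeric(1))
  ends <- vapply(transcripts, function(t) max(t$exons$end), numeric(1))
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(
    list(gene_id = gene_id, gene_name = gene_name, chrom = chrom,
         strand = strand, start = min(starts), end = max(ends),
         transcripts = transcripts),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d [%s], %d transcript(s)\n",
              x$gene_id, x$gene_name, x$chrom, x$start, x$end, x$strand,
              length(x$transcripts)))
  invisible(x)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s [%s], %d exon(s), %d CDS\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

# genomic span of a transcript
tx_span <- function(tx) c(min(tx$exons$start), max(tx$exons$end))

#' Intron intervals of a transcript, in transcription order
#'
#' @param tx A `transcript_model`.
#' @return data.frame of 0-based half-open intron intervals (genomic
#'   coordinates, rows in transcription order); zero rows for a
#'   single-exon transcript.
#' @export
transcript_introns <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 2L) return(empty_intervals())
  gs <- ex[order(ex$start), ]
  introns <- data.frame(start = gs$end[-nrow(gs)], end = gs$start[-1])
  if (tx$strand == "-") introns <- introns[rev(seq_len(nrow(introns))), ]
  rownames(introns) <- NULL
  introns
}

total_cds_length <- function(tx) sum(tx$cds$end - tx$cds$start)

# Retained-region helpers.  bp1 = genomic 0-based position of the LAST
# retained base of the 5' partner; bp2 = FIRST retained base of the 3'
# partner.  "Retained" is a transcription-order prefix (5' side) or suffix
# (3' side).  Each returns list(kept = intervals in transcription order,
# truncated = logical per kept row, n_excluded = exons wholly dropped).
retain_upto <- function(tx, bp) {
  ex <- tx$exons
  if (tx$strand == "+") {
    whole <- ex$end - 1L <= bp
    part <- ex$start <= bp & bp < ex$end - 1L
    kept <- ex[whole | part, , drop = FALSE]
    trunc <- part[whole | part]
    kept$end[trunc] <- bp + 1L
  } else {
    whole <- ex$start >= bp
    part <- ex$start < bp & bp <= ex$end - 1L
    kept <- ex[whole | part, , drop = FALSE]
    trunc <- part[whole | part]
    kept$start[trunc] <- bp
  }
  excl <- nrow(ex) - nrow(kept)
  rownames(kept) <- NULL
  list(kept = kept, truncated = trunc, n_excluded = excl)
}

retain_from <- function(tx, bp) {
  ex <- tx$exons
  if (tx$strand == "+") {
    whole <- ex$start >= bp
    part <- ex$start < bp & bp < ex$end
    kept <- ex[whole | part, , drop = FALSE]
    trunc <- part[whole | part]
    kept$start[trunc] <- bp
  } else {
    whole <- ex$end - 1L <= bp
    part <- ex$start <= bp & bp < ex$end - 1L
    kept <- ex[whole | part, , drop = FALSE]
    trunc <- part[whole | part]
    kept$end[trunc] <- bp + 1L
  }
  excl <- nrow(ex) - nrow(kept)
  rownames(kept) <- NULL
  list(kept = kept, truncated = trunc, n_excluded = excl)
}

# overlap (nt) between an interval set and a genomic half-open window
interval_overlap_length <- function(iv, lo, hi) {
  if (!nrow(iv)) return(0L)
  sum(pmax(0L, pmin(iv$end, hi) - pmax(iv$start, lo)))
}

# CDS nt of tx retained on the 5' side of bp1 (transcription prefix)
cds_retained_upto <- function(tx, bp1) {
  if (tx$strand == "+") interval_overlap_length(tx$cds, -Inf, bp1 + 1L)
  else interval_overlap_length(tx$cds, bp1, Inf)
}

# CDS nt of tx excluded upstream (transcription sense) of bp2
cds_excluded_before <- function(tx, bp2) {
  if (tx$strand == "+") interval_overlap_length(tx$cds, -Inf, bp2)
  else interval_overlap_length(tx$cds, bp2 + 1L, Inf)
}

# does a genomic point fall inside the transcript span?
bp_in_span <- function(tx, bp) {
  sp <- tx_span(tx)
  bp >= sp[1] && bp < sp[2]
}

# carrier cells may arrive as character vectors or nested lists
as_carriers <- function(x) as.character(unlist(x))

# annotation = named list of gene_model
as_annotation <- function(genes) {
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  structure(genes, class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d gene(s) on %d chromosome(s)\n",
              length(x), length(unique(vapply(x, `[[`, "", "chrom")))))
  invisible(x)
}
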