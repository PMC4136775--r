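#' Default fusion-table column mapping
#'
#' Fusion-caller report headers vary by tool version, so the mapping from
#' the internal field names to the input columns is configurable.  The
#' default follows a FusionMap-like report layout.
#'
#' @return Named character vector: internal field -> input column name.
#' @export
fusion_column_map <- function() {
  c(fusion_id = "FusionID", gene5 = "KnownGene1", gene3 = "KnownGene2",
    chrom5 = "Chromosome1", chrom3 = "Chromosome2",
    bp1 = "Position1", bp2 = "Position2",
    split_reads = "SeedCount", carriers = "Samples")
}

#' Parse a fusion-call table
#'
#' Reads a tab-separated fusion report into a `fusion_calls` table.
#' Breakpoints are 0-based genomic positions; under the default input
#' convention `bp1` is the last retained base of the 5' partner and `bp2`
#' the first retained base of the 3' partner.  Duplicate rows with the same
#' `(gene5, gene3, bp1, bp2)` are merged: carrier sets are unioned and the
#' maximum split-read count is kept.
#'
#' @param path Path to the TSV file.
#' @param colmap Column mapping, see [fusion_column_map()].
#' @param annotation Optional `gene_annotation`; partner genes absent from
#'   it trigger a warning and are flagged in the `unknown_gene` column.
#' @param convention Breakpoint dialect of the input: `"last-retained"`
#'   (default; `bp1`/`bp2` are the last/first retained bases) or
#'   `"first-excluded"` (breakpoints sit one base beyond the transcript
#'   in transcription direction; requires `annotation` to resolve
#'   strands, and is converted to the internal convention).
#' @return data.table of class `fusion_calls` with list-column `carriers`.
#' @export
parse_fusion_table <- function(path, colmap = fusion_column_map(),
                               annotation = NULL,
                               convention = c("last-retained",
                                              "first-excluded")) {
  convention <- match.arg(convention)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = colmap[["carriers"]]))
  need <- setdiff(colmap, names(raw))
  if (length(need)) stop("fusion table missing column(s): ",
                         paste(need, collapse = ", "))
  calls <- data.table::data.table(
    fusion_id = as.character(raw[[colmap[["fusion_id"]]]]),
    gene5 = as.character(raw[[colmap[["gene5"]]]]),
    gene3 = as.character(raw[[colmap[["gene3"]]]]),
    chrom5 = as.character(raw[[colmap[["chrom5"]]]]),
    chrom3 = as.character(raw[[colmap[["chrom3"]]]]),
    bp1 = as.integer(raw[[colmap[["bp1"]]]]),
    bp2 = as.integer(raw[[colmap[["bp2"]]]]),
    split_reads = as.integer(raw[[colmap[["split_reads"]]]]),
    carriers = lapply(raw[[colmap[["carriers"]]]], split_carrier_field))
  # merge duplicate (gene5, gene3, bp1, bp2) records across samples
  key <- paste(calls$gene5, calls$gene3, calls$bp1, calls$bp2, sep = "\r")
  if (anyDuplicated(key)) {
    idx <- split(seq_len(nrow(calls)), key)
    keep <- vapply(idx, `[[`, 0L, 1L)
    merged <- calls[sort(keep)]
    for (grp in idx[lengths(idx) > 1L]) {
      j <- which(sort(keep) == grp[1])
      merged$split_reads[j] <- max(calls$split_reads[grp])
      merged$carriers[[j]] <- sort(unique(unlist(calls$carriers[grp])))
    }
    calls <- merged
  }
  if (!is.null(annotation)) {
    known <- names(annotation)
    calls[, unknown_gene := !(gene5 %in% known) | !(gene3 %in% known)]
    if (any(calls$unknown_gene)) {
      warning(sum(calls$unknown_gene),
              " fusion call(s) reference genes absent from the annotation")
    }
  }
  if (convention == "first-excluded") {
    if (is.null(annotation)) {
      stop("the first-excluded dialect needs an annotation to resolve ",
           "strands")
    }
    for (i in seq_len(nrow(calls))) {
      g5 <- annotation[[calls$gene5[i]]]; g3 <- annotation[[calls$gene3[i]]]
      if (is.null(g5) || is.null(g3)) next
      # one base beyond the transcript in transcription direction ->
      # step back onto the last/first retained base
      data.table::set(calls, i, "bp1",
                      calls$bp1[i] + if (g5$strand == "+") -1L else 1L)
      data.table::set(calls, i, "bp2",
                      calls$bp2[i] + if (g3$strand == "+") 1L else -1L)
    }
  }
  data.table::setattr(calls, "class",
                      c("fusion_calls", class(data.table::data.table())))
  calls[]
}

split_carrier_field <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  sort(unique(strsplit(x, ",", fixed = TRUE)[[1]]))
}

#' Write a fusion-call table
#'
#' @param calls A `fusion_calls` table.
#' @param path Output path.
#' @param colmap Column mapping used for the output header.
#' @return `path`, invisibly.
#' @export
write_fusion_table <- function(calls, path, colmap = fusion_column_map()) {
  out <- data.table::data.table(
    a = calls$fusion_id, b = calls$gene5, c = calls$gene3,
    d = calls$chrom5, e = calls$chrom3, f = calls$bp1, g = calls$bp2,
    h = calls$split_reads,
    i = vapply(calls$carriers, paste, "", collapse = ","))
  data.table::setnames(out, colmap[c("fusion_id", "gene5", "gene3", "chrom5",
                                     "chrom3", "bp1", "bp2", "split_reads",
                                     "carriers")])
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Parse a transcript-level RPKM table
#'
#' Expected layout: `transcript_id`, `gene_id`, then one numeric column per
#' sample.
#'
#' @param path Path to the TSV file.
#' @return An `expression_table`: list with `values` (matrix, transcripts x
#'   samples), `transcript_id`, `gene_id`, `samples`.
#' @export
parse_rpkm <- function(path) {
  raw <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(c("transcript_id", "gene_id") %in% names(raw))) {
    stop("RPKM table must start with transcript_id and gene_id columns")
  }
  samples <- setdiff(names(raw), c("transcript_id", "gene_id"))
  values <- as.matrix(raw[, samples, with = FALSE])
  rownames(values) <- raw$transcript_id
  if (anyDuplicated(raw$transcript_id)) {
    stop("duplicate transcript_id in RPKM table")
  }
  if (any(values < 0, na.rm = TRUE)) stop("negative RPKM value")
  structure(list(values = values, transcript_id = raw$transcript_id,
                 gene_id = raw$gene_id, samples = samples),
            class = "expression_table")
}

#' Write a transcript-level RPKM table
#'
#' @param expr An `expression_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rpkm <- function(expr, path) {
  dt <- data.table::data.table(transcript_id = expr$transcript_id,
                               gene_id = expr$gene_id)
  dt <- cbind(dt, data.table::as.data.table(expr$values))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d transcript(s) x %d sample(s)\n",
              nrow(x$values), length(x$samples)))
  invisible(x)
}

#' Read a FASTQ file
#'
#' @param path Path to a FASTQ file.
#' @return data.frame with `id`, `seq`, `qual` (character columns).
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  data.frame(id = names(ss), seq = as.character(ss),
             qual = as.character(S4Vectors::mcols(ss)$qualities),
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' @param reads data.frame with `id`, `seq` and optionally `qual`
#'   (defaults to constant quality "I").
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if (is.null(reads$qual)) {
    vapply(nchar(reads$seq), function(n) strrep("I", n), "")
  } else reads$qual
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), con)
  invisible(path)
}
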