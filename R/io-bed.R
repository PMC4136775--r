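#' Parse a BED3/BED6 interval file
#'
#' BED is already 0-based half-open, so coordinates are adopted unchanged.
#' Optional name, score and strand columns are retained when present.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (strand `"*"` when unstranded).
#' @export
parse_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    score = if (!is.null(gr$score)) gr$score else NA_real_,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) {
    bad <- which(out$start >= out$end)[1]
    stop("BED interval with start >= end at record ", bad)
  }
  out
}

#' Write intervals as BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  iv <- as.data.frame(intervals)
  cols <- paste(iv$chrom, iv$start, iv$end, sep = "\t")
  if (!is.null(iv$name) && !all(is.na(iv$name))) {
    nm <- ifelse(is.na(iv$name), ".", iv$name)
    sc <- if (is.null(iv$score)) 0 else ifelse(is.na(iv$score), 0, iv$score)
    st <- if (is.null(iv$strand)) "." else ifelse(iv$strand %in% c("+", "-"),
                                                  iv$strand, ".")
    cols <- paste(cols, nm, sc, st, sep = "\t")
  }
  writeLines(cols, path)
  invisible(path)
}

# TRUE for each point falling inside any half-open interval on its chromosome
point_in_intervals <- function(chrom, pos, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(pos)))
  vapply(seq_along(pos), function(i) {
    any(intervals$chrom == chrom[i] &
          intervals$start <= pos[i] & pos[i] < intervals$end)
  }, logical(1))
}
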