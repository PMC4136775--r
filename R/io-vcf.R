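#' Parse a VCF into a genotype table of allele dosages
#'
#' Genotypes are recoded as unphased alternative-allele dosages: `0/0` -> 0,
#' `0/1` or `1/0` -> 1, `1/1` -> 2, `./.` -> `NA`.  Phased separators (`|`)
#' are treated like `/`.  Multi-allelic sites are split into one record per
#' alternative allele; the dosage of record k counts how many of the two
#' called alleles equal k.
#'
#' @param path Path to a VCF 4.x file (plain or gzip).
#' @param sample_ids Optional character vector: restrict (and order) the
#'   samples.  An error lists any requested sample absent from the file.
#' @return A `genotype_table`: list with `variants` (data.table: chrom,
#'   pos (1-based), variant_id, ref, alt, is_deletion), `dosages` (integer
#'   matrix, variants x samples, `NA` = missing) and `samples`.
#' @export
parse_vcf <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  all_samples <- colnames(vcf)
  if (is.null(sample_ids)) {
    sample_ids <- all_samples
  } else {
    absent <- setdiff(sample_ids, all_samples)
    if (length(absent)) {
      stop("samples absent from VCF: ", paste(absent, collapse = ", "))
    }
  }
  gt <- VariantAnnotation::geno(vcf)$GT[, sample_ids, drop = FALSE]
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt_list <- lapply(rr$ALT, as.character)
  ids <- names(rr)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)

  # fast path: all biallelic with standard GT codes
  code <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
            "1|0" = 1L, "1/1" = 2L, "1|1" = 2L, "./." = NA_integer_,
            ".|." = NA_integer_, "." = NA_integer_)
  if (all(lengths(alt_list) == 1L) && all(gt %in% names(code))) {
    dosages <- matrix(code[gt], nrow = nrow(gt))
    alt <- vapply(alt_list, `[[`, "", 1L)
    vid <- ifelse(is.na(ids) | ids %in% c(".", ""),
                  paste(chrom, pos, ref, alt, sep = ":"), ids)
    variants <- data.table::data.table(
      chrom = chrom, pos = pos, variant_id = vid, ref = ref, alt = alt,
      is_deletion = nchar(ref) > nchar(alt))
    rownames(dosages) <- vid
    colnames(dosages) <- sample_ids
    return(structure(list(variants = variants, dosages = dosages,
                          samples = sample_ids),
                     class = "genotype_table"))
  }

  rows <- list(); dos <- list(); r <- 0L
  for (i in seq_along(ids)) {
    alleles <- strsplit(gt[i, ], "[/|]")
    for (k in seq_along(alt_list[[i]])) {
      alt <- alt_list[[i]][k]
      d <- vapply(alleles, function(a) {
        if (any(a == ".")) return(NA_integer_)
        sum(a == as.character(k))
      }, integer(1))
      vid <- ids[i]
      if (is.na(vid) || vid == "." || vid == "") {
        vid <- paste(chrom[i], pos[i], ref[i], alt, sep = ":")
      } else if (length(alt_list[[i]]) > 1L) {
        vid <- paste(vid, alt, sep = ":")
      }
      r <- r + 1L
      rows[[r]] <- data.table::data.table(
        chrom = chrom[i], pos = pos[i], variant_id = vid, ref = ref[i],
        alt = alt, is_deletion = nchar(ref[i]) > nchar(alt))
      dos[[r]] <- d
    }
  }
  variants <- data.table::rbindlist(rows)
  dosages <- do.call(rbind, dos)
  rownames(dosages) <- variants$variant_id
  colnames(dosages) <- sample_ids
  structure(list(variants = variants, dosages = dosages,
                 samples = sample_ids),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d variant(s) x %d sample(s)\n",
              nrow(x$variants), length(x$samples)))
  invisible(x)
}

#' Write a genotype table as a minimal VCF 4.2 file
#'
#' Dosages are rendered as unphased GT strings (0 -> `0/0`, 1 -> `0/1`,
#' 2 -> `1/1`, `NA` -> `./.`).
#'
#' @param gt A `genotype_table` as returned by [parse_vcf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path) {
  codes <- c("0/0", "0/1", "1/1")
  g <- matrix(codes[gt$dosages + 1L], nrow = nrow(gt$dosages))
  g[is.na(gt$dosages)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gt$samples), collapse = "\t"))
  v <- gt$variants
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".",
                "GT", sep = "\t")
  body <- paste(body, apply(g, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
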