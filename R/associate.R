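# Case/control association of chimera presence with genetic variants:
# per-fusion variant extraction, MAF filter, Cochran-Armitage scan with
# per-fusion Bonferroni correction and carrier odds ratios, plus poly(A)
# and RBP-site annotation of variants and poly(A)-read selection.

#' Select fusions frequent enough to test for association
#'
#' @param frequencies data.table from [population_frequencies()] (needs
#'   `fusion_id`, `combined_frequency`).
#' @param min_freq Strict lower bound on pooled carrier frequency
#'   (default 0.05).
#' @return Character vector of fusion ids.
#' @export
select_testable_fusions <- function(frequencies, min_freq = 0.05) {
  frequencies$fusion_id[frequencies$combined_frequency > min_freq]
}

#' Variants inside the partner-gene loci of a fusion
#'
#' The tested interval is the union of the two partner-gene spans, each
#' extended by `flank` nucleotides on both sides.
#'
#' @param call Fusion call with `gene5`, `gene3`.
#' @param annotation A `gene_annotation`.
#' @param genotypes A `genotype_table`.
#' @param flank Extension in nt (default 200).
#' @return Row indices into `genotypes$variants`.
#' @export
variants_in_fusion_interval <- function(call, annotation, genotypes,
                                        flank = 200L) {
  stopifnot(flank >= 0)
  g5 <- annotation[[call$gene5]]; g3 <- annotation[[call$gene3]]
  v <- genotypes$variants
  pos0 <- v$pos - 1L                    # VCF is 1-based
  in_span <- function(g) {
    v$chrom == g$chrom & pos0 >= g$start - flank & pos0 < g$end + flank
  }
  which(in_span(g5) | in_span(g3))
}

#' Case/control trend-test scan for one fusion
#'
#' Samples carrying the fusion are cases, all others controls.  Variants
#' with minor allele frequency at or below `maf_min` are dropped (and
#' optionally indels); each remaining variant is tested with the
#' Cochran-Armitage trend test on the 2x3 dosage table (missing genotypes
#' excluded pairwise), Bonferroni-adjusted with m = the number of variants
#' tested for this fusion, and annotated with the carrier odds ratio.
#'
#' @param call Fusion call with `fusion_id`, `carriers`.
#' @param genotypes A `genotype_table`.
#' @param variant_idx Indices of the candidate variants (e.g. from
#'   [variants_in_fusion_interval()]); default all.
#' @param cohort data.frame with `sample_id` (defines the tested cohort).
#' @param maf_min Strict MAF threshold (default 0.05).
#' @param include_indels Include deletion/insertion records (default
#'   FALSE: SNVs only).
#' @param or_mode `"carrier"` (default): the odds ratio counts
#'   individuals with >= 1 alternative allele; `"allelic"`: it counts
#'   chromosomes (2 per individual).
#' @return data.table of class `association_results`, one row per tested
#'   variant: chrom, pos, variant_id, ref, alt, raw_p, adjusted_p, chi2,
#'   or_value, ci_low, ci_high, or_corrected, n_cases, n_controls,
#'   tested_m, significant.
#' @export
fusion_case_control_scan <- function(call, genotypes,
                                     variant_idx = NULL, cohort,
                                     maf_min = 0.05,
                                     include_indels = FALSE,
                                     or_mode = c("carrier", "allelic")) {
  or_mode <- match.arg(or_mode)
  if (is.null(variant_idx)) variant_idx <- seq_len(nrow(genotypes$variants))
  samples <- intersect(cohort$sample_id, genotypes$samples)
  carriers <- intersect(as_carriers(call$carriers[[1]]), samples)
  is_case <- samples %in% carriers
  dos <- genotypes$dosages[variant_idx, samples, drop = FALSE]
  v <- genotypes$variants[variant_idx]

  keep <- rep(TRUE, nrow(v))
  if (!include_indels) keep <- nchar(v$ref) == 1L & nchar(v$alt) == 1L
  usable <- rowSums(!is.na(dos)) > 0L
  keep <- keep & usable
  maf <- rep(NA_real_, nrow(v))
  maf[keep] <- apply(dos[keep, , drop = FALSE], 1L, minor_allele_frequency)
  keep <- keep & !is.na(maf) & maf > maf_min
  v <- v[keep]; dos <- dos[keep, , drop = FALSE]
  m <- nrow(v)
  if (!m) return(empty_association())

  rows <- lapply(seq_len(m), function(j) {
    d <- dos[j, ]
    ok <- !is.na(d)
    dj <- d[ok]; cs <- is_case[ok]
    cases <- tabulate(dj[cs] + 1L, 3L)
    controls <- tabulate(dj[!cs] + 1L, 3L)
    tt <- cochran_armitage_trend(cases, controls)
    orr <- if (or_mode == "carrier") {
      carrier_odds_ratio(sum(cases[2:3]), cases[1],
                         sum(controls[2:3]), controls[1])
    } else {
      carrier_odds_ratio(sum(dj[cs]), 2 * sum(cs) - sum(dj[cs]),
                         sum(dj[!cs]), 2 * sum(!cs) - sum(dj[!cs]))
    }
    data.table::data.table(
      fusion_id = call$fusion_id, variant_id = v$variant_id[j],
      chrom = v$chrom[j], pos = v$pos[j], ref = v$ref[j], alt = v$alt[j],
      maf = maf_of(dj), raw_p = tt$p, chi2 = tt$chi2,
      or_value = orr$or_value, ci_low = orr$ci_low, ci_high = orr$ci_high,
      or_corrected = orr$corrected,
      n_cases = sum(cs), n_controls = sum(!cs))
  })
  res <- data.table::rbindlist(rows)
  res[, tested_m := m]
  res[, adjusted_p := bonferroni_adjust(raw_p, m)]
  res[, significant := adjusted_p < 0.05]
  data.table::setattr(res, "class",
                      c("association_results", class(data.table::data.table())))
  res[]
}

maf_of <- function(d) minor_allele_frequency(d)

empty_association <- function() {
  res <- data.table::data.table(
    fusion_id = character(0), variant_id = character(0), chrom = character(0),
    pos = integer(0), ref = character(0), alt = character(0), maf = numeric(0),
    raw_p = numeric(0), chi2 = numeric(0), or_value = numeric(0),
    ci_low = numeric(0), ci_high = numeric(0), or_corrected = logical(0),
    n_cases = integer(0), n_controls = integer(0), tested_m = integer(0),
    adjusted_p = numeric(0), significant = logical(0))
  data.table::setattr(res, "class",
                      c("association_results", class(data.table::data.table())))
  res[]
}

#' Write association results with report-style column names
#'
#' Emits the conventional per-variant report layout: Gene, Chr, Position,
#' SNP, p_value, adjusted p-value, Ref/Alt, Odd ratio, 95% CI, plus
#' tested_m and the carrier counts.
#'
#' @param results An `association_results` table.
#' @param path Output path.
#' @param gene Optional character vector (parallel to `results`) naming
#'   the fusion's 5' partner gene; defaults to the fusion id.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(results, path, gene = NULL) {
  out <- data.table::data.table(
    Gene = if (is.null(gene)) results$fusion_id else gene,
    Chr = results$chrom, Position = results$pos, SNP = results$variant_id,
    p_value = results$raw_p, `adjusted p-value` = results$adjusted_p,
    `Ref/Alt` = paste(results$ref, results$alt, sep = "/"),
    `Odd ratio` = results$or_value,
    `95% CI` = sprintf("%.2f-%.2f", results$ci_low, results$ci_high),
    tested_m = results$tested_m, n_cases = results$n_cases,
    n_controls = results$n_controls)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Most significant variant per fusion
#'
#' Argmin of the raw p-value within each fusion's family; ties broken by
#' smaller genomic position, then lexicographic variant id.
#'
#' @param results An `association_results` table (possibly several
#'   fusions).
#' @return One row per fusion.
#' @export
top_variant_per_fusion <- function(results) {
  if (!nrow(results)) return(results)
  res <- data.table::setorder(data.table::copy(results),
                              fusion_id, raw_p, pos, variant_id)
  res[, .SD[1], by = fusion_id]
}

#' Annotate variants with overlapping interval features
#'
#' Each variant gets the labels of every feature interval containing its
#' position (half-open: a variant at a feature's `end` coordinate does not
#' overlap).
#'
#' @param variants data.table with `chrom`, `pos` (1-based).
#' @param features data.frame with `chrom`, `start`, `end`, `name`.
#' @return `variants` with a `features` character column
#'   (comma-separated labels, "" when none).
#' @export
overlap_variants_with_features <- function(variants, features) {
  pos0 <- variants$pos - 1L
  labs <- vapply(seq_len(nrow(variants)), function(i) {
    hit <- features$chrom == variants$chrom[i] &
      features$start <= pos0[i] & pos0[i] < features$end
    paste(features$name[hit], collapse = ",")
  }, "")
  out <- data.table::copy(data.table::as.data.table(variants))
  out[, features := labs]
  out[]
}

#' Screen 5'-partner poly(A) features for overlapping variants
#'
#' For each fusion's 5' partner gene, reports variants falling inside its
#' annotated poly(A) signal/site features, keeping only variants whose MAF
#' is at least the fusion's pooled carrier frequency (a causal poly(A)
#' variant cannot be rarer than the chimera it would explain).  Deletions
#' and SNVs are flagged separately.
#'
#' @param catalog A `fusion_calls` table with `combined_frequency`.
#' @param genotypes A `genotype_table`.
#' @param polya_features data.frame with `chrom`, `start`, `end`, `name`
#'   (feature type), `gene_id` column attributing features to 5' partner
#'   genes.
#' @return data.table: fusion_id, gene_id, feature, variant_id, pos, maf,
#'   is_deletion, retained; genes without any feature appear once with
#'   `feature = "no feature"`.
#' @export
polyA_variant_screen <- function(catalog, genotypes, polya_features) {
  v <- genotypes$variants
  maf <- apply(genotypes$dosages, 1L, function(d) {
    if (all(is.na(d))) NA_real_ else minor_allele_frequency(d)
  })
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    call <- catalog[i]
    feats <- polya_features[polya_features$gene_id == call$gene5, ,
                            drop = FALSE]
    if (!nrow(feats)) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        fusion_id = call$fusion_id, gene_id = call$gene5,
        feature = "no feature", variant_id = NA_character_,
        pos = NA_integer_, maf = NA_real_, is_deletion = NA,
        retained = NA)
      next
    }
    for (k in seq_len(nrow(feats))) {
      hit <- which(v$chrom == feats$chrom[k] &
                     v$pos - 1L >= feats$start[k] &
                     v$pos - 1L < feats$end[k])
      for (j in hit) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          fusion_id = call$fusion_id, gene_id = call$gene5,
          feature = feats$name[k], variant_id = v$variant_id[j],
          pos = v$pos[j], maf = maf[j], is_deletion = v$is_deletion[j],
          retained = !is.na(maf[j]) &
            maf[j] >= call$combined_frequency)
      }
    }
  }
  if (!length(rows)) {
    return(data.table::data.table(
      fusion_id = character(0), gene_id = character(0),
      feature = character(0), variant_id = character(0), pos = integer(0),
      maf = numeric(0), is_deletion = logical(0), retained = logical(0)))
  }
  data.table::rbindlist(rows)
}

#' Select and trim poly(A)-tailed / poly(T)-headed reads
#'
#' Keeps reads ending in a poly(A) tail of at least `min_tail` nt
#' (allowing up to `max_other_fraction` non-A bases inside the run) or
#' starting with the symmetric poly(T) head; the tail/head is trimmed.
#' Trimmed remainders shorter than `min_stub` nt or with dinucleotide
#' Shannon entropy below `complexity_threshold` bits are discarded as low
#' complexity.
#'
#' @param reads data.frame with `id`, `seq` (and optionally `qual`,
#'   trimmed alongside).
#' @param min_tail Minimum tail/head length (default 8).
#' @param max_other_fraction Maximum fraction of non-A (non-T) bases
#'   tolerated inside the run (default 0.1).
#' @param complexity_threshold Minimum dinucleotide entropy in bits
#'   (default 1.0).
#' @param min_stub Minimum trimmed-read length (default 20).
#' @return data.frame of kept reads (`id`, `seq`, `qual` if present) with
#'   columns `tail_type` (`"polyA"`/`"polyT"`) and `trimmed_nt`.
#' @export
polyA_read_selection <- function(reads, min_tail = 8L,
                                 max_other_fraction = 0.1,
                                 complexity_threshold = 1.0,
                                 min_stub = 20L) {
  stopifnot(min_tail >= 1)
  keep <- list()
  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    tail_len <- homopolymer_run(rev_chars(s), "A", max_other_fraction)
    head_len <- homopolymer_run(s, "T", max_other_fraction)
    type <- NULL; trim <- 0L
    if (tail_len >= min_tail && tail_len >= head_len) {
      type <- "polyA"; trim <- tail_len
      stub <- substr(s, 1L, nchar(s) - trim)
      qual <- if (!is.null(reads$qual)) substr(reads$qual[i], 1L,
                                               nchar(s) - trim)
    } else if (head_len >= min_tail) {
      type <- "polyT"; trim <- head_len
      stub <- substr(s, trim + 1L, nchar(s))
      qual <- if (!is.null(reads$qual)) substr(reads$qual[i], trim + 1L,
                                               nchar(reads$qual[i]))
    }
    if (is.null(type)) next
    if (nchar(stub) < min_stub) next
    if (dinucleotide_entropy(stub) < complexity_threshold) next
    row <- data.frame(id = reads$id[i], seq = stub,
                      tail_type = type, trimmed_nt = trim,
                      stringsAsFactors = FALSE)
    if (!is.null(reads$qual)) row$qual <- qual
    keep[[length(keep) + 1L]] <- row
  }
  out <- if (!length(keep)) {
    o <- data.frame(id = character(0), seq = character(0),
                    tail_type = character(0), trimmed_nt = integer(0),
                    stringsAsFactors = FALSE)
    if (!is.null(reads$qual)) o$qual <- character(0)
    o
  } else {
    do.call(rbind, keep)
  }
  # selection parameters travel with the result (logged on write)
  attr(out, "params") <- c(min_tail = min_tail,
                           max_other_fraction = max_other_fraction,
                           complexity_threshold = complexity_threshold,
                           min_stub = min_stub)
  out
}

rev_chars <- function(s) {
  paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

# longest prefix run of `base` allowing a bounded fraction of other bases,
# required to start and end on `base`
homopolymer_run <- function(s, base, max_other_fraction) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!length(ch) || ch[1] != base) return(0L)
  best <- 0L
  other <- 0L
  for (k in seq_along(ch)) {
    if (ch[k] != base) other <- other + 1L
    if (other <= max_other_fraction * k && ch[k] == base) best <- k
  }
  best
}

# Shannon entropy (bits) over overlapping dinucleotides
dinucleotide_entropy <- function(s) {
  n <- nchar(s)
  if (n < 2L) return(0)
  di <- substring(s, 1:(n - 1L), 2:n)
  p <- table(di) / (n - 1L)
  -sum(p * log2(p))
}
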