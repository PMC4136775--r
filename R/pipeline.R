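# End-to-end driver and a small command-line front end mirroring the
# stage interfaces: simulate, catalog, characterize, annotate,
# expression-report, associate.

#' Run the full pipeline on files in a directory
#'
#' Convenience driver: reads the study files (as emitted by
#' [simulate_study()]), builds the catalog, characterizes tandem fusions,
#' builds the custom chimeric annotation, compares expression and runs the
#' association scan for every testable fusion.  Outputs are written as
#' TSV/GTF next to the inputs (prefix `out_`).
#'
#' @param dir Directory containing `annotation.gtf`, `fusions.tsv`,
#'   `cohort.tsv`, and optionally `repeats.bed`, `rpkm.tsv`,
#'   `genotypes.vcf`.
#' @param min_split_reads,min_fusion_freq,min_maf,flank Stage thresholds.
#' @return List with `catalog`, `frequencies`, `venn`, `characterization`,
#'   `custom_annotation`, `expression` (NULL without rpkm.tsv),
#'   `association` (NULL without genotypes.vcf).
#' @export
run_pipeline <- function(dir, min_split_reads = 2L, min_fusion_freq = 0.05,
                         min_maf = 0.05, flank = 200L) {
  p <- function(f) file.path(dir, f)
  annotation <- parse_gtf(p("annotation.gtf"))
  calls <- parse_fusion_table(p("fusions.tsv"), annotation = annotation)
  cohort <- utils::read.table(p("cohort.tsv"), header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  repeats <- if (file.exists(p("repeats.bed"))) parse_bed(p("repeats.bed"))
  cat_res <- build_catalog(calls, annotation, cohort, repeats = repeats,
                           min_split_reads = min_split_reads)
  char_res <- characterize_fusions(cat_res$catalog, annotation)
  custom <- build_custom_annotation(cat_res$catalog, annotation)
  write_catalog(cat_res, p("out_catalog.tsv"))
  data.table::fwrite(char_res$characterization, p("out_characterization.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(char_res$pattern_table, p("out_patterns.tsv"),
                     sep = "\t", quote = FALSE)
  write_gtf(custom, p("out_custom.gtf"))

  expression <- NULL
  if (file.exists(p("rpkm.tsv"))) {
    expr <- parse_rpkm(p("rpkm.tsv"))
    gene_rpkm <- aggregate_gene_rpkm(expr)
    tandem <- cat_res$catalog[cat_res$catalog$orientation ==
                                "TANDEM_SAME_STRAND"]
    expression <- compare_chimera_expression(gene_rpkm, tandem)
    data.table::fwrite(data.table::data.table(
      D = expression$ks$D, p = expression$ks$p,
      median_chimera = expression$median_chimera,
      median_partner = expression$median_partner),
      p("out_expression.tsv"), sep = "\t", quote = FALSE)
  }

  association <- NULL
  if (file.exists(p("genotypes.vcf"))) {
    genotypes <- parse_vcf(p("genotypes.vcf"))
    testable <- select_testable_fusions(cat_res$frequencies, min_fusion_freq)
    res_list <- list()
    for (fid in testable) {
      call <- cat_res$catalog[cat_res$catalog$fusion_id == fid]
      if (call$orientation != "TANDEM_SAME_STRAND") next
      idx <- variants_in_fusion_interval(call, annotation, genotypes, flank)
      if (!length(idx)) next
      res_list[[fid]] <- fusion_case_control_scan(call, genotypes, idx,
                                                  cohort, maf_min = min_maf)
    }
    association <- data.table::rbindlist(res_list)
    if (nrow(association)) {
      data.table::fwrite(association, p("out_association.tsv"), sep = "\t",
                         quote = FALSE)
      write_association_table(top_variant_per_fusion(association),
                              p("out_top_variants.tsv"))
    }
  }
  list(catalog = cat_res$catalog, frequencies = cat_res$frequencies,
       venn = cat_res$venn, characterization = char_res$characterization,
       pattern_table = char_res$pattern_table,
       length_comparison = char_res$length_comparison,
       custom_annotation = custom, expression = expression,
       association = association)
}

#' Command-line entry point
#'
#' Subcommands: `simulate --out DIR [--seed N]`, `pipeline --dir DIR`,
#' `catalog --fusions F.tsv --gtf A.gtf --cohort C.tsv [--repeats R.bed]
#' [--min-split-reads 2] --out OUT.tsv`.  Installed alongside the package
#' as `exec/tandemchimera`.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the result of the subcommand.
#' @export
chimera_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: tandemchimera <simulate|pipeline|catalog> ",
                          "[--key value ...]")
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  switch(cmd,
    simulate = {
      spec <- cohort_spec(seed = as.integer(opts[["seed"]] %||% "1"))
      invisible(simulate_study(spec, opts[["out"]]))
    },
    pipeline = invisible(run_pipeline(
      opts[["dir"]],
      min_split_reads = as.integer(opts[["min-split-reads"]] %||% "2"))),
    catalog = {
      annotation <- parse_gtf(opts[["gtf"]])
      calls <- parse_fusion_table(opts[["fusions"]], annotation = annotation)
      cohort <- utils::read.table(opts[["cohort"]], header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
      repeats <- if (!is.null(opts[["repeats"]])) parse_bed(opts[["repeats"]])
      res <- build_catalog(calls, annotation, cohort, repeats = repeats,
                           min_split_reads =
                             as.integer(opts[["min-split-reads"]] %||% "2"))
      write_catalog(res, opts[["out"]])
      invisible(res)
    },
    stop("unknown subcommand: ", cmd))
}

parse_cli_opts <- function(args) {
  keys <- grep("^--", args)
  if (any(keys + 1L > length(args))) stop("option without value")
  stats::setNames(as.list(args[keys + 1L]), sub("^--", "", args[keys]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
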