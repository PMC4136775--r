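Package: tandemchimera
Title: Cataloging, Characterization and Genetic Association of Tandem RNA
    Chimeras in Population-Scale RNA-Seq
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to catalog and filter read-through (tandem) chimeric
    transcript calls against a gene annotation, classify their structure
    (genuine read-through, promoter swap, 3' UTR swap, in-frame and
    out-of-frame junctions), enumerate exon-exclusion patterns across all
    transcript isoform combinations, build custom chimeric transcript
    annotations for external quantifiers, compare chimera and partner-gene
    expression, characterize breakpoint-flanking intron lengths, and scan
    for genetic variants associated with chimera presence using a
    case/control Cochran-Armitage trend test. A synthetic-cohort generator
    emits self-consistent annotation, fusion calls, genotypes, expression
    tables and reads so that every pipeline stage is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
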