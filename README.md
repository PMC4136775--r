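# tandemchimera

Tools for studying **tandem RNA chimeras** — read-through transcripts that
splice together exons of two adjacent genes on the same strand — in
population-scale RNA-seq cohorts.

Read-through (conjoined-gene) transcripts are not a cancer-only
phenomenon: they occur in healthy tissue, mostly at low population
frequency, and their formation mechanism is unclear. Given fusion calls
from a split-read caller, a gene annotation, per-sample genotypes and
transcript-level expression, this package:

* **catalogs** the calls — split-read support filter (keep > 2 supporting
  reads), repeat-element breakpoint filter, orientation classification
  (tandem same-strand / inverted / different-strand / interchromosomal),
  breakpoint-vs-exon-boundary status, breakpoint distance `|bp2 − bp1|`,
  per-population carrier frequencies with venn-region counts, a
  partner-gene expression-presence filter and novelty annotation;
* **characterizes** each tandem chimera structurally — *genuine
  read-through* (both coding sequences intact), *promoter swap* (3′
  partner CDS under the 5′ partner promoter), *3′ UTR swap*, or a
  truncating junction that is *in-frame* / *out-of-frame* (in-frame iff
  `L5 ≡ S3 (mod 3)`, where `L5` is the retained coding length of the 5′
  partner and `S3` the excluded coding length of the 3′ partner);
  enumerates exon-exclusion patterns `(k5, k3)` over **all** transcript
  isoform combinations; and compares breakpoint-flanking intron lengths
  against the partner genes' other introns with a two-sample
  Kolmogorov–Smirnov test;
* **builds a custom chimeric annotation** (fused transcripts for every
  isoform combination, emitted as GTF for an external quantifier such as
  Flux Capacitor), aggregates transcript RPKM to gene level, and compares
  chimera vs partner-gene expression restricted to carrier samples;
* **associates** chimera presence with genetic variants: per fusion, all
  variants on the partner genes ±200 nt with minor allele frequency
  > 5% are tested with the **Cochran–Armitage trend test**
  (`T = Σ wᵢ(rᵢS − sᵢR)`, `χ² = T²/Var(T)`, weights 0/1/2) comparing
  carriers (cases) with non-carriers (controls), Bonferroni-adjusted
  within each fusion's variant family, with carrier odds ratios and 95%
  Wald intervals — plus poly(A)-site/RBP-site variant annotation and a
  poly(A)-read selection/trimming utility;
* **simulates** a fully self-consistent synthetic study (annotation,
  462-sample five-population cohort, fusion truth, genotypes with
  injected intronic causal variants at a chosen carrier odds ratio,
  expression, reads) so every stage is testable closed-loop against known
  truth.

## Worked example

```r
library(tandemchimera)

spec  <- cohort_spec(seed = 42, n_tandem = 40, n_testable = 4)
study <- simulate_study(spec, file.path(tempdir(), "demo"))
res   <- run_pipeline(file.path(tempdir(), "demo"))

table(res$catalog$orientation)
#>             INTERCHROM INTRACHROM_DIFF_STRAND   SAME_STRAND_INVERTED
#>                     10                     10                      8
#>     TANDEM_SAME_STRAND
#>                     40

res$pattern_table[1:3]          # exon-exclusion patterns, modal (1,1)
#>       k5    k3 weight
#> 1:     1     1   0.35
#> 2:     2     1   0.20
#> 3:     1     2   0.15

res$length_comparison$intron5$ks   # flanking introns vs background
#> Two-sample KS: D = 0.3513, p = 5.925e-08 (n = 80, 575)

res$expression$ks                  # chimera vs partner RPKM (carriers only)
#> Two-sample KS: D = 0.5833, p = 3.536e-70 (n = 354, 708)
round(c(res$expression$median_chimera, res$expression$median_partner), 2)
#> [1] 1.40 5.60

top_variant_per_fusion(res$association)[
  , .(fusion_id, variant_id, raw_p = signif(raw_p, 3),
      adjusted_p = signif(adjusted_p, 3), or = round(or_value, 2))]
#>    fusion_id variant_id    raw_p adjusted_p    or
#> 1:   FUS0001 rsS0000059 8.11e-05   8.11e-03  9.55
#> 2:   FUS0002 rsS0000140 2.71e-05   2.65e-03  4.08
#> 3:   FUS0003 rsS0000291 1.28e-09   1.26e-07  5.24
#> 4:   FUS0004 rsS0000325 5.88e-07   5.88e-05  6.97
```

All four top hits are exactly the causal variants the generator injected
(`study$causal`). The low `weight` column is the fraction of transcript
combinations showing each exclusion pattern; `adjusted_p` is Bonferroni
within each fusion's own variant family.

A command-line front end is installed with the package:

```sh
Rscript -e 'tandemchimera::chimera_cli()' simulate --out demo_dir --seed 1
Rscript -e 'tandemchimera::chimera_cli()' pipeline --dir demo_dir
```

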