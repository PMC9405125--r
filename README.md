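# consensusCNVR

Dual-caller consensus analysis of copy number variation (CNV) regions from
SNP-array intensity data, for population-genetic studies that contrast two
groups of populations — for example trypanotolerant West African taurine
cattle against West African zebu.

Array CNV surveys rarely trust a single caller. The standard design calls
CNVs per individual from Log R Ratio (LRR) and B Allele Frequency (BAF)
with two programs, screens samples (LRR sd ≤ 0.3, BAF drift ≤ 0.01) and
calls (log10 Bayes factor ≥ 10, *informative* above 30), then builds CNV
regions (CNVRs) in three consensus stages per cattle type:

1. **potential CNVRs** — calls overlapping by ≥ 1 bp merged across
   individuals (book-ended calls never merge);
2. **representative CNVRs** — regions recurring in ≥ 3 individuals or
   ≥ 2 populations within the type;
3. **candidate CNVRs** — pairwise intersection of the two callers'
   representative regions.

Candidates that overlap between the two cattle types are set aside as
*shared*; the remaining type-specific CNVRs are annotated against gene and
QTL intervals, with one-sided Fisher term enrichment
(fold enrichment = (k/n)/(K/N)) and cluster enrichment scores
(−log10 geometric mean p; significant at ≥ 1.3, i.e. p ≤ 0.05 for a single
term).

This package implements that whole workflow as composable R functions: a
copy-number hidden Markov model with two caller profiles (distance-decay
transitions; constant-penalty transitions plus Bayes-factor scoring),
sample QC, the three region stages on GenomicRanges interval algebra,
specificity classification with an explicit accounting table, and the
annotation/enrichment layer. A synthetic cohort generator — marker maps,
spiked truth events of copy number 0/1/3/4, per-sample LRR/BAF profiles —
makes every stage testable without any array download. See the methods
vignette (`vignettes/consensus-cnvr-methods.Rmd`) for the model and its
assumptions.

## Worked example

Simulate a 30-sample cohort (two cattle types, three populations each) with
four spiked recurrent regions — two taurine-specific, one zebu-specific,
one carried by both types — and run the full pipeline:

```r
library(consensusCNVR)

config <- list(
  seed = 11L,
  simulate = list(
    map = list(n_chromosomes = 3, markers_per_chromosome = 1500,
               mean_spacing_bp = 1000),
    cohort = list(
      taurine = list(populations = c("Lagunaire", "NDamaBF", "NDamaCo"),
                     n_per_population = 5),
      zebu    = list(populations = c("Bororo", "ZebuPeulBe", "ZebuPeulBF"),
                     n_per_population = 5)
    ),
    design = list(
      shared = data.frame(
        cattle_type = c("taurine", "taurine", "zebu", "taurine,zebu"),
        n_carriers  = c(5, 4, 5, 6),
        n_markers   = c(40, 30, 35, 30),
        copy_number = c(3, 1, 3, 1)),
      private_rate = 0.2
    )
  )
)
res <- run_pipeline(config, "cnvr_demo")

print(res$accounting$per_type, row.names = FALSE)
#>  cattle_type candidates absorbed specific
#>      taurine          3        1        2
#>         zebu          2        1        1
cat("shared:", res$accounting$shared, " final:", res$accounting$final, "\n")
#> shared: 1  final: 4

print(res$final[, c("final_id", "chrom", "start_bp", "end_bp", "label")],
      row.names = FALSE)
#>  final_id chrom start_bp  end_bp            label
#>     F0001     2    32601   67708 taurine_specific
#>     F0002     2   402830  428467           shared
#>     F0003     2  1294400 1319166    zebu_specific
#>     F0004     3    56805   86066 taurine_specific
```

The accounting table is the bookkeeping of the specificity stage: per type,
`specific + absorbed = candidates`, and across the run
`specific_taurine + specific_zebu + shared = final` (2 + 1 + 1 = 4 here).
Each spiked region came back at its locus with the right label — the
cross-type spike on chromosome 2 is `shared`, not specific — which
`recovery_stats()` quantifies against the truth set:

```r
rs <- recovery_stats(res$final, res$data$shared_regions)
cat(sprintf("recall %.2f  precision %.2f\n", rs$recall, rs$precision))
#> recall 1.00  precision 1.00
```

Enrichment scoring works on any term cluster; for three member terms with
Fisher p-values 2.28e-3, 7.28e-3 and 9.22e-3:

```r
cs <- cluster_score(c(2.28e-3, 7.28e-3, 9.22e-3))
cat(sprintf("cluster score %.2f  significant %s\n",
            cs$enrichment_score, cs$significant))
#> cluster score 2.27  significant TRUE
```

`run_pipeline()` writes every stage's tables (QC, calls per caller,
potential/candidate/final regions as TSV + BED, summaries, accounting,
manifest with config hash and seed) under the output directory. A thin
command-line wrapper is included at `inst/scripts/cnvr-run.R`
(`Rscript cnvr-run.R --config pipeline.yaml --out run_dir --seed 7`).

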