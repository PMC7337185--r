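# tesilence

Transposable-element (TE) landscapes and piRNA-mediated silencing in
*Drosophila* gonads, as a tidyverse-style R package.

TE families persist in genomes as collections of diverged, often
truncated copies. Gonads keep them in check through the piRNA pathway:
small RNAs transcribed from genomic piRNA clusters guide the cleavage of
TE transcripts, and the "ping-pong" amplification cycle leaves a
diagnostic 10-nt 5′-overlap between sense and antisense piRNAs. How much
piRNA a family attracts relates to its genomic footprint — copy number,
element length, within-family nucleotide diversity (π) — and its
expression level. `tesilence` implements this whole analysis arc:

* **Annotation** — merge fragmented similarity-search hits into TE
  insertion calls (gap-merge rule bounded by the consensus length),
  summarize each family's copy number, lengths, full-length fraction
  and π.
* **Small RNA** — size-partition reads, count miRNAs for normalization,
  align reads to TE consensus sequences, classify families as
  ovary-/testis-biased from normalized fold changes.
* **Ping-pong** — per-family 5′-overlap histograms via length-stratified
  cross-correlation, z-score of the 10-nt bin against neighboring bins.
* **Clusters** — genome-wide fixed-window screen for piRNA clusters from
  uniquely mapping reads, tissue-specificity calls, TE density profiles.
* **Statistics** — exact-enumeration Wilcoxon rank-sum, Pearson
  correlation with exact p-values, the full trait correlation web, and
  high- vs low-copy comparisons.
* **Synthetic data** — fully seeded generators for genomes, TE
  landscapes, hit tables, small-RNA libraries and trait tables with
  known ground truth, so every stage is testable offline.

All functions take and return tibbles, results support
`generics::tidy()` / `glance()` and `ggplot2::autoplot()`, and all
genomic intervals are 0-based half-open internally (converted at I/O
boundaries). See `vignettes/methods.Rmd` for the models, parameter
choices and limitations.

## Worked example

Simulate a small TE landscape, annotate it from (simulated) similarity
hits, and check recovery against the planted truth:

```r
library(tesilence)
library(dplyr)

specs <- bind_rows(
  family_spec("TEA", 1500, copy_number = 12, divergence = 0.05),
  family_spec("TEB", 900,  copy_number = 30, divergence = 0.02),
  family_spec("TEC", 2500, copy_number = 5,  divergence = 0.10))

sim  <- simulate_genome(specs, contig_lengths = rep(100000L, 4), seed = 42)
hits <- simulate_hits(sim, split_prob = 0.3, seed = 43)   # fragmented hits
ins  <- annotate_genome(hits, sim$consensus)              # merge + filter
fam  <- summarize_families(ins, sim$consensus, sim$genome)
fam
#> # A tibble: 3 × 6
#>   family_id copy_number median_length full_length_count     pi consensus_length
#>   <chr>           <int>         <dbl>             <int>  <dbl>            <int>
#> 1 TEA                12         1500                  8 0.0855             1500
#> 2 TEB                30          750.                13 0.0371              900
#> 3 TEC                 5         2260                  2 0.145              2500

count(sim$truth$insertions, family_id)   # planted copy numbers: 12 / 30 / 5
#> # A tibble: 3 × 2
#>   family_id     n
#>   <chr>     <int>
#> 1 TEA          12
#> 2 TEB          30
#> 3 TEC           5
```

Every planted copy is recovered exactly, despite 30 % of copies being
reported as split hits. Now simulate an ovary small-RNA library with
planted ping-pong pairs and detect the signature:

```r
lib <- simulate_smallrna(sim, library_spec(
  "ovary", n_mirna_reads = 2000,
  te_read_budget = c(TEA = 600, TEB = 400, TEC = 200),
  pingpong_fraction = 0.4, seed = 44))

aln <- align_to_consensus(lib$reads, sim$consensus)
pp  <- ping_pong_signature(aln)
as_tibble(pp) |> select(-overlap_counts)
#> # A tibble: 3 × 6
#>   family_id n_pirnas pairs10   z10 significant   ppr
#>   <chr>        <int>   <int> <dbl> <lgl>       <dbl>
#> 1 TEA            581     182  17.4 TRUE        0.313
#> 2 TEB            398     125  12.7 TRUE        0.314
#> 3 TEC            141      23  14.9 TRUE        0.163
```

All three families show the 10-nt overlap enrichment (z ≫ 1.96), as
planted. The full pipeline — genome, two tissues, annotation, piRNA
quantification, ping-pong, clusters, mRNA counts and the trait
correlation web — runs from one seed:

```r
res <- run_pipeline(default_config(seed = 1))
as_tibble(res$correlations) |> filter(var1 == "pirna_level")
```

## Command-line interface

A thin CLI wraps the same functions
(`inst/cli/tesilence.R`, installed under
`system.file("cli", "tesilence.R", package = "tesilence")`):

```sh
Rscript tesilence.R simulate  --config cfg.yaml -o out/
Rscript tesilence.R annotate  --hits hits.tsv --consensus te.fa \
                              --genome genome.fa -o ann/
Rscript tesilence.R smallrna  --reads ovary.fa testis.fa --consensus te.fa \
                              --mirna mirna.fa -o sr/
Rscript tesilence.R pingpong  --assignments sr/alignments_ovary.tsv -o pp.tsv
Rscript tesilence.R clusters  --ovary ovary.fa --testis testis.fa \
                              --genome genome.fa --annotations ann/te_annotation.gff3 -o cl/
Rscript tesilence.R correlate --summary ann/family_summary.tsv \
                              --pirna sr/pirna_levels.tsv --mrna mrna.tsv -o stats/
```

All subcommands log progress to stderr; `-v`/`--verbose` and
`-q`/`--quiet` adjust verbosity. Configuration files are YAML.

## Tests and reproducing the results

The test suite (testthat 3e) validates each algorithm against
independent oracles — brute-force π, exhaustive Wilcoxon enumeration,
all-pairs overlap counting, a leftmost-pair merge oracle — plus
planted-truth recovery and calibration experiments:

```r
testthat::test_dir("tests/testthat", package = "tesilence",
                   load_package = "installed")
```

The headline metrics (copy-number recovery, π accuracy, ping-pong null
false-positive rate and power, cluster sensitivity and class accuracy,
correlation-web sign pattern, copy-effect detection rate) are
reproduced by:

```sh
Rscript scripts/acceptance.R --seed 1 --out metrics.json
```

Every random draw derives from `--seed`; rerunning with the same seed
gives byte-identical pipeline outputs.
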