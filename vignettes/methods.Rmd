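---
title: "Methods: transposable-element landscapes and piRNA silencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transposable-element landscapes and piRNA silencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(tesilence)
library(dplyr)
```

# Scope

`tesilence` models how transposable-element (TE) families in an insect
gonad are detected, quantified and silenced. It covers five analysis
layers — genome annotation, within-family nucleotide diversity, small-RNA
quantification, ping-pong amplification signatures, and piRNA cluster
discovery — plus the statistical layer that ties family traits together.
Every layer has a matching synthetic generator, so each algorithm can be
validated against planted ground truth, and the full pipeline runs
end-to-end from a single seed.

This vignette documents the model behind each step, the default
parameters and why they were chosen, the assumptions the generators make,
and the known limitations.

# Coordinate and data conventions

All genomic intervals are **0-based half-open** internally. Conversions
to 1-based inclusive happen only at I/O boundaries: `read_hits()`
converts 12-column tabular search hits (1-based, with minus-strand hits
encoded by descending subject coordinates) on the way in; `write_gff3()`
converts on the way out; BED stays 0-based. Every analysis function takes
and returns tibbles, so the whole pipeline composes with dplyr verbs, and
result objects implement `generics::tidy()` / `glance()` plus
`autoplot()`.

# Genome annotation

## Hit merging

A similarity search reports one row per local alignment, so a single
interrupted TE copy arrives as several collinear fragments. After
discarding hits below `min_identity` (default 80 %), hits of one family
on one contig are sorted by start and scanned left to right. The current
merged insertion (the *hull* of the hits absorbed so far) absorbs the
next hit when either

* the hit overlaps the hull, or
* the joined span — hull length + hit length + intervening gap, which is
  algebraically the span of their union — is **shorter than the family's
  consensus length**.

The second clause is the biological argument: two fragments whose
combined extent still fits inside one element are more plausibly one
interrupted copy than two independent insertions. The rule is applied to
*successive* hits only; a left-to-right scan with a growing hull is
provably equivalent to repeatedly merging the leftmost mergeable
adjacent pair, which is the oracle the tests check against.

Merged insertions carry an alignment-length-weighted mean percent
identity, a completeness fraction (span / consensus length), and a
full-length flag (completeness ≥ `full_length_min`, default 0.98).
When copies of *different* families overlap, the conflict is resolved
greedily: contained or heavily overlapping calls lose to the call with
the larger aligned span (ties broken by identity).

## Family summaries

`summarize_families()` reduces the insertion table to one row per family:
copy number, median copy length, full-length count and fraction, and —
when the genome is supplied — nucleotide diversity of the aligned copies.

# Nucleotide diversity (π)

`nucleotide_diversity()` implements π over an aligned set of copies:
for each pair of sequences, the proportion of differing sites among
pairwise-comparable columns (both characters in `{A,C,G,T}`; gaps and
`N` are excluded per pair, not per column), averaged over all pairs with
frequency weights. With equal weights `1/n` this is

$$\pi = 2 \sum_{i<j} \frac{1}{n^2} \, d_{ij}$$

where $d_{ij}$ is the pairwise difference proportion. The implementation
vectorises over columns; the test suite checks it to `1e-12` against a
literal double-loop oracle on random gapped alignments, because the
vectorised bookkeeping (per-pair comparable-site masks) is exactly the
kind of code where an off-by-one survives casual testing.

`align_copies()` prepares input for π from unaligned copies of one
family by anchoring each copy at its best-matching consensus offset —
adequate here because the generator produces substitution-only copies
(see Limitations).

# Small-RNA quantification

Reads are first partitioned by length: the piRNA size window is
`size = c(19, 30)` nucleotides (inclusive), chosen to bracket the
canonical 23–29 nt piRNA range with margin for the simulated length
jitter. Reads matching an annotated miRNA exactly (either orientation)
are counted separately and serve as the per-library normalisation
denominator, mimicking the common practice of normalising gonadal
small-RNA libraries to a shared miRNA complement.

Remaining reads are aligned to the TE consensus set in both orientations
with at most `max_mismatch = 3` mismatches, keeping only best-stratum
hits; reads hitting multiple families at the best stratum are dropped
from per-family counts (unique-mapper counting, the conservative
standard choice). Family counts are scaled to reads per million miRNA
reads, and each family gets a sex-bias class from the ovary/testis fold
change with a pseudocount of 1: `ovary_biased` above `fold` (default 2),
`testis_biased` below `1/fold`, else `unbiased`.

# Ping-pong signature

For one family and tissue, every antisense read pair whose footprints on
the consensus overlap defines a 5′-to-5′ overlap
$k = \text{minus}_{5'} - \text{plus}_{5'} + 1$. The overlap histogram for
$k = 1..K$ (default `K = 20`) is computed as a cross-correlation of the
per-position 5′-end counts of the two strands, stratified by read-length
pair so the physical constraint $k \le L_+ + L_- - 1$ is honoured exactly;
the tests prove this equal to the brute-force all-pairs loop.

The signature statistic is the z-score of the 10-nt bin against the other
$K - 1$ bins (population standard deviation), significant at $z > 1.96$.
Background bins 1–20 minus the signal bin give 19 background values —
enough for a stable empirical mean and SD while staying inside the
physically possible overlap range for 23–30 nt reads. Calibration on
simulated null libraries (uniform 5′ ends, no ping-pong pairing) gives a
false-positive rate of ~2–6 % at spec-scale library sizes, consistent
with the nominal 5 %; power on libraries with half the reads in planted
ping-pong pairs is ~100 %. An optional `collapse` mode counts distinct
(offset, strand, length) species once, as PCR-duplicate-averse analyses
do.

# piRNA cluster discovery

Reads that map to a *unique* genomic location (at most
`max_mismatch = 1`) are binned into non-overlapping 1-kb windows by their
5′ position. A window is called a cluster when its pooled read count
strictly exceeds `min_density` reads per kb (default 5, so 6 reads call a
1-kb window and 5 do not — the boundary the tests pin). Windows are
classed `ovary`, `testis`, or `both` by which tissues individually clear
the same density threshold; windows that only clear it pooled are classed
`both` with a `low_confidence` flag. `te_density_profile()` then overlays
the annotation to report, per window, the fraction covered by TEs of each
sex-bias class.

# Statistics

Two statistical primitives are implemented rather than bought, because
their exactness is itself a deliverable:

* `pearson_cor()` — Pearson correlation with the exact t-distributed
  p-value, checked to `1e-12` against a closed-form oracle (and against
  `cor.test`).
* `wilcoxon_ranksum()` — rank-sum test with **exact enumeration** of all
  $\binom{n_x+n_y}{n_x}$ group assignments (doubled one-tail, midranks
  for ties) whenever both groups have ≤ 8 observations, switching to the
  tie-corrected normal approximation above that. The exact branch is
  verified against full bitmask enumeration for every group-size
  combination up to 8×8.

`correlation_web()` computes all ten pairwise correlations among
piRNA level, mRNA level, copy number, median length and π; count-like
traits are log10-transformed first (`transform = TRUE`) since abundances
and copy numbers are multiplicative quantities. P-values are
Benjamini–Hochberg adjusted across the ten edges.
`copy_class_compare()` contrasts piRNA levels of high- vs low-copy
families (boundary: ≥ 20 copies) within each expression class.

# Synthetic data generators

The generators are the package's ground truth and are deliberately
simple enough to reason about:

* **Genome** (`simulate_genome()`): TE copies are planted on random
  contigs/strands with per-site substitution divergence drawn up to the
  family's `divergence`; a `full_length_fraction` of copies is complete,
  the rest truncated uniformly down to `min_truncation`. Copies never
  overlap, and same-family copies keep a spacing of at least one
  consensus length (`family_spacing = 1`) so that two distinct planted
  copies can never satisfy the gap-merge inequality — copy-number
  recovery is then a property of the annotation algorithm, not of lucky
  placement. Optional piRNA cluster tiles are reserved kb-aligned and
  TE-free.
* **Small-RNA libraries** (`simulate_smallrna()`): miRNA reads from the
  miRNA contig, per-family TE read budgets (antisense-biased), an
  optional `pingpong_fraction` of reads generated as proper 10-nt
  5′-overlap pairs, and cluster-derived reads from the reserved tiles.
* **Expression counts** (`simulate_counts()`): negative-binomial mRNA
  counts whose log-mean increases with log10 copy number.
* **Trait scenario** (`simulate_trait_table()`): a paper-like per-family
  trait table with planted positive piRNA–mRNA, piRNA–copy-number and
  piRNA–length effects and a negative piRNA–π effect. Each effect is
  planted **on the scale the correlation web measures it** (log10 for
  counts, linear for length and π); planting on a different scale
  attenuates the measured correlation and was the root cause of an early
  power shortfall. The scenario size used in validation is 150 families:
  a power sweep showed the all-four-edges-significant rate rising from
  ~58 % at 50 families through ~95 % at 100 to ~99 % at 150, while the
  function default stays at 50 for interactive use.

## Problem sizes

Default validation scales are the package's own choice: a 2-Mb genome
with 20 families (5–60 copies each, divergence ≤ 0.1) for annotation
recovery; 100 families × 2000 reads for ping-pong null calibration; 100
planted 1-kb cluster windows for cluster recovery; 100 seeds for the
copy-number effect detection rate. The full default pipeline
(`run_pipeline(default_config(seed))`, 12 families, 10 × 150-kb contigs,
two tissues) runs in well under a minute.

# Reproducibility

All randomness flows from integer seeds; identical seeds give
byte-identical pipeline outputs (checked with `md5sum` in the acceptance
tests). `scripts/acceptance.R --seed <int> --out <path>` reruns the
pipeline and calibration experiments against the installed package and
writes the headline metrics as flat JSON.

# Limitations

* The genome generator is substitution-only: no indels, nesting, or
  segmental duplication. `align_copies()` relies on this; real copies
  would need a proper multiple aligner before π.
* Read simulation has no sequencing error or PCR-duplicate model
  (`collapse` exists but duplicates are never planted).
* Cluster discovery uses fixed non-overlapping windows; real boundaries
  are fuzzy and merging adjacent windows is left to the caller.
* Unique-mapper counting undercounts young, homogeneous families whose
  reads multi-map.
* The merge rule cannot separate two genuinely adjacent same-family
  copies closer than one consensus length; the generator's
  `family_spacing` sidesteps this by construction, real genomes do not.
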