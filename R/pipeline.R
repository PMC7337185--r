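#' Default synthetic TE landscape
#'
#' Twelve families spanning the three TE classes, consensus lengths from 0.8
#' to 3 kb, copy numbers from 5 to 60, per-site divergence up to 9% and
#' full-length fractions from 0.3 to 0.8 — a landscape mixing young,
#' high-copy, full-length-rich families with older, degraded ones.
#'
#' @return Family spec tibble for [simulate_genome()].
#' @export
default_specs <- function() {
  n <- 12
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    family_spec(
      family_id = sprintf("TE%02d", i),
      consensus_length = round(seq(800, 3000, length.out = n))[i],
      te_class = rep(c("LTR", "non-LTR", "DNA"), length.out = n)[i],
      copy_number = c(5, 8, 12, 15, 18, 22, 25, 30, 35, 40, 50, 60)[i],
      divergence = rep(c(0.01, 0.03, 0.06, 0.09), length.out = n)[i],
      full_length_fraction = rep(c(0.8, 0.5, 0.3), length.out = n)[i],
      min_truncation = 0.25)
  }))
}

#' Default pipeline configuration
#'
#' The conditions of the standard synthetic experiment: the
#' [default_specs()] landscape on 1.5 Mb of background across 10 contigs, 20
#' planted piRNA-cluster windows dominated by ovary-only activity, ovary
#' libraries with a strong ping-pong fraction and most families
#' ovary-biased, and a planted positive copy-number effect on mRNA counts.
#' Per-family ovary piRNA budgets grow with copy number and consensus length
#' and shrink with divergence, mirroring the trait correlations the
#' statistical layer looks for.
#'
#' @param seed Integer master seed; every stage derives its own stream from
#'   it.
#' @return Named list of parameters accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1L) {
  specs <- default_specs()
  n <- nrow(specs)
  sex_bias <- rep(c("ovary_biased", "unbiased", "ovary_biased",
                    "testis_biased", "ovary_biased", "unbiased"),
                  length.out = n)
  ovary_budget <- round(8 * specs$copy_number *
                          (specs$consensus_length / 1500)^0.5 *
                          exp(-8 * specs$divergence))
  # Testis budgets are set on the normalized scale: the testis library has
  # half the miRNA depth, so a family with equal normalized output gets half
  # the raw reads. Biased families sit at 4-fold normalized enrichment.
  testis_budget <- round(ovary_budget * 0.5 *
    ifelse(sex_bias == "ovary_biased", 0.25,
           ifelse(sex_bias == "testis_biased", 4, 1)))
  list(
    seed = as.integer(seed),
    specs = specs,
    contig_lengths = rep(150000L, 10),
    clusters = tibble::tibble(
      tissue_class = c("ovary_only", "testis_only", "both"),
      n = c(16L, 2L, 2L)),
    split_prob = 0.2,
    min_identity = 80,
    full_length_min = 0.98,
    ovary = list(n_mirna = 20000L,
                 te_budget = setNames(ovary_budget, specs$family_id),
                 pingpong_fraction = 0.6, cluster_budget = 30L),
    testis = list(n_mirna = 10000L,
                  te_budget = setNames(testis_budget, specs$family_id),
                  pingpong_fraction = 0.2, cluster_budget = 30L),
    mrna = list(effect = 1, dispersion = 5, intercept = 2),
    smallrna_size = c(19L, 30L),
    pirna_size = c(23L, 30L),
    max_mismatch_consensus = 3L,
    max_mismatch_genome = 1L,
    window = 1000L,
    min_density = 5,
    fold = 2
  )
}

#' Run the full synthetic analysis pipeline
#'
#' Simulation, TE annotation, small-RNA quantification, ping-pong
#' signatures, piRNA-cluster screening and the trait correlation layer, end
#' to end. Rerunning with the same configuration and seed reproduces every
#' table exactly.
#'
#' @param config Configuration list, see [default_config()].
#' @param outdir Optional directory; when given, every major table and
#'   sequence set is written there (FASTA/GFF3/BED/TSV).
#' @return Named list: `sim`, `hits`, `insertions`, `families`, `libraries`,
#'   `pirna` (levels/assignments/alignments), `pingpong`, `cluster_windows`,
#'   `profiles`, `mrna`, `traits`, `correlations`, `copy_class_tests`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  seed <- config$seed
  sim <- simulate_genome(config$specs, config$contig_lengths, seed,
                         clusters = config$clusters)
  hits <- simulate_hits(sim, split_prob = config$split_prob, seed = seed + 1L)
  insertions <- annotate_genome(hits, sim$consensus,
                                min_identity = config$min_identity,
                                full_length_min = config$full_length_min)
  families <- summarize_families(insertions, sim$consensus, sim$genome)

  mk_lib <- function(tissue, offset) {
    p <- config[[tissue]]
    simulate_smallrna(sim, library_spec(
      tissue, n_mirna_reads = p$n_mirna, te_read_budget = p$te_budget,
      pingpong_fraction = p$pingpong_fraction,
      cluster_read_budget = p$cluster_budget, seed = seed + offset))
  }
  libs <- list(ovary = mk_lib("ovary", 2L), testis = mk_lib("testis", 3L))

  quant <- quantify_pirna(libs$ovary$reads, libs$testis$reads,
                          sim$consensus, sim$mirna,
                          size = config$smallrna_size,
                          max_mismatch = config$max_mismatch_consensus,
                          fold = config$fold)

  # piRNA-sized consensus alignments of uniquely assigned reads, per tissue
  aln <- dplyr::bind_rows(lapply(names(libs), function(t) {
    reads <- partition_by_size(libs[[t]]$reads,
                               config$pirna_size[1], config$pirna_size[2])
    a <- align_to_consensus(reads, sim$consensus,
                            config$max_mismatch_consensus)
    assigned <- quant$assignments[[t]]
    a |>
      dplyr::semi_join(dplyr::filter(assigned, .data$status == "assigned"),
                       by = c("read_id", "family_id")) |>
      dplyr::mutate(tissue = t)
  }))
  pingpong <- ping_pong_signature(aln)

  genome_no_mirna <- sim$genome[sim$genome$id != "contig_mirna", ]
  gmap <- dplyr::bind_rows(lapply(names(libs), function(t) {
    partition_by_size(libs[[t]]$reads,
                      config$pirna_size[1], config$pirna_size[2]) |>
      map_unique_genome(sim$genome, config$max_mismatch_genome) |>
      dplyr::mutate(tissue = t)
  }))
  gmap <- gmap[gmap$contig != "contig_mirna", ]
  contig_lengths <- setNames(nchar(genome_no_mirna$sequence),
                             genome_no_mirna$id)
  windows <- screen_windows(gmap, contig_lengths,
                            window = config$window,
                            min_density = config$min_density)
  classes <- dplyr::select(quant$levels, "family_id", "sex_bias_class")
  profiles <- te_density_profile(windows, insertions, classes,
                                 window = config$window)

  mrna <- simulate_counts(config$specs, effect = config$mrna$effect,
                          dispersion = config$mrna$dispersion,
                          seed = seed + 4L,
                          intercept = config$mrna$intercept)
  traits <- make_trait_table(families, quant$levels, mrna)
  correlations <- correlation_web(traits)
  copy_tests <- copy_class_compare(traits, by = NULL)

  res <- list(sim = sim, hits = hits, insertions = insertions,
              families = families, libraries = libs, pirna = quant,
              alignments = aln, pingpong = pingpong,
              cluster_windows = windows, profiles = profiles, mrna = mrna,
              traits = traits, correlations = correlations,
              copy_class_tests = copy_tests)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_fasta(res$sim$genome, p("genome.fa"))
  write_fasta(res$sim$consensus, p("consensus.fa"))
  write_fasta(res$sim$mirna, p("mirna.fa"))
  for (t in names(res$libraries)) {
    reads <- dplyr::rename(res$libraries[[t]]$reads, id = "read_id")
    write_fasta(reads[c("id", "sequence")], p(paste0("reads_", t, ".fa")))
  }
  write_hits(res$hits, p("hits.tsv"))
  write_gff3(res$insertions, p("te_annotation.gff3"))
  write_bed6(res$insertions, p("te_annotation.bed"))
  readr::write_tsv(res$families, p("family_summary.tsv"))
  readr::write_tsv(res$pirna$levels, p("pirna_levels.tsv"))
  readr::write_tsv(dplyr::select(tibble::as_tibble(res$pingpong),
                                 -"overlap_counts"),
                   p("pingpong.tsv"))
  write_cluster_bed(res$cluster_windows, p("clusters.bed"))
  readr::write_tsv(res$cluster_windows, p("cluster_windows.tsv"))
  readr::write_tsv(res$profiles, p("te_density_profiles.tsv"))
  readr::write_tsv(res$mrna, p("mrna_counts.tsv"))
  readr::write_tsv(res$traits, p("trait_table.tsv"))
  readr::write_tsv(tibble::as_tibble(unclass(res$correlations)),
                   p("correlations.tsv"))
  readr::write_tsv(res$copy_class_tests, p("copy_class_tests.tsv"))
  invisible(outdir)
}

#' Simulate a paper-like per-family trait table
#'
#' Families get log-uniform copy numbers, uniform median lengths, divergence-
#' driven nucleotide diversity, negative-binomial mRNA counts increasing
#' with copy number (via [simulate_counts()]), and a piRNA level that grows
#' with mRNA level, copy number and length and declines with diversity —
#' the correlation structure the trait web is designed to detect.
#'
#' @param n_families Number of families.
#' @param seed Integer seed.
#' @param effect_mrna,effect_copy,effect_length,effect_pi Log10-scale slopes
#'   of the piRNA level on each trait. Each effect is planted on the scale
#'   the correlation web measures it on: log10 for mRNA and copy number,
#'   linear for median length (scaled to its range) and diversity.
#' @param noise_sd Log10-scale residual noise of the piRNA level.
#' @return Trait tibble accepted by [correlation_web()].
#' @export
simulate_trait_table <- function(n_families = 50, seed = 1L,
                                 effect_mrna = 0.6, effect_copy = 0.4,
                                 effect_length = 0.7, effect_pi = -4,
                                 noise_sd = 0.25) {
  withr::with_seed(seed, {
    copy_number <- pmax(1, round(10^runif(n_families, log10(3), log10(80))))
    d <- runif(n_families, 0, 0.12)
    pi <- 2 * d * (1 - d) * exp(stats::rnorm(n_families, 0, 0.1))
    median_length <- runif(n_families, 300, 4000)
    fam <- tibble::tibble(family_id = sprintf("F%03d", seq_len(n_families)),
                          copy_number = copy_number)
    mrna <- simulate_counts(fam, effect = 1, dispersion = 5,
                            seed = sample.int(2^30, 1))
    log_pirna <- 0.5 +
      effect_mrna * log10(mrna$mrna_count + 1) +
      effect_copy * log10(copy_number) +
      effect_length * (median_length - 300) / 3700 +
      effect_pi * pi +
      stats::rnorm(n_families, 0, noise_sd)
    tibble::tibble(
      family_id = fam$family_id,
      pirna_level = 10^log_pirna,
      mrna_level = mrna$mrna_count,
      copy_number = copy_number,
      median_length = median_length,
      pi = pi)
  })
}
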