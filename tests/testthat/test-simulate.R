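small_specs <- function() {
  dplyr::bind_rows(
    family_spec("TEA", 500, "LTR", copy_number = 6, divergence = 0.02,
                full_length_fraction = 0.5),
    family_spec("TEB", 800, "DNA", copy_number = 4, divergence = 0,
                full_length_fraction = 1))
}

test_that("family_spec validates its arguments", {
  expect_error(family_spec("X", 100, te_class = "viral"))
  expect_error(family_spec("X", 100, divergence = 0.5))
  expect_error(family_spec("X", 100, min_truncation = 1))
  expect_error(family_spec("X", 100, full_length_fraction = 2))
})

test_that("simulate_genome is deterministic in its seed", {
  a <- simulate_genome(small_specs(), c(30000L, 30000L), seed = 5L)
  b <- simulate_genome(small_specs(), c(30000L, 30000L), seed = 5L)
  c <- simulate_genome(small_specs(), c(30000L, 30000L), seed = 6L)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth$insertions, b$truth$insertions)
  expect_false(identical(a$genome$sequence, c$genome$sequence))
})

test_that("planted copies are written into the genome as recorded", {
  sim <- simulate_genome(small_specs(), c(30000L, 30000L), seed = 5L)
  gen <- setNames(sim$genome$sequence, sim$genome$id)
  ins <- sim$truth$insertions
  for (i in seq_len(nrow(ins))) {
    seg <- substring(gen[ins$contig[i]], ins$start[i] + 1L, ins$end[i])
    expected <- if (ins$strand[i] == "+") ins$copy_seq[i] else
      revcomp(ins$copy_seq[i])
    expect_identical(unname(seg), expected)
  }
})

test_that("planted copies never overlap and same-family copies keep spacing", {
  sim <- simulate_genome(small_specs(), c(40000L, 40000L), seed = 11L)
  ins <- sim$truth$insertions
  cons_len <- setNames(nchar(sim$consensus$sequence), sim$consensus$id)
  for (ctg in unique(ins$contig)) {
    d <- ins[ins$contig == ctg, ]
    d <- d[order(d$start), ]
    if (nrow(d) < 2) next
    gaps <- d$start[-1] - d$end[-nrow(d)]
    expect_true(all(gaps >= 0))
    same <- d$family_id[-1] == d$family_id[-nrow(d)]
    if (any(same)) {
      need <- cons_len[d$family_id[-1][same]]
      expect_true(all(gaps[same] >= need))
    }
  }
})

test_that("planted cluster windows are kilobase tiles kept TE-free", {
  sim <- simulate_genome(
    small_specs(), c(40000L, 40000L), seed = 3L,
    clusters = tibble::tibble(tissue_class = c("ovary_only", "both"),
                              n = c(3L, 1L)))
  cl <- sim$truth$clusters
  expect_equal(nrow(cl), 4)
  expect_true(all(cl$start %% 1000 == 0))
  expect_true(all(cl$end - cl$start == 1000))
  ins <- sim$truth$insertions
  for (i in seq_len(nrow(cl))) {
    same_ctg <- ins[ins$contig == cl$contig[i], ]
    expect_false(any(same_ctg$start < cl$end[i] &
                     same_ctg$end > cl$start[i]))
  }
})

test_that("the miRNA contig carries the 50 planted miRNAs", {
  sim <- simulate_genome(small_specs(), 30000L, seed = 2L)
  expect_equal(nrow(sim$mirna), 50)
  expect_true(all(nchar(sim$mirna$sequence) == 22))
  contig <- sim$genome$sequence[sim$genome$id == "contig_mirna"]
  expect_true(all(vapply(sim$mirna$sequence, grepl, logical(1),
                         x = contig, fixed = TRUE)))
})

test_that("truth pi is 0 for a zero-divergence family", {
  sim <- simulate_genome(small_specs(), c(30000L, 30000L), seed = 9L)
  expect_identical(sim$truth$pi$true_pi[sim$truth$pi$family_id == "TEB"], 0)
  expect_gt(sim$truth$pi$true_pi[sim$truth$pi$family_id == "TEA"], 0)
})

test_that("an overfull landscape is rejected upfront", {
  specs <- family_spec("BIG", 5000, copy_number = 20)
  expect_error(simulate_genome(specs, 100000L, seed = 1L), "80%")
})

test_that("simulate_smallrna honors budgets and miRNA identity", {
  sim <- simulate_genome(small_specs(), c(30000L, 30000L), seed = 5L)
  lib <- simulate_smallrna(sim, library_spec(
    "ovary", n_mirna_reads = 100,
    te_read_budget = c(TEA = 40, TEB = 20), seed = 8L))
  expect_equal(nrow(lib$reads), 160)
  expect_equal(nrow(lib$provenance), 160)
  src <- table(lib$provenance$source)
  expect_equal(unname(src[["mirna"]]), 100)
  expect_equal(unname(src[["te"]]), 60)
  mir_ids <- lib$provenance$read_id[lib$provenance$source == "mirna"]
  mir_reads <- lib$reads$sequence[lib$reads$read_id %in% mir_ids]
  expect_true(all(mir_reads %in% sim$mirna$sequence))
  fam_counts <- table(lib$provenance$family_id[lib$provenance$source == "te"])
  expect_equal(unname(fam_counts[["TEA"]]), 40)
  expect_equal(unname(fam_counts[["TEB"]]), 20)
  lens <- nchar(lib$reads$sequence[lib$reads$read_id %in%
                                   lib$provenance$read_id[
                                     lib$provenance$source == "te"]])
  expect_true(all(lens >= 23 & lens <= 30))
})

test_that("ping-pong pairs in the library have exact 10-nt 5'-5' overlaps", {
  specs <- family_spec("TEP", 2000, copy_number = 1, divergence = 0,
                       full_length_fraction = 1)
  sim <- simulate_genome(specs, 20000L, seed = 4L)
  lib <- simulate_smallrna(sim, library_spec(
    "ovary", n_mirna_reads = 0, te_read_budget = c(TEP = 200),
    pingpong_fraction = 1, seed = 4L))
  aln <- align_to_consensus(lib$reads, sim$consensus, max_mismatch = 0)
  counts <- overlap_distribution(aln)
  # 100 planted pairs, plus a few incidental combinations among the reads
  expect_gte(unname(counts[["10"]]), 100)
  expect_true(zscore_signature(counts)$significant)
})

test_that("simulate_counts is seeded and validates dispersion", {
  fams <- tibble::tibble(family_id = c("A", "B", "C"),
                         copy_number = c(5, 20, 80))
  a <- simulate_counts(fams, effect = 1, dispersion = 5, seed = 3L)
  b <- simulate_counts(fams, effect = 1, dispersion = 5, seed = 3L)
  expect_identical(a, b)
  expect_error(simulate_counts(fams, 1, dispersion = 0, seed = 1L),
               "dispersion")
})

test_that("simulate_hits with split_prob 0 yields one exact hit per copy", {
  sim <- simulate_genome(small_specs(), c(30000L, 30000L), seed = 5L)
  hits <- simulate_hits(sim, split_prob = 0, seed = 1L)
  ins <- sim$truth$insertions
  expect_equal(nrow(hits), nrow(ins))
  hits <- hits[order(hits$contig, hits$start), ]
  ins <- ins[order(ins$contig, ins$start), ]
  expect_equal(hits$start, ins$start)
  expect_equal(hits$end, ins$end)
  expect_equal(hits$strand, ins$strand)
  expect_true(all(hits$percent_identity >= 90))
})

test_that("split hits still tile the original insertion span", {
  sim <- simulate_genome(small_specs(), c(30000L, 30000L), seed = 5L)
  hits <- simulate_hits(sim, split_prob = 1, seed = 1L)
  ins <- sim$truth$insertions
  expect_gt(nrow(hits), nrow(ins))
  for (i in seq_len(nrow(ins))) {
    mine <- hits[hits$contig == ins$contig[i] &
                 hits$start >= ins$start[i] & hits$end <= ins$end[i], ]
    expect_gte(nrow(mine), 1)
    expect_equal(min(mine$start), ins$start[i])
    expect_equal(max(mine$end), ins$end[i])
  }
})

test_that("simulate_trait_table is deterministic with expected columns", {
  a <- simulate_trait_table(n_families = 20, seed = 2L)
  b <- simulate_trait_table(n_families = 20, seed = 2L)
  expect_identical(a, b)
  expect_equal(nrow(a), 20)
  expect_true(all(c("family_id", "pirna_level", "mrna_level", "copy_number",
                    "median_length", "pi") %in% names(a)))
  expect_true(all(a$pirna_level > 0))
  expect_true(all(a$pi >= 0))
})
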