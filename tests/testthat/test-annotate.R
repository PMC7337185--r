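mk_hits <- function(starts, ends, identity = 90, family = "FAM",
                    contig = "chr", strand = "+") {
  tibble::tibble(
    family_id = family, contig = contig, strand = strand,
    percent_identity = rep_len(identity, length(starts)),
    alignment_length = ends - starts,
    start = as.integer(starts), end = as.integer(ends),
    e_value = 0, bit_score = 100)
}

test_that("filter_hits keeps the identity boundary", {
  hits <- mk_hits(c(0, 100, 200), c(50, 150, 250),
                  identity = c(79.99, 80, 95))
  kept <- filter_hits(hits)
  expect_equal(kept$percent_identity, c(80, 95))
})

test_that("gap rule hand case: 400 + 401 with gap vs consensus 1000 merges", {
  # joined span 801 strictly below consensus length 1000: one insertion
  hits <- mk_hits(c(0, 400), c(400, 801))
  merged <- merge_family_hits(hits, consensus_length = 1000)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, 0L)
  expect_equal(merged$end, 801L)
  expect_equal(merged$n_merged_hits, 2L)
})

test_that("gap rule hand case: joined 801 vs consensus 600 stays split", {
  hits <- mk_hits(c(0, 400), c(400, 801))
  merged <- merge_family_hits(hits, consensus_length = 600)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$start, c(0L, 400L))
  expect_equal(merged$end, c(400L, 801L))
})

test_that("the merge inequality is strict at the boundary", {
  # joined length exactly equal to the consensus length: no merge
  hits <- mk_hits(c(0, 500), c(400, 700))   # 400 + 200 + gap 100 = 700
  expect_equal(nrow(merge_family_hits(hits, consensus_length = 700)), 2)
  expect_equal(nrow(merge_family_hits(hits, consensus_length = 701)), 1)
})

test_that("overlapping hits merge regardless of the consensus length", {
  hits <- mk_hits(c(0, 350), c(400, 900))
  merged <- merge_family_hits(hits, consensus_length = 100)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$end, 900L)
})

test_that("merged identity is weighted by alignment length", {
  hits <- tibble::tibble(
    family_id = "FAM", contig = "chr", strand = "+",
    percent_identity = c(90, 80), alignment_length = c(100L, 300L),
    start = c(0L, 120L), end = c(100L, 420L), e_value = 0, bit_score = 100)
  merged <- merge_family_hits(hits, consensus_length = 2000)
  expect_equal(merged$identity, (90 * 100 + 80 * 300) / 400)
})

test_that("full-length call uses the 98% completeness threshold", {
  merged <- merge_family_hits(mk_hits(0, 980), consensus_length = 1000)
  expect_true(merged$full_length)
  merged <- merge_family_hits(mk_hits(0, 979), consensus_length = 1000)
  expect_false(merged$full_length)
})

test_that("merge_family_hits rejects mixed groups", {
  hits <- dplyr::bind_rows(mk_hits(0, 100, family = "A"),
                           mk_hits(200, 300, family = "B"))
  expect_error(merge_family_hits(hits, 1000), "one family")
})

test_that("contained cross-family calls resolve to the higher identity", {
  ins <- dplyr::bind_rows(
    merge_family_hits(mk_hits(100, 900, identity = 95, family = "A"), 800),
    merge_family_hits(mk_hits(300, 600, identity = 99, family = "B"), 300))
  res <- resolve_cross_family_overlaps(ins)
  expect_equal(res$family_id, "B")
})

test_that("partial cross-family overlaps below the threshold both survive", {
  # overlap 100 of shorter span 400: 25% < 50% reciprocal threshold
  ins <- dplyr::bind_rows(
    merge_family_hits(mk_hits(0, 500, identity = 95, family = "A"), 500),
    merge_family_hits(mk_hits(400, 800, identity = 90, family = "B"), 400))
  res <- resolve_cross_family_overlaps(ins)
  expect_equal(sort(res$family_id), c("A", "B"))
})

test_that("identity ties resolve to the longer span", {
  ins <- dplyr::bind_rows(
    merge_family_hits(mk_hits(0, 400, identity = 95, family = "B"), 400),
    merge_family_hits(mk_hits(0, 600, identity = 95, family = "A"), 600))
  res <- resolve_cross_family_overlaps(ins)
  expect_equal(res$family_id, "A")
})

test_that("annotate_genome recovers a small planted landscape exactly", {
  specs <- dplyr::bind_rows(
    family_spec("TEA", 600, copy_number = 5, divergence = 0.03,
                full_length_fraction = 0.5),
    family_spec("TEB", 1200, copy_number = 4, divergence = 0.05,
                full_length_fraction = 0.5))
  sim <- simulate_genome(specs, c(40000L, 40000L), seed = 21L)
  hits <- simulate_hits(sim, split_prob = 0.5, seed = 22L)
  ins <- annotate_genome(hits, sim$consensus)
  got <- dplyr::count(ins, family_id)
  expect_equal(got$n[got$family_id == "TEA"], 5L)
  expect_equal(got$n[got$family_id == "TEB"], 4L)
  truth <- sim$truth$insertions[order(sim$truth$insertions$contig,
                                      sim$truth$insertions$start), ]
  expect_equal(ins$start, truth$start)
  expect_equal(ins$end, truth$end)
})

test_that("annotate_genome rejects hits for unknown families", {
  cons <- tibble::tibble(id = "A", sequence = strrep("A", 100))
  expect_error(annotate_genome(mk_hits(0, 50, family = "ZZ"), cons),
               "unknown family ZZ")
})

test_that("summarize_families reports traits and a genome-based pi", {
  specs <- dplyr::bind_rows(
    family_spec("TEA", 500, copy_number = 4, divergence = 0.04,
                full_length_fraction = 1),
    family_spec("TEB", 700, copy_number = 3, divergence = 0,
                full_length_fraction = 1))
  sim <- simulate_genome(specs, c(30000L, 30000L), seed = 31L)
  hits <- simulate_hits(sim, split_prob = 0, seed = 32L)
  ins <- annotate_genome(hits, sim$consensus)
  no_genome <- summarize_families(ins, sim$consensus)
  expect_true(all(is.na(no_genome$pi)))
  fam <- summarize_families(ins, sim$consensus, sim$genome)
  expect_equal(fam$copy_number, c(4L, 3L))
  expect_equal(fam$full_length_count, c(4L, 3L))
  expect_equal(fam$consensus_length, c(500L, 700L))
  expect_identical(fam$pi[fam$family_id == "TEB"], 0)
  expect_equal(fam$pi[fam$family_id == "TEA"],
               sim$truth$pi$true_pi[sim$truth$pi$family_id == "TEA"])
})
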