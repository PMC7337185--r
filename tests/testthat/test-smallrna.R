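test_that("partition_by_size is inclusive on both bounds", {
  reads <- tibble::tibble(read_id = paste0("r", 1:4),
                          sequence = strrep("A", c(18, 19, 30, 31)))
  kept <- partition_by_size(reads, 19, 30)
  expect_equal(kept$read_id, c("r2", "r3"))
  expect_error(partition_by_size(reads, 30, 19), "lo")
})

test_that("count_mirna matches exactly in either orientation", {
  mirna <- tibble::tibble(id = "mir_1", sequence = "ACGTACGTACGTACGTACGTAC")
  reads <- tibble::tibble(
    read_id = paste0("r", 1:4),
    sequence = c("ACGTACGTACGTACGTACGTAC",            # exact
                 revcomp("ACGTACGTACGTACGTACGTAC"),   # reverse complement
                 "ACGTACGTACGTACGTACGTA",             # one nt short
                 "ACGTACGTACGTACGTACGTAG"))           # one mismatch
  expect_equal(count_mirna(reads, mirna), 2)
  expect_error(count_mirna(reads, mirna[0, ]), "empty miRNA")
})

test_that("align_to_consensus agrees with the brute-force oracle", {
  withr::local_seed(17)
  for (rep in 1:10) {
    cons <- tibble::tibble(
      id = c("A", "B"),
      sequence = vapply(c(150, 200), function(L) {
        paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
      }, character(1)))
    reads <- tibble::tibble(
      read_id = paste0("r", 1:12),
      sequence = vapply(1:12, function(i) {
        src <- cons$sequence[sample(2, 1)]
        L <- sample(20:28, 1)
        s <- sample(nchar(src) - L, 1)
        rd <- substr(src, s, s + L - 1)
        chars <- strsplit(rd, "")[[1]]
        nmut <- sample(0:4, 1)
        if (nmut > 0) {
          at <- sample(L, nmut)
          chars[at] <- vapply(chars[at], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }, character(1))
        }
        rd <- paste(chars, collapse = "")
        if (runif(1) < 0.5) rd else revcomp(rd)
      }, character(1)))
    got <- align_to_consensus(reads, cons, max_mismatch = 3)
    want <- oracle_match(reads$sequence, cons$sequence, 3,
                         best_stratum = TRUE)
    got_cmp <- sort_hits(tibble::tibble(
      read = match(got$read_id, reads$read_id),
      ref = match(got$family_id, cons$id),
      start = got$offset, strand = got$strand,
      mismatches = got$mismatches))
    expect_equal(got_cmp, sort_hits(want), ignore_attr = TRUE)
  }
})

test_that("assign_unique_family keeps one-family reads and drops the rest", {
  aln <- tibble::tibble(
    read_id = c("r1", "r2", "r2", "r3", "r3"),
    family_id = c("A", "A", "A", "A", "B"),
    offset = c(0L, 5L, 40L, 0L, 0L),
    strand = "+", mismatches = 0L, length = 25L)
  got <- assign_unique_family(aln)
  expect_equal(got$status[got$read_id == "r1"], "assigned")
  expect_equal(got$status[got$read_id == "r2"], "assigned")
  expect_equal(got$n_placements[got$read_id == "r2"], 2L)
  expect_equal(got$status[got$read_id == "r3"], "discarded")
  expect_true(is.na(got$family_id[got$read_id == "r3"]))
})

test_that("count_family_reads zero-fills requested families", {
  assignments <- tibble::tibble(
    read_id = c("r1", "r2", "r3"), family_id = c("A", "A", NA),
    status = c("assigned", "assigned", "discarded"),
    n_placements = c(1L, 1L, 2L))
  got <- count_family_reads(assignments, families = c("A", "B"))
  expect_equal(got$raw_count, c(2L, 0L))
})

test_that("normalization and sex-bias classification follow the fold rule", {
  counts <- tibble::tibble(
    family_id = rep(c("up", "down", "flat", "edge"), each = 2),
    tissue = rep(c("ovary", "testis"), 4),
    raw_count = c(400L, 50L,   10L, 160L,   100L, 50L,   299L, 74L))
  totals <- c(ovary = 2e5, testis = 1e5)
  got <- normalize_and_classify(counts, totals, fold = 2)
  expect_equal(got$ovary_norm[got$family_id == "up"], 400 / 2e5 * 1e6)
  expect_equal(got$testis_norm[got$family_id == "up"], 50 / 1e5 * 1e6)
  expect_equal(got$fold_change[got$family_id == "up"],
               ((400 + 1) / 2e5) / ((50 + 1) / 1e5))
  expect_equal(got$sex_bias_class[got$family_id == "up"], "ovary_biased")
  expect_equal(got$sex_bias_class[got$family_id == "down"], "testis_biased")
  expect_equal(got$sex_bias_class[got$family_id == "flat"], "unbiased")
  # fold change exactly 2 is not strictly greater: unbiased
  expect_equal(got$fold_change[got$family_id == "edge"], 2)
  expect_equal(got$sex_bias_class[got$family_id == "edge"], "unbiased")
  expect_error(normalize_and_classify(counts, c(ovary = 0, testis = 1e5)),
               "positive")
})

test_that("missing tissues are zero-filled before classification", {
  counts <- tibble::tibble(family_id = "A", tissue = "ovary",
                           raw_count = 30L)
  got <- normalize_and_classify(counts, c(ovary = 1e5, testis = 1e5))
  expect_equal(got$testis_raw, 0L)
  expect_equal(got$sex_bias_class, "ovary_biased")
})

test_that("quantify_pirna recovers a planted ovary-biased family", {
  specs <- dplyr::bind_rows(
    family_spec("UP", 900, copy_number = 3, divergence = 0.01,
                full_length_fraction = 1),
    family_spec("FLAT", 1100, copy_number = 3, divergence = 0.01,
                full_length_fraction = 1))
  sim <- simulate_genome(specs, c(40000L, 40000L), seed = 51L)
  ovary <- simulate_smallrna(sim, library_spec(
    "ovary", n_mirna_reads = 500,
    te_read_budget = c(UP = 200, FLAT = 50), seed = 52L))
  testis <- simulate_smallrna(sim, library_spec(
    "testis", n_mirna_reads = 500,
    te_read_budget = c(UP = 20, FLAT = 50), seed = 53L))
  quant <- quantify_pirna(ovary$reads, testis$reads, sim$consensus,
                          sim$mirna)
  expect_equal(unname(quant$mirna_totals), c(500, 500))
  lv <- quant$levels
  expect_equal(lv$sex_bias_class[lv$family_id == "UP"], "ovary_biased")
  expect_equal(lv$sex_bias_class[lv$family_id == "FLAT"], "unbiased")
  # nearly every emitted TE read should map back to its family
  expect_gt(lv$ovary_raw[lv$family_id == "UP"], 180)
})
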