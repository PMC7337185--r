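#' Keep reads within an inclusive length window
#'
#' @param reads Read tibble with `read_id`, `sequence`.
#' @param lo,hi Inclusive length bounds, nt (19-30 for TE-derived small RNAs,
#'   23-30 for piRNAs).
#' @return Filtered read tibble.
#' @export
partition_by_size <- function(reads, lo, hi) {
  if (lo > hi) stop("lo must not exceed hi", call. = FALSE)
  len <- nchar(reads$sequence)
  reads[len >= lo & len <= hi, , drop = FALSE]
}

#' Count miRNA reads in a library
#'
#' A read counts as a miRNA when it matches a reference miRNA sequence
#' exactly, full length, in either orientation. The count is the library's
#' normalization denominator.
#'
#' @param reads Read tibble (the whole library, before size partitioning).
#' @param mirna miRNA reference tibble (`id`, `sequence`).
#' @return Integer count.
#' @export
count_mirna <- function(reads, mirna) {
  if (nrow(mirna) == 0) stop("empty miRNA reference set", call. = FALSE)
  targets <- unique(c(mirna$sequence, revcomp(mirna$sequence)))
  sum(reads$sequence %in% targets)
}

#' Align reads end-to-end to a set of TE consensus sequences
#'
#' Ungapped full-length scan of every consensus, both strands, reporting all
#' placements in each read's best stratum (its minimum mismatch count), and
#' nothing above `max_mismatch`.
#'
#' @param reads Read tibble.
#' @param consensus Consensus tibble (`id`, `sequence`).
#' @param max_mismatch Mismatch ceiling (default 3).
#' @return Alignment tibble: `read_id`, `family_id`, `offset` (0-based
#'   leftmost position on the consensus), `strand`, `mismatches`, `length`.
#' @export
align_to_consensus <- function(reads, consensus, max_mismatch = 3) {
  hits <- match_reads_cpp(reads$sequence, consensus$sequence,
                          as.integer(max_mismatch), TRUE)
  tibble::tibble(
    read_id = reads$read_id[hits$read],
    family_id = consensus$id[hits$ref],
    offset = hits$start,
    strand = hits$strand,
    mismatches = hits$mismatches,
    length = nchar(reads$sequence[hits$read]))
}

#' Assign each read to a unique TE family or discard it
#'
#' A read whose best-stratum placements all fall on one consensus is
#' assigned to that family (multiple positions on that consensus are fine);
#' a read whose best stratum spans two or more families is discarded.
#'
#' @param alignments Best-stratum alignment tibble from
#'   [align_to_consensus()].
#' @return Tibble `read_id`, `family_id` (`NA` when discarded), `status`
#'   (`"assigned"` or `"discarded"`), `n_placements`.
#' @export
assign_unique_family <- function(alignments) {
  alignments |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(
      n_families = dplyr::n_distinct(.data$family_id),
      family_id = .data$family_id[1],
      n_placements = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(
      status = ifelse(.data$n_families == 1, "assigned", "discarded"),
      family_id = ifelse(.data$n_families == 1, .data$family_id,
                         NA_character_)) |>
    dplyr::select("read_id", "family_id", "status", "n_placements")
}

#' Count assigned reads per family
#'
#' @param assignments Output of [assign_unique_family()].
#' @param families Optional character vector of family ids to report
#'   (zero-filled).
#' @return Tibble `family_id`, `raw_count`.
#' @export
count_family_reads <- function(assignments, families = NULL) {
  counts <- assignments |>
    dplyr::filter(.data$status == "assigned") |>
    dplyr::count(.data$family_id, name = "raw_count")
  if (!is.null(families)) {
    counts <- tibble::tibble(family_id = families) |>
      dplyr::left_join(counts, by = "family_id") |>
      dplyr::mutate(raw_count = tidyr::replace_na(.data$raw_count, 0L))
  }
  counts
}

#' Normalize piRNA counts by miRNA abundance and classify sex bias
#'
#' Per-family piRNA counts are scaled to counts per million miRNA reads.
#' The ovary/testis fold change is computed with a pseudocount of one raw
#' read in each tissue (keeping the rule total and monotone when one tissue
#' has zero reads); a family is ovary-biased when the ratio exceeds `fold`,
#' testis-biased when it is below `1/fold`, otherwise unbiased.
#'
#' @param counts Long tibble: `family_id`, `tissue` (`"ovary"`/`"testis"`),
#'   `raw_count`.
#' @param mirna_totals Named numeric vector or tibble (`tissue`,
#'   `mirna_total`) of per-library miRNA counts; both must be positive.
#' @param fold Fold-change threshold (default 2).
#' @return Tibble per family: raw and normalized counts per tissue,
#'   `fold_change` (ovary over testis), `sex_bias_class`.
#' @export
normalize_and_classify <- function(counts, mirna_totals, fold = 2) {
  if (is.data.frame(mirna_totals)) {
    mirna_totals <- setNames(mirna_totals$mirna_total, mirna_totals$tissue)
  }
  if (any(is.na(mirna_totals[c("ovary", "testis")])) ||
      any(mirna_totals[c("ovary", "testis")] <= 0)) {
    stop("miRNA totals must be positive for both tissues", call. = FALSE)
  }
  wide <- counts |>
    tidyr::pivot_wider(id_cols = "family_id", names_from = "tissue",
                       values_from = "raw_count", values_fill = 0L)
  for (t in c("ovary", "testis")) if (!t %in% names(wide)) wide[[t]] <- 0L
  mo <- mirna_totals[["ovary"]]; mt <- mirna_totals[["testis"]]
  wide |>
    dplyr::transmute(
      family_id = .data$family_id,
      ovary_raw = .data$ovary, testis_raw = .data$testis,
      ovary_norm = .data$ovary / mo * 1e6,
      testis_norm = .data$testis / mt * 1e6,
      fold_change = ((.data$ovary + 1) / mo) / ((.data$testis + 1) / mt),
      sex_bias_class = dplyr::case_when(
        .data$fold_change > fold ~ "ovary_biased",
        .data$fold_change < 1 / fold ~ "testis_biased",
        TRUE ~ "unbiased"))
}

#' Quantify per-family piRNA production in two gonadal libraries
#'
#' Convenience wrapper over the small-RNA stage: size-partition each
#' library, count miRNAs, align to the consensus set, keep uniquely assigned
#' reads, and normalize/classify.
#'
#' @param ovary,testis Read tibbles for the two libraries.
#' @param consensus Consensus tibble.
#' @param mirna miRNA reference tibble.
#' @param size Inclusive length window used for the TE mapping (default
#'   `c(19, 30)`).
#' @param max_mismatch Mismatch ceiling for consensus mapping.
#' @param fold Sex-bias fold-change threshold.
#' @param exclude_mirna Remove reads that count as miRNAs (exact full-length
#'   match, either orientation) before TE mapping, the usual library
#'   cleaning step (default `TRUE`).
#' @return List with `levels` (the [normalize_and_classify()] table),
#'   `assignments` (per tissue) and `mirna_totals`.
#' @export
quantify_pirna <- function(ovary, testis, consensus, mirna,
                           size = c(19L, 30L), max_mismatch = 3, fold = 2,
                           exclude_mirna = TRUE) {
  libs <- list(ovary = ovary, testis = testis)
  mirna_totals <- vapply(libs, count_mirna, numeric(1), mirna = mirna)
  mirna_seqs <- unique(c(mirna$sequence, revcomp(mirna$sequence)))
  assignments <- lapply(libs, function(reads) {
    if (exclude_mirna) {
      reads <- reads[!reads$sequence %in% mirna_seqs, , drop = FALSE]
    }
    reads |>
      partition_by_size(size[1], size[2]) |>
      align_to_consensus(consensus, max_mismatch) |>
      assign_unique_family()
  })
  counts <- dplyr::bind_rows(lapply(names(libs), function(t) {
    count_family_reads(assignments[[t]], consensus$id) |>
      dplyr::mutate(tissue = t)
  }))
  list(levels = normalize_and_classify(counts, mirna_totals, fold),
       assignments = assignments,
       mirna_totals = mirna_totals)
}
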