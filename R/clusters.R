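#' Map piRNA reads uniquely to a genome
#'
#' End-to-end scan of both strands of every contig with a mismatch ceiling
#' (default 1). A read is kept only when its best stratum (minimum mismatch
#' count) contains exactly one placement genome-wide; multimapping reads are
#' excluded.
#'
#' @param reads piRNA read tibble (already size-partitioned to 23-30 nt).
#' @param genome Genome sequence tibble.
#' @param max_mismatch Mismatch ceiling (default 1).
#' @return Alignment tibble: `read_id`, `contig`, `offset`, `strand`,
#'   `mismatches`, `length`, `five_prime` (genomic position of the 5' end).
#' @export
map_unique_genome <- function(reads, genome, max_mismatch = 1) {
  hits <- match_reads_cpp(reads$sequence, genome$sequence,
                          as.integer(max_mismatch), TRUE)
  keep <- !(duplicated(hits$read) | duplicated(hits$read, fromLast = TRUE))
  hits <- hits[keep, , drop = FALSE]
  len <- nchar(reads$sequence[hits$read])
  tibble::tibble(
    read_id = reads$read_id[hits$read],
    contig = genome$id[hits$ref],
    offset = hits$start,
    strand = hits$strand,
    mismatches = hits$mismatches,
    length = len,
    five_prime = ifelse(hits$strand == "+", hits$start,
                        hits$start + len - 1L))
}

#' Classify a cluster window's tissue specificity
#'
#' A tissue is called active when its own unique piRNA count exceeds the
#' density threshold. Windows active in one tissue are `ovary_only` /
#' `testis_only`; active in both, `both`. A window that passed the screen on
#' pooled counts alone (neither tissue individually above threshold) is
#' reported as `both` with `low_confidence = TRUE`.
#'
#' @param ovary_count,testis_count Per-window unique piRNA counts.
#' @param threshold Per-tissue activity threshold in reads per window
#'   (strict `>`, default 5).
#' @return Tibble `tissue_class`, `low_confidence`, vectorized over windows.
#' @export
classify_tissue <- function(ovary_count, testis_count, threshold = 5) {
  o <- ovary_count > threshold
  t <- testis_count > threshold
  tibble::tibble(
    tissue_class = dplyr::case_when(
      o & t ~ "both",
      o & !t ~ "ovary_only",
      !o & t ~ "testis_only",
      TRUE ~ "both"),
    low_confidence = !o & !t)
}

#' Screen the genome for piRNA cluster windows
#'
#' Non-overlapping windows anchored at coordinate 0 tile each contig; a read
#' belongs to the window containing its 5' end. A window is a cluster window
#' when its pooled unique piRNA count strictly exceeds
#' `min_density * window / 1000` (more than five piRNAs per kb by default);
#' tissue specificity is then called per tissue with the same threshold.
#'
#' @param alignments Unique-alignment tibble from [map_unique_genome()] with
#'   a `tissue` column.
#' @param contig_lengths Optional named integer vector of contig lengths,
#'   used to clip the last window of each contig.
#' @param window Window width, nt (default 1000).
#' @param min_density Density threshold in reads per kb (strict `>`).
#' @return Tibble: `contig`, `window_start`, `window_end`, `ovary_count`,
#'   `testis_count`, `pooled_count`, `tissue_class`, `low_confidence`.
#' @export
screen_windows <- function(alignments, contig_lengths = NULL,
                           window = 1000L, min_density = 5) {
  if (window <= 0) stop("window must be positive", call. = FALSE)
  threshold <- min_density * window / 1000
  counts <- alignments |>
    dplyr::mutate(window_start = (.data$five_prime %/% window) * window) |>
    dplyr::count(.data$contig, .data$window_start, .data$tissue) |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "n",
                       values_fill = 0L)
  for (t in c("ovary", "testis")) if (!t %in% names(counts)) counts[[t]] <- 0L
  counts <- counts |>
    dplyr::rename(ovary_count = "ovary", testis_count = "testis") |>
    dplyr::relocate("ovary_count", "testis_count",
                    .after = "window_start") |>
    dplyr::mutate(pooled_count = .data$ovary_count + .data$testis_count) |>
    dplyr::filter(.data$pooled_count > threshold)
  cls <- classify_tissue(counts$ovary_count, counts$testis_count, threshold)
  counts |>
    dplyr::mutate(window_end = if (is.null(contig_lengths))
                    .data$window_start + window
                  else pmin(.data$window_start + window,
                            contig_lengths[.data$contig]),
                  tissue_class = cls$tissue_class,
                  low_confidence = cls$low_confidence) |>
    dplyr::relocate("window_end", .after = "window_start") |>
    dplyr::arrange(.data$contig, .data$window_start)
}

#' TE presence profiles along cluster windows
#'
#' For each cluster tissue class and each TE sex-bias class (plus `"all"`),
#' the profile value at window position `p` is the fraction of windows of
#' that class in which position `p` is covered by at least one insertion of
#' a family in that TE class.
#'
#' @param windows Cluster window tibble from [screen_windows()].
#' @param insertions TE insertion tibble.
#' @param classes Tibble `family_id`, `sex_bias_class`.
#' @param window Window width, nt.
#' @return A `te_density_profile` tibble: `window_class`, `te_class`,
#'   `position` (0-based within the window), `density` in `[0, 1]`, and
#'   `n_windows`.
#' @export
te_density_profile <- function(windows, insertions, classes,
                               window = 1000L) {
  insertions <- dplyr::left_join(insertions, classes, by = "family_id")
  insertions$sex_bias_class[is.na(insertions$sex_bias_class)] <- "unbiased"
  te_classes <- c("all", sort(unique(insertions$sex_bias_class)))
  out <- list()
  for (wc in sort(unique(windows$tissue_class))) {
    w <- windows[windows$tissue_class == wc, ]
    for (tc in te_classes) {
      ins <- if (tc == "all") insertions else
        insertions[insertions$sex_bias_class == tc, ]
      acc <- numeric(window)
      for (i in seq_len(nrow(w))) {
        cov <- logical(window)
        ws <- w$window_start[i]
        hit <- ins[ins$contig == w$contig[i] &
                   ins$start < ws + window & ins$end > ws, ]
        for (j in seq_len(nrow(hit))) {
          a <- max(hit$start[j] - ws, 0L) + 1L
          b <- min(hit$end[j] - ws, window)
          cov[a:b] <- TRUE
        }
        acc <- acc + cov
      }
      out[[paste(wc, tc)]] <- tibble::tibble(
        window_class = wc, te_class = tc,
        position = seq_len(window) - 1L,
        density = if (nrow(w) > 0) acc / nrow(w) else acc,
        n_windows = nrow(w))
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("te_density_profile", class(res))
  res
}

#' @export
autoplot.te_density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$density,
                                       colour = .data$te_class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ window_class) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "position in 1-kb cluster window (nt)",
                  y = "mean TE presence",
                  colour = "TE expression class") +
    ggplot2::theme_minimal()
}

#' Write cluster windows as BED6
#'
#' One BED record per cluster window, name = tissue class, score = pooled
#' unique piRNA count.
#'
#' @param windows Cluster window tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_bed <- function(windows, path) {
  lines <- character(0)
  if (nrow(windows) > 0) {
    lines <- paste(windows$contig, windows$window_start, windows$window_end,
                   windows$tissue_class, windows$pooled_count, ".",
                   sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
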