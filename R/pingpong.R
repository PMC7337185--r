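#' 5'-5' overlap distribution of sense and antisense piRNAs
#'
#' For one family's consensus alignments: every (plus-strand read, minus-
#' strand read) combination whose reads physically overlap contributes at
#' the overlap length `k = m - s + 1`, where `s` is the plus read's 5' end
#' (its leftmost consensus position) and `m` the minus read's 5' end (its
#' rightmost position). Ping-pong amplification leaves an excess at `k = 10`.
#' Pairing is counted over all combinations at an offset, not capped per
#' read; counting is done by cross-correlating 5'-end position counts per
#' read-length pair, which is equivalent to the all-pairs double loop.
#'
#' @param alignments Alignment tibble of one family (columns `family_id`,
#'   `offset`, `strand`, `length`).
#' @param K Largest overlap tracked (default 20).
#' @param collapse Collapse duplicate placements (same strand, offset,
#'   length) to one before pairing (default `FALSE`).
#' @return Named integer vector of length `K`: pair counts at overlaps
#'   `1..K`.
#' @export
overlap_distribution <- function(alignments, K = 20, collapse = FALSE) {
  if (dplyr::n_distinct(alignments$family_id) > 1) {
    stop("overlap_distribution() expects alignments of one family",
         call. = FALSE)
  }
  counts <- setNames(integer(K), seq_len(K))
  if (nrow(alignments) == 0) return(counts)
  if (collapse) {
    alignments <- dplyr::distinct(alignments, .data$strand, .data$offset,
                                  .data$length)
  }
  plus <- alignments[alignments$strand == "+", ]
  minus <- alignments[alignments$strand == "-", ]
  if (nrow(plus) == 0 || nrow(minus) == 0) return(counts)
  plus$p5 <- plus$offset
  minus$p5 <- minus$offset + minus$length - 1L
  # Stratify by the (plus length, minus length) pair: a pair at overlap k
  # keeps a physical footprint overlap only while k <= Lp + Lm - 1 (the
  # minus read's start must not pass the plus read's end).
  nbins <- max(c(plus$p5, minus$p5)) + 1L
  for (lp in unique(plus$length)) {
    p5 <- plus$p5[plus$length == lp]
    tp <- tabulate(p5 + 1L, nbins = nbins)
    for (lm in unique(minus$length)) {
      m5 <- minus$p5[minus$length == lm]
      tm <- tabulate(m5 + 1L, nbins = nbins)
      kmax <- min(K, lp + lm - 1L)
      if (kmax < 1) next
      for (k in seq_len(kmax)) {
        # minus 5' = plus 5' + k - 1
        idx <- seq_len(length(tp) - k + 1L)
        counts[k] <- counts[k] + sum(tp[idx] * tm[idx + k - 1L])
      }
    }
  }
  counts
}

#' Ping-pong z-score at overlap 10
#'
#' The signal is the pair count at overlap 10; the background is the counts
#' at every other tracked overlap. `z10 = (counts[10] - mean(bg)) /
#' sd_pop(bg)` with the population (divide-by-N) standard deviation. The
#' signature is significant when `z10 > 1.96` (one-sided 2.5%). A zero
#' background SD yields `+Inf` (significant) when the signal exceeds the
#' background mean, and an undefined, non-significant score otherwise.
#'
#' @param counts Overlap count vector from [overlap_distribution()].
#' @param signal Overlap length carrying the ping-pong signal (default 10).
#' @return List with `z10` and `significant`.
#' @export
zscore_signature <- function(counts, signal = 10) {
  bg <- counts[-signal]
  mu <- mean(bg)
  sd_pop <- sqrt(mean((bg - mu)^2))
  if (sd_pop == 0) {
    if (counts[signal] > mu) {
      return(list(z10 = Inf, significant = TRUE))
    }
    return(list(z10 = NA_real_, significant = FALSE))
  }
  z <- (counts[signal] - mu) / sd_pop
  list(z10 = z, significant = z > 1.96)
}

#' Ping-pong pairs per piRNA
#'
#' The heatmap metric: 10-nt overlapping pairs normalized by the family's
#' piRNA count. Reported as missing when the family has no piRNAs.
#'
#' @param n_pairs10 Pair count at overlap 10.
#' @param n_pirnas Number of piRNAs assigned to the family.
#' @return A number, or `NA` when `n_pirnas` is 0.
#' @export
pairs_per_pirna <- function(n_pairs10, n_pirnas) {
  stopifnot(n_pirnas >= 0)
  if (n_pirnas == 0) return(NA_real_)
  n_pairs10 / n_pirnas
}

#' Ping-pong signatures for every family (and tissue) in an alignment table
#'
#' @param alignments Alignment tibble, optionally with a `tissue` column.
#' @param K Largest overlap tracked.
#' @param collapse See [overlap_distribution()].
#' @return A `pingpong_signature` tibble: one row per family (x tissue) with
#'   `n_pirnas`, `pairs10`, `z10`, `significant`, `ppr`, and the full
#'   overlap histogram in the list column `overlap_counts`.
#' @export
ping_pong_signature <- function(alignments, K = 20, collapse = FALSE) {
  groups <- c("family_id", intersect("tissue", names(alignments)))
  res <- alignments |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::group_modify(function(d, key) {
      d$family_id <- key$family_id
      counts <- overlap_distribution(d, K = K, collapse = collapse)
      zs <- zscore_signature(counts)
      n <- if ("read_id" %in% names(d)) dplyr::n_distinct(d$read_id)
           else nrow(d)
      tibble::tibble(
        n_pirnas = n, pairs10 = counts[[10]],
        z10 = zs$z10, significant = zs$significant,
        ppr = pairs_per_pirna(counts[[10]], n),
        overlap_counts = list(counts))
    }) |>
    dplyr::ungroup()
  class(res) <- c("pingpong_signature", class(res))
  res
}

#' @export
tidy.pingpong_signature <- function(x, ...) {
  x |>
    dplyr::mutate(k = purrr::map(.data$overlap_counts,
                                 ~ tibble::tibble(overlap = seq_along(.x),
                                                  pairs = unname(.x)))) |>
    dplyr::select(-"overlap_counts") |>
    tidyr::unnest("k")
}

#' @export
glance.pingpong_signature <- function(x, ...) {
  tibble::tibble(
    n_families = dplyr::n_distinct(x$family_id),
    n_significant = sum(x$significant, na.rm = TRUE),
    median_ppr = median(x$ppr, na.rm = TRUE))
}

#' @export
autoplot.pingpong_signature <- function(object, ...) {
  d <- tidy.pingpong_signature(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$overlap, y = .data$pairs)) +
    ggplot2::geom_col(ggplot2::aes(
      fill = .data$overlap == 10), show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c("grey60", "firebrick")) +
    ggplot2::facet_wrap(~ family_id, scales = "free_y") +
    ggplot2::labs(x = "5'-5' overlap (nt)", y = "read pairs",
                  title = "Ping-pong overlap signatures") +
    ggplot2::theme_minimal()
}
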