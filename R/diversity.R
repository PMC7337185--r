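#' Place family copies on consensus coordinates
#'
#' Ungapped sliding-window placement: each copy is put at the consensus
#' offset minimizing its Hamming distance (leftmost offset on ties) and
#' padded with gaps outside the copy. Adequate for substitution-only
#' divergence; indel-bearing copies would need a gapped aligner.
#'
#' @param copies Character vector of copy sequences, oriented like the
#'   consensus.
#' @param consensus Consensus sequence (single string).
#' @return Character vector of gapped sequences, all of consensus length.
#' @export
align_copies_to_consensus <- function(copies, consensus) {
  L <- nchar(consensus)
  vapply(copies, function(cp) {
    if (nchar(cp) > L) {
      stop("copy is longer than the consensus", call. = FALSE)
    }
    fit <- best_offset_cpp(cp, consensus)
    off <- fit[1]
    paste0(strrep("-", off), cp, strrep("-", L - off - nchar(cp)))
  }, character(1), USE.NAMES = FALSE)
}

#' Nucleotide diversity of aligned copies
#'
#' Frequency-weighted mean pairwise difference:
#' `pi = 2 * sum_{i>j} x_i x_j pi_ij`, where `pi_ij` is the per-site
#' difference between copies i and j over columns where both carry a plain
#' base (gap and `N` columns are excluded pairwise). With the default equal
#' frequencies `x_i = 1/n` — each genomic copy counted once — two copies
#' differing at 1 of 100 comparable sites give `2 * 0.25 * 0.01 = 0.005`.
#' A pair with no comparable column contributes 0 with a warning. Returns 0
#' for fewer than two copies.
#'
#' @param aligned Character vector of gapped sequences of equal length.
#' @param frequencies Optional copy frequencies summing to 1 (default
#'   `1/n` each).
#' @return Nucleotide diversity, a non-negative number.
#' @export
nucleotide_diversity <- function(aligned, frequencies = NULL) {
  n <- length(aligned)
  if (n < 2) return(0)
  if (dplyr::n_distinct(nchar(aligned)) != 1) {
    stop("aligned sequences must all have the same length", call. = FALSE)
  }
  if (is.null(frequencies)) {
    frequencies <- rep(1 / n, n)
  } else {
    stopifnot(length(frequencies) == n,
              abs(sum(frequencies) - 1) < 1e-8)
  }
  m <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  ok <- m == "A" | m == "C" | m == "G" | m == "T"
  total <- 0
  warned <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0) {
        warned <- TRUE
        next
      }
      pij <- sum(m[i, comp] != m[j, comp]) / nc
      total <- total + frequencies[i] * frequencies[j] * pij
    }
  }
  if (warned) {
    warning("copy pair(s) with no comparable columns contribute 0 to pi",
            call. = FALSE)
  }
  2 * total
}
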