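#' Filter similarity hits by percent identity
#'
#' Hits below the identity cutoff against their family consensus are removed;
#' the boundary itself is kept (a hit at exactly the cutoff survives). Row
#' order is preserved.
#'
#' @param hits Hit tibble from [read_hits()] or [simulate_hits()].
#' @param min_identity Identity cutoff in percent (default 80).
#' @return Filtered hit tibble.
#' @export
filter_hits <- function(hits, min_identity = 80) {
  dplyr::filter(hits, .data$percent_identity >= min_identity)
}

#' Merge successive hits of one family into insertion calls
#'
#' Operates on the hits of a single family on one contig and strand, sorted
#' by genomic start. Two successive pieces are merged when their genomic
#' spans overlap, or when the sum of their lengths plus the gap between them
#' is strictly smaller than the consensus length (two fragments of one
#' interrupted insertion cannot jointly exceed their consensus). Merging is
#' transitive left to right: the growing insertion's hull is compared against
#' the next hit. The merged call spans the union hull; its identity is the
#' alignment-length-weighted mean of the merged hits.
#'
#' @param hits Hit tibble restricted to one (family, contig, strand).
#' @param consensus_length Length of the family consensus, nt.
#' @param full_length_min Completeness threshold for the full-length call
#'   (fraction of consensus length, default 0.98).
#' @return Insertion tibble: `family_id`, `contig`, `start`, `end`, `strand`,
#'   `identity`, `n_merged_hits`, `completeness`, `full_length`.
#' @export
merge_family_hits <- function(hits, consensus_length, full_length_min = 0.98) {
  if (nrow(hits) == 0) return(empty_insertions())
  if (dplyr::n_distinct(hits$family_id) > 1 ||
      dplyr::n_distinct(hits$contig) > 1 ||
      dplyr::n_distinct(hits$strand) > 1) {
    stop("merge_family_hits() expects hits of one family, contig and strand",
         call. = FALSE)
  }
  hits <- dplyr::arrange(hits, .data$start, .data$end)
  cur_start <- hits$start[1]; cur_end <- hits$end[1]
  cur_w <- hits$alignment_length[1]
  cur_id <- hits$percent_identity[1] * cur_w
  cur_n <- 1L
  out <- list(); oi <- 0L
  flush <- function() {
    oi <<- oi + 1L
    out[[oi]] <<- tibble::tibble(
      family_id = hits$family_id[1], contig = hits$contig[1],
      start = cur_start, end = cur_end, strand = hits$strand[1],
      identity = cur_id / cur_w, n_merged_hits = cur_n)
  }
  for (i in seq_len(nrow(hits))[-1]) {
    s <- hits$start[i]; e <- hits$end[i]
    overlap <- s < cur_end
    gap <- s - cur_end
    joined <- (cur_end - cur_start) + (e - s) + gap
    if (overlap || joined < consensus_length) {
      cur_end <- max(cur_end, e)
      cur_w <- cur_w + hits$alignment_length[i]
      cur_id <- cur_id + hits$percent_identity[i] * hits$alignment_length[i]
      cur_n <- cur_n + 1L
    } else {
      flush()
      cur_start <- s; cur_end <- e
      cur_w <- hits$alignment_length[i]
      cur_id <- hits$percent_identity[i] * cur_w
      cur_n <- 1L
    }
  }
  flush()
  res <- dplyr::bind_rows(out)
  res$completeness <- (res$end - res$start) / consensus_length
  res$full_length <- res$completeness >= full_length_min
  res
}

empty_insertions <- function() {
  tibble::tibble(family_id = character(0), contig = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 identity = numeric(0), n_merged_hits = integer(0),
                 completeness = numeric(0), full_length = logical(0))
}

#' Resolve overlapping insertion calls from different families
#'
#' When calls from two families cover essentially the same locus — one span
#' contained in the other, or reciprocal overlap of at least
#' `reciprocal_overlap` of the shorter span — only the call with the higher
#' consensus identity is kept (ties: the longer span, then the
#' lexicographically smaller family id). Partially overlapping calls with
#' substantial family-specific flanks are both retained as independent
#' insertions. Resolution is greedy in priority order, so a call is dropped
#' only if it conflicts with a retained higher-priority call.
#'
#' @param insertions Insertion tibble covering all families.
#' @param reciprocal_overlap Fraction of the shorter span that triggers a
#'   conflict (default 0.5).
#' @return Insertion tibble sorted by (contig, start).
#' @export
resolve_cross_family_overlaps <- function(insertions,
                                          reciprocal_overlap = 0.5) {
  if (nrow(insertions) < 2) {
    return(dplyr::arrange(insertions, .data$contig, .data$start))
  }
  ord <- order(-insertions$identity,
               -(insertions$end - insertions$start),
               insertions$family_id)
  kept <- list(); ki <- 0L
  for (i in ord) {
    cand <- insertions[i, ]
    conflict <- FALSE
    for (k in seq_len(ki)) {
      other <- kept[[k]]
      if (other$contig != cand$contig) next
      if (other$family_id == cand$family_id) next
      ov <- min(cand$end, other$end) - max(cand$start, other$start)
      if (ov <= 0) next
      shorter <- min(cand$end - cand$start, other$end - other$start)
      contained <- ov == shorter
      if (contained || ov / shorter >= reciprocal_overlap) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) {
      ki <- ki + 1L
      kept[[ki]] <- cand
    }
  }
  dplyr::arrange(dplyr::bind_rows(kept), .data$contig, .data$start)
}

#' Annotate a genome's TE insertions from raw similarity hits
#'
#' Full annotation stage: identity filter, per-(family, contig, strand) hit
#' merging, and cross-family conflict resolution.
#'
#' @param hits Hit tibble.
#' @param consensus Consensus sequence tibble (`id`, `sequence`); only
#'   lengths are used here.
#' @param min_identity Identity cutoff in percent.
#' @param full_length_min Completeness threshold for the full-length call.
#' @param reciprocal_overlap Cross-family conflict trigger.
#' @return Insertion tibble sorted by (contig, start).
#' @export
annotate_genome <- function(hits, consensus, min_identity = 80,
                            full_length_min = 0.98,
                            reciprocal_overlap = 0.5) {
  cons_len <- setNames(nchar(consensus$sequence), consensus$id)
  unknown <- setdiff(unique(hits$family_id), names(cons_len))
  if (length(unknown) > 0) {
    stop("hits reference unknown family ", unknown[1], call. = FALSE)
  }
  hits <- filter_hits(hits, min_identity)
  merged <- hits |>
    dplyr::group_by(.data$family_id, .data$contig, .data$strand) |>
    dplyr::group_split() |>
    purrr::map(~ merge_family_hits(.x, cons_len[[.x$family_id[1]]],
                                   full_length_min)) |>
    dplyr::bind_rows()
  if (nrow(merged) == 0) return(empty_insertions())
  resolve_cross_family_overlaps(merged, reciprocal_overlap)
}

#' Summarize per-family genomic traits of an annotation
#'
#' For every family: copy number, median genomic span length, full-length
#' copy count, and (when the genome is supplied) nucleotide diversity of the
#' copies after placing each on consensus coordinates.
#'
#' @param insertions Insertion tibble from [annotate_genome()].
#' @param consensus Consensus sequence tibble.
#' @param genome Optional genome sequence tibble; without it `pi` is `NA`.
#' @return Tibble: `family_id`, `copy_number`, `median_length`,
#'   `full_length_count`, `pi`, `consensus_length`.
#' @export
summarize_families <- function(insertions, consensus, genome = NULL) {
  cons_len <- setNames(nchar(consensus$sequence), consensus$id)
  base <- insertions |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(
      copy_number = dplyr::n(),
      median_length = median(.data$end - .data$start),
      full_length_count = sum(.data$full_length),
      .groups = "drop") |>
    dplyr::mutate(consensus_length = unname(cons_len[.data$family_id]))
  if (is.null(genome)) {
    base$pi <- NA_real_
  } else {
    genome_seq <- setNames(genome$sequence, genome$id)
    cons_seq <- setNames(consensus$sequence, consensus$id)
    base$pi <- vapply(base$family_id, function(fam) {
      rows <- insertions[insertions$family_id == fam, ]
      if (nrow(rows) < 2) return(0)
      copies <- extract_copies(rows, genome_seq)
      aln <- align_copies_to_consensus(copies, cons_seq[[fam]])
      nucleotide_diversity(aln)
    }, numeric(1), USE.NAMES = FALSE)
  }
  dplyr::relocate(base, "pi", .after = "full_length_count")
}

# Pull insertion sequences out of the genome, oriented to match the consensus.
extract_copies <- function(rows, genome_seq) {
  seqs <- substring(genome_seq[rows$contig], rows$start + 1L, rows$end)
  seqs[rows$strand == "-"] <- revcomp(seqs[rows$strand == "-"])
  unname(seqs)
}
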