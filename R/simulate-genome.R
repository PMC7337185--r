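#' Describe one synthetic TE family
#'
#' @param family_id Family name.
#' @param consensus_length Length of the family consensus, nt.
#' @param te_class One of `"LTR"`, `"non-LTR"`, `"DNA"`.
#' @param copy_number Number of genomic copies to plant (>= 0).
#' @param divergence Per-site substitution probability in `[0, 0.2]` applied
#'   independently to every planted copy.
#' @param full_length_fraction Probability that a planted copy keeps the whole
#'   consensus; the remainder are truncated.
#' @param min_truncation Minimum retained fraction for truncated copies; the
#'   retained fraction is uniform on `[min_truncation, 0.98)` and anchored at
#'   a uniformly chosen consensus end.
#' @return One-row tibble usable with [simulate_genome()]; rows can be bound
#'   together to describe a multi-family landscape.
#' @export
family_spec <- function(family_id, consensus_length, te_class = "LTR",
                        copy_number = 10, divergence = 0.05,
                        full_length_fraction = 0.5, min_truncation = 0.2) {
  stopifnot(
    is.character(family_id), nchar(family_id) > 0,
    consensus_length >= 1,
    te_class %in% c("LTR", "non-LTR", "DNA"),
    copy_number >= 0,
    divergence >= 0, divergence <= 0.2,
    full_length_fraction >= 0, full_length_fraction <= 1,
    min_truncation > 0, min_truncation < 0.98
  )
  tibble::tibble(
    family_id = family_id,
    consensus_length = as.integer(consensus_length),
    te_class = te_class,
    copy_number = as.integer(copy_number),
    divergence = divergence,
    full_length_fraction = full_length_fraction,
    min_truncation = min_truncation
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute each site independently with probability `rate`, always to one of
# the three alternative bases (no indels).
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) > 0) {
    bases <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(bases, b), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Simulate a genome with a planted TE landscape and piRNA clusters
#'
#' Background contigs are i.i.d. uniform nucleotides. Each planted TE copy is
#' the family consensus, possibly truncated to a contiguous interval anchored
#' at one end, mutated i.i.d. at the family's divergence rate, and written
#' over a uniformly chosen non-overlapping genomic segment on a uniformly
#' chosen strand. Planted piRNA-cluster windows are kilobase-aligned,
#' TE-free tiles reserved before any copy is placed, each assigned a tissue
#' activity pattern. A dedicated contig carrying 50 synthetic 22-nt miRNA
#' sequences is appended; it is excluded from TE annotation and serves as the
#' normalization reference. Every planted feature is recorded in the returned
#' ground truth.
#'
#' @param specs Tibble of family rows from [family_spec()].
#' @param contig_lengths Integer vector of background contig lengths.
#' @param seed Integer seed; all randomness in the simulation flows from it.
#' @param clusters Optional tibble with columns `tissue_class` (one of
#'   `"ovary_only"`, `"testis_only"`, `"both"`) and `n`, giving how many
#'   cluster windows of each activity class to plant.
#' @param cluster_width Width of each planted cluster window, nt (kilobase
#'   tiles by default so planted windows coincide with the screening grid).
#' @param family_spacing Minimum distance, in units of the family's
#'   consensus length, kept between two copies of the same family (default
#'   1). Keeps planted copies dispersed, as genomic TE insertions are, and
#'   guarantees that distinct planted copies remain separable by
#'   gap-tolerant hit merging (two fragments a full consensus length apart
#'   can never look like one interrupted insertion).
#' @return A list with elements `genome` (sequence tibble; contigs `contig_1`,
#'   ... plus `contig_mirna`), `consensus` (sequence tibble, one row per
#'   family), `mirna` (the 50 miRNA sequences), and `truth` (list with
#'   tibbles `insertions`, `clusters`, `pi`, plus the `specs` used).
#' @export
simulate_genome <- function(specs, contig_lengths, seed, clusters = NULL,
                            cluster_width = 1000L, family_spacing = 1) {
  stopifnot(nrow(specs) >= 1, all(contig_lengths >= 1))
  total_te <- sum(specs$copy_number * specs$consensus_length)
  if (total_te >= 0.8 * sum(contig_lengths)) {
    stop("planted TE length exceeds 80% of total contig length; ",
         "use longer contigs", call. = FALSE)
  }
  withr::with_seed(seed, {
    contigs <- setNames(
      vapply(contig_lengths, random_dna, character(1)),
      paste0("contig_", seq_along(contig_lengths)))
    occupied <- lapply(contig_lengths, function(...) {
      tibble::tibble(start = integer(0), end = integer(0),
                     family_id = character(0))
    })

    # Reserve kilobase-aligned, TE-free cluster windows first.
    cluster_truth <- tibble::tibble(
      cluster_id = character(0), contig = character(0),
      start = integer(0), end = integer(0), tissue_class = character(0))
    if (!is.null(clusters) && sum(clusters$n) > 0) {
      classes <- rep(clusters$tissue_class, clusters$n)
      tiles <- dplyr::bind_rows(lapply(seq_along(contig_lengths), function(ci) {
        n_tiles <- contig_lengths[ci] %/% cluster_width
        tibble::tibble(ci = ci, start = (seq_len(n_tiles) - 1L) * cluster_width)
      }))
      if (length(classes) > nrow(tiles)) {
        stop("not enough kilobase tiles to plant the requested clusters",
             call. = FALSE)
      }
      pick <- tiles[sample(nrow(tiles), length(classes)), , drop = FALSE]
      cluster_truth <- tibble::tibble(
        cluster_id = paste0("cluster_", seq_along(classes)),
        contig = names(contigs)[pick$ci],
        start = pick$start,
        end = pick$start + as.integer(cluster_width),
        tissue_class = classes)
      for (k in seq_len(nrow(pick))) {
        ci <- pick$ci[k]
        occupied[[ci]] <- dplyr::bind_rows(
          occupied[[ci]],
          tibble::tibble(start = pick$start[k],
                         end = pick$start[k] + as.integer(cluster_width),
                         family_id = NA_character_))
      }
    }

    consensus <- tibble::tibble(
      id = specs$family_id,
      sequence = vapply(specs$consensus_length, random_dna, character(1)))

    ins <- list()
    copy_i <- 0L
    for (f in seq_len(nrow(specs))) {
      sp <- specs[f, ]
      cons <- consensus$sequence[f]
      L <- sp$consensus_length
      for (k in seq_len(sp$copy_number)) {
        copy_i <- copy_i + 1L
        full <- runif(1) < sp$full_length_fraction
        if (full) {
          cs <- 0L; ce <- L
        } else {
          frac <- runif(1, sp$min_truncation, 0.98)
          keep <- max(1L, as.integer(round(frac * L)))
          if (runif(1) < 0.5) { cs <- 0L; ce <- keep }      # 5' anchored
          else { cs <- L - keep; ce <- L }                  # 3' anchored
        }
        fragment <- substr(cons, cs + 1L, ce)
        copy_seq <- mutate_seq(fragment, sp$divergence)
        len <- nchar(copy_seq)
        placed <- FALSE
        pad <- as.integer(ceiling(family_spacing * L))
        for (attempt in seq_len(1000L)) {
          ci <- sample(seq_along(contig_lengths), 1,
                       prob = pmax(contig_lengths - len, 1))
          if (contig_lengths[ci] < len) next
          pos <- sample.int(contig_lengths[ci] - len + 1L, 1) - 1L
          occ <- occupied[[ci]]
          if (any(pos < occ$end & pos + len > occ$start)) next
          same <- !is.na(occ$family_id) & occ$family_id == sp$family_id
          if (any(pos < occ$end[same] + pad &
                  pos + len > occ$start[same] - pad)) next
          strand <- sample(c("+", "-"), 1)
          genomic <- if (strand == "+") copy_seq else revcomp(copy_seq)
          substr(contigs[ci], pos + 1L, pos + len) <- genomic
          occupied[[ci]] <- dplyr::bind_rows(
            occ, tibble::tibble(start = pos, end = pos + len,
                                family_id = sp$family_id))
          ins[[copy_i]] <- tibble::tibble(
            copy_id = paste0("copy_", copy_i),
            family_id = sp$family_id,
            contig = names(contigs)[ci],
            start = pos, end = pos + len, strand = strand,
            full_length = full, cons_start = cs, cons_end = ce,
            copy_seq = copy_seq)
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("could not place a copy of ", sp$family_id,
               " after 1000 attempts; use larger contigs", call. = FALSE)
        }
      }
    }
    insertions <- if (copy_i > 0) dplyr::bind_rows(ins) else tibble::tibble(
      copy_id = character(0), family_id = character(0), contig = character(0),
      start = integer(0), end = integer(0), strand = character(0),
      full_length = logical(0), cons_start = integer(0),
      cons_end = integer(0), copy_seq = character(0))

    # Dedicated miRNA contig: 50 synthetic 22-nt sequences with 30-nt spacers.
    mirna <- tibble::tibble(
      id = paste0("mir_", seq_len(50)),
      sequence = vapply(rep(22L, 50), random_dna, character(1)))
    spacers <- vapply(rep(30L, 51), random_dna, character(1))
    mirna_contig <- paste0(paste0(spacers[-51], mirna$sequence,
                                  collapse = ""), spacers[51])
    genome <- tibble::tibble(
      id = c(names(contigs), "contig_mirna"),
      sequence = c(unname(contigs), mirna_contig))

    true_pi <- true_family_pi(insertions, consensus)

    list(genome = genome, consensus = consensus, mirna = mirna,
         truth = list(insertions = insertions, clusters = cluster_truth,
                      pi = true_pi, specs = specs))
  })
}

# Empirical nucleotide diversity of the planted copies, computed directly from
# the generator's own records (copies are already on consensus coordinates, so
# no alignment step is involved): the ground-truth counterpart of the
# pipeline-side estimate.
true_family_pi <- function(insertions, consensus) {
  dplyr::bind_rows(lapply(unique(insertions$family_id), function(fam) {
    rows <- insertions[insertions$family_id == fam, ]
    L <- nchar(consensus$sequence[consensus$id == fam])
    gapped <- vapply(seq_len(nrow(rows)), function(i) {
      paste0(strrep("-", rows$cons_start[i]), rows$copy_seq[i],
             strrep("-", L - rows$cons_end[i]))
    }, character(1))
    tibble::tibble(family_id = fam, true_pi = nucleotide_diversity(gapped))
  }))
}
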