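#' Describe one synthetic small-RNA library
#'
#' @param tissue `"ovary"` or `"testis"`.
#' @param n_mirna_reads Number of miRNA reads to emit (exact copies of the
#'   planted miRNA set).
#' @param te_read_budget Named integer vector: TE-derived reads per family
#'   (names are family ids), or a single number applied to every family.
#' @param pingpong_fraction Fraction of each family's TE reads emitted as
#'   sense/antisense pairs whose 5' ends overlap by exactly 10 nt.
#' @param read_length_range Inclusive range of TE/cluster read lengths, nt.
#' @param cluster_read_budget Reads per planted cluster window active in this
#'   tissue.
#' @param seed Integer seed for this library.
#' @return A one-element list of class `library_spec`.
#' @export
library_spec <- function(tissue, n_mirna_reads = 1000,
                         te_read_budget = 200, pingpong_fraction = 0,
                         read_length_range = c(23L, 30L),
                         cluster_read_budget = 0, seed = 1L) {
  stopifnot(
    tissue %in% c("ovary", "testis"),
    n_mirna_reads >= 0, all(te_read_budget >= 0),
    pingpong_fraction >= 0, pingpong_fraction <= 1,
    length(read_length_range) == 2,
    read_length_range[1] <= read_length_range[2],
    cluster_read_budget >= 0
  )
  structure(list(tissue = tissue, n_mirna_reads = as.integer(n_mirna_reads),
                 te_read_budget = te_read_budget,
                 pingpong_fraction = pingpong_fraction,
                 read_length_range = as.integer(read_length_range),
                 cluster_read_budget = as.integer(cluster_read_budget),
                 seed = as.integer(seed)),
            class = "library_spec")
}

#' Simulate one small-RNA library from a planted genome
#'
#' miRNA reads are exact copies drawn from the 50 planted miRNA sequences.
#' TE-derived reads of uniform length in the configured range are sampled
#' from the planted copies of each family. A `pingpong_fraction` of each
#' family's budget is emitted as read pairs: an antisense read with 5' end at
#' copy position `p` and a sense read with 5' end at `p - 9`, i.e. an exact
#' 10-nt 5'-5' overlap. Remaining TE reads get uniform positions and strands.
#' Cluster reads are sampled from planted cluster windows active in the
#' library's tissue; the random background makes them uniquely mappable.
#'
#' @param sim Result of [simulate_genome()].
#' @param spec A [library_spec()].
#' @return List with `reads` (tibble `read_id`, `sequence`, `tissue`) and
#'   `provenance` (one row per read: `read_id`, `source`, `family_id`,
#'   `copy_id`, `cluster_id`, `strand`, `five_prime`).
#' @export
simulate_smallrna <- function(sim, spec) {
  stopifnot(inherits(spec, "library_spec"))
  truth <- sim$truth
  budgets <- spec$te_read_budget
  if (length(budgets) == 1 && is.null(names(budgets))) {
    budgets <- setNames(rep(as.integer(budgets), nrow(sim$consensus)),
                        sim$consensus$id)
  }
  if (any(budgets > 0)) {
    missing_src <- setdiff(names(budgets)[budgets > 0],
                           truth$insertions$family_id)
    if (length(missing_src) > 0) {
      stop("read budget > 0 but no planted copies for family ",
           missing_src[1], call. = FALSE)
    }
  }
  active <- truth$clusters
  if (nrow(active) > 0) {
    active <- active[active$tissue_class == "both" |
                     active$tissue_class == paste0(spec$tissue, "_only"), ]
  }
  if (spec$cluster_read_budget > 0 && nrow(active) == 0 &&
      nrow(truth$clusters) == 0) {
    stop("cluster read budget > 0 but no planted clusters", call. = FALSE)
  }

  withr::with_seed(spec$seed, {
    reads <- list(); prov <- list()

    if (spec$n_mirna_reads > 0) {
      pick <- sample(nrow(sim$mirna), spec$n_mirna_reads, replace = TRUE)
      reads$mirna <- tibble::tibble(
        read_id = sprintf("%s_mir_%06d", spec$tissue,
                          seq_len(spec$n_mirna_reads)),
        sequence = sim$mirna$sequence[pick])
      prov$mirna <- tibble::tibble(
        read_id = reads$mirna$read_id, source = "mirna",
        family_id = NA_character_, copy_id = sim$mirna$id[pick],
        cluster_id = NA_character_, strand = "+", five_prime = NA_integer_)
    }

    lo <- spec$read_length_range[1]; hi <- spec$read_length_range[2]
    te_r <- list(); te_p <- list()
    for (fam in names(budgets)) {
      b <- budgets[[fam]]
      if (b == 0) next
      copies <- truth$insertions[truth$insertions$family_id == fam, ]
      n_pairs <- floor(b * spec$pingpong_fraction / 2)
      n_single <- b - 2L * n_pairs
      out <- sample_te_reads(copies, fam, n_pairs, n_single, lo, hi,
                             spec$tissue)
      te_r[[fam]] <- out$reads; te_p[[fam]] <- out$prov
    }
    if (length(te_r) > 0) {
      reads$te <- dplyr::bind_rows(te_r); prov$te <- dplyr::bind_rows(te_p)
    }

    if (spec$cluster_read_budget > 0 && nrow(active) > 0) {
      cl_r <- list(); cl_p <- list()
      for (k in seq_len(nrow(active))) {
        cl <- active[k, ]
        contig_seq <- sim$genome$sequence[sim$genome$id == cl$contig]
        n <- spec$cluster_read_budget
        len <- sample(lo:hi, n, replace = TRUE)
        pos <- vapply(len, function(l) {
          cl$start + sample.int(cl$end - cl$start - l + 1L, 1) - 1L
        }, integer(1))
        strand <- sample(c("+", "-"), n, replace = TRUE)
        seqs <- substring(contig_seq, pos + 1L, pos + len)
        seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
        ids <- sprintf("%s_%s_%04d", spec$tissue, cl$cluster_id, seq_len(n))
        cl_r[[k]] <- tibble::tibble(read_id = ids, sequence = seqs)
        cl_p[[k]] <- tibble::tibble(
          read_id = ids, source = "cluster", family_id = NA_character_,
          copy_id = NA_character_, cluster_id = cl$cluster_id,
          strand = strand,
          five_prime = ifelse(strand == "+", pos, pos + len - 1L))
      }
      reads$cluster <- dplyr::bind_rows(cl_r)
      prov$cluster <- dplyr::bind_rows(cl_p)
    }

    reads <- dplyr::bind_rows(reads)
    reads$tissue <- spec$tissue
    list(reads = reads, provenance = dplyr::bind_rows(prov))
  })
}

# Sample ping-pong pairs and background reads from one family's planted
# copies, vectorized with rejection resampling for copies too short for the
# drawn read geometry. Positions are on the copy's own (consensus-oriented)
# sequence.
sample_te_reads <- function(copies, fam, n_pairs, n_single, lo, hi, tissue) {
  clen_all <- nchar(copies$copy_seq)
  reads <- list(); prov <- list()

  if (n_pairs > 0) {
    ci <- sample.int(nrow(copies), n_pairs, replace = TRUE)
    la <- sample(lo:hi, n_pairs, replace = TRUE)
    ls <- sample(lo:hi, n_pairs, replace = TRUE)
    p_min <- pmax(la - 1L, 9L)
    p_max <- clen_all[ci] + 8L - ls
    for (attempt in seq_len(1000L)) {
      bad <- which(p_min > p_max)
      if (length(bad) == 0) break
      ci[bad] <- sample.int(nrow(copies), length(bad), replace = TRUE)
      la[bad] <- sample(lo:hi, length(bad), replace = TRUE)
      ls[bad] <- sample(lo:hi, length(bad), replace = TRUE)
      p_min[bad] <- pmax(la[bad] - 1L, 9L)
      p_max[bad] <- clen_all[ci[bad]] + 8L - ls[bad]
    }
    if (any(p_min > p_max)) {
      stop("copies of ", fam, " too short for ping-pong pairs", call. = FALSE)
    }
    pos <- p_min + floor(runif(n_pairs) * (p_max - p_min + 1))  # antisense 5'
    seqs <- copies$copy_seq[ci]
    sense <- substr(seqs, pos - 9L + 1L, pos - 9L + ls)
    anti <- revcomp(substr(seqs, pos - la + 2L, pos + 1L))
    ids_s <- sprintf("%s_%s_pp_%05d", tissue, fam, 2L * seq_len(n_pairs) - 1L)
    ids_a <- sprintf("%s_%s_pp_%05d", tissue, fam, 2L * seq_len(n_pairs))
    reads$pp <- tibble::tibble(
      read_id = c(rbind(ids_s, ids_a)), sequence = c(rbind(sense, anti)))
    prov$pp <- tibble::tibble(
      read_id = reads$pp$read_id, source = "te", family_id = fam,
      copy_id = copies$copy_id[rep(ci, each = 2)],
      cluster_id = NA_character_,
      strand = rep(c("+", "-"), n_pairs),
      five_prime = as.integer(c(rbind(pos - 9L, pos))))
  }

  if (n_single > 0) {
    ci <- sample.int(nrow(copies), n_single, replace = TRUE)
    l <- sample(lo:hi, n_single, replace = TRUE)
    for (attempt in seq_len(1000L)) {
      bad <- which(clen_all[ci] < l)
      if (length(bad) == 0) break
      ci[bad] <- sample.int(nrow(copies), length(bad), replace = TRUE)
      l[bad] <- sample(lo:hi, length(bad), replace = TRUE)
    }
    if (any(clen_all[ci] < l)) {
      stop("copies of ", fam, " too short for the read length range",
           call. = FALSE)
    }
    s <- floor(runif(n_single) * (clen_all[ci] - l + 1))
    strand <- sample(c("+", "-"), n_single, replace = TRUE)
    seq <- substr(copies$copy_seq[ci], s + 1L, s + l)
    seq[strand == "-"] <- revcomp(seq[strand == "-"])
    ids <- sprintf("%s_%s_bg_%05d", tissue, fam, seq_len(n_single))
    reads$bg <- tibble::tibble(read_id = ids, sequence = seq)
    prov$bg <- tibble::tibble(
      read_id = ids, source = "te", family_id = fam,
      copy_id = copies$copy_id[ci], cluster_id = NA_character_,
      strand = strand,
      five_prime = as.integer(ifelse(strand == "+", s, s + l - 1L)))
  }
  list(reads = dplyr::bind_rows(reads), prov = dplyr::bind_rows(prov))
}

#' Simulate a per-family mRNA count table with a planted copy-number effect
#'
#' Counts follow a negative-binomial law whose log10-mean is
#' `intercept + effect * log10(copy_number)`; `dispersion` is the NB size
#' parameter (the Poisson limit as it grows).
#'
#' @param families Tibble with `family_id` and `copy_number`.
#' @param effect Slope of log10 expression on log10 copy number.
#' @param dispersion NB size parameter (> 0).
#' @param seed Integer seed.
#' @param intercept Baseline log10 mean count.
#' @return Tibble `family_id`, `copy_number`, `true_mean`, `mrna_count`.
#' @export
simulate_counts <- function(families, effect, dispersion, seed,
                            intercept = 2) {
  stopifnot(nrow(families) >= 2)
  if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  withr::with_seed(seed, {
    mu <- ifelse(families$copy_number > 0,
                 10^(intercept + effect * log10(families$copy_number)), 0)
    tibble::tibble(
      family_id = families$family_id,
      copy_number = families$copy_number,
      true_mean = mu,
      mrna_count = rnbinom(length(mu), mu = mu, size = dispersion))
  })
}

#' Emit a 12-column similarity-hit table for a planted genome
#'
#' Each planted copy yields one hit (or, with probability `split_prob`, two
#' overlapping sub-hits, exercising downstream hit merging). Percent identity
#' is computed from the realized mismatches between the copy and its
#' consensus interval, so the table behaves like genuine search output on the
#' synthetic genome.
#'
#' @param sim Result of [simulate_genome()].
#' @param split_prob Probability of reporting a copy as two overlapping hits.
#' @param seed Integer seed (used only for the split choices).
#' @param path Optional path; when given, the table is also written as a
#'    12-column TSV.
#' @return Hit tibble in the same layout as [read_hits()] returns.
#' @export
simulate_hits <- function(sim, split_prob = 0, seed = 1L, path = NULL) {
  ins <- sim$truth$insertions
  cons <- setNames(sim$consensus$sequence, sim$consensus$id)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(ins)), function(i) {
      x <- ins[i, ]
      segs <- list(c(x$cons_start, x$cons_end))
      len <- x$cons_end - x$cons_start
      if (len >= 80 && runif(1) < split_prob) {
        m <- x$cons_start + sample(30:(len - 30), 1)
        o <- sample(5:20, 1)                     # overlap between sub-hits
        segs <- list(c(x$cons_start, m + o), c(m, x$cons_end))
      }
      dplyr::bind_rows(lapply(segs, function(sg) {
        # genomic span of the sub-hit within the insertion
        off1 <- sg[1] - x$cons_start; off2 <- sg[2] - x$cons_start
        if (x$strand == "+") {
          g1 <- x$start + off1; g2 <- x$start + off2
        } else {
          g1 <- x$end - off2; g2 <- x$end - off1
        }
        cseg <- substr(cons[[x$family_id]], sg[1] + 1L, sg[2])
        kseg <- substr(x$copy_seq, off1 + 1L, off2)
        mm <- hamming(cseg, kseg)
        tibble::tibble(
          family_id = x$family_id, contig = x$contig,
          percent_identity = round(100 * (1 - mm / nchar(cseg)), 2),
          alignment_length = nchar(cseg),
          start = g1, end = g2, strand = x$strand,
          e_value = 0, bit_score = round(2 * nchar(cseg) - 3 * mm, 1))
      }))
    })
    hits <- dplyr::bind_rows(rows)
    if (!is.null(path)) write_hits(hits, path)
    hits
  })
}

#' Write a hit tibble as a 12-column tab-separated file
#'
#' The inverse of [read_hits()]: internal 0-based half-open coordinates are
#' converted back to 1-based inclusive subject coordinates, minus-strand hits
#' getting descending subject coordinates.
#'
#' @param hits Hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  s1 <- ifelse(hits$strand == "+", hits$start + 1L, hits$end)
  s2 <- ifelse(hits$strand == "+", hits$end, hits$start + 1L)
  lines <- paste(hits$family_id, hits$contig, hits$percent_identity,
                 hits$alignment_length, 0L, 0L,
                 1L, hits$alignment_length, s1, s2,
                 hits$e_value, hits$bit_score, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}
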