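# Independent brute-force oracles. Each reimplements a package computation by
# a structurally different route (double loops, fixpoint iteration, bitmask
# enumeration) so that agreement is a genuine two-route check, not the same
# code called twice.

# --- nucleotide diversity: literal double loop over copies and columns ------
oracle_pi <- function(aligned, frequencies = NULL) {
  n <- length(aligned)
  if (n < 2) return(0)
  if (is.null(frequencies)) frequencies <- rep(1 / n, n)
  chars <- lapply(aligned, function(s) utf8ToInt(s))
  bases <- utf8ToInt("ACGT")
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j >= i) next
      a <- chars[[i]]; b <- chars[[j]]
      diffs <- 0L; comparable <- 0L
      for (p in seq_along(a)) {
        if ((a[p] %in% bases) && (b[p] %in% bases)) {
          comparable <- comparable + 1L
          if (a[p] != b[p]) diffs <- diffs + 1L
        }
      }
      if (comparable > 0) {
        total <- total + frequencies[i] * frequencies[j] * diffs / comparable
      }
    }
  }
  2 * total
}

random_alignment <- function(n_max = 10, len_max = 200, gap_prob = 0.15) {
  n <- sample(2:n_max, 1)
  len <- sample(10:len_max, 1)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T", "-", "N"), len, replace = TRUE,
                 prob = c(rep((1 - gap_prob) / 4, 4), gap_prob * 0.8,
                          gap_prob * 0.2)),
          collapse = "")
  }, character(1))
}

# --- hit merging: one-step fixpoint over successive pieces -----------------
# The rule merges SUCCESSIVE hits, so pieces stay sorted by genomic start and
# only adjacent pieces can fuse. One fixpoint step merges the leftmost
# adjacent pair whose hulls overlap or whose joint span is strictly below
# the consensus length; steps repeat until no pair qualifies. Pieces are
# kept as index sets into the original hit table, and every hull, weight and
# identity is recomputed from scratch from those sets at the end — a
# different bookkeeping route from the implementation's running
# accumulators.
oracle_merge_family <- function(hits, consensus_length,
                                full_length_min = 0.98) {
  ord <- order(hits$start, hits$end)
  pieces <- as.list(ord)   # each piece = vector of hit row indices
  hull <- function(idx) c(min(hits$start[idx]), max(hits$end[idx]))
  repeat {
    if (length(pieces) < 2) break
    spans <- t(vapply(pieces, hull, numeric(2)))
    o <- order(spans[, 1], spans[, 2])
    pieces <- pieces[o]; spans <- spans[o, , drop = FALSE]
    merged <- FALSE
    for (i in seq_len(length(pieces) - 1)) {
      a <- spans[i, ]; b <- spans[i + 1, ]
      overlaps <- b[1] < a[2]
      joined <- (a[2] - a[1]) + (b[2] - b[1]) + (b[1] - a[2])
      if (overlaps || joined < consensus_length) {
        pieces[[i]] <- c(pieces[[i]], pieces[[i + 1]])
        pieces[[i + 1]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  res <- dplyr::bind_rows(lapply(pieces, function(idx) {
    w <- hits$alignment_length[idx]
    tibble::tibble(
      family_id = hits$family_id[1], contig = hits$contig[1],
      start = min(hits$start[idx]), end = max(hits$end[idx]),
      strand = hits$strand[1],
      identity = sum(hits$percent_identity[idx] * w) / sum(w),
      n_merged_hits = length(idx))
  }))
  res <- res[order(res$start), ]
  res$completeness <- (res$end - res$start) / consensus_length
  res$full_length <- res$completeness >= full_length_min
  res
}

random_hit_table <- function(max_hits = 8) {
  n <- sample(1:max_hits, 1)
  starts <- sort(sample(0:2000, n))
  lens <- sample(50:400, n, replace = TRUE)
  tibble::tibble(
    family_id = "FAM", contig = "chr", strand = "+",
    percent_identity = round(runif(n, 80, 100), 2),
    alignment_length = lens,
    start = starts, end = starts + lens,
    e_value = 0, bit_score = 100)
}

# --- read matching: brute force scan in R ----------------------------------
oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

oracle_match <- function(reads, refs, max_mismatch, best_stratum = TRUE) {
  rows <- list(); k <- 0L
  for (i in seq_along(reads)) {
    found <- list(); fk <- 0L
    for (strand in c("+", "-")) {
      rd <- if (strand == "+") reads[i] else oracle_revcomp(reads[i])
      rc <- strsplit(rd, "")[[1]]
      for (r in seq_along(refs)) {
        fc <- strsplit(refs[r], "")[[1]]
        if (length(rc) > length(fc)) next
        for (pos in 0:(length(fc) - length(rc))) {
          seg <- fc[pos + seq_along(rc)]
          mm <- sum(seg != rc | rc == "N")
          if (mm <= max_mismatch) {
            fk <- fk + 1L
            found[[fk]] <- tibble::tibble(
              read = i, ref = r, start = pos, strand = strand,
              mismatches = mm)
          }
        }
      }
    }
    if (fk > 0) {
      f <- dplyr::bind_rows(found)
      if (best_stratum) f <- f[f$mismatches == min(f$mismatches), ]
      k <- k + 1L
      rows[[k]] <- f
    }
  }
  if (k == 0) {
    return(tibble::tibble(read = integer(0), ref = integer(0),
                          start = integer(0), strand = character(0),
                          mismatches = integer(0)))
  }
  dplyr::bind_rows(rows)
}

sort_hits <- function(h) {
  h <- tibble::as_tibble(h)[c("read", "ref", "start", "strand", "mismatches")]
  h[order(h$read, h$ref, h$start, h$strand), ]
}

# --- ping-pong overlap histogram: all-pairs double loop --------------------
# A (plus read, minus read) pair contributes at k = minus 5' - plus 5' + 1
# when 1 <= k <= K and the two read footprints physically intersect.
oracle_overlap <- function(alignments, K = 20) {
  counts <- setNames(integer(K), seq_len(K))
  plus <- alignments[alignments$strand == "+", ]
  minus <- alignments[alignments$strand == "-", ]
  for (i in seq_len(nrow(plus))) {
    ps <- plus$offset[i]; pe <- plus$offset[i] + plus$length[i] - 1L
    for (j in seq_len(nrow(minus))) {
      ms <- minus$offset[j]; me <- minus$offset[j] + minus$length[j] - 1L
      if (max(ps, ms) > min(pe, me)) next   # no footprint intersection
      k <- me - ps + 1L
      if (k >= 1 && k <= K) counts[k] <- counts[k] + 1L
    }
  }
  counts
}

random_pingpong_alignments <- function(n_max = 200, span = 300) {
  n <- sample(10:n_max, 1)
  tibble::tibble(
    read_id = paste0("r", seq_len(n)), family_id = "FAM",
    offset = sample(0:span, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    mismatches = 0L,
    length = sample(23:30, n, replace = TRUE))
}

# --- Pearson correlation: closed-form sums + t transform -------------------
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  r <- (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(t), df = n - 2))
}

# --- exact Wilcoxon: bitmask enumeration of all group assignments ----------
oracle_wilcoxon_exact <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  stopifnot(n <= 16)
  ranks <- rank(c(x, y))
  w <- sum(ranks[seq_len(nx)])
  masks <- 0:(2^n - 1)
  bits <- vapply(seq_len(n) - 1L,
                 function(b) bitwAnd(masks, bitwShiftL(1L, b)) > 0,
                 logical(length(masks)))
  keep <- rowSums(bits) == nx
  ws <- as.vector(bits[keep, , drop = FALSE] %*% ranks)
  eps <- 1e-9
  min(1, 2 * min(mean(ws <= w + eps), mean(ws >= w - eps)))
}
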