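#' Read a FASTA file into a sequence tibble
#'
#' Sequences are uppercased and RNA `U` is converted to `T`, so downstream
#' code can assume the alphabet `{A,C,G,T,N}`. FASTQ files are accepted too
#' (qualities are discarded).
#'
#' @param path Path to a FASTA (or FASTQ) file.
#' @return A tibble with columns `id` (the header token up to the first
#'   whitespace) and `sequence`.
#' @export
read_fasta <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", path)) "fastq" else "fasta"
  set <- Biostrings::readBStringSet(path, format = fmt)
  if (length(set) == 0) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate id ", dup[1], " in ", path, call. = FALSE)
  }
  seqs <- gsub("U", "T", toupper(as.character(set)), fixed = TRUE)
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Write a sequence tibble to FASTA
#'
#' @param records Tibble with columns `id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a 12-column tabular similarity-search hit file
#'
#' Expects the standard 12-column tab-separated layout (query id, subject id,
#' percent identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score). Subject coordinates given in
#' descending order encode a minus-strand hit; ingestion makes the strand
#' explicit and converts subject coordinates to the package-internal 0-based
#' half-open convention.
#'
#' @param path Path to the tab-separated hit file.
#' @return A tibble with columns `family_id`, `contig`, `percent_identity`,
#'   `alignment_length`, `start`, `end` (0-based half-open), `strand`,
#'   `e_value`, `bit_score`, in file order.
#' @export
read_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    stop("line ", bad, ": expected 12 columns, found ", nf[bad], call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  s_start <- as.integer(m[, 9]); s_end <- as.integer(m[, 10])
  hits <- tibble::tibble(
    family_id = m[, 1],
    contig = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    alignment_length = as.integer(m[, 4]),
    start = pmin(s_start, s_end) - 1L,
    end = pmax(s_start, s_end),
    strand = ifelse(s_start > s_end, "-", "+"),
    e_value = as.numeric(m[, 11]),
    bit_score = as.numeric(m[, 12])
  )
  stopifnot(all(hits$percent_identity >= 0 & hits$percent_identity <= 100))
  hits
}

#' Write merged TE insertions as GFF3
#'
#' Internal 0-based half-open spans are converted to the 1-based inclusive
#' GFF3 convention. Input must already be sorted by (contig, start).
#'
#' @param insertions Insertion tibble (see [annotate_genome()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(insertions, path) {
  check_sorted(insertions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(insertions) > 0) {
    attrs <- sprintf(
      "ID=%s;family=%s;identity=%.4g;completeness=%.4g;full_length=%s",
      paste0(insertions$family_id, "_", seq_len(nrow(insertions))),
      insertions$family_id, insertions$identity, insertions$completeness,
      ifelse(insertions$full_length, "true", "false"))
    writeLines(paste(insertions$contig, "tesilence", "transposable_element",
                     insertions$start + 1L, insertions$end, ".",
                     insertions$strand, ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Read TE insertions back from a GFF3 annotation file
#'
#' Inverse of [write_gff3()]: 1-based inclusive GFF3 records become 0-based
#' half-open insertion rows, with the family, identity, completeness and
#' full-length call recovered from the attribute column.
#'
#' @param path Path to a GFF3 file written by [write_gff3()].
#' @return Insertion tibble (see [annotate_genome()]); `n_merged_hits` is
#'   not stored in GFF3 and comes back as `NA`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_insertions())
  m <- matrix(unlist(strsplit(lines, "\t", fixed = TRUE)),
              ncol = 9L, byrow = TRUE)
  attr_field <- function(name) {
    sub(sprintf(".*%s=([^;]*).*", name), "\\1", m[, 9])
  }
  tibble::tibble(
    family_id = attr_field("family"),
    contig = m[, 1],
    start = as.integer(m[, 4]) - 1L,
    end = as.integer(m[, 5]),
    strand = m[, 7],
    identity = as.numeric(attr_field("identity")),
    n_merged_hits = NA_integer_,
    completeness = as.numeric(attr_field("completeness")),
    full_length = attr_field("full_length") == "true")
}

#' Write merged TE insertions as BED6
#'
#' BED is 0-based half-open, matching the internal convention directly.
#' Score column carries percent identity. Input must be sorted by
#' (contig, start).
#'
#' @inheritParams write_gff3
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(insertions, path) {
  check_sorted(insertions)
  lines <- character(0)
  if (nrow(insertions) > 0) {
    lines <- paste(insertions$contig, insertions$start, insertions$end,
                   insertions$family_id, round(insertions$identity, 1),
                   insertions$strand, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

check_sorted <- function(insertions) {
  if (nrow(insertions) < 2) return(invisible(TRUE))
  o <- order(insertions$contig, insertions$start)
  if (!identical(o, seq_len(nrow(insertions)))) {
    stop("insertions must be sorted by (contig, start)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a pipeline configuration file
#'
#' One YAML file holds every tunable of a synthetic run, including the single
#' integer seed that all randomness flows from.
#'
#' @param path Path to a YAML config.
#' @return A named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
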