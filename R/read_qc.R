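#' Read and write FASTQ files
#'
#' Reads are carried as a tibble with columns `id`, `seq` (over `A,C,G,T,N`)
#' and `qual` (Phred+33 quality string of the same length). Parsing and
#' serialisation go through Biostrings.
#'
#' @param path Path to a FASTQ file (Phred+33).
#' @return `read_fastq()`: a tibble of reads. `write_fastq()`: `path`,
#'   invisibly.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  reads <- tibble(
    id = names(ss) %||% character(length(ss)),
    seq = as.character(ss),
    qual = as.character(S4Vectors::mcols(ss)$qualities)
  )
  validate_reads(reads)
}

#' @rdname read_fastq
#' @param reads A tibble of reads (`id`, `seq`, `qual`).
#' @export
write_fastq <- function(reads, path) {
  reads <- validate_reads(reads)
  if (nrow(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$id
  Biostrings::writeXStringSet(
    ss, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual)
  )
  invisible(path)
}

validate_reads <- function(reads) {
  if (!all(c("id", "seq", "qual") %in% names(reads))) {
    abort("reads need columns id, seq, qual")
  }
  reads <- as_tibble(reads)
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    bad <- which(nchar(reads$seq) != nchar(reads$qual))[[1]]
    abort(paste0("read '", reads$id[[bad]], "': seq and qual lengths differ"))
  }
  reads
}

# per-read integer Phred scores from a Phred+33 string
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Filter raw reads into clean reads
#'
#' A read is removed by the first failing rule, in order: (a) the adapter
#' occurs as an exact substring of the sequence; (b) the fraction of `N`
#' bases exceeds `max_n_frac`; (c) the fraction of bases with Phred quality
#' `<= low_qual_phred` exceeds `low_qual_frac`. Each removed read is counted
#' once, under its first failing rule, so removal counts plus survivors sum
#' to the input count and filtering the clean stream again removes nothing.
#'
#' The thresholds default to conventional vendor QC settings; sources that
#' filter with unpublished criteria can be emulated by adjusting them.
#'
#' @param reads A tibble of reads (`id`, `seq`, `qual`; see [read_fastq()]).
#' @param adapter Non-empty adapter sequence matched exactly.
#' @param max_n_frac Maximum tolerated fraction of `N` bases.
#' @param low_qual_phred Phred score at or below which a base counts as
#'   low-quality.
#' @param low_qual_frac Maximum tolerated fraction of low-quality bases.
#' @return A list with `clean` (tibble of surviving reads) and `report`
#'   (tibble with one row per rule: `rule`, `removed`, plus a `clean` row).
#' @export
filter_reads <- function(reads, adapter = "AGATCGGAAGAGC", max_n_frac = 0.10,
                         low_qual_phred = 5L, low_qual_frac = 0.5) {
  reads <- validate_reads(reads)
  if (!is.character(adapter) || length(adapter) != 1 || nchar(adapter) == 0) {
    abort("adapter must be a single non-empty string")
  }
  if (max_n_frac < 0 || max_n_frac > 1 || low_qual_frac < 0 || low_qual_frac > 1) {
    abort("fractions must lie in [0, 1]")
  }
  n <- nrow(reads)
  if (n == 0) {
    return(list(
      clean = reads,
      report = tibble(rule = c("adapter", "poly_n", "low_quality", "clean"),
                      removed = c(0L, 0L, 0L, 0L))
    ))
  }
  len <- nchar(reads$seq)
  has_adapter <- str_detect(reads$seq, fixed(adapter))
  n_frac <- str_count(reads$seq, fixed("N")) / len
  low_frac <- vapply(phred_scores(reads$qual),
                     function(q) mean(q <= low_qual_phred), numeric(1))
  verdict <- dplyr::case_when(
    has_adapter ~ "adapter",
    n_frac > max_n_frac ~ "poly_n",
    low_frac > low_qual_frac ~ "low_quality",
    TRUE ~ "clean"
  )
  rules <- c("adapter", "poly_n", "low_quality", "clean")
  list(
    clean = reads[verdict == "clean", ],
    report = tibble(
      rule = rules,
      removed = vapply(rules, function(r) sum(verdict == r), integer(1),
                       USE.NAMES = FALSE)
    )
  )
}

#' Summary quality statistics of a read set
#'
#' Computes the aggregate statistics conventionally reported for clean
#' sequencing data: read and base totals, the fractions of bases with Phred
#' quality at least 20 and at least 30, and the GC fraction of called
#' (non-`N`) bases. An empty read set yields zero counts and `NA` fractions.
#'
#' @param reads A tibble of reads (`id`, `seq`, `qual`).
#' @return A one-row tibble: `n_reads`, `total_bases`, `q20_frac`,
#'   `q30_frac`, `gc_frac`.
#' @export
summarize_quality <- function(reads) {
  reads <- validate_reads(reads)
  if (nrow(reads) == 0) {
    return(tibble(n_reads = 0L, total_bases = 0,
                  q20_frac = NA_real_, q30_frac = NA_real_, gc_frac = NA_real_))
  }
  scores <- unlist(phred_scores(reads$qual))
  gc <- sum(str_count(reads$seq, "[GC]"))
  called <- sum(str_count(reads$seq, "[ACGT]"))
  tibble(
    n_reads = nrow(reads),
    total_bases = sum(nchar(reads$seq)),
    q20_frac = mean(scores >= 20),
    q30_frac = mean(scores >= 30),
    gc_frac = if (called > 0) gc / called else NA_real_
  )
}

#' Clean-base totals from per-group read counts
#'
#' Turns a table of clean-read counts into per-group and overall totals of
#' clean bases, in gigabases, for fixed-length reads. With 278,269,246
#' reads of 150 bp this yields 41.74 G clean bases.
#'
#' @param read_counts A data frame with columns `group`, `clean_reads` and
#'   `read_length_bp`.
#' @return A tibble with one row per group plus a `total` row: `group`,
#'   `clean_reads`, `clean_bases`, `clean_gbases`.
#' @export
clean_base_summary <- function(read_counts) {
  if (!all(c("group", "clean_reads", "read_length_bp") %in% names(read_counts))) {
    abort("read_counts needs columns group, clean_reads, read_length_bp")
  }
  per <- as_tibble(read_counts) |>
    mutate(clean_bases = .data$clean_reads * .data$read_length_bp,
           clean_gbases = .data$clean_bases / 1e9) |>
    select("group", "clean_reads", "clean_bases", "clean_gbases")
  bind_rows(per, tibble(
    group = "total",
    clean_reads = sum(per$clean_reads),
    clean_bases = sum(per$clean_bases),
    clean_gbases = sum(per$clean_bases) / 1e9
  ))
}
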