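#' Genome annotations as exon tables
#'
#' Throughout the package a genome annotation is an ordinary tibble with one
#' row per exon and columns `chrom`, `start`, `end`, `strand`,
#' `transcript_id`, `gene_id`, `biotype`. Coordinates are 0-based, half-open
#' (`start < end`); on-disk GTF is 1-based inclusive and converted at the
#' I/O boundary. `biotype` is one of `"coding"`, `"annotated_lncRNA"` or
#' `"unknown"`.
#'
#' `as_annotation()` validates a data frame against those invariants
#' (strand in `{+,-}`; exons of a transcript on one chromosome and strand,
#' sorted, pairwise non-overlapping) and returns it as a tibble with exons
#' ordered by transcript and start.
#'
#' @param x A data frame with the columns listed above (`biotype` optional;
#'   defaults to `"unknown"`).
#' @return A tibble of exons.
#' @export
#' @examples
#' ann <- as_annotation(data.frame(
#'   chrom = "chr1", start = c(100, 300), end = c(200, 400), strand = "+",
#'   transcript_id = "tx1", gene_id = "g1", biotype = "coding"
#' ))
#' transcript_table(ann)
as_annotation <- function(x) {
  required <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)
  if (!"biotype" %in% names(x)) x$biotype <- "unknown"
  bad_bt <- setdiff(unique(x$biotype), c("coding", "annotated_lncRNA", "unknown"))
  if (length(bad_bt) > 0) {
    abort(paste0("unknown biotype value(s): ", paste(bad_bt, collapse = ", ")))
  }
  if (nrow(x) == 0) {
    return(x[, c(required, "biotype")])
  }
  if (!all(x$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-' for every exon")
  }
  if (any(x$start < 0) || any(x$start >= x$end)) {
    abort("exon coordinates must satisfy 0 <= start < end")
  }
  x <- arrange(x, .data$transcript_id, .data$start)
  per_tx <- x |>
    group_by(.data$transcript_id) |>
    summarise(
      n_chrom = n_distinct(.data$chrom),
      n_strand = n_distinct(.data$strand),
      n_gene = n_distinct(.data$gene_id),
      overlapping = any(.data$start[-1] < .data$end[-length(.data$end)]),
      .groups = "drop"
    )
  if (any(per_tx$n_chrom > 1)) {
    abort(paste0("transcript(s) with exons on multiple chromosomes: ",
                 paste(per_tx$transcript_id[per_tx$n_chrom > 1], collapse = ", ")))
  }
  if (any(per_tx$n_strand > 1) || any(per_tx$n_gene > 1)) {
    abort("each transcript must have a single strand and gene_id")
  }
  if (any(per_tx$overlapping)) {
    abort(paste0("transcript(s) with overlapping exons: ",
                 paste(per_tx$transcript_id[per_tx$overlapping], collapse = ", ")))
  }
  x[, c(required, "biotype")]
}

#' Read a GTF file into an exon table
#'
#' Exon features of a GTF 2.2 file become rows of an annotation tibble (see
#' [as_annotation()]); coordinates are converted from the on-disk 1-based
#' inclusive convention to the internal 0-based half-open one. A `biotype`
#' (or `transcript_biotype`/`gene_biotype`) attribute, when present, is
#' mapped onto `coding` / `annotated_lncRNA` / `unknown`; anything
#' mentioning "lnc" counts as an annotated lncRNA, `protein_coding`/`coding`/
#' `mRNA` as coding.
#'
#' Malformed lines (fewer than 9 tab-separated fields) and exon features
#' without a `transcript_id` attribute raise an error naming the offending
#' line number. Transcripts with exons on several chromosomes, and exon
#' strands other than `+`/`-`, are rejected.
#'
#' @param path Path to a GTF file.
#' @return An annotation tibble of exons.
#' @seealso [write_gtf()]
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  content <- !grepl("^\\s*(#|$)", lines)
  for (i in which(content)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9) {
      abort(paste0("malformed GTF line ", i, ": expected 9 tab-separated fields, got ",
                   length(fields)))
    }
    if (identical(fields[[3]], "exon") &&
        !grepl("transcript_id", fields[[9]], fixed = TRUE)) {
      abort(paste0("GTF line ", i, ": exon feature lacks a transcript_id attribute"))
    }
  }
  if (!any(content)) {
    return(as_annotation(tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), transcript_id = character(),
      gene_id = character(), biotype = character()
    )))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0) {
    return(as_annotation(tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), transcript_id = character(),
      gene_id = character(), biotype = character()
    )))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    abort("exon feature with strand other than '+'/'-'; stranded models are required")
  }
  mc <- S4Vectors::mcols(gr)
  bt_col <- intersect(c("biotype", "transcript_biotype", "gene_biotype"), names(mc))
  raw_bt <- if (length(bt_col) > 0) as.character(mc[[bt_col[[1]]]]) else
    rep(NA_character_, length(gr))
  biotype <- dplyr::case_when(
    is.na(raw_bt) ~ "unknown",
    grepl("lnc", raw_bt, ignore.case = TRUE) ~ "annotated_lncRNA",
    raw_bt %in% c("coding", "protein_coding", "mRNA") ~ "coding",
    TRUE ~ "unknown"
  )
  as_annotation(tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    transcript_id = as.character(mc$transcript_id),
    gene_id = as.character(mc$gene_id),
    biotype = biotype
  ))
}

#' Write an exon table to a GTF file
#'
#' Internal 0-based half-open exon coordinates are converted back to the
#' GTF 1-based inclusive convention. The emitted file round-trips through
#' [read_gtf()] to an equivalent annotation (ids, strands, coordinates and
#' biotypes preserved; row order is not significant).
#'
#' @param ann An annotation tibble (validated via [as_annotation()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  ann <- as_annotation(ann)
  if (nrow(ann) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand
  )
  S4Vectors::mcols(gr)$source <- "lncpair"
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- ann$gene_id
  S4Vectors::mcols(gr)$transcript_id <- ann$transcript_id
  S4Vectors::mcols(gr)$biotype <- ann$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Per-transcript and per-gene summaries of an annotation
#'
#' `transcript_table()` returns one row per transcript with its exon count,
#' mature length (sum of exon lengths) and genomic span; `gene_table()`
#' returns one row per gene with its locus span (min exon start to max exon
#' end across all member transcripts, introns included).
#'
#' @param ann An annotation tibble.
#' @return A tibble with one row per transcript (or gene).
#' @export
transcript_table <- function(ann) {
  ann <- as_annotation(ann)
  if (nrow(ann) == 0) {
    return(tibble(transcript_id = character(), gene_id = character(),
                  chrom = character(), strand = character(),
                  biotype = character(), n_exons = integer(),
                  length = integer(), start = integer(), end = integer()))
  }
  ann |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = .data$gene_id[1],
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      biotype = .data$biotype[1],
      n_exons = n(),
      length = sum(.data$end - .data$start),
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    )
}

#' @rdname transcript_table
#' @export
gene_table <- function(ann) {
  ann <- as_annotation(ann)
  if (nrow(ann) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), biotype = character(),
                  n_transcripts = integer(), start = integer(),
                  end = integer()))
  }
  ann |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      biotype = .data$biotype[1],
      n_transcripts = n_distinct(.data$transcript_id),
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    )
}

#' Genomic gap between two intervals
#'
#' The number of bases strictly between two 0-based half-open intervals:
#' `NA` when the chromosomes differ, 0 when the intervals overlap or abut,
#' otherwise `max(starts) - min(ends)`. Vectorised with the usual recycling
#' of length-1 inputs; symmetric in its arguments.
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end` (extra
#'   columns are ignored).
#' @return An integer vector of gaps (`NA` for different chromosomes).
#' @export
#' @examples
#' a <- data.frame(chrom = "chr1", start = 100, end = 200)
#' b <- data.frame(chrom = "chr1", start = 400, end = 500)
#' genomic_gap(a, b) # 200
genomic_gap <- function(a, b) {
  for (d in list(a, b)) {
    if (!all(c("chrom", "start", "end") %in% names(d))) {
      abort("intervals need columns chrom, start, end")
    }
  }
  n <- max(nrow(a), nrow(b))
  if (nrow(a) %in% c(1L, n) && nrow(b) %in% c(1L, n)) {
    idx_a <- if (nrow(a) == 1L) rep(1L, n) else seq_len(n)
    idx_b <- if (nrow(b) == 1L) rep(1L, n) else seq_len(n)
  } else {
    abort("interval tables must have equal row counts (or one row)")
  }
  gap <- pmax(0L,
              as.integer(pmax(a$start[idx_a], b$start[idx_b]) -
                           pmin(a$end[idx_a], b$end[idx_b])))
  gap[a$chrom[idx_a] != b$chrom[idx_b]] <- NA_integer_
  gap
}

#' Transcripts overlapping a query interval
#'
#' Interval lookup over transcript spans, strand-blind. Returns the ids of
#' all transcripts whose genomic span (first exon start to last exon end)
#' overlaps the half-open query interval; equivalent to a linear scan over
#' [transcript_table()].
#'
#' @param ann An annotation tibble.
#' @param chrom Chromosome name.
#' @param start,end Query interval, 0-based half-open.
#' @return A character vector of transcript ids.
#' @export
overlapping_transcripts <- function(ann, chrom, start, end) {
  tx <- transcript_table(ann)
  tx <- tx[tx$chrom == chrom & tx$start < end & tx$end > start, ]
  tx$transcript_id
}

# GRanges over exons (internal); 1-based closed coordinates for IRanges
exon_granges <- function(ann) {
  GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand,
    transcript_id = ann$transcript_id,
    gene_id = ann$gene_id,
    biotype = ann$biotype
  )
}

# pairs of (query transcript, subject transcript) with >=1 bp exonic overlap;
# strand_mode: "same", "opposite", or "any"
exonic_overlap_pairs <- function(query_ann, subject_ann, strand_mode = "any") {
  if (nrow(query_ann) == 0 || nrow(subject_ann) == 0) {
    return(tibble(query = character(), subject = character()))
  }
  q <- exon_granges(query_ann)
  s <- exon_granges(subject_ann)
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  qs <- as.character(BiocGenerics::strand(q))[S4Vectors::queryHits(hits)]
  ss <- as.character(BiocGenerics::strand(s))[S4Vectors::subjectHits(hits)]
  keep <- switch(strand_mode,
    same = qs == ss,
    opposite = qs != ss,
    any = rep(TRUE, length(hits)),
    abort("strand_mode must be 'same', 'opposite' or 'any'")
  )
  distinct(tibble(
    query = q$transcript_id[S4Vectors::queryHits(hits)][keep],
    subject = s$transcript_id[S4Vectors::subjectHits(hits)][keep]
  ))
}
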