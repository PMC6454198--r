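#' Five-step lncRNA filtration cascade
#'
#' Assembled candidate transcripts are filtered, strictly in order, by
#' (1) exon count (at least `min_exons`), (2) mature length (strictly more
#' than `min_len` bp), (3) comparison with the annotated transcriptome:
#' candidates with same-strand exonic overlap against annotated coding
#' exons are eliminated, while candidates with same-strand exonic overlap
#' against annotated lncRNAs are labelled `annotated_lncRNA`; (4) expression
#' (FPKM summary across samples at least `min_fpkm`); (5) coding potential:
#' survivors predicted coding by at least one predictor become `TUCP`
#' (transcripts of uncertain coding potential), the rest `novel_lncRNA`.
#' Annotated-lncRNA matches are still subject to steps 1, 2 and 4 (an
#' unexpressed transcript is not reported) but bypass step 5.
#'
#' Step 3 eliminates on *same-strand* exonic overlap only: a transcript
#' overlapping coding exons on the opposite strand must survive to be
#' classifiable as an antisense lncRNA (see [classify_lncrna()]).
#'
#' @param candidates Annotation tibble of candidate transcripts.
#' @param reference Annotation tibble of the annotated transcriptome, with
#'   `biotype` set to `coding` / `annotated_lncRNA`.
#' @param fpkm Expression tibble (`feature_id` + sample columns) covering
#'   every candidate transcript.
#' @param coding_calls Data frame with a `transcript_id` column and one
#'   logical column per predictor (`TRUE` = predicted coding); must cover
#'   every transcript reaching step 5.
#' @param min_exons,min_len,min_fpkm Cascade thresholds (defaults 2,
#'   200 bp, 0.5 FPKM).
#' @param fpkm_stat How FPKM is summarised across samples for step 4:
#'   `"max"` (default, permissive) or `"mean"`.
#' @return An object of class `lnc_filtration`: a list with `report`
#'   (tibble: `transcript_id`, `outcome`, `first_failing_step`), `steps`
#'   (survivor counts after each step) and the parameters used. `tidy()`
#'   returns the per-transcript report, `glance()` the outcome counts.
#' @export
filter_lncrna_candidates <- function(candidates, reference, fpkm, coding_calls,
                                     min_exons = 2L, min_len = 200L,
                                     min_fpkm = 0.5, fpkm_stat = c("max", "mean")) {
  candidates <- as_annotation(candidates)
  reference <- as_annotation(reference)
  fpkm_stat <- match.arg(fpkm_stat)
  tx <- transcript_table(candidates)
  n0 <- nrow(tx)
  if (n0 == 0) {
    res <- list(
      report = tibble(transcript_id = character(), outcome = character(),
                      first_failing_step = character()),
      steps = tibble(step = c("input", "exon_count", "length",
                              "coding_exon_overlap", "expression"),
                     survivors = rep(0L, 5)),
      params = list(min_exons = min_exons, min_len = min_len,
                    min_fpkm = min_fpkm, fpkm_stat = fpkm_stat)
    )
    class(res) <- "lnc_filtration"
    return(res)
  }

  outcome <- rep(NA_character_, n0)
  failing <- rep(NA_character_, n0)
  alive <- rep(TRUE, n0)

  # step 1: exon count
  fail1 <- alive & tx$n_exons < min_exons
  outcome[fail1] <- "rejected"; failing[fail1] <- "exon_count"; alive[fail1] <- FALSE
  s1 <- sum(alive)

  # step 2: transcript length (strict)
  fail2 <- alive & tx$length <= min_len
  outcome[fail2] <- "rejected"; failing[fail2] <- "length"; alive[fail2] <- FALSE
  s2 <- sum(alive)

  # step 3: comparison with the annotated transcriptome (same strand, exonic)
  coding_ref <- reference[reference$biotype == "coding", ]
  lnc_ref <- reference[reference$biotype == "annotated_lncRNA", ]
  hits_coding <- exonic_overlap_pairs(candidates, coding_ref, "same")
  hits_lnc <- exonic_overlap_pairs(candidates, lnc_ref, "same")
  fail3 <- alive & tx$transcript_id %in% hits_coding$query
  outcome[fail3] <- "rejected"; failing[fail3] <- "coding_exon_overlap"
  alive[fail3] <- FALSE
  is_annotated <- tx$transcript_id %in% hits_lnc$query
  s3 <- sum(alive)

  # step 4: expression level
  fmat <- counts_matrix(fpkm, integer_only = FALSE)
  missing_f <- setdiff(tx$transcript_id[alive], rownames(fmat))
  if (length(missing_f) > 0) {
    abort(paste0("candidate(s) without an FPKM row: ",
                 paste(head(missing_f, 5), collapse = ", ")))
  }
  fstat <- rep(NA_real_, n0)
  present <- tx$transcript_id %in% rownames(fmat)
  fsub <- fmat[tx$transcript_id[present], , drop = FALSE]
  fstat[present] <- if (fpkm_stat == "max") {
    apply(fsub, 1, max)
  } else {
    rowMeans(fsub)
  }
  fail4 <- alive & fstat < min_fpkm
  outcome[fail4] <- "rejected"; failing[fail4] <- "expression"; alive[fail4] <- FALSE
  s4 <- sum(alive)

  # annotated lncRNA matches bypass step 5
  ann_ok <- alive & is_annotated
  outcome[ann_ok] <- "annotated_lncRNA"; alive[ann_ok] <- FALSE

  # step 5: coding potential of the remaining novel candidates
  if (any(alive)) {
    if (!"transcript_id" %in% names(coding_calls)) {
      abort("coding_calls needs a transcript_id column")
    }
    calls <- as_tibble(coding_calls)
    pred_cols <- setdiff(names(calls), "transcript_id")
    if (length(pred_cols) == 0) abort("coding_calls has no predictor columns")
    missing_c <- setdiff(tx$transcript_id[alive], calls$transcript_id)
    if (length(missing_c) > 0) {
      abort(paste0("no coding call for transcript(s) reaching step 5: ",
                   paste(head(missing_c, 5), collapse = ", ")))
    }
    any_coding <- apply(as.data.frame(calls[, pred_cols]) == TRUE, 1, any)
    coding_of <- setNames(any_coding, calls$transcript_id)
    verdict <- coding_of[tx$transcript_id[alive]]
    outcome[alive] <- ifelse(verdict, "TUCP", "novel_lncRNA")
  }

  res <- list(
    report = tibble(transcript_id = tx$transcript_id, outcome = outcome,
                    first_failing_step = failing),
    steps = tibble(
      step = c("input", "exon_count", "length", "coding_exon_overlap",
               "expression"),
      survivors = c(n0, s1, s2, s3, s4)
    ),
    params = list(min_exons = min_exons, min_len = min_len,
                  min_fpkm = min_fpkm, fpkm_stat = fpkm_stat)
  )
  class(res) <- "lnc_filtration"
  res
}

#' @export
tidy.lnc_filtration <- function(x, ...) x$report

#' @export
glance.lnc_filtration <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$report),
    n_novel = sum(x$report$outcome == "novel_lncRNA"),
    n_annotated = sum(x$report$outcome == "annotated_lncRNA"),
    n_tucp = sum(x$report$outcome == "TUCP"),
    n_rejected = sum(x$report$outcome == "rejected")
  )
}

#' @export
print.lnc_filtration <- function(x, ...) {
  cat("lncRNA filtration cascade\n")
  print(x$steps)
  print(glance(x))
  invisible(x)
}

#' Positional classification of lncRNAs
#'
#' Each lncRNA is assigned exactly one positional class relative to the
#' annotated coding genes: `antisense` if any of its exons overlaps a
#' coding exon on the opposite strand; `intronic` if it lies entirely
#' within a coding gene's span without any exonic overlap; `lincRNA`
#' otherwise (in particular when it overlaps no coding gene span at all).
#' Precedence is antisense > intronic > lincRNA.
#'
#' @param lncs Annotation tibble of lncRNA transcripts.
#' @param reference Annotation tibble; only `biotype == "coding"` rows are
#'   used.
#' @return A tibble with `transcript_id` and `class`.
#' @export
classify_lncrna <- function(lncs, reference) {
  lncs <- as_annotation(lncs)
  reference <- as_annotation(reference)
  coding <- reference[reference$biotype == "coding", ]
  tx <- transcript_table(lncs)
  if (nrow(tx) == 0) return(tibble(transcript_id = character(), class = character()))

  antisense_ids <- exonic_overlap_pairs(lncs, coding, "opposite")$query
  exonic_any <- exonic_overlap_pairs(lncs, coding, "any")$query
  genes <- gene_table(coding)

  cls <- vapply(seq_len(nrow(tx)), function(i) {
    id <- tx$transcript_id[[i]]
    if (id %in% antisense_ids) return("antisense")
    contained <- genes$chrom == tx$chrom[[i]] &
      genes$start <= tx$start[[i]] & genes$end >= tx$end[[i]]
    if (any(contained) && !(id %in% exonic_any)) return("intronic")
    "lincRNA"
  }, character(1))
  tibble(transcript_id = tx$transcript_id, class = cls)
}

#' Open-reading-frame coding heuristic
#'
#' A built-in stand-in coding-potential predictor: a sequence is called
#' coding when the longest ATG-initiated open reading frame in any of the
#' three forward frames spans at least `min_orf_aa` codons (the ATG
#' included, the stop excluded; an ORF may run off the 3' end).
#'
#' @param seq Character vector of sequences over `A,C,G,T,N`.
#' @param min_orf_aa Minimum ORF length in codons (default 100).
#' @return A logical vector of coding verdicts.
#' @export
orf_coding_heuristic <- function(seq, min_orf_aa = 100L) {
  vapply(toupper(seq), function(s) {
    longest_orf_codons(s) >= min_orf_aa
  }, logical(1), USE.NAMES = FALSE)
}

longest_orf_codons <- function(s) {
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  n <- nchar(s)
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3
    if (ncod < 1) next
    codons <- substring(s, frame + 1 + 3 * (seq_len(ncod) - 1),
                        frame + 3 * seq_len(ncod))
    atg <- which(codons == "ATG")
    if (length(atg) == 0) next
    stop_idx <- which(codons %in% stops)
    for (a in atg) {
      nxt <- stop_idx[stop_idx > a]
      len <- if (length(nxt) > 0) nxt[[1]] - a else ncod - a + 1L
      if (len > best) best <- len
    }
  }
  best
}

#' Coding calls from the ORF heuristic
#'
#' Convenience wrapper building a coding-call table (one predictor column,
#' `orf`) from transcript sequences, in the shape consumed by
#' [filter_lncrna_candidates()].
#'
#' @param seqs A data frame with columns `transcript_id` and `seq`.
#' @param min_orf_aa Passed to [orf_coding_heuristic()].
#' @return A tibble with `transcript_id` and logical `orf`.
#' @export
orf_coding_calls <- function(seqs, min_orf_aa = 100L) {
  if (!all(c("transcript_id", "seq") %in% names(seqs))) {
    abort("seqs needs columns transcript_id and seq")
  }
  tibble(transcript_id = seqs$transcript_id,
         orf = orf_coding_heuristic(seqs$seq, min_orf_aa))
}

#' Distribution summaries of transcript features
#'
#' Per-class five-number-plus-mean summaries of transcript length, exon
#' count and expression, in a shape suitable for plotting lncRNA-vs-mRNA
#' comparisons (lncRNAs are typically shorter, have fewer exons and are
#' expressed lower than mRNAs).
#'
#' @param ann Annotation tibble of the transcripts to summarise.
#' @param classes A data frame with `transcript_id` and `class` assigning
#'   each transcript to a summary class (e.g. `lncRNA` / `mRNA`).
#' @param fpkm Optional expression tibble; when given, an `fpkm` metric
#'   (per-transcript mean across samples) is summarised too.
#' @return A tibble with columns `class`, `metric`, `n`, `min`, `q25`,
#'   `median`, `q75`, `max`, `mean`.
#' @export
summarize_transcript_features <- function(ann, classes, fpkm = NULL) {
  tx <- transcript_table(ann)
  if (!all(c("transcript_id", "class") %in% names(classes))) {
    abort("classes needs columns transcript_id and class")
  }
  tx <- inner_join(tx, as_tibble(classes), by = "transcript_id")
  if (nrow(tx) == 0) abort("no transcripts left after joining classes")
  vals <- tibble(class = tx$class, metric = "length", value = as.numeric(tx$length)) |>
    bind_rows(tibble(class = tx$class, metric = "n_exons",
                     value = as.numeric(tx$n_exons)))
  if (!is.null(fpkm)) {
    fmat <- counts_matrix(fpkm, integer_only = FALSE)
    idx <- tx$transcript_id %in% rownames(fmat)
    vals <- bind_rows(vals, tibble(
      class = tx$class[idx], metric = "fpkm",
      value = rowMeans(fmat[tx$transcript_id[idx], , drop = FALSE])
    ))
  }
  vals |>
    group_by(.data$class, .data$metric) |>
    summarise(
      n = n(),
      min = min(.data$value),
      q25 = unname(quantile(.data$value, 0.25)),
      median = median(.data$value),
      q75 = unname(quantile(.data$value, 0.75)),
      max = max(.data$value),
      mean = mean(.data$value),
      .groups = "drop"
    )
}
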