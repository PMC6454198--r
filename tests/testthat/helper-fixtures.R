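# small in-code fixtures and independent oracles shared across tests

toy_annotation <- function() {
  as_annotation(tibble::tribble(
    ~chrom, ~start, ~end, ~strand, ~transcript_id, ~gene_id, ~biotype,
    "chr1",    100,  200,     "+",          "tx1",     "g1",  "coding",
    "chr1",    300,  400,     "+",          "tx1",     "g1",  "coding",
    "chr1",    150,  250,     "+",          "tx2",     "g1",  "coding",
    "chr1",   5000, 5400,     "-",          "tx3",     "g2",  "coding",
    "chr2",    100,  300,     "+",          "tx4",     "g3",  "annotated_lncRNA"
  ))
}

# brute-force gap between half-open intervals by counting bases strictly
# between them
gap_oracle <- function(s1, e1, s2, e2) {
  x <- seq(min(s1, s2), max(e1, e2) - 1)
  in1 <- x >= s1 & x < e1
  in2 <- x >= s2 & x < e2
  sum(!in1 & !in2 & x >= min(e1, e2) & x < max(s1, s2))
}

# independent rule-by-rule re-implementation of the filtration cascade,
# written with plain loops against the literal rule statements
cascade_oracle <- function(candidates, reference, fpkm, coding_calls,
                           min_exons = 2, min_len = 200, min_fpkm = 0.5) {
  cand_ids <- unique(candidates$transcript_id)
  fmat <- as.data.frame(fpkm[, -1])
  rownames(fmat) <- fpkm$feature_id
  exonic_overlap <- function(ex_a, ex_b) {
    for (i in seq_len(nrow(ex_a))) for (j in seq_len(nrow(ex_b))) {
      if (ex_a$chrom[i] == ex_b$chrom[j] &&
          ex_a$start[i] < ex_b$end[j] && ex_a$end[i] > ex_b$start[j]) {
        return(TRUE)
      }
    }
    FALSE
  }
  out <- data.frame(transcript_id = cand_ids,
                    outcome = NA_character_,
                    first_failing_step = NA_character_)
  for (idx in seq_along(cand_ids)) {
    id <- cand_ids[[idx]]
    ex <- candidates[candidates$transcript_id == id, ]
    if (nrow(ex) < min_exons) {
      out$outcome[idx] <- "rejected"; out$first_failing_step[idx] <- "exon_count"
      next
    }
    if (sum(ex$end - ex$start) <= min_len) {
      out$outcome[idx] <- "rejected"; out$first_failing_step[idx] <- "length"
      next
    }
    same_strand <- reference[reference$strand == ex$strand[1], ]
    coding_ref <- same_strand[same_strand$biotype == "coding", ]
    lnc_ref <- same_strand[same_strand$biotype == "annotated_lncRNA", ]
    if (nrow(coding_ref) > 0 && exonic_overlap(ex, coding_ref)) {
      out$outcome[idx] <- "rejected"
      out$first_failing_step[idx] <- "coding_exon_overlap"
      next
    }
    annotated <- nrow(lnc_ref) > 0 && exonic_overlap(ex, lnc_ref)
    if (max(as.numeric(fmat[id, ])) < min_fpkm) {
      out$outcome[idx] <- "rejected"; out$first_failing_step[idx] <- "expression"
      next
    }
    if (annotated) {
      out$outcome[idx] <- "annotated_lncRNA"
      next
    }
    calls <- coding_calls[coding_calls$transcript_id == id, -1, drop = FALSE]
    out$outcome[idx] <- if (any(unlist(calls))) "TUCP" else "novel_lncRNA"
  }
  out
}

# brute-force BH step-up straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(pmin(1, p[o][i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# brute-force longest ATG-initiated forward-frame ORF, codon by codon
orf_oracle <- function(s, min_orf_aa) {
  s <- toupper(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0
  for (start in seq_len(max(nchar(s) - 2, 0))) {
    if (substr(s, start, start + 2) != "ATG") next
    len <- 0
    pos <- start
    while (pos + 2 <= nchar(s)) {
      codon <- substr(s, pos, pos + 2)
      if (len > 0 && codon %in% stops) break
      len <- len + 1
      pos <- pos + 3
    }
    best <- max(best, len)
  }
  best >= min_orf_aa
}

random_counts <- function(nfeat, samples, mu = 100, size = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(nfeat * length(samples), mu = mu, size = size), nfeat)
  colnames(m) <- samples
  dplyr::bind_cols(tibble::tibble(feature_id = paste0("f", seq_len(nfeat))),
                   tibble::as_tibble(m))
}
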