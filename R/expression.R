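#' FPKM from a count matrix
#'
#' Fragments Per Kilobase of exon per Million mapped fragments:
#' `FPKM[f, s] = count[f, s] * 1e9 / (length[f] * library_size[s])`.
#' Feature length is the mature transcript length (sum of exon lengths).
#' Library sizes default to the per-sample column sums of the count matrix;
#' explicit totals (e.g. mapped-fragment counts) may be supplied instead.
#'
#' @param counts A data frame with a `feature_id` column and one numeric
#'   column of non-negative counts per sample.
#' @param feature_lengths A data frame with columns `feature_id` and
#'   `length` (bp, > 0), or a named numeric vector.
#' @param library_sizes Optional named numeric vector (or single-row data
#'   frame) of per-sample totals; defaults to column sums.
#' @return A tibble of FPKM values with the same shape as `counts`.
#' @export
#' @examples
#' counts <- data.frame(feature_id = "tx1", s1 = 100)
#' compute_fpkm(counts, c(tx1 = 1000), library_sizes = c(s1 = 1e6)) # 100
compute_fpkm <- function(counts, feature_lengths, library_sizes = NULL) {
  m <- counts_matrix(counts)
  len <- length_vector(feature_lengths)
  missing_len <- setdiff(rownames(m), names(len))
  if (length(missing_len) > 0) {
    abort(paste0("no length for feature(s): ",
                 paste(head(missing_len, 5), collapse = ", ")))
  }
  len <- len[rownames(m)]
  if (any(len <= 0)) abort("feature lengths must be > 0")
  if (is.null(library_sizes)) {
    library_sizes <- colSums(m)
  } else {
    if (is.data.frame(library_sizes)) {
      library_sizes <- setNames(as.numeric(library_sizes[1, ]),
                                names(library_sizes))
    }
    missing_ls <- setdiff(colnames(m), names(library_sizes))
    if (length(missing_ls) > 0) {
      abort(paste0("no library size for sample(s): ",
                   paste(missing_ls, collapse = ", ")))
    }
    library_sizes <- library_sizes[colnames(m)]
  }
  if (any(library_sizes <= 0)) abort("library sizes must be > 0")
  fpkm <- m * 1e9 / outer(len, library_sizes)
  matrix_to_tibble(fpkm)
}

#' Gene-level expression by summing member transcripts
#'
#' Gene FPKMs are the per-sample sums of the FPKMs of the transcripts in
#' each gene group, so total expression is conserved under the grouping.
#' `gene_level_counts()` applies the same summation to raw counts.
#'
#' @param fpkm,counts A data frame with a `feature_id` column (transcript
#'   ids) and one numeric column per sample.
#' @param tx2gene A data frame with columns `transcript_id` and `gene_id`,
#'   or an annotation tibble (the mapping is derived from it). Every matrix
#'   feature must map to a gene.
#' @return A tibble with `feature_id` (gene ids) and the sample columns.
#' @export
gene_level_fpkm <- function(fpkm, tx2gene) {
  map <- tx2gene_map(tx2gene)
  m <- counts_matrix(fpkm, integer_only = FALSE)
  orphans <- setdiff(rownames(m), map$transcript_id)
  if (length(orphans) > 0) {
    abort(paste0("feature(s) not mapped to any gene: ",
                 paste(head(orphans, 5), collapse = ", ")))
  }
  gene <- map$gene_id[match(rownames(m), map$transcript_id)]
  agg <- rowsum(m, group = gene)
  matrix_to_tibble(agg)
}

#' @rdname gene_level_fpkm
#' @export
gene_level_counts <- gene_level_fpkm

# ---- internal matrix plumbing -------------------------------------------

counts_matrix <- function(counts, integer_only = FALSE) {
  if (!"feature_id" %in% names(counts)) {
    abort("expression/count tables need a feature_id column")
  }
  sample_cols <- setdiff(names(counts), "feature_id")
  if (length(sample_cols) == 0) abort("no sample columns found")
  if (anyDuplicated(counts$feature_id)) abort("duplicated feature_id values")
  m <- as.matrix(as.data.frame(counts[, sample_cols]))
  if (!is.numeric(m)) abort("sample columns must be numeric")
  rownames(m) <- counts$feature_id
  if (any(m < 0)) abort("negative values in count/expression matrix")
  if (any(!is.finite(m))) abort("non-finite values in count/expression matrix")
  m
}

# like counts_matrix but allows negative values (log-scale expression)
expr_matrix <- function(expr) {
  if (!"feature_id" %in% names(expr)) {
    abort("expression tables need a feature_id column")
  }
  if (anyDuplicated(expr$feature_id)) abort("duplicated feature_id values")
  m <- as.matrix(as.data.frame(expr[, setdiff(names(expr), "feature_id")]))
  if (!is.numeric(m)) abort("sample columns must be numeric")
  if (any(!is.finite(m))) abort("non-finite values in expression matrix")
  rownames(m) <- expr$feature_id
  m
}

matrix_to_tibble <- function(m) {
  bind_cols(tibble(feature_id = rownames(m)), as_tibble(m))
}

length_vector <- function(feature_lengths) {
  if (is.data.frame(feature_lengths)) {
    if (!all(c("feature_id", "length") %in% names(feature_lengths))) {
      abort("feature_lengths needs columns feature_id and length")
    }
    setNames(as.numeric(feature_lengths$length), feature_lengths$feature_id)
  } else if (is.numeric(feature_lengths) && !is.null(names(feature_lengths))) {
    feature_lengths
  } else {
    abort("feature_lengths must be a named numeric vector or a data frame")
  }
}

tx2gene_map <- function(tx2gene) {
  if (all(c("transcript_id", "gene_id") %in% names(tx2gene))) {
    distinct(as_tibble(tx2gene)[, c("transcript_id", "gene_id")])
  } else {
    abort("tx2gene needs columns transcript_id and gene_id")
  }
}
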