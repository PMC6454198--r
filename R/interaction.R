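#' Pearson correlation with a t-distribution p-value
#'
#' The sample Pearson correlation with the classical two-sided test:
#' `t = r * sqrt((n - 2) / (1 - r^2))` against Student's t with `n - 2`
#' degrees of freedom. For `|r| = 1` the p-value is reported as the
#' smallest representable positive double rather than zero.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return A one-row tibble: `n`, `r`, `statistic`, `df`, `p`.
#' @export
#' @examples
#' pearson_test(1:9, c(1, 3, 2, 4, 5, 7, 6, 8, 9))
pearson_test <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need n >= 3 observations")
  if (var(x) == 0 || var(y) == 0) {
    abort("undefined correlation: zero variance in x or y")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1) .Machine$double.xmin else max(ct$p.value,
                                                      .Machine$double.xmin)
  tibble(n = length(x), r = r, statistic = unname(ct$statistic),
         df = unname(ct$parameter), p = p)
}

# vectorised two-sided t p-value from correlations (same model as
# pearson_test); used for all-pairs edge screens
pearson_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  p <- 2 * pt(-abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps)),
              df = n - 2)
  ifelse(abs(r) >= 1, .Machine$double.xmin, pmax(p, .Machine$double.xmin))
}

#' Co-expression edges between DE lncRNAs and DE mRNAs
#'
#' Every (lncRNA, mRNA) pair is tested for Pearson correlation over *all*
#' samples of the expression table (not per comparison: a pair has one
#' correlation, while DE status is comparison-specific). An edge is kept
#' when `|r| >= min_abs_r` and `p <= max_p`; negative correlations are
#' edges too. Pairs with zero variance in either member are untestable and
#' dropped.
#'
#' @param expr Expression tibble (`feature_id` + sample columns); values
#'   are correlated as given, so pass log-scale expression if that is the
#'   intended scale.
#' @param lnc_ids,mrna_ids Feature ids of the differentially expressed
#'   lncRNAs and mRNAs; all must be rows of `expr`.
#' @param min_abs_r Minimum absolute correlation (default 0.95).
#' @param max_p Maximum p-value (default 1e-4).
#' @return A tibble of edges: `lnc_id`, `mrna_id`, `r`, `p`.
#' @export
coexpression_edges <- function(expr, lnc_ids, mrna_ids,
                               min_abs_r = 0.95, max_p = 1e-4) {
  m <- expr_matrix(expr)
  missing_f <- setdiff(c(lnc_ids, mrna_ids), rownames(m))
  if (length(missing_f) > 0) {
    abort(paste0("feature(s) missing from expr: ",
                 paste(head(missing_f, 5), collapse = ", ")))
  }
  empty <- tibble(lnc_id = character(), mrna_id = character(),
                  r = numeric(), p = numeric())
  if (length(lnc_ids) == 0 || length(mrna_ids) == 0) return(empty)
  n <- ncol(m)
  lm <- t(m[lnc_ids, , drop = FALSE])
  mm <- t(m[mrna_ids, , drop = FALSE])
  suppressWarnings(rmat <- cor(lm, mm))
  edges <- tibble(
    lnc_id = rep(lnc_ids, times = length(mrna_ids)),
    mrna_id = rep(mrna_ids, each = length(lnc_ids)),
    r = as.vector(rmat)
  ) |>
    filter(!is.na(.data$r)) |>
    mutate(p = pearson_p(.data$r, n)) |>
    filter(abs(.data$r) >= min_abs_r, .data$p <= max_p)
  arrange(edges, .data$lnc_id, .data$mrna_id)
}

#' Co-localization edges between DE lncRNAs and DE mRNAs
#'
#' Genomic proximity edges: a (lncRNA transcript, mRNA gene) pair on the
#' same chromosome whose spans are separated by at most `window` bases.
#' The distance is the gap between the lncRNA transcript span and the mRNA
#' gene locus span (0 when they overlap); the location is given for the
#' lncRNA relative to the mRNA's strand: `upstream` (5' side), `downstream`
#' (3' side) or `overlapping` (distance 0).
#'
#' @param ann Annotation tibble containing both the lncRNA transcripts and
#'   the mRNA genes.
#' @param lnc_ids Transcript ids of the DE lncRNAs.
#' @param mrna_gene_ids Gene ids of the DE mRNAs.
#' @param window Maximum separation in bp (default 100,000).
#' @return A tibble of edges: `lnc_id`, `mrna_id`, `distance_bp`,
#'   `location`.
#' @export
colocalization_edges <- function(ann, lnc_ids, mrna_gene_ids, window = 1e5) {
  tx <- transcript_table(ann)
  genes <- gene_table(ann)
  missing_l <- setdiff(lnc_ids, tx$transcript_id)
  missing_m <- setdiff(mrna_gene_ids, genes$gene_id)
  if (length(missing_l) > 0 || length(missing_m) > 0) {
    abort(paste0("feature(s) missing from annotation: ",
                 paste(head(c(missing_l, missing_m), 5), collapse = ", ")))
  }
  lnc <- tx[tx$transcript_id %in% lnc_ids, ]
  mrna <- genes[genes$gene_id %in% mrna_gene_ids, ]
  empty <- tibble(lnc_id = character(), mrna_id = character(),
                  distance_bp = integer(), location = character())
  if (nrow(lnc) == 0 || nrow(mrna) == 0) return(empty)

  pairs <- tidyr::crossing(li = seq_len(nrow(lnc)), mi = seq_len(nrow(mrna)))
  a <- lnc[pairs$li, c("chrom", "start", "end")]
  b <- mrna[pairs$mi, c("chrom", "start", "end")]
  gap <- genomic_gap(a, b)
  keep <- !is.na(gap) & gap <= window
  if (!any(keep)) return(empty)
  li <- pairs$li[keep]; mi <- pairs$mi[keep]; gap <- gap[keep]
  lnc_left <- lnc$end[li] <= mrna$start[mi]
  location <- dplyr::case_when(
    gap == 0 ~ "overlapping",
    (mrna$strand[mi] == "+") == lnc_left ~ "upstream",
    TRUE ~ "downstream"
  )
  tibble(
    lnc_id = lnc$transcript_id[li],
    mrna_id = mrna$gene_id[mi],
    distance_bp = gap,
    location = location
  ) |> arrange(.data$lnc_id, .data$mrna_id)
}

#' Overlap of co-expression and co-localization edges
#'
#' Interaction candidates are the (lncRNA, mRNA) pairs present in both edge
#' lists, carrying both edges' attributes.
#'
#' @param coexp Co-expression edges ([coexpression_edges()]).
#' @param coloc Co-localization edges ([colocalization_edges()]).
#' @return A tibble: `lnc_id`, `mrna_id`, `r`, `p`, `distance_bp`,
#'   `location`.
#' @export
overlap_interactions <- function(coexp, coloc) {
  inner_join(as_tibble(coexp), as_tibble(coloc),
             by = c("lnc_id", "mrna_id")) |>
    arrange(.data$lnc_id, .data$mrna_id)
}

#' Candidates shared by every comparison
#'
#' Intersects per-comparison candidate lists on the (lncRNA, mRNA) pair;
#' a pair qualifies only when present in every comparison. The result
#' carries the attributes from the first comparison's list plus a
#' `comparisons` column naming all of them.
#'
#' @param per_comparison A named list of candidate tibbles (each with
#'   `lnc_id` and `mrna_id`).
#' @return A tibble of shared pairs with a `comparisons` column.
#' @export
intersect_across_comparisons <- function(per_comparison) {
  if (length(per_comparison) == 0) abort("need at least one comparison")
  if (is.null(names(per_comparison)) || any(names(per_comparison) == "")) {
    names(per_comparison) <- paste0("comparison_", seq_along(per_comparison))
  }
  keys <- lapply(per_comparison, function(d) {
    paste(d$lnc_id, d$mrna_id, sep = "\r")
  })
  shared <- reduce(keys, intersect)
  first <- as_tibble(per_comparison[[1]])
  out <- first[paste(first$lnc_id, first$mrna_id, sep = "\r") %in% shared, ]
  out$comparisons <- paste(names(per_comparison), collapse = ";")
  arrange(out, .data$lnc_id, .data$mrna_id)
}

#' Venn region counts for two or three sets
#'
#' Counts every membership region of 2 or 3 feature-id sets (the centre
#' region being the full intersection), as tallied for Venn diagrams of
#' differentially expressed features across comparisons.
#'
#' @param sets A named list of 2 or 3 character vectors.
#' @return A tibble with one logical membership column per set, a `region`
#'   label, and `count`.
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 3) abort("venn_counts supports exactly 2 or 3 sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("sets must be named")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0) {
    membership <- matrix(logical(0), ncol = k, dimnames = list(NULL, names(sets)))
  }
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))
  names(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  counts <- vapply(seq_len(nrow(patterns)), function(i) {
    pat <- unlist(patterns[i, ])
    if (length(universe) == 0) return(0L)
    sum(apply(membership, 1, function(row) all(row == pat)))
  }, integer(1))
  out <- as_tibble(patterns)
  out$region <- vapply(seq_len(nrow(patterns)), function(i) {
    paste(names(sets)[unlist(patterns[i, ])], collapse = "&")
  }, character(1))
  out$count <- counts
  arrange(out, dplyr::desc(rowSums(as.data.frame(out[names(sets)]))))
}
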