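#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the study set hits it more often than
#' expected by chance when drawing `n` genes from a universe of `N` that
#' contains `K` term members: `p = P[X >= k]` for
#' `X ~ Hypergeometric(N, K, n)`. P-values are Benjamini-Hochberg adjusted
#' across all tested terms. The rich factor `k / K` is reported per term.
#' Terms with fewer than `min_term_size` members after intersection with
#' the universe are untestable and skipped (their number is recorded in the
#' `skipped_terms` attribute).
#'
#' @param study Character vector of study-set gene ids; must be a subset
#'   of `universe`.
#' @param term_map A data frame with columns `term_id`, `term_name`,
#'   `gene_id` (one row per membership).
#' @param universe Character vector of background gene ids (non-empty).
#' @param min_term_size Minimum in-universe term size (default 2).
#' @return A tibble sorted by `padj` then `p` with columns `term_id`,
#'   `term_name`, `k`, `K`, `n`, `N`, `rich_factor`, `p`, `padj`.
#' @export
#' @examples
#' tm <- data.frame(term_id = "T1", term_name = "term one",
#'                  gene_id = paste0("g", 1:5))
#' hypergeom_enrich(paste0("g", 1:5), tm, paste0("g", 1:10))
hypergeom_enrich <- function(study, term_map, universe, min_term_size = 2L) {
  if (length(universe) == 0) abort("universe is empty")
  if (!all(c("term_id", "term_name", "gene_id") %in% names(term_map))) {
    abort("term_map needs columns term_id, term_name, gene_id")
  }
  universe <- unique(universe)
  study <- unique(study)
  outside <- setdiff(study, universe)
  if (length(outside) > 0) {
    abort(paste0("study gene(s) outside the universe: ",
                 paste(head(outside, 5), collapse = ", ")))
  }
  tm <- as_tibble(term_map) |>
    filter(.data$gene_id %in% universe) |>
    distinct(.data$term_id, .data$term_name, .data$gene_id)
  sizes <- tm |> count(.data$term_id, name = "K")
  testable <- sizes$term_id[sizes$K >= min_term_size]
  skipped <- sum(sizes$K < min_term_size)
  n <- length(study); N <- length(universe)
  rows <- tm |>
    filter(.data$term_id %in% testable) |>
    group_by(.data$term_id) |>
    summarise(
      term_name = .data$term_name[[1]],
      k = sum(.data$gene_id %in% study),
      K = n(),
      .groups = "drop"
    ) |>
    mutate(
      n = n, N = N,
      rich_factor = .data$k / .data$K,
      p = pmax(phyper(.data$k - 1, .data$K, N - .data$K, n, lower.tail = FALSE),
               .Machine$double.xmin)
    )
  rows$padj <- bh_adjust(rows$p)
  out <- rows |>
    select("term_id", "term_name", "k", "K", "n", "N", "rich_factor",
           "p", "padj") |>
    arrange(.data$padj, .data$p, .data$term_id)
  attr(out, "skipped_terms") <- skipped
  out
}
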