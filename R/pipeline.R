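#' End-to-end lncRNA-mRNA interaction pipeline
#'
#' Runs the full analysis from a single configuration: lncRNA discovery
#' (five-step filtration of candidate transcripts), FPKM computation,
#' per-comparison negative-binomial differential expression (gene-level
#' for mRNAs, transcript-level for lncRNAs), co-expression and
#' co-localization edges between DE lncRNAs and DE mRNAs, their overlap
#' into interaction candidates, the intersection of candidates across all
#' comparisons, and (when a term map is supplied) hypergeometric
#' enrichment of the candidate mRNA partners. TUCPs (transcripts of
#' uncertain coding potential) are carried through differential expression
#' but excluded from the interaction analysis.
#'
#' @param reference Annotation tibble of the annotated transcriptome
#'   (coding genes and annotated lncRNAs), or a GTF path.
#' @param candidates Annotation tibble of candidate transcripts, or a GTF
#'   path.
#' @param counts Transcript-level count tibble (`feature_id` + samples),
#'   or a TSV path.
#' @param design A [study_design()] tibble, or a TSV path with columns
#'   `sample`, `group`.
#' @param coding_calls Coding-call table for the candidates, or a TSV
#'   path.
#' @param comparisons List of `c(B, A)` group pairs; defaults to all
#'   ordered "later vs earlier" pairs of the design's groups plus the
#'   reverse of the last (for 3 groups: 2 vs 1, 3 vs 1, 2 vs 3).
#' @param term_map Optional term-to-gene map for enrichment.
#' @param min_exons,min_len,min_fpkm Filtration thresholds (see
#'   [filter_lncrna_candidates()]).
#' @param de_alpha DE significance threshold on adjusted p.
#' @param min_abs_r,max_p Co-expression thresholds (see
#'   [coexpression_edges()]).
#' @param window Co-localization window in bp.
#' @param output_dir Optional directory; when given, every result table is
#'   persisted as TSV together with a plain-text run manifest.
#' @return An object of class `lnc_pipeline_result`: a list with
#'   `filtration`, `fpkm`, `classes`, `de` (per comparison, lncRNA / mRNA
#'   / TUCP), `coexpression`, `colocalization`, `candidates` (per
#'   comparison), `shared_candidates`, `enrichment` (or `NULL`), and
#'   `manifest`. `glance()` returns per-comparison summary counts.
#' @export
run_lnc_pipeline <- function(reference, candidates, counts, design,
                             coding_calls,
                             comparisons = NULL, term_map = NULL,
                             min_exons = 2L, min_len = 200L, min_fpkm = 0.5,
                             de_alpha = 0.05, min_abs_r = 0.95, max_p = 1e-4,
                             window = 1e5, output_dir = NULL) {
  if (is.character(reference)) reference <- read_gtf(reference)
  if (is.character(candidates)) candidates <- read_gtf(candidates)
  if (is.character(counts)) counts <- readr::read_tsv(counts, show_col_types = FALSE)
  if (is.character(design)) design <- readr::read_tsv(design, show_col_types = FALSE)
  if (is.character(coding_calls)) {
    coding_calls <- readr::read_tsv(coding_calls, show_col_types = FALSE)
  }
  reference <- as_annotation(reference)
  candidates <- as_annotation(candidates)
  annotation <- as_annotation(bind_rows(reference, candidates))
  groups <- unique(design$group)
  if (is.null(comparisons)) {
    if (length(groups) < 2) abort("need >= 2 groups")
    comparisons <- list()
    for (i in seq_along(groups)[-1]) {
      comparisons[[length(comparisons) + 1]] <- c(groups[[i]], groups[[1]])
    }
    if (length(groups) >= 3) {
      comparisons[[length(comparisons) + 1]] <- c(groups[[2]], groups[[3]])
    }
  }
  cmp_label <- vapply(comparisons, function(x) paste(x[[1]], "vs", x[[2]]),
                      character(1))

  # expression: transcript FPKM, then gene-level for mRNAs
  tx_all <- transcript_table(annotation)
  lengths <- setNames(tx_all$length, tx_all$transcript_id)
  present <- intersect(counts$feature_id, names(lengths))
  counts <- counts[counts$feature_id %in% present, ]
  fpkm <- compute_fpkm(counts, lengths[present])

  # discovery
  filtration <- filter_lncrna_candidates(candidates, reference, fpkm,
                                         coding_calls, min_exons, min_len,
                                         min_fpkm)
  rep_tbl <- filtration$report
  lnc_ids <- rep_tbl$transcript_id[rep_tbl$outcome %in%
                                     c("novel_lncRNA", "annotated_lncRNA")]
  tucp_ids <- rep_tbl$transcript_id[rep_tbl$outcome == "TUCP"]
  classes <- classify_lncrna(
    candidates[candidates$transcript_id %in% lnc_ids, ], reference)

  # mRNA gene-level counts; lncRNA and TUCP transcript-level
  coding_tx <- reference[reference$biotype == "coding", ]
  tx2gene <- distinct(coding_tx[, c("transcript_id", "gene_id")])
  mrna_counts <- counts[counts$feature_id %in% tx2gene$transcript_id, ]
  gene_counts <- gene_level_counts(mrna_counts, tx2gene)
  lnc_counts <- counts[counts$feature_id %in% lnc_ids, ]
  tucp_counts <- counts[counts$feature_id %in% tucp_ids, ]

  gene_fpkm <- gene_level_fpkm(fpkm[fpkm$feature_id %in% tx2gene$transcript_id, ],
                               tx2gene)
  expr_all <- bind_rows(gene_fpkm, fpkm[fpkm$feature_id %in% lnc_ids, ])
  expr_log <- expr_all
  expr_log[, -1] <- log2(expr_all[, -1] + 1)

  # normalisation and dispersion are estimated once across every feature
  # entering a DE test (mRNA genes + lncRNA/TUCP transcripts): small
  # per-class matrices alone give a fragile shared-dispersion target
  de_space <- bind_rows(gene_counts, lnc_counts, tucp_counts)
  sf <- estimate_size_factors(de_space)
  disp <- estimate_dispersion(de_space, design, sf)

  de <- list()
  run_de <- function(cts) {
    if (nrow(cts) < 2) return(NULL)
    d_sub <- disp[match(cts$feature_id, disp$feature_id), ]
    lapply(comparisons, function(cmp) {
      nb_diffexpr(cts, design, cmp, dispersions = d_sub, size_factors = sf,
                  alpha = de_alpha)
    }) |> setNames(cmp_label)
  }
  de$mrna <- run_de(gene_counts)
  de$lncrna <- run_de(lnc_counts)
  de$tucp <- run_de(tucp_counts)

  coexp <- list(); coloc <- list(); cands <- list()
  for (cmp in cmp_label) {
    de_l <- if (!is.null(de$lncrna)) {
      r <- de$lncrna[[cmp]]$results; r$feature_id[r$is_de]
    } else character(0)
    de_m <- if (!is.null(de$mrna)) {
      r <- de$mrna[[cmp]]$results; r$feature_id[r$is_de]
    } else character(0)
    coexp[[cmp]] <- coexpression_edges(expr_log, de_l, de_m, min_abs_r, max_p)
    coloc[[cmp]] <- colocalization_edges(annotation, de_l, de_m, window)
    cands[[cmp]] <- overlap_interactions(coexp[[cmp]], coloc[[cmp]])
  }
  shared <- if (length(cands) > 0) intersect_across_comparisons(cands) else NULL

  enrichment <- NULL
  if (!is.null(term_map)) {
    expressed <- gene_fpkm$feature_id[
      apply(as.data.frame(gene_fpkm[, -1]), 1, max) >= min_fpkm]
    study <- unique(unlist(lapply(cands, function(d) d$mrna_id)))
    study <- intersect(study, expressed)
    if (length(study) > 0) {
      enrichment <- hypergeom_enrich(study, term_map, expressed)
    }
  }

  manifest <- c(
    paste0("package_version\t", as.character(utils::packageVersion("lncpair"))),
    paste0("comparisons\t", paste(cmp_label, collapse = ";")),
    paste0("min_exons\t", min_exons), paste0("min_len\t", min_len),
    paste0("min_fpkm\t", min_fpkm), paste0("de_alpha\t", de_alpha),
    paste0("min_abs_r\t", min_abs_r), paste0("max_p\t", max_p),
    paste0("window\t", window)
  )

  res <- list(filtration = filtration, fpkm = fpkm, classes = classes,
              de = de, coexpression = coexp, colocalization = coloc,
              candidates = cands, shared_candidates = shared,
              enrichment = enrichment, manifest = manifest)
  class(res) <- "lnc_pipeline_result"
  if (!is.null(output_dir)) write_pipeline_result(res, output_dir)
  res
}

write_pipeline_result <- function(res, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, name) {
    readr::write_tsv(d, file.path(output_dir, paste0(name, ".tsv")), na = ".")
  }
  w(res$filtration$report, "filtration_report")
  w(res$filtration$steps, "filtration_steps")
  w(res$classes, "lnc_classes")
  slug <- function(x) gsub("[^A-Za-z0-9]+", "_", x)
  for (lvl in names(res$de)) {
    for (cmp in names(res$de[[lvl]])) {
      w(res$de[[lvl]][[cmp]]$results, paste0("de_", lvl, "_", slug(cmp)))
    }
  }
  for (cmp in names(res$candidates)) {
    w(res$coexpression[[cmp]], paste0("coexpression_", slug(cmp)))
    w(res$colocalization[[cmp]], paste0("colocalization_", slug(cmp)))
    w(res$candidates[[cmp]], paste0("candidates_", slug(cmp)))
  }
  if (!is.null(res$shared_candidates)) w(res$shared_candidates, "shared_candidates")
  if (!is.null(res$enrichment)) w(res$enrichment, "enrichment")
  writeLines(res$manifest, file.path(output_dir, "manifest.tsv"))
  invisible(output_dir)
}

#' @export
glance.lnc_pipeline_result <- function(x, ...) {
  cmps <- names(x$candidates)
  bind_rows(lapply(cmps, function(cmp) {
    g <- function(lvl) {
      if (is.null(x$de[[lvl]])) return(c(0L, 0L))
      gl <- glance(x$de[[lvl]][[cmp]])
      c(gl$n_up, gl$n_down)
    }
    l <- g("lncrna"); m <- g("mrna"); t <- g("tucp")
    tibble(comparison = cmp,
           lnc_up = l[[1]], lnc_down = l[[2]],
           mrna_up = m[[1]], mrna_down = m[[2]],
           tucp_up = t[[1]], tucp_down = t[[2]],
           coexpression = nrow(x$coexpression[[cmp]]),
           colocalization = nrow(x$colocalization[[cmp]]),
           candidates = nrow(x$candidates[[cmp]]))
  }))
}

#' @export
print.lnc_pipeline_result <- function(x, ...) {
  cat("lncRNA-mRNA interaction pipeline result\n")
  print(glance(x))
  if (!is.null(x$shared_candidates)) {
    cat("candidates shared by all comparisons:", nrow(x$shared_candidates), "\n")
  }
  invisible(x)
}

#' Ratio of two fatty acids in a diet-composition table
#'
#' Computes a fatty-acid ratio (e.g. DHA/EPA, i.e. C22:6n-3 over C20:5n-3)
#' from a diet-composition table of percentages of total fatty acids.
#'
#' @param table A data frame with a `fatty_acid` column and one numeric
#'   column per diet.
#' @param numerator,denominator Fatty-acid names (rows of `table`).
#' @param diet Diet column name.
#' @return A one-row tibble: `diet`, `numerator`, `denominator`, `ratio`
#'   (full precision) and `ratio_2dp` (rounded to 2 decimals).
#' @export
#' @examples
#' diets <- read_diet_table(lncpair_example("diet_fatty_acids.tsv"))
#' diet_ratio(diets, "C22:6n-3", "C20:5n-3", "D/E-2.75")
diet_ratio <- function(table, numerator, denominator, diet) {
  if (!"fatty_acid" %in% names(table)) abort("table needs a fatty_acid column")
  if (!diet %in% names(table)) abort(paste0("no diet column '", diet, "'"))
  num <- table[[diet]][table$fatty_acid == numerator]
  den <- table[[diet]][table$fatty_acid == denominator]
  if (length(num) != 1 || length(den) != 1) {
    abort("numerator and denominator must each match exactly one row")
  }
  if (den == 0) abort("zero denominator fatty acid")
  tibble(diet = diet, numerator = numerator, denominator = denominator,
         ratio = num / den, ratio_2dp = round(num / den, 2))
}

#' Bundled plain-text example tables
#'
#' `lncpair_example()` resolves the path of a bundled fixture;
#' `read_diet_table()`, `read_interaction_table()` and
#' `read_sequencing_summary()` load the bundled diet fatty-acid
#' composition table, the printed lncRNA-mRNA match table (per-comparison
#' co-expression/co-localization attributes), and the per-group clean-read
#' totals.
#'
#' @param file File name under the package's `extdata` (empty to list
#'   all).
#' @return A path, or a tibble for the readers.
#' @export
lncpair_example <- function(file = "") {
  if (file == "") {
    dir(system.file("extdata", package = "lncpair"))
  } else {
    path <- system.file("extdata", file, package = "lncpair")
    if (path == "") abort(paste0("no bundled file '", file, "'"))
    path
  }
}

#' @rdname lncpair_example
#' @param path Path to the TSV file (defaults to the bundled copy).
#' @export
read_diet_table <- function(path = lncpair_example("diet_fatty_acids.tsv")) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname lncpair_example
#' @export
read_interaction_table <- function(path = lncpair_example("interaction_matches.tsv")) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname lncpair_example
#' @export
read_sequencing_summary <- function(path = lncpair_example("sequencing_summary.tsv")) {
  readr::read_tsv(path, show_col_types = FALSE)
}
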