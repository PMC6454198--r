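#' Study designs and comparisons
#'
#' A study design is a tibble mapping samples to groups; comparisons are
#' ordered pairs `c(B, A)` read as "B vs A", with log2 fold changes of B
#' relative to A.
#'
#' @param samples Character vector of sample ids (must match count-matrix
#'   columns).
#' @param groups Character vector of group labels, one per sample.
#' @return A tibble with columns `sample` and `group`.
#' @export
study_design <- function(samples, groups) {
  if (length(samples) != length(groups)) {
    abort("samples and groups must have equal length")
  }
  if (anyDuplicated(samples)) abort("duplicated sample ids")
  tibble(sample = as.character(samples), group = as.character(groups))
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed as the median across features of the
#' ratio of each sample's count to the feature's geometric mean over
#' samples (features with a zero count in any sample are excluded from the
#' reference), then rescaled so the geometric mean of the factors is 1.
#'
#' @param counts Count tibble (`feature_id` + sample columns).
#' @return A tibble with columns `sample` and `size_factor`.
#' @export
estimate_size_factors <- function(counts) {
  m <- counts_matrix(counts)
  if (any(colSums(m) == 0)) abort("sample(s) with all-zero counts")
  pos <- rowSums(m == 0) == 0
  if (!any(pos)) abort("no feature has nonzero counts in every sample")
  logm <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(logm)
  raw <- apply(logm, 2, function(col) exp(median(col - ref)))
  sf <- raw / exp(mean(log(raw)))
  tibble(sample = colnames(m), size_factor = unname(sf))
}

#' Per-feature negative-binomial dispersion
#'
#' Within-group method-of-moments estimates on normalised counts,
#' `max(0, (s^2 - m) / m^2)` averaged over groups (NB parameterisation
#' `variance = mu + phi * mu^2`), then shrunk toward the across-feature
#' mean with `prior_df` pseudo-degrees of freedom:
#' `phi = (d * phi_g + prior_df * mean(phi)) / (d + prior_df)`, where `d`
#' is the within-group residual degrees of freedom. With few replicates the
#' per-feature estimate is dominated by the shared value; with many it
#' converges to the feature's own. Estimates are floored at `1e-8`.
#'
#' @param counts Count tibble (`feature_id` + sample columns).
#' @param design A [study_design()] covering every sample; groups with at
#'   least two replicates contribute.
#' @param size_factors Optional precomputed [estimate_size_factors()]
#'   output.
#' @param prior_df Shrinkage weight of the across-feature mean (default
#'   20).
#' @return A tibble with `feature_id`, `dispersion_raw` (unshrunk) and
#'   `dispersion`.
#' @export
estimate_dispersion <- function(counts, design, size_factors = NULL,
                                prior_df = 20) {
  m <- counts_matrix(counts)
  design <- check_design(design, colnames(m))
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  sf <- setNames(size_factors$size_factor, size_factors$sample)[colnames(m)]
  norm <- sweep(m, 2, sf, "/")
  groups <- split(design$sample, design$group)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  if (length(groups) == 0) abort("no group has >= 2 replicates")
  mom <- function(truncate) {
    matrix(vapply(groups, function(ss) {
      sub <- norm[, ss, drop = FALSE]
      mu <- rowMeans(sub)
      s2 <- apply(sub, 1, var)
      out <- rep(NA_real_, nrow(sub))
      ok <- mu > 0
      est <- (s2[ok] - mu[ok]) / mu[ok]^2
      out[ok] <- if (truncate) pmax(0, est) else est
      out
    }, numeric(nrow(norm))), nrow = nrow(norm))
  }
  raw <- rowMeans(mom(TRUE), na.rm = TRUE)
  raw[is.nan(raw)] <- 0
  # the shrinkage target averages the *untruncated* estimates: truncating at
  # zero before averaging would bias the shared dispersion upward
  target <- max(mean(rowMeans(mom(FALSE), na.rm = TRUE), na.rm = TRUE), 0)
  d <- sum(vapply(groups, length, integer(1)) - 1L)
  shrunk <- (d * raw + prior_df * target) / (d + prior_df)
  tibble(feature_id = rownames(m),
         dispersion_raw = unname(raw),
         dispersion = pmax(unname(shrunk), 1e-8))
}

#' Negative-binomial Wald test between two groups
#'
#' For each feature, counts are normalised by median-of-ratios size
#' factors and group means compared with a Wald test on the log scale:
#' `z = (log(mu_B + c) - log(mu_A + c)) / SE`, with the standard error from
#' the delta method under the NB variance `mu + phi * mu^2`:
#' `SE^2 = (1/(mu_A + c) + phi) / n_A + (1/(mu_B + c) + phi) / n_B`.
#' Two-sided p-values come from the normal reference; the pseudo-count `c`
#' (default 1 normalised count) keeps fold changes finite when one group is
#' unobserved. Features with all-zero counts in both groups report
#' `log2fc = 0, p = 1`. P-values are Benjamini-Hochberg adjusted across
#' features and a feature is called differentially expressed when
#' `padj < alpha`; direction is `up`/`down` by the sign of `log2fc`
#' (`none` for an exact zero).
#'
#' @param counts Count tibble (`feature_id` + sample columns).
#' @param design A [study_design()].
#' @param comparison Character pair `c(B, A)`, read "B vs A"; both groups
#'   need at least two samples.
#' @param dispersions Optional [estimate_dispersion()] output (computed
#'   from `counts` and `design` when omitted).
#' @param size_factors Optional [estimate_size_factors()] output.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param pseudocount The offset `c` above (default 1).
#' @return An object of class `nb_de` with a `results` tibble
#'   (`feature_id`, `comparison`, `mean_a`, `mean_b`, `log2fc`, `stat`,
#'   `p`, `padj`, `is_de`, `direction`). `tidy()` returns the tibble,
#'   `glance()` the per-comparison up/down tallies, `autoplot()` a volcano
#'   plot.
#' @export
nb_diffexpr <- function(counts, design, comparison, dispersions = NULL,
                        size_factors = NULL, alpha = 0.05, pseudocount = 1) {
  m <- counts_matrix(counts)
  design <- check_design(design, colnames(m))
  if (length(comparison) != 2 || comparison[[1]] == comparison[[2]]) {
    abort("comparison must name two distinct groups c(B, A)")
  }
  b <- comparison[[1]]; a <- comparison[[2]]
  missing_g <- setdiff(c(b, a), unique(design$group))
  if (length(missing_g) > 0) {
    abort(paste0("group(s) not in design: ", paste(missing_g, collapse = ", ")))
  }
  sa <- design$sample[design$group == a]
  sb <- design$sample[design$group == b]
  if (length(sa) < 2 || length(sb) < 2) {
    abort("both comparison groups need >= 2 samples")
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(counts, design, size_factors)
  }
  sf <- setNames(size_factors$size_factor, size_factors$sample)[colnames(m)]
  norm <- sweep(m, 2, sf, "/")
  phi <- setNames(dispersions$dispersion, dispersions$feature_id)[rownames(m)]
  if (any(is.na(phi))) abort("dispersions must cover every feature")

  mu_a <- rowMeans(norm[, sa, drop = FALSE])
  mu_b <- rowMeans(norm[, sb, drop = FALSE])
  c0 <- pseudocount
  se <- sqrt((1 / (mu_a + c0) + phi) / length(sa) +
               (1 / (mu_b + c0) + phi) / length(sb))
  z <- (log(mu_b + c0) - log(mu_a + c0)) / se
  p <- 2 * pnorm(-abs(z))
  log2fc <- log2((mu_b + c0) / (mu_a + c0))

  zero_both <- rowSums(m[, c(sa, sb), drop = FALSE]) == 0
  z[zero_both] <- 0; p[zero_both] <- 1; log2fc[zero_both] <- 0

  padj <- bh_adjust(p)
  is_de <- padj < alpha
  direction <- dplyr::case_when(
    !is_de ~ NA_character_,
    log2fc > 0 ~ "up",
    log2fc < 0 ~ "down",
    TRUE ~ "none"
  )
  res <- list(
    results = tibble(
      feature_id = rownames(m),
      comparison = paste(b, "vs", a),
      mean_a = unname(mu_a), mean_b = unname(mu_b),
      log2fc = unname(log2fc), stat = unname(z),
      p = unname(p), padj = unname(padj),
      is_de = unname(is_de), direction = direction
    ),
    comparison = c(B = b, A = a),
    alpha = alpha,
    size_factors = size_factors,
    dispersions = dispersions
  )
  class(res) <- "nb_de"
  res
}

#' @export
tidy.nb_de <- function(x, ...) x$results

#' @export
glance.nb_de <- function(x, ...) {
  r <- x$results
  tibble(
    comparison = r$comparison[[1]] %||% paste(x$comparison[["B"]], "vs",
                                              x$comparison[["A"]]),
    n_features = nrow(r),
    n_de = sum(r$is_de),
    n_up = sum(r$is_de & r$direction == "up", na.rm = TRUE),
    n_down = sum(r$is_de & r$direction == "down", na.rm = TRUE),
    alpha = x$alpha
  )
}

#' @export
print.nb_de <- function(x, ...) {
  cat("negative-binomial differential expression\n")
  print(glance(x))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment
#' (`adj_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, mapped back to the
#' input order). Thin validated wrapper over `stats::p.adjust(method =
#' "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return The adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no NA")
  }
  p.adjust(p, method = "BH")
}

#' Differential-expression calls and tallies
#'
#' Applies the significance rule `padj < alpha` to a result table and
#' tallies up/down calls by the sign of the fold change; features with a
#' fold change of exactly zero are flagged `none` and excluded from both
#' tallies.
#'
#' @param results A tibble with `feature_id`, `log2fc`, `padj` (e.g.
#'   `tidy()` of an `nb_de` object).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return A list with `results` (input plus `is_de`, `direction`) and
#'   `counts` (one-row tibble `n_de`, `n_up`, `n_down`, `n_none`).
#' @export
call_de <- function(results, alpha = 0.05) {
  if (!all(c("feature_id", "log2fc", "padj") %in% names(results))) {
    abort("results needs columns feature_id, log2fc, padj")
  }
  r <- as_tibble(results)
  r$is_de <- r$padj < alpha
  r$direction <- dplyr::case_when(
    !r$is_de ~ NA_character_,
    r$log2fc > 0 ~ "up",
    r$log2fc < 0 ~ "down",
    TRUE ~ "none"
  )
  list(
    results = r,
    counts = tibble(
      n_de = sum(r$is_de),
      n_up = sum(r$is_de & r$direction == "up", na.rm = TRUE),
      n_down = sum(r$is_de & r$direction == "down", na.rm = TRUE),
      n_none = sum(r$is_de & r$direction == "none", na.rm = TRUE)
    )
  )
}

check_design <- function(design, samples) {
  if (!all(c("sample", "group") %in% names(design))) {
    abort("design needs columns sample and group")
  }
  design <- as_tibble(design)
  missing_s <- setdiff(samples, design$sample)
  if (length(missing_s) > 0) {
    abort(paste0("sample(s) missing from design: ",
                 paste(missing_s, collapse = ", ")))
  }
  design[design$sample %in% samples, ]
}
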