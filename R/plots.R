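#' Volcano plot of a differential-expression result
#'
#' @param object An `nb_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nb_de <- function(object, ...) {
  r <- object$results
  ggplot(r, aes(x = .data$log2fc, y = -log10(pmax(.data$padj, 1e-300)),
                colour = .data$is_de)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_hline(yintercept = -log10(object$alpha), linetype = "dashed") +
    labs(x = "log2 fold change", y = "-log10 adjusted p",
         colour = paste0("padj < ", object$alpha),
         title = r$comparison[[1]] %||% "differential expression") +
    theme_minimal()
}

#' Survivor counts along the filtration cascade
#'
#' @param object An `lnc_filtration` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lnc_filtration <- function(object, ...) {
  s <- object$steps
  s$step <- factor(s$step, levels = s$step)
  ggplot(s, aes(x = .data$step, y = .data$survivors)) +
    geom_col(fill = "steelblue") +
    labs(x = "cascade step (survivors after)", y = "transcripts",
         title = "lncRNA filtration cascade") +
    theme_minimal()
}

#' Per-class transcript feature distributions
#'
#' Plots the summaries of [summarize_transcript_features()] as median
#' points with interquartile ranges, one facet per metric, mirroring the
#' usual lncRNA-versus-mRNA length/exon/expression comparisons.
#'
#' @param summaries Output of [summarize_transcript_features()].
#' @return A ggplot.
#' @export
plot_feature_summaries <- function(summaries) {
  ggplot(summaries, aes(x = .data$class, y = .data$median)) +
    ggplot2::geom_pointrange(aes(ymin = .data$q25, ymax = .data$q75)) +
    facet_wrap(~.data$metric, scales = "free_y") +
    labs(x = NULL, y = "median (IQR)") +
    theme_minimal()
}

#' Bar chart of Venn region counts
#'
#' @param regions Output of [venn_counts()].
#' @return A ggplot.
#' @export
plot_venn_regions <- function(regions) {
  regions$region <- factor(regions$region, levels = regions$region)
  ggplot(regions, aes(x = .data$region, y = .data$count)) +
    geom_col(fill = "darkorange") +
    labs(x = "membership region", y = "features") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
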