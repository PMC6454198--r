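#' Livak 2^-ddCt relative expression
#'
#' Relative quantification of qPCR cycle-threshold (CT) values against a
#' reference gene and a calibrator group, assuming an amplification
#' efficiency of exactly 2:
#' `dCT_s = CT[target, s] - CT[reference, s]`,
#' `ddCT_s = dCT_s - mean(dCT over the calibrator group)`,
#' `RQ_s = 2^(-ddCT_s)`.
#' By construction the geometric mean of RQ over the calibrator group is 1,
#' and adding a constant to every CT of one sample leaves RQ unchanged.
#'
#' @param ct A data frame of CT measurements with columns `sample`,
#'   `group`, `gene`, `ct`; the target and reference genes must be measured
#'   in every sample.
#' @param target Target gene id.
#' @param reference Reference (housekeeping) gene id.
#' @param calibrator_group Group label whose mean dCT calibrates the scale;
#'   must be non-empty.
#' @return A tibble with one row per sample: `sample`, `group`,
#'   `delta_ct`, `delta_delta_ct`, `rq`.
#' @export
ddct_relative_expression <- function(ct, target, reference, calibrator_group) {
  if (!all(c("sample", "group", "gene", "ct") %in% names(ct))) {
    abort("ct needs columns sample, group, gene, ct")
  }
  ct <- as_tibble(ct)
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    abort("CT values must be finite and > 0")
  }
  wide <- ct |>
    filter(.data$gene %in% c(target, reference)) |>
    tidyr::pivot_wider(id_cols = c("sample", "group"), names_from = "gene",
                       values_from = "ct")
  if (!target %in% names(wide) || anyNA(wide[[target]])) {
    abort(paste0("target gene '", target, "' not measured in every sample"))
  }
  if (!reference %in% names(wide) || anyNA(wide[[reference]])) {
    abort(paste0("reference gene '", reference, "' not measured in every sample"))
  }
  if (!any(wide$group == calibrator_group)) {
    abort(paste0("calibrator group '", calibrator_group, "' has no samples"))
  }
  wide$delta_ct <- unname(wide[[target]] - wide[[reference]])
  cal <- mean(wide$delta_ct[wide$group == calibrator_group])
  wide$delta_delta_ct <- wide$delta_ct - cal
  wide$rq <- 2^(-wide$delta_delta_ct)
  wide[, c("sample", "group", "delta_ct", "delta_delta_ct", "rq")]
}
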