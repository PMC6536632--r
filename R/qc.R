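#' Recording quality control
#'
#' Applies the standard whole-cell exclusion rules: series resistance above
#' 25 MOhm, resting membrane potential more depolarized than -50 mV, or
#' baseline fluctuation above 10% all fail the cell. Missing metadata fails
#' conservatively.
#'
#' @param metadata list (or a `trace_set`) with `series_resistance_MOhm`,
#'   `rmp_mV`, `drift_fraction`.
#' @param max_rs series-resistance cutoff (MOhm).
#' @param max_rmp most depolarized admissible resting potential (mV).
#' @param max_drift admissible baseline fluctuation (fraction).
#' @return One-row tibble `pass` (logical) and `reasons` (comma-separated
#'   string, empty when passing).
#' @examples
#' qc_filter(list(series_resistance_MOhm = 30, rmp_mV = -70,
#'                drift_fraction = 0.05))
#' @export
qc_filter <- function(metadata, max_rs = 25, max_rmp = -50, max_drift = 0.10) {
  if (inherits(metadata, "trace_set")) metadata <- metadata$metadata
  reasons <- character(0)
  need <- c("series_resistance_MOhm", "rmp_mV", "drift_fraction")
  have <- vapply(need, function(f) {
    !is.null(metadata[[f]]) && is.finite(metadata[[f]])
  }, logical(1))
  if (!all(have)) {
    reasons <- c(reasons, "missing-metadata")
  } else {
    if (metadata$series_resistance_MOhm > max_rs) {
      reasons <- c(reasons, "series resistance")
    }
    if (metadata$rmp_mV > max_rmp) reasons <- c(reasons, "RMP")
    if (metadata$drift_fraction > max_drift) reasons <- c(reasons, "drift")
  }
  tibble::tibble(pass = length(reasons) == 0,
                 reasons = paste(reasons, collapse = ", "))
}
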