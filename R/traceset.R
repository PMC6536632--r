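#' Construct a set of current-clamp sweeps for one cell
#'
#' A `trace_set` holds the voltage responses of one cell to a family of
#' current steps on a shared uniform time grid, with time zero at step onset,
#' plus the recording metadata needed for quality control.
#'
#' @param cell_id cell label.
#' @param time numeric time grid in seconds (uniform, `t = 0` at step onset).
#' @param voltages numeric matrix, one column per sweep (mV).
#' @param currents injected current of each sweep (pA), unique, one per column.
#' @param step_duration duration of the current step (s).
#' @param metadata list with `series_resistance_MOhm`, `rmp_mV`,
#'   `drift_fraction` (missing entries allowed; QC then fails conservatively).
#' @param truth optional list of generator ground truth (kept verbatim).
#' @return A `trace_set` object.
#' @export
trace_set <- function(cell_id, time, voltages, currents,
                      step_duration = 1, metadata = list(), truth = NULL) {
  voltages <- as.matrix(voltages)
  if (length(time) != nrow(voltages)) {
    abort("`time` and `voltages` rows must agree.")
  }
  if (length(currents) != ncol(voltages)) {
    abort("one current per sweep column is required.")
  }
  if (anyDuplicated(currents)) abort("sweep currents must be unique.")
  if (!all(is.finite(voltages))) abort("voltages must be finite.")
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-9)) abort("`time` must be a uniform grid.")
  ord <- order(currents)
  voltages <- voltages[, ord, drop = FALSE]
  currents <- currents[ord]
  colnames(voltages) <- paste0("I_", currents)
  structure(
    list(cell_id = cell_id, time = time, voltages = voltages,
         currents = currents, step_duration = step_duration,
         metadata = metadata, truth = truth),
    class = "trace_set"
  )
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf(
    "<trace_set> %s: %d sweeps (%g..%g pA), %g kHz, step %g s\n",
    x$cell_id, length(x$currents), min(x$currents), max(x$currents),
    1 / diff(x$time[1:2]) / 1000, x$step_duration
  ))
  invisible(x)
}

#' @describeIn trace_set long-format view: `time_s`, `current_pA`, `voltage_mV`.
#' @param x a `trace_set`.
#' @param ... unused.
#' @export
as_tibble.trace_set <- function(x, ...) {
  tibble::tibble(
    cell_id = x$cell_id,
    time_s = rep(x$time, times = length(x$currents)),
    current_pA = rep(x$currents, each = length(x$time)),
    voltage_mV = as.vector(x$voltages)
  )
}

sampling_rate <- function(ts) 1 / (ts$time[2] - ts$time[1])

get_sweep <- function(ts, current) {
  i <- match(current, ts$currents)
  if (is.na(i)) abort(sprintf("no sweep at %g pA", current))
  ts$voltages[, i]
}

# index window of the step [0, step_duration)
step_window <- function(ts) {
  which(ts$time >= 0 & ts$time < ts$step_duration)
}

#' Write / read the sweep-table CSV dialect
#'
#' One CSV per cell: column `time_s` then one voltage column per sweep named
#' `I_<pA>`; a JSON sidecar (`<path>.json`) stores the cell id, step duration
#' and QC metadata.
#'
#' @param ts a [trace_set()].
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_sweep_csv()` returns `path` invisibly; `read_sweep_csv()`
#'   returns a [trace_set()].
#' @export
write_sweep_csv <- function(ts, path) {
  df <- tibble::as_tibble(as.data.frame(ts$voltages))
  df <- dplyr::bind_cols(tibble::tibble(time_s = ts$time), df)
  readr::write_csv(df, path)
  side <- list(
    cell_id = ts$cell_id,
    step_duration_s = ts$step_duration,
    series_resistance_MOhm = ts$metadata$series_resistance_MOhm,
    rmp_mV = ts$metadata$rmp_mV,
    drift_fraction = ts$metadata$drift_fraction
  )
  jsonlite::write_json(side[!vapply(side, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "time_s") abort("first column must be `time_s`.")
  vc <- grep("^I_", names(df), value = TRUE)
  if (length(vc) == 0) abort("no sweep columns (`I_<pA>`) found.")
  currents <- as.numeric(sub("^I_", "", vc))
  if (any(is.na(currents))) abort("sweep column names must be `I_<pA>`.")
  meta <- list()
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
  trace_set(
    cell_id = side$cell_id %||% sub("\\.csv$", "", basename(path)),
    time = df$time_s,
    voltages = as.matrix(df[vc]),
    currents = currents,
    step_duration = side$step_duration_s %||% 1,
    metadata = list(
      series_resistance_MOhm = side$series_resistance_MOhm,
      rmp_mV = side$rmp_mV,
      drift_fraction = side$drift_fraction
    )
  )
}

#' Plot the sweeps of a trace set
#'
#' @param object a [trace_set()].
#' @param currents optional subset of sweep currents to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.trace_set <- function(object, currents = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(currents)) df <- dplyr::filter(df, .data$current_pA %in% currents)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$voltage_mV,
                                   group = .data$current_pA,
                                   colour = .data$current_pA)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "membrane potential (mV)",
                  colour = "I (pA)", title = object$cell_id) +
    ggplot2::theme_minimal()
}
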