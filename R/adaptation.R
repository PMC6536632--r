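#' Choose the criterion sweep for adaptation analysis
#'
#' Adaptation statistics depend on the drive, so they are measured on a
#' standard sweep: either the available sweep nearest 50 pA above the current
#' threshold (`"plus50"`, the default) or the smallest sweep that fires at
#' least ten APs (`"ten_spikes"`). Both conventions appear in practice and
#' are exposed.
#'
#' @param ts a [trace_set()].
#' @param policy `"plus50"` or `"ten_spikes"`.
#' @param dvdt_criterion AP detection criterion (mV/ms).
#' @return Sweep current in pA, or `NA` when no sweep qualifies.
#' @export
select_criterion_sweep <- function(ts, policy = c("plus50", "ten_spikes"),
                                   dvdt_criterion = 10) {
  policy <- match.arg(policy)
  counts <- sweep_spike_counts(ts, dvdt_criterion)
  if (policy == "plus50") {
    thr <- current_threshold(ts, dvdt_criterion)
    if (is.na(thr)) return(NA_real_)
    cand <- which(ts$currents > 0 & counts >= 1)
    cand[which.min(abs(ts$currents[cand] - (thr + 50)))] |>
      (\(j) ts$currents[j])()
  } else {
    hit <- which(ts$currents > 0 & counts >= 10)
    if (length(hit) == 0) return(NA_real_)
    min(ts$currents[hit])
  }
}

#' Instantaneous-frequency series of a spike train
#'
#' The instantaneous frequency is the inverse of the interval between
#' successive APs; each value is timestamped at the midpoint of its
#' interval, measured from the first spike. The midpoint is where the
#' interval average best represents the underlying rate, which keeps
#' exponential fits of the decay essentially unbiased.
#'
#' @param spike_times increasing spike times (s), at least 2.
#' @return Tibble `interval`, `t_s` (interval midpoint measured from the
#'   first spike), `if_Hz` and `if_norm` (first value = 1).
#' @export
instantaneous_frequency_series <- function(spike_times) {
  if (length(spike_times) < 2) {
    abort("at least two spikes are required for an IF series.")
  }
  if (any(diff(spike_times) <= 0)) abort("spike times must be increasing.")
  iv <- 1 / diff(spike_times)
  n <- length(spike_times)
  tibble::tibble(
    interval = seq_along(iv),
    t_s = (spike_times[-1] + spike_times[-n]) / 2 - spike_times[1],
    if_Hz = iv,
    if_norm = iv / iv[1]
  )
}

#' Adaptation ratio of a per-spike series
#'
#' Frequency adaptation is reported as `1 - mean(last k) / mean(first k)`
#' of the instantaneous frequencies (defaults: first 2, last 3, so a
#' non-adapting train scores 0); amplitude and duration adaptation are the
#' plain last/first ratios (defaults: single first/last values, so a
#' constant train scores 1).
#'
#' @param values per-interval IF values (mode `"frequency"`) or per-spike
#'   amplitudes/half-widths.
#' @param mode `"frequency"`, `"amplitude"` or `"duration"`.
#' @param first_k,last_k how many leading/trailing values to average;
#'   `NULL` uses the mode's convention (2/3 for frequency, 1/1 otherwise).
#' @return Dimensionless ratio, `NA` when the series is too short.
#' @export
adaptation_ratio <- function(values, mode = c("frequency", "amplitude",
                                              "duration"),
                             first_k = NULL, last_k = NULL) {
  mode <- match.arg(mode)
  first_k <- first_k %||% if (mode == "frequency") 2L else 1L
  last_k <- last_k %||% if (mode == "frequency") 3L else 1L
  if (length(values) < first_k + last_k) return(NA_real_)
  r <- mean(tail(values, last_k)) / mean(head(values, first_k))
  if (mode == "frequency") 1 - r else r
}

#' Maximum frequency adaptation in absolute terms
#'
#' The largest drop of instantaneous frequency below the initial value
#' (Hz); an alternative adaptation measure used for within-type
#' comparisons.
#'
#' @param if_values instantaneous frequencies (Hz).
#' @return Drop in Hz (`NA` for fewer than 2 values).
#' @export
max_freq_adaptation_hz <- function(if_values) {
  if (length(if_values) < 2) return(NA_real_)
  mean(head(if_values, 2)) - min(if_values)
}

#' Detect a post-stimulus plateau potential
#'
#' A plateau holds the membrane well above rest after the current step ends,
#' interrupting adaptation; such responses are excluded from kinetics
#' summaries.
#'
#' @param voltage,time sweep samples (mV, s).
#' @param stim_offset end of the current step (s).
#' @param rmp resting membrane potential (mV).
#' @param criterion_mv depolarization above `rmp` that counts as a plateau.
#' @param window_ms averaging window after the offset (ms).
#' @return Logical.
#' @export
detect_plateau <- function(voltage, time, stim_offset, rmp,
                           criterion_mv = 20, window_ms = 100) {
  w <- which(time >= stim_offset & time <= stim_offset + window_ms / 1000)
  if (length(w) == 0) return(FALSE)
  mean(voltage[w]) > rmp + criterion_mv
}

#' Classify the curvature of AP broadening
#'
#' Fits a parabola to the normalized half-width against spike index; the
#' sign of its quadratic coefficient separates accelerating (positive
#' curvature) from saturating (negative curvature) broadening. Only
#' negative-curvature trains are conventionally entered into
#' single-exponential broadening fits.
#'
#' @param half_widths per-spike half-widths (ms), at least 4.
#' @param tol absolute quadratic coefficient below which the series counts
#'   as flat.
#' @return `"positive"`, `"negative"`, `"flat"`, or `NA` for < 4 spikes.
#' @export
classify_broadening_curvature <- function(half_widths, tol = 1e-3) {
  ok <- is.finite(half_widths)
  if (sum(ok) < 4) return(NA_character_)
  y <- half_widths[ok] / half_widths[ok][1]
  i <- seq_along(half_widths)[ok]
  cf <- coef(lm(y ~ i + I(i^2)))[[3]]
  if (abs(cf) < tol) "flat" else if (cf > 0) "positive" else "negative"
}
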