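#' Detect action potentials in a voltage trace
#'
#' The spike threshold is defined as the inflection of the AP upstroke: the
#' first sample at which the smoothed voltage derivative crosses
#' `dvdt_criterion` before the peak. A short boxcar smooths the derivative so
#' recording noise does not trigger detection; a refractory separation
#' suppresses double counts.
#'
#' @param voltage voltage samples (mV).
#' @param time time grid (s), uniform.
#' @param dvdt_criterion threshold-crossing slope (mV/ms).
#' @param refractory_ms minimum separation between detected onsets (ms).
#' @param smooth_ms boxcar width used for the detection derivative (ms).
#' @param min_rise minimum rise (mV) above onset within `rise_window_ms`
#'   for a crossing to count as a spike; rejects slow depolarizing ramps
#'   whose noisy derivative grazes the criterion.
#' @param rise_window_ms window for the `min_rise` check (ms).
#' @return Integer vector of onset (threshold) sample indices.
#' @export
detect_aps <- function(voltage, time, dvdt_criterion = 10,
                       refractory_ms = 1, smooth_ms = 0.2, min_rise = 15,
                       rise_window_ms = 1) {
  check_positive(dvdt_criterion, "dvdt_criterion")
  stopifnot(length(voltage) == length(time), length(voltage) >= 3)
  dt_ms <- (time[2] - time[1]) * 1000
  k <- max(1L, round(smooth_ms / dt_ms))
  vs <- if (k > 1) stats::filter(voltage, rep(1 / k, k), sides = 2) else voltage
  vs[is.na(vs)] <- voltage[is.na(vs)]
  dvdt <- c(diff(vs) / dt_ms, 0)

  above <- dvdt >= dvdt_criterion
  onsets <- which(above & !c(FALSE, above[-length(above)]))
  if (length(onsets) == 0) return(integer(0))

  # confirm each crossing reaches a real spike and enforce refractoriness
  keep <- integer(0)
  last <- -Inf
  horizon <- round(rise_window_ms / dt_ms)
  dvdt_raw <- c(diff(voltage) / dt_ms, 0)
  for (i in onsets) {
    if ((i - last) * dt_ms < refractory_ms) next
    w <- i:min(i + horizon, length(voltage))
    if (max(voltage[w]) - voltage[i] >= min_rise) {
      # refine against the raw derivative: smoothing can fire a sample or
      # two before the true inflection
      fw <- i:min(i + 2 * k, length(voltage) - 1)
      hit <- fw[dvdt_raw[fw] >= dvdt_criterion]
      keep <- c(keep, if (length(hit) > 0) hit[1] else i)
      last <- i
    }
  }
  keep
}

#' Waveform metrics of one detected AP
#'
#' Computes the standard single-spike measurements, all referenced to the
#' detected threshold: amplitude (threshold to peak), half-width at
#' half-maximal amplitude (linear interpolation at the crossings), AHP
#' (trough after the peak minus threshold, negative by convention) and the
#' extreme rise/fall slopes within the event.
#'
#' @param voltage,time as in [detect_aps()].
#' @param onset onset sample index of this AP.
#' @param next_onset onset of the following AP (bounds the search windows),
#'   or `NA`.
#' @param peak_window_ms maximum look-ahead for the peak (ms).
#' @param ahp_window_ms maximum look-ahead for the AHP trough (ms).
#' @return One-row tibble: `threshold_time_s`, `threshold_v`, `peak_v`,
#'   `amplitude`, `half_width_ms`, `ahp`, `max_rise`, `max_fall`, `reliable`.
#' @export
ap_waveform_metrics <- function(voltage, time, onset, next_onset = NA,
                                peak_window_ms = 15, ahp_window_ms = 50) {
  n <- length(voltage)
  stopifnot(onset >= 1, onset <= n)
  dt_ms <- (time[2] - time[1]) * 1000
  lim <- if (is.na(next_onset)) n else min(next_onset - 1L, n)
  pk_end <- min(onset + round(peak_window_ms / dt_ms), lim)
  wpk <- onset:pk_end
  ipk <- wpk[which.max(voltage[wpk])]

  thr_v <- voltage[onset]
  peak_v <- voltage[ipk]
  amp <- peak_v - thr_v
  reliable <- ipk < pk_end && amp > 0

  half <- thr_v + amp / 2
  t_up <- cross_time(voltage, time, onset, ipk, half, rising = TRUE)
  tr_end <- min(ipk + round(ahp_window_ms / dt_ms), lim)
  t_dn <- cross_time(voltage, time, ipk, tr_end, half, rising = FALSE)
  hw <- if (is.na(t_up) || is.na(t_dn)) NA_real_ else (t_dn - t_up) * 1000

  wtr <- ipk:tr_end
  itr <- wtr[which.min(voltage[wtr])]
  ahp <- voltage[itr] - thr_v

  dvdt <- diff(voltage) / dt_ms
  max_rise <- if (ipk > onset) max(dvdt[onset:(ipk - 1)]) else NA_real_
  max_fall <- if (itr > ipk) min(dvdt[ipk:(itr - 1)]) else NA_real_

  tibble::tibble(
    threshold_time_s = time[onset], threshold_v = thr_v, peak_v = peak_v,
    amplitude = amp, half_width_ms = hw, ahp = ahp,
    max_rise = max_rise, max_fall = max_fall, reliable = reliable
  )
}

# linearly interpolated time of the first crossing of `level` in [i1, i2]
cross_time <- function(voltage, time, i1, i2, level, rising = TRUE) {
  if (i2 <= i1) return(NA_real_)
  v <- voltage[i1:i2]
  hit <- if (rising) which(v[-1] >= level & v[-length(v)] < level) else
    which(v[-1] <= level & v[-length(v)] > level)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  frac <- (level - v[i]) / (v[i + 1] - v[i])
  time[i1 + i - 1] + frac * (time[2] - time[1])
}

# detect + measure every AP in a sweep; tibble with one row per AP
ap_table <- function(voltage, time, dvdt_criterion = 10, ...) {
  on <- detect_aps(voltage, time, dvdt_criterion, ...)
  if (length(on) == 0) {
    return(tibble::tibble(
      threshold_time_s = numeric(0), threshold_v = numeric(0),
      peak_v = numeric(0), amplitude = numeric(0),
      half_width_ms = numeric(0), ahp = numeric(0),
      max_rise = numeric(0), max_fall = numeric(0), reliable = logical(0)
    ))
  }
  nxt <- c(on[-1], NA)
  purrr::map2_dfr(on, nxt, function(i, j) {
    ap_waveform_metrics(voltage, time, i, j)
  })
}
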