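#' Extract the 12 intrinsic electrical properties of one cell
#'
#' Runs the full single-cell measurement chain on a [trace_set()]: passive
#' properties from the I-V relation (input resistance, resting potential,
#' sag, membrane time constant and derived capacitance), single-spike
#' waveform metrics of the first AP on the criterion sweep, and the
#' adaptation ratios of frequency and amplitude over the criterion train.
#' Undefined quantities (e.g. no suprathreshold sweep) are returned as `NA`,
#' never imputed.
#'
#' @param ts a [trace_set()].
#' @param dvdt_criterion AP detection criterion (mV/ms).
#' @param criterion_policy criterion-sweep policy, see
#'   [select_criterion_sweep()].
#' @param freq_first_k,freq_last_k averaging spans of the frequency
#'   adaptation ratio.
#' @return One-row tibble: `cell_id`, the 12 canonical features (see
#'   [ephys_feature_names()]), then auxiliary columns `tau_m_ms`,
#'   `ap_duration_adaptation`, `max_freq_adaptation_Hz`,
#'   `criterion_current_pA`, `n_criterion_spikes`, `plateau`.
#' @examples
#' arch <- striatal_archetypes()$MSN
#' ts <- render_recording(arch, make_protocol(sampling_rate = 10000), seed = 2)
#' extract_feature_vector(ts)[, 1:6]
#' @export
extract_feature_vector <- function(ts, dvdt_criterion = 10,
                                   criterion_policy = "plus50",
                                   freq_first_k = 2, freq_last_k = 3) {
  stopifnot(inherits(ts, "trace_set"))
  iv <- fit_iv_passive(ts)
  sag <- measure_sag(ts)
  tau <- measure_tau_cm(ts, iv$r_in_MOhm)
  thr <- current_threshold(ts, dvdt_criterion)

  out <- tibble::tibble(
    cell_id = ts$cell_id,
    cm_pF = tau$cm_pF, r_in_MOhm = iv$r_in_MOhm, rmp_mV = iv$rmp_mV,
    sag_mV = sag, ahp_mV = NA_real_, ap_amplitude_mV = NA_real_,
    ap_freq_adaptation = NA_real_, ap_amp_adaptation = NA_real_,
    ap_half_width_ms = NA_real_, max_fall_mV_per_ms = NA_real_,
    max_rise_mV_per_ms = NA_real_, current_threshold_pA = thr,
    tau_m_ms = tau$tau_m_ms, ap_duration_adaptation = NA_real_,
    max_freq_adaptation_Hz = NA_real_, criterion_current_pA = NA_real_,
    n_criterion_spikes = 0L, plateau = NA
  )
  if (is.na(thr)) return(out)

  crit <- select_criterion_sweep(ts, criterion_policy, dvdt_criterion)
  if (is.na(crit)) return(out)
  w <- step_window(ts)
  v <- get_sweep(ts, crit)
  aps <- ap_table(v[w], ts$time[w], dvdt_criterion)
  out$criterion_current_pA <- crit
  out$n_criterion_spikes <- nrow(aps)
  out$plateau <- detect_plateau(v, ts$time, ts$step_duration,
                                rmp = iv$rmp_mV)
  if (nrow(aps) == 0) return(out)

  out$ahp_mV <- aps$ahp[1]
  out$ap_amplitude_mV <- aps$amplitude[1]
  out$ap_half_width_ms <- aps$half_width_ms[1]
  out$max_rise_mV_per_ms <- aps$max_rise[1]
  out$max_fall_mV_per_ms <- aps$max_fall[1]

  if (nrow(aps) >= 2) {
    ifs <- instantaneous_frequency_series(aps$threshold_time_s)
    out$ap_freq_adaptation <- adaptation_ratio(
      ifs$if_Hz, "frequency", freq_first_k, freq_last_k)
    out$max_freq_adaptation_Hz <- max_freq_adaptation_hz(ifs$if_Hz)
    out$ap_amp_adaptation <- adaptation_ratio(aps$amplitude, "amplitude")
    out$ap_duration_adaptation <- adaptation_ratio(aps$half_width_ms,
                                                   "duration")
  }
  out
}

#' Extract features for a cohort of cells
#'
#' Applies [qc_filter()] then [extract_feature_vector()] to every cell.
#' QC-failed cells are kept in the table with their exclusion reasons and
#' `NA` features, never silently dropped.
#'
#' @param cells list of [trace_set()] objects.
#' @param ... passed to [extract_feature_vector()].
#' @return Tibble with one row per cell: `cell_id`, `qc_pass`,
#'   `qc_reasons`, then the feature columns.
#' @export
extract_features <- function(cells, ...) {
  purrr::map_dfr(cells, function(ts) {
    qc <- qc_filter(ts)
    if (!qc$pass) {
      return(tibble::tibble(cell_id = ts$cell_id, qc_pass = FALSE,
                            qc_reasons = qc$reasons))
    }
    dplyr::bind_cols(
      tibble::tibble(cell_id = ts$cell_id, qc_pass = TRUE, qc_reasons = ""),
      extract_feature_vector(ts, ...)[, -1]
    )
  })
}

#' Per-cell adaptation kinetics report
#'
#' Quantifies the adaptation time courses on the criterion sweep of one
#' cell: the adaptation ratios, bi-exponential time constants of the
#' instantaneous-frequency decay, amplitude-decay time constants, the
#' curvature class of AP broadening (with a single-exponential broadening
#' fit for negative-curvature trains), and the plateau flag. Sweeps with a
#' plateau are reported but their fits are marked excluded.
#'
#' @param ts a [trace_set()].
#' @param dvdt_criterion,criterion_policy as in [extract_feature_vector()].
#' @param min_spikes minimum spikes required for exponential fits.
#' @return One-row tibble.
#' @export
adaptation_report <- function(ts, dvdt_criterion = 10,
                              criterion_policy = "plus50", min_spikes = 8) {
  stopifnot(inherits(ts, "trace_set"))
  # resting reference for plateau detection: the I-V intercept when
  # hyperpolarizing sweeps exist, otherwise the pre-step baseline
  rmp <- tryCatch(fit_iv_passive(ts)$rmp_mV, error = function(e) {
    mean(ts$voltages[ts$time < 0, 1])
  })
  crit <- select_criterion_sweep(ts, criterion_policy, dvdt_criterion)
  base <- tibble::tibble(
    cell_id = ts$cell_id, criterion_current_pA = crit, n_spikes = 0L,
    plateau = NA, excluded = NA,
    freq_adaptation = NA_real_, amp_adaptation = NA_real_,
    duration_adaptation = NA_real_,
    if_tau_fast_s = NA_real_, if_tau_slow_s = NA_real_,
    if_amp_fast = NA_real_, if_amp_slow = NA_real_,
    amp_tau_fast_s = NA_real_, amp_tau_slow_s = NA_real_,
    broadening_curvature = NA_character_, broadening_tau_s = NA_real_
  )
  if (is.na(crit)) return(base)
  w <- step_window(ts)
  v <- get_sweep(ts, crit)
  aps <- ap_table(v[w], ts$time[w], dvdt_criterion)
  base$n_spikes <- nrow(aps)
  base$plateau <- detect_plateau(v, ts$time, ts$step_duration, rmp)
  base$excluded <- base$plateau
  if (nrow(aps) < 3) return(base)

  ifs <- instantaneous_frequency_series(aps$threshold_time_s)
  base$freq_adaptation <- adaptation_ratio(ifs$if_Hz, "frequency")
  base$amp_adaptation <- adaptation_ratio(aps$amplitude, "amplitude")
  base$duration_adaptation <- adaptation_ratio(aps$half_width_ms, "duration")
  base$broadening_curvature <- classify_broadening_curvature(aps$half_width_ms)

  if (nrow(aps) >= min_spikes && !base$plateau) {
    ff <- fit_adaptation_exponential(ifs$t_s, ifs$if_norm, 2)
    if (ff$converged) {
      base$if_tau_fast_s <- ff$taus[1]; base$if_tau_slow_s <- ff$taus[2]
      base$if_amp_fast <- ff$amplitudes[1]; base$if_amp_slow <- ff$amplitudes[2]
    }
    t_sp <- aps$threshold_time_s - aps$threshold_time_s[1]
    fa <- fit_adaptation_exponential(t_sp, aps$amplitude / aps$amplitude[1], 2)
    if (fa$converged) {
      base$amp_tau_fast_s <- fa$taus[1]; base$amp_tau_slow_s <- fa$taus[2]
    }
    # broadening grows toward a ceiling; fit the remaining gap, which decays
    if (identical(base$broadening_curvature, "negative")) {
      wnorm <- aps$half_width_ms / aps$half_width_ms[1]
      gap <- max(wnorm) - wnorm
      fb <- fit_adaptation_exponential(t_sp, gap + 1e-3, 1)
      if (fb$converged) base$broadening_tau_s <- fb$taus[1]
    }
  }
  base
}
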