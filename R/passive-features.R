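#' Input resistance and resting potential from the I-V relation
#'
#' Fits a least-squares line through the (current, steady-state voltage)
#' points of the non-depolarizing sweeps; the slope is the input resistance
#' (MOhm) and the intercept the resting membrane potential (mV). Steady
#' state is the mean over the final `ss_window` seconds of the step. Sweeps
#' driven below `v_floor` are excluded to stay within the linear range.
#'
#' @param ts a [trace_set()].
#' @param ss_window steady-state averaging window (s).
#' @param v_floor most hyperpolarized steady state admitted to the fit (mV).
#' @return One-row tibble `r_in_MOhm`, `rmp_mV`, `n_sweeps`.
#' @export
fit_iv_passive <- function(ts, ss_window = 0.1, v_floor = -110) {
  stopifnot(inherits(ts, "trace_set"))
  sub <- which(ts$currents <= 0)
  ss <- vapply(sub, function(j) steady_state(ts, j, ss_window), numeric(1))
  ok <- ss >= v_floor
  if (sum(ok) < 2) {
    abort("at least two usable non-depolarizing sweeps are required.")
  }
  fit <- lm(ss[ok] ~ ts$currents[sub][ok])
  tibble::tibble(
    r_in_MOhm = unname(coef(fit)[2]) * 1000, # mV/pA -> MOhm
    rmp_mV = unname(coef(fit)[1]),
    n_sweeps = sum(ok)
  )
}

steady_state <- function(ts, j, ss_window = 0.1) {
  w <- which(ts$time >= ts$step_duration - ss_window & ts$time < ts$step_duration)
  mean(ts$voltages[w, j])
}

#' Sag amplitude near a target hyperpolarization
#'
#' On the hyperpolarizing sweep whose steady state is nearest `target_v`,
#' the sag is the (non-negative) difference between the steady-state voltage
#' and the early trough. The trace is lightly smoothed before the trough
#' search so noise does not inflate the minimum.
#'
#' @param ts a [trace_set()].
#' @param target_v target steady-state voltage (mV).
#' @param trough_window search window for the trough from step onset (s).
#' @param smooth_ms boxcar smoothing before the trough search (ms).
#' @return Sag amplitude in mV, or `NA` if no hyperpolarizing sweep exists.
#' @export
measure_sag <- function(ts, target_v = -100, trough_window = 0.3,
                        smooth_ms = 1) {
  stopifnot(inherits(ts, "trace_set"))
  hyp <- which(ts$currents < 0)
  if (length(hyp) == 0) return(NA_real_)
  ss <- vapply(hyp, function(j) steady_state(ts, j), numeric(1))
  j <- hyp[which.min(abs(ss - target_v))]
  dt_ms <- (ts$time[2] - ts$time[1]) * 1000
  k <- max(1L, round(smooth_ms / dt_ms))
  v <- ts$voltages[, j]
  vs <- if (k > 1) stats::filter(v, rep(1 / k, k), sides = 2) else v
  w <- which(ts$time >= 0 & ts$time <= trough_window)
  trough <- min(vs[w], na.rm = TRUE)
  max(0, steady_state(ts, j) - trough)
}

#' Membrane time constant and capacitance
#'
#' Fits the charging phase of the smallest hyperpolarizing step and derives
#' the capacitance as `tau_m / r_in` (a convention that makes the synthetic
#' ground truth checkable; amplifier readings of capacitance are not
#' available offline). Because hyperpolarizing steps carry a sag component
#' whose relaxation contaminates a plain exponential, the fit includes an
#' optional sag term (`(1 - e^(-t/tau)) + s * (e^(-t/tau_sag) - e^(-t/tau))`)
#' and falls back to the single exponential when that fit fails.
#'
#' @param ts a [trace_set()].
#' @param r_in input resistance (MOhm), e.g. from [fit_iv_passive()].
#' @param fit_window portion of the step used for the fit (s).
#' @return One-row tibble `tau_m_ms`, `cm_pF` (both `NA` if no usable sweep
#'   or the fit fails).
#' @export
measure_tau_cm <- function(ts, r_in, fit_window = 0.15) {
  stopifnot(inherits(ts, "trace_set"))
  hyp <- which(ts$currents < 0)
  und <- tibble::tibble(tau_m_ms = NA_real_, cm_pF = NA_real_)
  if (length(hyp) == 0) return(und)
  # hyperpolarizing sweep with a well-resolved but clearly subthreshold
  # deflection (nearest -15 mV): good signal-to-noise without leaving the
  # linear range
  defl <- vapply(hyp, function(j) {
    steady_state(ts, j) - mean(ts$voltages[ts$time < 0, j])
  }, numeric(1))
  j <- hyp[which.min(abs(defl + 15))]
  if (abs(defl[which.min(abs(defl + 15))]) < 1) return(und)
  w <- which(ts$time >= 0 & ts$time <= fit_window)
  t_ms <- ts$time[w] * 1000
  v <- ts$voltages[w, j]
  v0 <- mean(ts$voltages[ts$time < 0, j])
  dv <- steady_state(ts, j) - v0
  if (abs(dv) < 1) return(und) # essentially flat
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ v0f + a * ((1 - exp(-t_ms / tau)) +
                       s * (exp(-t_ms / tsag) - exp(-t_ms / tau))),
      start = list(v0f = v0, a = dv, tau = 15, s = 0.05, tsag = 50),
      lower = c(-Inf, -Inf, 0.1, 0, 1),
      control = minpack.lm::nls.lm.control(maxiter = 300)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ v0f + a * (1 - exp(-t_ms / tau)),
        start = list(v0f = v0, a = dv, tau = 15),
        lower = c(-Inf, -Inf, 0.1),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) return(und)
  tau <- unname(coef(fit)[["tau"]])
  tibble::tibble(tau_m_ms = tau, cm_pF = tau / r_in * 1000)
}

#' Current threshold (rheobase)
#'
#' Smallest depolarizing sweep current that evokes at least one detected AP.
#'
#' @param ts a [trace_set()].
#' @param dvdt_criterion detection criterion (mV/ms), see [detect_aps()].
#' @return Current in pA, or `NA` when no sweep spikes.
#' @export
current_threshold <- function(ts, dvdt_criterion = 10) {
  counts <- sweep_spike_counts(ts, dvdt_criterion)
  dep <- which(ts$currents > 0)
  hit <- dep[counts[dep] >= 1]
  if (length(hit) == 0) return(NA_real_)
  min(ts$currents[hit])
}

# spike count of every sweep (detection restricted to the step window)
sweep_spike_counts <- function(ts, dvdt_criterion = 10) {
  w <- step_window(ts)
  vapply(seq_along(ts$currents), function(j) {
    if (ts$currents[j] <= 0) return(0L)
    length(detect_aps(ts$voltages[w, j], ts$time[w], dvdt_criterion))
  }, integer(1))
}
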