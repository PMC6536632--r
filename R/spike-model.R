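#' Parameters of the adapting spike-train model
#'
#' The instantaneous firing rate during a sustained depolarization is modelled
#' as a bi-exponential decay from an initial rate toward a steady rate,
#'
#'   IF(t) = f_end + (f0 - f_end) * (w_fast * exp(-t / tau_fast) +
#'                                   (1 - w_fast) * exp(-t / tau_slow)),
#'
#' with the current dependence f0(I) = gain * (I - rheobase) above rheobase.
#' Spike times are emitted by integrating IF(t). Peak amplitude and
#' half-width of successive spikes relax along the same bi-exponential toward
#' `amp_ratio_end` / `width_ratio_end` of their initial values, emulating the
#' amplitude decay and spike broadening seen during adaptation in striatal
#' neurons.
#'
#' @param f0 initial instantaneous frequency at the criterion current (Hz).
#' @param f_end steady-state frequency late in the train (Hz), `0 < f_end <= f0`.
#' @param w_fast weight of the fast adaptation component in `[0, 1]`.
#' @param tau_fast,tau_slow fast/slow adaptation time constants (s),
#'   `tau_fast <= tau_slow`.
#' @param amp0 amplitude of the first spike, threshold to peak (mV).
#' @param amp_ratio_end asymptotic last/first amplitude ratio.
#' @param width0 half-width of the first spike (ms).
#' @param width_ratio_end asymptotic last/first half-width ratio.
#' @param rheobase smallest current that fires the cell (pA).
#' @param gain slope of the frequency-current relation (Hz/pA).
#' @return A `spike_model_params` list.
#' @export
spike_model_params <- function(f0 = 50, f_end = 25, w_fast = 0.4,
                               tau_fast = 0.05, tau_slow = 0.5,
                               amp0 = 85, amp_ratio_end = 0.8,
                               width0 = 2, width_ratio_end = 1.5,
                               rheobase = 40, gain = 1) {
  check_positive(f0, "f0"); check_positive(f_end, "f_end")
  check_number(w_fast, "w_fast", lower = 0, upper = 1)
  check_positive(tau_fast, "tau_fast"); check_positive(tau_slow, "tau_slow")
  check_positive(amp0, "amp0"); check_positive(amp_ratio_end, "amp_ratio_end")
  check_positive(width0, "width0"); check_positive(width_ratio_end, "width_ratio_end")
  check_number(rheobase, "rheobase"); check_positive(gain, "gain")
  if (f_end > f0) abort("`f_end` must not exceed `f0`.")
  if (tau_fast > tau_slow) abort("`tau_fast` must not exceed `tau_slow`.")
  structure(
    list(f0 = f0, f_end = f_end, w_fast = w_fast,
         tau_fast = tau_fast, tau_slow = tau_slow,
         amp0 = amp0, amp_ratio_end = amp_ratio_end,
         width0 = width0, width_ratio_end = width_ratio_end,
         rheobase = rheobase, gain = gain),
    class = "spike_model_params"
  )
}

# normalized bi-exponential relaxation h(0) = 1, h(Inf) = 0
adaptation_kernel <- function(t, params) {
  params$w_fast * exp(-t / params$tau_fast) +
    (1 - params$w_fast) * exp(-t / params$tau_slow)
}

# closed-form instantaneous rate at time t (s) for a given injected current.
# current = NULL evaluates the model at its nominal f0.
spike_rate <- function(t, params, current = NULL) {
  f0 <- if (is.null(current)) params$f0 else
    params$gain * (current - params$rheobase)
  if (f0 <= 0) return(rep(0, length(t)))
  # the end/start ratio is a property of the cell, preserved across currents
  f_end <- f0 * params$f_end / params$f0
  f_end + (f0 - f_end) * adaptation_kernel(t, params)
}

#' Generate spike times from the adapting rate model
#'
#' Spikes are emitted by integrating the instantaneous rate: after a short
#' fixed onset latency, successive spikes are placed so that the integral of
#' IF(t) between them equals one. With `jitter_cv = 0` the train is fully
#' deterministic; otherwise each interspike interval is multiplied by
#' log-normal noise with the given coefficient of variation (which keeps the
#' train ordered).
#'
#' @param params a [spike_model_params()] object.
#' @param current injected current (pA); `NULL` uses the nominal `f0`.
#' @param duration length of the current step (s).
#' @param seed integer seed (only used when `jitter_cv > 0`).
#' @param jitter_cv coefficient of variation of multiplicative ISI noise.
#' @param onset_latency delay from step onset to the first spike (s).
#' @return Numeric vector of strictly increasing spike times in
#'   `[0, duration]`; empty when the current is below rheobase.
#' @examples
#' p <- spike_model_params(f0 = 50, f_end = 50) # no adaptation
#' length(adapting_spike_times(p, duration = 1, jitter_cv = 0))
#' @export
adapting_spike_times <- function(params, current = NULL, duration = 1,
                                 seed = NULL, jitter_cv = 0.05,
                                 onset_latency = 0.003) {
  stopifnot(inherits(params, "spike_model_params"))
  check_positive(duration, "duration")
  check_number(jitter_cv, "jitter_cv", lower = 0)
  if (!is.null(current) && current < params$rheobase) {
    return(numeric(0))
  }

  # integrate the rate on a fine grid and invert the cumulative intensity
  dt <- 1e-4
  tg <- seq(0, duration, by = dt)
  rate <- spike_rate(tg, params, current)
  cum <- cumsum(rate) * dt # expected spike count since onset

  t0 <- onset_latency
  if (t0 >= duration) return(numeric(0))
  times <- t0
  i0 <- findInterval(t0, tg)
  target <- cum[i0] + 1
  repeat {
    i <- findInterval(target, cum)
    if (i >= length(tg)) break
    # linear interpolation inside the grid cell
    tt <- tg[i] + dt * (target - cum[i]) / max(cum[i + 1] - cum[i], 1e-12)
    if (tt > duration) break
    times <- c(times, tt)
    target <- target + 1
  }

  if (jitter_cv > 0) {
    if (!is.null(seed)) {
      times <- with_seed(seed, jitter_isis(times, jitter_cv, t0, duration))
    } else {
      times <- jitter_isis(times, jitter_cv, t0, duration)
    }
  }
  times
}

jitter_isis <- function(times, cv, t0, duration) {
  if (length(times) < 2) return(times)
  isis <- diff(times)
  sl <- sqrt(log(1 + cv^2))
  isis <- isis * exp(rnorm(length(isis), -sl^2 / 2, sl))
  out <- t0 + cumsum(c(0, isis))
  out[out <= duration]
}
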